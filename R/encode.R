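#' Encode a pair of strings over their joint reduced alphabet
#'
#' Characters absent from both strings play no role in the distance, so the
#' working alphabet is restricted to the symbols actually present.  Codes are
#' integers in `[0, s)` assigned in first-occurrence order scanning `a` then
#' `b`, which makes the encoding deterministic; `s <= m + n` always holds.
#'
#' @param a,b character strings (either may be empty).
#' @return An object of class `encoded_pair` with fields `a`, `b` (integer
#'   code vectors), `a_chars`, `b_chars` (the original characters), `m`, `n`
#'   (lengths), `s` (alphabet size), and `code_map` (character vector such
#'   that `code_map[code + 1]` is the original symbol).
#' @examples
#' p <- encode_pair("dafac", "fdbbec")
#' p$s        # 6 distinct symbols
#' @export
encode_pair <- function(a, b) {
  ca <- split_chars(a)
  cb <- split_chars(b)
  code_map <- unique(c(ca, cb))
  structure(list(
    a = match(ca, code_map) - 1L,
    b = match(cb, code_map) - 1L,
    a_chars = ca, b_chars = cb,
    m = length(ca), n = length(cb),
    s = length(code_map), code_map = code_map
  ), class = "encoded_pair")
}

split_chars <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("sequences must be single, non-NA character strings", call. = FALSE)
  if (nchar(x) == 0L) character(0) else strsplit(x, "", fixed = TRUE)[[1L]]
}

#' Decode an integer code vector of an encoded pair back to a string
#' @param codes integer codes in `[0, s)`.
#' @param pair an [encode_pair()] object supplying the code map.
#' @return A character string.
#' @export
decode_codes <- function(codes, pair) {
  if (length(codes) == 0L) return("")
  paste(pair$code_map[codes + 1L], collapse = "")
}

as_encoded_pair <- function(a, b = NULL) {
  if (inherits(a, "encoded_pair")) {
    if (!is.null(b)) stop("'b' must be omitted when 'a' is an encoded_pair",
                          call. = FALSE)
    return(a)
  }
  encode_pair(a, b)
}

#' @export
print.encoded_pair <- function(x, ...) {
  cat(sprintf("<encoded_pair> m=%d n=%d s=%d\n", x$m, x$n, x$s))
  invisible(x)
}
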