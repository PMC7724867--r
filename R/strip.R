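#' Cache-blocked linear-space DL distance (Strip_DL2)
#'
#' Computes the same refined recurrence as [ls_dl2()] but processes the
#' matrix in `ceiling(n / q)` vertical strips of `q` columns each (the last
#' strip is narrower when `q` does not divide `n`).  Each strip is filled
#' with the LS_DL2 inner loop over row arrays restricted to the strip's
#' columns; state crosses strip boundaries through three column arrays:
#' `C[i] = H[i, j_e]` (rightmost column of the strip processed so far),
#' `C1[i] = H[i, j_e - 1]`, and `FC[i] = H[i-2, l-1]` where `l` is the last
#' column so far with `B[l] == A[i]` (`maxVal` where undefined), plus a
#' length-`s` record of each symbol's last column.  Narrow strips keep the
#' row working set inside cache, which is the point of the blocking; the
#' distance is identical to [ls_dl2()] for every `q`.
#'
#' @inheritParams ls_dl2
#' @param q strip width, an integer `>= 1`.  `q >= n` degenerates to a
#'   single strip.
#' @return A `dl_result` with column-oriented arrays `C`, `C1`, `FC`
#'   (indices `i = 0..m`, value for `i` in slot `i + 1`) and the strip width
#'   `q`.
#' @examples
#' strip_dl2("dafac", "fdbbec", q = 2)$distance   # 5
#' @export
strip_dl2 <- function(a, b = NULL, costs = dl_costs(), q = 1L,
                      maxVal = NULL) {
  pair <- as_encoded_pair(a, b)
  costs <- as_dl_costs(costs)
  stop_unless_valid(costs, "refined")
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 1)
    stop("strip width 'q' must be an integer >= 1", call. = FALSE)
  q <- as.integer(q)
  if (is.null(maxVal)) maxVal <- default_maxval(pair, costs)
  check_maxval(maxVal, pair, costs)
  raw <- cpp_strip_dl2(pair$a, pair$b, pair$s, costs$S, costs$I, costs$D,
                       costs$T, q, maxVal)
  structure(list(distance = raw$distance,
                 C = drop_sentinel(raw$C), C1 = drop_sentinel(raw$C1),
                 FC = drop_sentinel(raw$FC),
                 maxVal = maxVal, m = pair$m, n = pair$n, q = q,
                 dp_elements = raw$dp_elements, swapped = FALSE),
            class = "dl_result")
}

#' Choose a strip width from a cache-capacity model
#'
#' Models the strip working set as the three row arrays local to a strip,
#' `3 * (q + 3)` elements, plus the three length-`(m + 2)` column arrays,
#' and returns the largest `q >= 1` whose working set fits in `cache_bytes`
#' (capped at `n` when `n` is supplied).  The model is deliberately simple;
#' callers that know better can pass an explicit `q` to [strip_dl2()].
#'
#' @param m number of rows (length of the first string).
#' @param cache_bytes cache capacity in bytes.
#' @param element_bytes bytes per DP element (8 for double precision).
#' @param n optional number of columns used as an upper bound for `q`.
#' @return An integer strip width in `[1, n]`.
#' @examples
#' choose_strip_width(1000, cache_bytes = 10 * 2^20, element_bytes = 4)
#' @export
choose_strip_width <- function(m, cache_bytes, element_bytes = 8, n = Inf) {
  stopifnot(m >= 0, cache_bytes > 0, element_bytes > 0)
  q <- floor((cache_bytes / element_bytes - 3 * (m + 2)) / 3) - 3
  q <- max(1, q)
  if (is.finite(n)) q <- min(q, max(1, n))
  as.integer(q)
}
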