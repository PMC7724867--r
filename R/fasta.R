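#' Read the first record of a FASTA file
#'
#' Accepts the standard dialect: a `>` header line (identifier plus optional
#' description, both ignored) followed by one or more sequence lines, which
#' are concatenated with surrounding whitespace stripped and case preserved.
#' Only the first record is read; later records are ignored.
#'
#' @param path path to a readable FASTA file.
#' @return The first record's sequence as a character string.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x some description", "DAF", "AC"), f)
#' read_fasta_first_record(f)   # "DAFAC"
#' @export
read_fasta_first_record <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    stop("FASTA file is empty: ", path, call. = FALSE)
  if (!startsWith(lines[1L], ">"))
    stop("malformed FASTA header: first line must start with '>'",
         call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs))
    stop("FASTA file contains no records: ", path, call. = FALSE)
  gsub("[[:space:]]", "", as.character(seqs[[1L]]))
}
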