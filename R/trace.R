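#' Construct an edit trace
#'
#' A trace for strings `A` (length `m`) and `B` (length `n`) is a set of
#' lines `(u, v)` connecting position `u` of `A` to position `v` of `B`,
#' with all `u` distinct and all `v` distinct.  A line is *balanced* when
#' `A[u] == B[v]`; two lines `(u1, v1)`, `(u2, v2)` *cross* when `u1 < u2`
#' and `v1 > v2`.  Unattached `A` positions are deletions, unattached `B`
#' positions insertions, unbalanced lines substitutions, and a crossing pair
#' of balanced lines a transposition (with the characters between them
#' deleted/inserted).
#'
#' @param u,v integer vectors of equal length: line endpoints (1-based).
#' @param m,n the string lengths the trace refers to.
#' @return An object of class `dl_trace`.
#' @examples
#' dl_trace(c(1, 3, 4, 5), c(2, 1, 3, 6), m = 5, n = 6)
#' @export
dl_trace <- function(u, v, m, n) {
  if (length(u) != length(v))
    stop("'u' and 'v' must have equal length", call. = FALSE)
  structure(list(u = as.integer(u), v = as.integer(v),
                 m = as.integer(m), n = as.integer(n)),
            class = "dl_trace")
}

#' @export
print.dl_trace <- function(x, ...) {
  cat(sprintf("<dl_trace> %d line(s) for strings of length %d and %d\n",
              length(x$u), x$m, x$n))
  if (length(x$u)) {
    ord <- order(x$u)
    cat(paste0("  (", x$u[ord], ",", x$v[ord], ")", collapse = " "), "\n")
  }
  invisible(x)
}

#' Is a set of lines a valid trace?
#'
#' Checks the two defining conditions: every endpoint in bounds
#' (`1 <= u <= m`, `1 <= v <= n`) and no two lines sharing a `u` or a `v`.
#'
#' @param trace a [dl_trace()].
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_trace <- function(trace) {
  stopifnot(inherits(trace, "dl_trace"))
  u <- trace$u; v <- trace$v
  all(u >= 1L) && all(u <= trace$m) &&
    all(v >= 1L) && all(v <= trace$n) &&
    !anyDuplicated(u) && !anyDuplicated(v)
}

#' Classify trace lines as balanced or unbalanced
#'
#' Line `(u, v)` is balanced iff `A[u] == B[v]`.
#'
#' @param trace a valid [dl_trace()].
#' @param pair the [encode_pair()] of the two strings.
#' @return A data frame with columns `u`, `v`, and logical `balanced`.
#' @examples
#' p <- encode_pair("dafac", "fdbbec")
#' tr <- dl_trace(c(1, 3, 4, 5), c(2, 1, 3, 6), p$m, p$n)
#' classify_lines(tr, p)   # (4,3) is the only unbalanced line
#' @export
classify_lines <- function(trace, pair) {
  if (!is_valid_trace(trace)) stop("not a valid trace", call. = FALSE)
  data.frame(u = trace$u, v = trace$v,
             balanced = pair$a[trace$u] == pair$b[trace$v])
}

#' Enumerate crossing line pairs of a trace
#'
#' @param trace a valid [dl_trace()].
#' @return A data frame with one row per unordered crossing pair, columns
#'   `u1`, `v1`, `u2`, `v2` ordered so that `u1 < u2` (hence `v1 > v2`).
#' @export
crossing_pairs <- function(trace) {
  if (!is_valid_trace(trace)) stop("not a valid trace", call. = FALSE)
  u <- trace$u; v <- trace$v
  k <- length(u)
  out <- data.frame(u1 = integer(0), v1 = integer(0),
                    u2 = integer(0), v2 = integer(0))
  if (k < 2L) return(out)
  idx <- utils::combn(k, 2L)
  for (c in seq_len(ncol(idx))) {
    i <- idx[1L, c]; j <- idx[2L, c]
    if (u[i] > u[j]) { tmp <- i; i <- j; j <- tmp }
    if (v[i] > v[j])
      out[nrow(out) + 1L, ] <- c(u[i], v[i], u[j], v[j])
  }
  out
}

#' Convert a trace to an ordered edit script
#'
#' Interprets the trace as edit operations: unattached `A` positions become
#' deletions, unattached `B` positions insertions, unbalanced lines
#' substitutions, non-crossing balanced lines retains (cost 0), and each
#' crossing pair of balanced lines a transposition of `A[u1]` and `A[u2]`
#' (the intervening deletions and insertions appear as their own
#' operations).  Crossing pairs must be disjoint -- no line in two crossings
#' -- and must consist of balanced lines; other crossings have no defined
#' operation reading and are rejected.
#'
#' Operations are ordered left to right by `B` coordinate, with each
#' deletion placed where its `A` character falls relative to the attached
#' positions, so the script reads as a single left-to-right pass.
#'
#' @param trace a valid [dl_trace()].
#' @param pair the [encode_pair()] of the two strings.
#' @param costs a [dl_costs()] model.
#' @return An object of class `dl_edit_script`: a data frame with columns
#'   `op` (`"retain"`, `"substitute"`, `"delete"`, `"insert"`,
#'   `"transpose"`), `u`, `v`, `u2`, `v2` (transpose partners, `NA`
#'   otherwise), `char`, and `cost`, with attribute `total_cost`.
#' @examples
#' p <- encode_pair("dafac", "fdbbec")
#' tr <- dl_trace(c(1, 3, 4, 5), c(2, 1, 3, 6), p$m, p$n)
#' sc <- trace_to_edit_script(tr, p)
#' attr(sc, "total_cost")          # 5
#' apply_edit_script(sc, p)        # "fdbbec"
#' @export
trace_to_edit_script <- function(trace, pair, costs = dl_costs()) {
  if (!is_valid_trace(trace)) stop("not a valid trace", call. = FALSE)
  costs <- as_dl_costs(costs)
  cls <- classify_lines(trace, pair)
  cps <- crossing_pairs(trace)
  if (nrow(cps)) {
    key <- function(u, v) paste(u, v)
    involved <- c(key(cps$u1, cps$v1), key(cps$u2, cps$v2))
    if (anyDuplicated(involved))
      stop("overlapping crossings: a line participates in more than one ",
           "crossing pair", call. = FALSE)
    bal <- stats::setNames(cls$balanced, key(cls$u, cls$v))
    if (!all(bal[involved]))
      stop("crossing pair involving an unbalanced line has no edit ",
           "interpretation", call. = FALSE)
  }
  in_crossing <- if (nrow(cps))
    paste(cls$u, cls$v) %in% c(paste(cps$u1, cps$v1), paste(cps$u2, cps$v2))
  else rep(FALSE, nrow(cls))

  ops <- list()
  add <- function(op, u = NA, v = NA, u2 = NA, v2 = NA, char = "", cost = 0) {
    ops[[length(ops) + 1L]] <<- data.frame(
      op = op, u = u, v = v, u2 = u2, v2 = v2, char = char, cost = cost)
  }
  # attached lines outside crossings
  for (r in seq_len(nrow(cls))) {
    if (in_crossing[r]) next
    u <- cls$u[r]; v <- cls$v[r]
    if (cls$balanced[r]) add("retain", u, v, char = pair$a_chars[u])
    else add("substitute", u, v, char = pair$b_chars[v], cost = costs$S)
  }
  # crossing pairs: one transposition each
  for (r in seq_len(nrow(cps)))
    add("transpose", cps$u1[r], cps$v1[r], cps$u2[r], cps$v2[r],
        char = paste0(pair$a_chars[cps$u1[r]], pair$a_chars[cps$u2[r]]),
        cost = costs$T)
  # unattached positions
  for (u in setdiff(seq_len(pair$m), trace$u))
    add("delete", u = u, char = pair$a_chars[u], cost = costs$D)
  for (v in setdiff(seq_len(pair$n), trace$v))
    add("insert", v = v, char = pair$b_chars[v], cost = costs$I)
  if (!length(ops))
    return(structure(data.frame(op = character(0), u = integer(0),
                                v = integer(0), u2 = integer(0),
                                v2 = integer(0), char = character(0),
                                cost = numeric(0)),
                     total_cost = 0,
                     class = c("dl_edit_script", "data.frame")))
  script <- do.call(rbind, ops)

  # left-to-right ordering: attached ops and inserts sort by v; a deletion
  # at u sorts just after the largest v attached left of u
  sortkey <- numeric(nrow(script))
  for (r in seq_len(nrow(script))) {
    if (script$op[r] == "delete") {
      left_v <- trace$v[trace$u < script$u[r]]
      sortkey[r] <- (if (length(left_v)) max(left_v) else 0) +
        script$u[r] / (pair$m + pair$n + 2)
    } else {
      sortkey[r] <- script$v[r]
    }
  }
  script <- script[order(sortkey), , drop = FALSE]
  rownames(script) <- NULL
  structure(script, total_cost = sum(script$cost), class =
              c("dl_edit_script", "data.frame"))
}

#' Apply an edit script to the first string
#'
#' Reconstructs the target string from the script: every `B` position is
#' produced by exactly one retain (copying the `A` character), substitute or
#' insert (copying the `B` character), or transpose endpoint (copying the
#' swapped `A` characters); deletions consume their `A` positions.  Errors
#' if the script does not cover each position of either string exactly once.
#'
#' @param script a [trace_to_edit_script()] result.
#' @param pair the [encode_pair()] the script was built from.
#' @return The reconstructed string (equal to `B` for a well-formed script).
#' @export
apply_edit_script <- function(script, pair) {
  out <- rep(NA_character_, pair$n)
  used_u <- integer(0)
  place <- function(v, ch) {
    if (v < 1 || v > pair$n || !is.na(out[v]))
      stop("script writes position ", v, " of B more than once or out of ",
           "bounds", call. = FALSE)
    out[v] <<- ch
  }
  for (r in seq_len(nrow(script))) {
    op <- script$op[r]
    if (op == "retain") {
      place(script$v[r], pair$a_chars[script$u[r]])
      used_u <- c(used_u, script$u[r])
    } else if (op == "substitute") {
      place(script$v[r], pair$b_chars[script$v[r]])
      used_u <- c(used_u, script$u[r])
    } else if (op == "insert") {
      place(script$v[r], pair$b_chars[script$v[r]])
    } else if (op == "delete") {
      used_u <- c(used_u, script$u[r])
    } else if (op == "transpose") {
      place(script$v[r], pair$a_chars[script$u[r]])
      place(script$v2[r], pair$a_chars[script$u2[r]])
      used_u <- c(used_u, script$u[r], script$u2[r])
    } else stop("unknown operation '", op, "'", call. = FALSE)
  }
  if (!setequal(used_u, seq_len(pair$m)) || anyDuplicated(used_u))
    stop("script does not consume each position of A exactly once",
         call. = FALSE)
  if (anyNA(out))
    stop("script does not produce every position of B", call. = FALSE)
  paste(out, collapse = "")
}

#' @export
print.dl_edit_script <- function(x, ...) {
  cat(sprintf("<dl_edit_script> %d operation(s), total cost %g\n",
              nrow(x), attr(x, "total_cost")))
  print.data.frame(x)
  invisible(x)
}
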