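# Divide-and-conquer combination rules.
#
# At a node bisecting B at column h, the forward pass supplies arrays over A
# positions q = 0..m (value for q in slot q + 1):
#   g[q]  = d(A[1:q],   B[1:h])        final row
#   g1[q] = d(A[1:q],   B[1:h-1])      next-to-final row
#   gt[q] = d(A[1:q-2], B[1:v2-1])     transposition helper, v2 the rightmost
#                                      occurrence of A[q] in B[1:h]
# The backward pass runs on the reversed suffixes and is re-indexed once into
# original coordinates: slot p (p = 1..m+1) holds the value for the suffix
# starting at A position p:
#   gb[p]  = d(A[p:m],   B[h+1:n])
#   g1b[p] = d(A[p:m],   B[h+2:n])
#   gtb[p] = d(A[p+2:m], B[v1+1:n])    v1 the leftmost occurrence of A[p]
#                                      in B[h+1:n]
# Re-indexing is a plain reversal of the raw backward array.

#' Combine forward and backward final rows: no center crossing
#'
#' Evaluates `min over 0 <= i <= m of Rf[i] + Rb[i+1]`, the optimal cost of
#' a trace that splits cleanly at the bisection column: `A[1:i]` aligned to
#' the left half of `B`, `A[i+1:m]` to the right half.  Ties break toward
#' the smallest `i`.
#'
#' @param rf forward final row, length `m + 1`, value for index `i` in slot
#'   `i + 1`.
#' @param rb re-indexed backward final row, length `m + 1`, value for the
#'   suffix starting at position `p` in slot `p` (`p = 1..m+1`).
#' @return A list with `cost` and the split index `i`.
#' @examples
#' combine_no_cc(c(0, 1, 2), c(2, 1, 0))
#' @export
combine_no_cc <- function(rf, rb) {
  if (length(rf) != length(rb))
    stop("forward and backward arrays differ in length", call. = FALSE)
  total <- rf + rb
  i <- which.min(total) - 1L
  list(cost = total[i + 1L], i = i)
}

#' Center crossing with v-endpoints adjacent in B
#'
#' The crossing lines are `(u1, h+1)` and `(u2, h)` with `u1 < u2`; the cost
#' is `R1f[u1-1] + R1b[u2+1] + (u2-u1-1)*D + T` (which reduces to
#' `... + (u2 - u1)` for unit costs).  When the characters of `A` and the
#' two middle characters of `B` are supplied, candidates are restricted to
#' balanced lines (`A[u1] == B[h+1]`, `A[u2] == B[h]`), which is what the
#' trace algorithm requires for the implied transposition to reproduce `B`;
#' without them the minimum is taken over all `1 <= u1 < u2 <= m`.
#'
#' @param r1f forward next-to-final row, slot `i + 1` for index `i`.
#' @param r1b re-indexed backward next-to-final row, slot `p` for suffix `p`.
#' @param costs a [dl_costs()] model.
#' @param a optional integer codes of `A`.
#' @param b_h,b_h1 optional codes of `B[h]` and `B[h+1]`.
#' @return A list with `cost` (`Inf` when no candidate exists), `u1`, `u2`.
#' @export
combine_cc_adjacent_b <- function(r1f, r1b, costs = dl_costs(), a = NULL,
                                  b_h = NULL, b_h1 = NULL) {
  if (length(r1f) != length(r1b))
    stop("forward and backward arrays differ in length", call. = FALSE)
  costs <- as_dl_costs(costs)
  m <- length(r1f) - 1L
  none <- list(cost = Inf, u1 = NA_integer_, u2 = NA_integer_)
  if (m < 2L) return(none)
  u <- seq_len(m)
  ok1 <- if (is.null(a)) rep(TRUE, m) else a == b_h1
  ok2 <- if (is.null(a)) rep(TRUE, m) else a == b_h
  term <- ifelse(ok1, r1f[u] - u * costs$D, Inf)  # r1f[u1 - 1] at slot u1
  pref <- cummin(term)                            # over u1 <= given index
  best <- none
  for (u2 in which(ok2)) {
    if (u2 < 2L || !is.finite(pref[u2 - 1L])) next
    cand <- pref[u2 - 1L] + (u2 - 1L) * costs$D + costs$T + r1b[u2 + 1L]
    if (cand < best$cost) {
      u1 <- match(pref[u2 - 1L], term[seq_len(u2 - 1L)])
      best <- list(cost = cand, u1 = u1, u2 = u2)
    }
  }
  best
}

#' Center crossing with u-endpoints adjacent in A
#'
#' The crossing lines are `(u1, v1)` and `(u2, v2)` with `u2 = u1 + 1`,
#' `v2` the rightmost occurrence of `A[u2]` in `B[1:h]` and `v1` the
#' leftmost occurrence of `A[u1]` in `B[h+1:n]`; the cost is
#' `FRf[u1+1] + FRb[u2-1] + (v1-v2-1)*I + T`.  Candidates lacking either
#' occurrence are skipped; `cost = Inf` signals that none exists.
#'
#' @param frf forward transposition-helper array, slot `i + 1` for index `i`.
#' @param frb re-indexed backward helper, slot `p` for position `p`.
#' @param a integer codes of `A` (length `m`).
#' @param b integer codes of `B` (length `n`).
#' @param h bisection column (`1 <= h < n`).
#' @param costs a [dl_costs()] model.
#' @return A list with `cost`, `u1`, `u2`, `v1`, `v2`.
#' @export
combine_cc_adjacent_a <- function(frf, frb, a, b, h, costs = dl_costs()) {
  if (length(frf) != length(frb))
    stop("forward and backward arrays differ in length", call. = FALSE)
  costs <- as_dl_costs(costs)
  m <- length(a)
  none <- list(cost = Inf, u1 = NA_integer_, u2 = NA_integer_,
               v1 = NA_integer_, v2 = NA_integer_)
  if (m < 2L || h < 1L || h >= length(b)) return(none)
  s_max <- max(a, b) + 1L
  v2_of <- rep(NA_integer_, s_max)  # rightmost occurrence in B[1:h]
  for (j in seq_len(h)) v2_of[b[j] + 1L] <- j
  v1_of <- rep(NA_integer_, s_max)  # leftmost occurrence in B[h+1:n]
  for (j in rev(seq.int(h + 1L, length(b)))) v1_of[b[j] + 1L] <- j
  u1 <- seq_len(m - 1L)
  v2 <- v2_of[a[u1 + 1L] + 1L]
  v1 <- v1_of[a[u1] + 1L]
  ok <- !is.na(v2) & !is.na(v1)
  if (!any(ok)) return(none)
  cand <- rep(Inf, m - 1L)
  cand[ok] <- frf[u1[ok] + 2L] + frb[u1[ok]] +
    (v1[ok] - v2[ok] - 1) * costs$I + costs$T
  best <- which.min(cand)
  if (!is.finite(cand[best])) return(none)
  list(cost = cand[best], u1 = best, u2 = best + 1L,
       v1 = v1[best], v2 = v2[best])
}
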