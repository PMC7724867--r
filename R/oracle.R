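#' Exact DL distance by cost-ordered search over edit sequences
#'
#' An independent reference for tiny instances: explores the space of
#' evolving strings under single-character substitution, insertion,
#' deletion, and adjacent-pair swap, in order of accumulated cost
#' (Dijkstra-style, guided by an admissible weighted-Levenshtein lower
#' bound), and returns the cost of the first path reaching `b`.  It shares
#' no recurrence with the dynamic-programming algorithms, which is what
#' makes it useful as an oracle.  The working alphabet is the symbols
#' occurring in either string; restricting to it is lossless because an
#' optimal edit sequence can always be normalised to a trace, which only
#' ever writes characters of `b`.
#'
#' Refuses strings longer than 8 characters -- the state space grows too
#' fast beyond that, and the full-matrix algorithms cover larger sizes.
#'
#' @inheritParams lw_full_matrix
#' @param cost_bound search cut-off; defaults to `m*D + n*I` (delete
#'   everything, insert everything), which every instance can meet.
#'   Returns `Inf` if no sequence within the bound exists.
#' @return The minimum edit cost (a single number).
#' @examples
#' bfs_dl("CA", "ABC")        # 2: CA -> AC -> ABC
#' @export
bfs_dl <- function(a, b = NULL, costs = dl_costs(), cost_bound = NULL) {
  pair <- as_encoded_pair(a, b)
  costs <- as_dl_costs(costs)
  if (pair$m > 8L || pair$n > 8L)
    stop("bfs_dl is an oracle for tiny instances only (lengths <= 8)",
         call. = FALSE)
  if (is.null(cost_bound))
    cost_bound <- pair$m * costs$D + pair$n * costs$I
  if (!is.finite(cost_bound)) stop("'cost_bound' must be finite",
                                   call. = FALSE)
  cpp_bfs_dl(pair$a, pair$b, pair$s, costs$S, costs$I, costs$D, costs$T,
             cost_bound + 1e-9, max_states = 5000000L)
}

#' Enumerate candidate center crossings at a bisection column
#'
#' For a small instance, lists every pair of balanced lines
#' `(u1, v1), (u2, v2)` with `u1 < u2`, `v2 <= h < v1`, no occurrence of
#' `A[u1]` in `A` strictly between `u1` and `u2`, and no occurrence of
#' `A[u2]` in `B` strictly between `v2` and `v1` -- the defining conditions
#' of a center crossing -- and evaluates each candidate's trace cost
#' `H[u1-1, v2-1] + H'[u2+1, v1+1] + (u2-u1-1)*D + T + (v1-v2-1)*I`
#' from full forward and backward matrices.  Used to validate the
#' divide-and-conquer combiners by brute force.
#'
#' @param pair an [encode_pair()] (lengths at most 20).
#' @param h bisection column, `1 <= h < n`.
#' @param costs a [dl_costs()] model.
#' @return A data frame with columns `u1`, `v1`, `u2`, `v2`, `cost`
#'   (zero rows when no candidate exists).
#' @export
enumerate_center_crossings <- function(pair, h, costs = dl_costs()) {
  costs <- as_dl_costs(costs)
  m <- pair$m; n <- pair$n
  if (m > 20L || n > 20L)
    stop("enumeration oracle is restricted to lengths <= 20", call. = FALSE)
  if (h < 1L || h >= n)
    return(data.frame(u1 = integer(0), v1 = integer(0), u2 = integer(0),
                      v2 = integer(0), cost = numeric(0)))
  Hf <- cpp_full_matrix(pair$a, pair$b, costs$S, costs$I, costs$D, costs$T,
                        FALSE)$H
  Hb <- cpp_full_matrix(rev(pair$a), rev(pair$b), costs$S, costs$I, costs$D,
                        costs$T, FALSE)$H
  # suffix cost d(A[i:m], B[j:n]) in original coordinates
  suff <- function(i, j) Hb[m - i + 2L, n - j + 2L]
  out <- data.frame(u1 = integer(0), v1 = integer(0), u2 = integer(0),
                    v2 = integer(0), cost = numeric(0))
  for (u1 in seq_len(m)) for (u2 in seq_len(m)) {
    if (u2 <= u1) next
    for (v1 in seq.int(h + 1L, n)) for (v2 in seq_len(h)) {
      if (pair$a[u1] != pair$b[v1] || pair$a[u2] != pair$b[v2]) next
      between_a <- if (u2 - u1 > 1L) pair$a[(u1 + 1L):(u2 - 1L)] else integer(0)
      if (any(between_a == pair$a[u1])) next
      between_b <- if (v1 - v2 > 1L) pair$b[(v2 + 1L):(v1 - 1L)] else integer(0)
      if (any(between_b == pair$b[v2])) next
      cost <- Hf[u1, v2] + suff(u2 + 1L, v1 + 1L) +
        (u2 - u1 - 1L) * costs$D + costs$T + (v1 - v2 - 1L) * costs$I
      out[nrow(out) + 1L, ] <- c(u1, v1, u2, v2, cost)
    }
  }
  out
}
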