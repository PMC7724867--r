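#' Full-matrix DL distance, Lowrance-Wagner recurrence
#'
#' Fills the complete (m+1) x (n+1) dynamic-programming matrix `H`, where
#' `H[i, j]` is the minimum edit cost between the prefixes `A[1:i]` and
#' `B[1:j]`.  Boundary: `H[i, 0] = i*D`, `H[0, j] = j*I`.  Interior cells
#' take the minimum of substitution, insertion, deletion, and the
#' transposition case `H[k-1, l-1] + (i-k-1)*D + T + (j-l-1)*I`, with `k` the
#' rightmost occurrence of `B[j]` in `A` before position `i` and `l` the
#' rightmost occurrence of `A[i]` in `B` before position `j` (skipped when
#' either does not exist).  Requires `I + D <= 2T`.  Quadratic space; serves
#' as the reference the linear-space routines are verified against.
#'
#' @param a,b character strings, or an `encoded_pair` as `a` with `b` absent.
#' @param costs a [dl_costs()] model.
#' @return A list with `distance` and the matrix `H` (row `i+1`, column `j+1`
#'   hold `H[i, j]`).
#' @examples
#' lw_full_matrix("dafac", "fdbbec")$distance   # 5
#' @export
lw_full_matrix <- function(a, b = NULL, costs = dl_costs()) {
  pair <- as_encoded_pair(a, b)
  costs <- as_dl_costs(costs)
  stop_unless_valid(costs, "lw")
  cpp_full_matrix(pair$a, pair$b, costs$S, costs$I, costs$D, costs$T, FALSE)
}

#' Full-matrix DL distance, refined recurrence
#'
#' Same boundary and first three cases as [lw_full_matrix()], but the
#' transposition case is restricted to cells with `A[i] != B[j]` and
#' `min(i - k, j - l) == 1`:
#' `H[k-1, j-2] + (i-k-1)*D + T` when `j - l == 1`, and
#' `H[i-2, l-1] + (j-l-1)*I + T` when `i - k == 1`.  Whenever
#' `2S <= I + D <= 2T` the restriction is lossless -- a transposition spanning
#' a wider gap never beats substitutions plus insertions -- so the matrix is
#' cell-by-cell identical to the Lowrance-Wagner one.  This is the recurrence
#' the linear-space algorithms implement.
#'
#' @inheritParams lw_full_matrix
#' @return A list with `distance` and the matrix `H`.
#' @export
refined_full_matrix <- function(a, b = NULL, costs = dl_costs()) {
  pair <- as_encoded_pair(a, b)
  costs <- as_dl_costs(costs)
  stop_unless_valid(costs, "refined")
  cpp_full_matrix(pair$a, pair$b, costs$S, costs$I, costs$D, costs$T, TRUE)
}

#' Default sentinel value for the linear-space arrays
#'
#' Any reachable cell costs at most `m*D + n*I` (delete everything, insert
#' everything), so `(m + n + 1) * max(S, I, D, T) + 1` strictly dominates
#' every finite value while keeping sentinel arithmetic finite in doubles.
#'
#' @param pair an `encoded_pair`.
#' @param costs a [dl_costs()] model.
#' @return A single number.
#' @export
default_maxval <- function(pair, costs = dl_costs()) {
  costs <- as_dl_costs(costs)
  (pair$m + pair$n + 1) * max(costs$S, costs$I, costs$D, costs$T, 1) + 1
}

#' Linear-space DL distance (LS_DL2)
#'
#' Computes the refined-recurrence distance row by row using four
#' one-dimensional arrays -- `R` (current row), `R1` (previous row), `FR`
#' (the transposition helper holding `H[k-1, q-2]` per column), and a
#' length-`s` last-occurrence index -- so working storage is `O(m + n + s)`
#' elements and no quadratic matrix is ever materialised.  The matrix is
#' conceptually augmented with a row and column `-1` whose entries all equal
#' the sentinel `maxVal`.
#'
#' On return the arrays carry the final-row semantics needed by the
#' divide-and-conquer trace algorithms: `R[q] = H[m, q]`,
#' `R1[q] = H[m-1, q]`, and `FR[q] = H[k-1, q-2]` where `k` is the last row
#' with `A[k] == B[q]` (`maxVal` where no such row exists).  Public arrays
#' are indexed `q = 0..n` with the value for `q` in slot `q + 1`.
#'
#' @inheritParams lw_full_matrix
#' @param maxVal sentinel strictly exceeding any reachable finite cell value;
#'   defaults to [default_maxval()].  Values not exceeding `m*D + n*I` are
#'   rejected.
#' @param swap if `TRUE`, swap the two strings internally (useful when
#'   `m < n` to shrink the arrays by a constant factor).  The distance is
#'   unchanged; the returned arrays are then column-oriented over `A`
#'   positions and named `C`, `C1`, `FC`.
#' @return An object of class `dl_result`: `distance`, the boundary arrays,
#'   `maxVal`, `m`, `n`, and `dp_elements` (the exact number of DP array
#'   elements allocated, for the linear-space contract).
#' @examples
#' r <- ls_dl2("dafac", "fdbbec")
#' r$distance          # 5
#' r$R                 # final row of H, indices 0..6
#' @export
ls_dl2 <- function(a, b = NULL, costs = dl_costs(), maxVal = NULL,
                   swap = FALSE) {
  pair <- as_encoded_pair(a, b)
  costs <- as_dl_costs(costs)
  stop_unless_valid(costs, "refined")
  if (is.null(maxVal)) maxVal <- default_maxval(pair, costs)
  check_maxval(maxVal, pair, costs)
  if (swap) {
    cs <- swap_id(costs)
    raw <- cpp_ls_dl2(pair$b, pair$a, pair$s, cs$S, cs$I, cs$D, cs$T, maxVal)
    out <- list(distance = raw$distance,
                C = drop_sentinel(raw$R), C1 = drop_sentinel(raw$R1),
                FC = drop_sentinel(raw$FR),
                maxVal = maxVal, m = pair$m, n = pair$n,
                dp_elements = raw$dp_elements, swapped = TRUE)
  } else {
    raw <- cpp_ls_dl2(pair$a, pair$b, pair$s, costs$S, costs$I, costs$D,
                      costs$T, maxVal)
    out <- list(distance = raw$distance,
                R = drop_sentinel(raw$R), R1 = drop_sentinel(raw$R1),
                FR = drop_sentinel(raw$FR),
                maxVal = maxVal, m = pair$m, n = pair$n,
                dp_elements = raw$dp_elements, swapped = FALSE)
  }
  structure(out, class = "dl_result")
}

# internal arrays carry the augmented index -1 in slot 1
drop_sentinel <- function(x) x[-1L]

check_maxval <- function(maxVal, pair, costs) {
  if (!is.numeric(maxVal) || length(maxVal) != 1L || !is.finite(maxVal))
    stop("'maxVal' must be a single finite number", call. = FALSE)
  if (maxVal <= pair$m * costs$D + pair$n * costs$I)
    stop("'maxVal' too small: it must strictly exceed m*D + n*I",
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.dl_result <- function(x, ...) {
  cat(sprintf("<dl_result> distance=%g (m=%d, n=%d, %s arrays)\n",
              x$distance, x$m, x$n,
              if (!is.null(x$C)) "column" else "row"))
  invisible(x)
}
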