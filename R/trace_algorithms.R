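#' Optimal trace in linear space (LS_TRACE2)
#'
#' Hirschberg-style divide and conquer: bisect `B` at column
#' `h = floor(n/2)`, run the linear-space pass forward on
#' `(B[1:h], A)` and backward on the reversed suffixes, and combine the
#' final boundary arrays under three rules -- a clean split with no center
#' crossing ([combine_no_cc()]), a center crossing whose `B` endpoints are
#' the two middle columns ([combine_cc_adjacent_b()]), and a center crossing
#' whose `A` endpoints are adjacent ([combine_cc_adjacent_a()]).  The
#' cheapest rule fixes either a split column or the two transposition lines,
#' and the algorithm recurses on the induced subproblems.  Ties prefer the
#' clean split, then the adjacent-in-B crossing, then the adjacent-in-A one.
#'
#' Subproblems with `m <= 1` or `n <= 2` are solved by a constant-width full
#' matrix with direct backtracking, so peak working memory stays linear in
#' `m + n`.
#'
#' @inheritParams lw_full_matrix
#' @return A list with `distance` and `trace` (a [dl_trace()]); converting
#'   the trace with [trace_to_edit_script()] yields a script of total cost
#'   equal to `distance`.
#' @examples
#' r <- ls_trace2("dafac", "fdbbec")
#' r$distance                      # 5
#' is_valid_trace(r$trace)         # TRUE
#' @export
ls_trace2 <- function(a, b = NULL, costs = dl_costs()) {
  pair <- as_encoded_pair(a, b)
  costs <- as_dl_costs(costs)
  stop_unless_valid(costs, "refined")
  maxVal <- default_maxval(pair, costs)
  swapped <- swap_id(costs)
  # forward/backward pass over (B-part rows, A-part columns); I/D swapped so
  # row deletions are charged as A->B insertions and vice versa
  pass <- function(bpart, apart) {
    raw <- cpp_ls_dl2(bpart, apart, pair$s, swapped$S, swapped$I, swapped$D,
                      swapped$T, maxVal)
    list(g = drop_sentinel(raw$R), g1 = drop_sentinel(raw$R1),
         gt = drop_sentinel(raw$FR))
  }
  dnc_trace(pair, costs, pass)
}

#' Optimal trace via the strip algorithm (Strip_TRACE2)
#'
#' Identical recursion and combination rules to [ls_trace2()], but the
#' forward and backward passes are executed by the cache-blocked strip
#' algorithm, whose final column arrays `C`, `C1`, `FC` over `A` positions
#' play exactly the roles of `R`, `R1`, `FR` in the combiners.  The returned
#' trace is identical to [ls_trace2()]'s for every strip width.
#'
#' @inheritParams ls_trace2
#' @param q strip width passed to the underlying [strip_dl2()] passes.
#' @return A list with `distance` and `trace`.
#' @export
strip_trace2 <- function(a, b = NULL, costs = dl_costs(), q = 32L) {
  pair <- as_encoded_pair(a, b)
  costs <- as_dl_costs(costs)
  stop_unless_valid(costs, "refined")
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 1)
    stop("strip width 'q' must be an integer >= 1", call. = FALSE)
  q <- as.integer(q)
  maxVal <- default_maxval(pair, costs)
  # unswapped: rows are A-part positions, columns B-part; the column arrays
  # returned by the strip pass are indexed by A positions as required
  pass <- function(bpart, apart) {
    raw <- cpp_strip_dl2(apart, bpart, pair$s, costs$S, costs$I, costs$D,
                         costs$T, q, maxVal)
    list(g = drop_sentinel(raw$C), g1 = drop_sentinel(raw$C1),
         gt = drop_sentinel(raw$FC))
  }
  dnc_trace(pair, costs, pass)
}

# shared divide-and-conquer driver; `pass(bpart, apart)` must return the
# three boundary arrays over A-part indices 0..length(apart)
dnc_trace <- function(pair, costs, pass) {
  a <- pair$a; b <- pair$b
  acc_u <- integer(0); acc_v <- integer(0)
  push_line <- function(u, v) {
    acc_u[[length(acc_u) + 1L]] <<- u
    acc_v[[length(acc_v) + 1L]] <<- v
  }
  rec <- function(alo, ahi, blo, bhi) {
    msub <- ahi - alo + 1L
    nsub <- bhi - blo + 1L
    if (msub == 0L || nsub == 0L)
      return(msub * costs$D + nsub * costs$I)
    if (msub <= 1L || nsub <= 2L)
      return(backtrack_base(a[alo:ahi], b[blo:bhi], costs, alo, blo,
                            push_line))
    h <- nsub %/% 2L
    asub <- a[alo:ahi]
    fwd <- pass(b[blo:(blo + h - 1L)], asub)
    bwd <- pass(rev(b[(blo + h):bhi]), rev(asub))
    gb <- rev(bwd$g); g1b <- rev(bwd$g1); gtb <- rev(bwd$gt)
    nc <- combine_no_cc(fwd$g, gb)
    cb <- combine_cc_adjacent_b(fwd$g1, g1b, costs, asub,
                                b[blo + h - 1L], b[blo + h])
    ca <- combine_cc_adjacent_a(fwd$gt, gtb, asub, b[blo:bhi], h, costs)
    if (nc$cost <= cb$cost && nc$cost <= ca$cost) {
      i <- nc$i
      left <- rec(alo, alo + i - 1L, blo, blo + h - 1L)
      right <- rec(alo + i, ahi, blo + h, bhi)
      left + right
    } else if (cb$cost <= ca$cost) {
      push_line(alo + cb$u1 - 1L, blo + h)        # (u1, h+1) in local coords
      push_line(alo + cb$u2 - 1L, blo + h - 1L)   # (u2, h)
      left <- rec(alo, alo + cb$u1 - 2L, blo, blo + h - 2L)
      right <- rec(alo + cb$u2, ahi, blo + h + 1L, bhi)
      left + right + (cb$u2 - cb$u1 - 1L) * costs$D + costs$T
    } else {
      push_line(alo + ca$u1 - 1L, blo + ca$v1 - 1L)
      push_line(alo + ca$u2 - 1L, blo + ca$v2 - 1L)
      left <- rec(alo, alo + ca$u1 - 2L, blo, blo + ca$v2 - 2L)
      right <- rec(alo + ca$u2, ahi, blo + ca$v1, bhi)
      left + right + (ca$v1 - ca$v2 - 1L) * costs$I + costs$T
    }
  }
  distance <- rec(1L, pair$m, 1L, pair$n)
  list(distance = distance,
       trace = dl_trace(acc_u, acc_v, pair$m, pair$n))
}

# base case: full Lowrance-Wagner matrix on a tiny subinstance (m <= 1 or
# n <= 2, so the matrix is constant-width) with direct backtracking;
# emits lines in global coordinates and returns the subproblem cost
backtrack_base <- function(asub, bsub, costs, alo, blo, push_line) {
  m <- length(asub); n <- length(bsub)
  H <- cpp_full_matrix(asub, bsub, costs$S, costs$I, costs$D, costs$T,
                       FALSE)$H
  eq <- function(x, y) abs(x - y) < 1e-9
  i <- m; j <- n
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L) {
      subc <- if (asub[i] == bsub[j]) 0 else costs$S
      if (eq(H[i + 1L, j + 1L], H[i, j] + subc)) {
        push_line(alo + i - 1L, blo + j - 1L)
        i <- i - 1L; j <- j - 1L
        next
      }
      if (eq(H[i + 1L, j + 1L], H[i, j + 1L] + costs$D)) {
        i <- i - 1L
        next
      }
      if (eq(H[i + 1L, j + 1L], H[i + 1L, j] + costs$I)) {
        j <- j - 1L
        next
      }
      k <- last_before(asub, bsub[j], i)
      l <- last_before(bsub, asub[i], j)
      if (!is.na(k) && !is.na(l) &&
          eq(H[i + 1L, j + 1L],
             H[k, l] + (i - k - 1L) * costs$D + costs$T +
               (j - l - 1L) * costs$I)) {
        push_line(alo + k - 1L, blo + j - 1L)
        push_line(alo + i - 1L, blo + l - 1L)
        i <- k - 1L; j <- l - 1L
        next
      }
      stop("internal error: no recurrence case matches during backtracking")
    } else if (i > 0L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  H[m + 1L, n + 1L]
}

last_before <- function(x, code, pos) {
  idx <- which(x[seq_len(pos - 1L)] == code)
  if (length(idx)) idx[length(idx)] else NA_integer_
}
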