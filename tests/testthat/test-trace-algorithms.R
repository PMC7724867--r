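test_that("divide-and-conquer traces are optimal, valid, and applicable", {
  expect_optimal_trace("dafac", "fdbbec")
  expect_optimal_trace("dafac", "fdbbec", q = 3L)
  expect_optimal_trace("ab", "ba")
  expect_optimal_trace("xyz", "xyz")
  expect_optimal_trace("", "abc")
  expect_optimal_trace("abc", "")
  set.seed(61)
  for (r in 1:60) {
    s <- sample(c(2, 4, 20), 1)
    a <- rand_string(30, s); b <- rand_string(30, s)
    costs <- if (r %% 3) dl_costs() else rand_refined_costs()
    expect_optimal_trace(a, b, costs)
    expect_optimal_trace(a, b, costs, q = sample(c(1L, 2L, 7L), 1))
  }
})

test_that("identical strings yield distance 0 and the identity trace", {
  r <- ls_trace2("PROTEIN", "PROTEIN")
  expect_equal(r$distance, 0)
  ord <- order(r$trace$u)
  expect_equal(r$trace$u[ord], 1:7)
  expect_equal(r$trace$v[ord], 1:7)
})

test_that("empty-side inputs yield empty traces and boundary costs", {
  costs <- dl_costs(S = 1, I = 2, D = 3, T = 3)
  r <- ls_trace2("", "abc", costs = costs)
  expect_equal(r$distance, 3 * 2)
  expect_length(r$trace$u, 0L)
  r2 <- strip_trace2("abcd", "", costs = costs, q = 2L)
  expect_equal(r2$distance, 4 * 3)
  expect_length(r2$trace$u, 0L)
})

test_that("strip and linear-space trace algorithms return identical traces
           for every strip width", {
  set.seed(62)
  for (r in 1:25) {
    s <- sample(c(2, 4), 1)
    a <- rand_string(25, s); b <- rand_string(25, s, min_len = 1L)
    ref <- ls_trace2(a, b)
    for (q in c(1L, 2L, max(1L, nchar(b)))) {
      alt <- strip_trace2(a, b, q = q)
      expect_equal(alt$distance, ref$distance)
      expect_identical(alt$trace[c("u", "v")], ref$trace[c("u", "v")])
    }
  }
})

test_that("returned traces never have overlapping crossings", {
  set.seed(63)
  for (r in 1:30) {
    a <- rand_string(25, 3); b <- rand_string(25, 3)
    tr <- ls_trace2(a, b)$trace
    cps <- crossing_pairs(tr)
    if (nrow(cps)) {
      keys <- c(paste(cps$u1, cps$v1), paste(cps$u2, cps$v2))
      expect_false(anyDuplicated(keys) > 0)
      # crossing lines produced by the algorithm are always balanced
      p <- encode_pair(a, b)
      cls <- classify_lines(tr, p)
      bal <- stats::setNames(cls$balanced, paste(cls$u, cls$v))
      expect_true(all(bal[keys]))
    }
  }
})

test_that("distance is preserved under reversal of both strings", {
  set.seed(64)
  for (r in 1:25) {
    a <- rand_string(25, 4); b <- rand_string(25, 4)
    costs <- if (r %% 2) dl_costs() else rand_refined_costs()
    expect_equal(ls_trace2(a, b, costs = costs)$distance,
                 ls_trace2(reverse_chars(a), reverse_chars(b),
                           costs = costs)$distance)
  }
})

test_that("at the root split the best combination rule equals the
           subproblem optimum", {
  set.seed(65)
  for (r in 1:25) {
    s <- sample(2:4, 1)
    a <- rand_string(12, s, min_len = 2L)
    b <- rand_string(12, s, min_len = 3L)
    pair <- encode_pair(a, b)
    h <- pair$n %/% 2L
    costs <- if (r %% 2) dl_costs() else rand_refined_costs()
    sw <- dl_costs(costs$S, costs$D, costs$I, costs$T)
    maxVal <- default_maxval(pair, costs)
    fwd <- ls_dl2(encode_pair(substr(b, 1, h), a), costs = sw,
                  maxVal = maxVal)
    bwd <- ls_dl2(encode_pair(reverse_chars(substring(b, h + 1)),
                              reverse_chars(a)), costs = sw,
                  maxVal = maxVal)
    nc <- combine_no_cc(fwd$R, rev(bwd$R))
    cb <- combine_cc_adjacent_b(fwd$R1, rev(bwd$R1), costs, pair$a,
                                pair$b[h], pair$b[h + 1L])
    ca <- combine_cc_adjacent_a(fwd$FR, rev(bwd$FR), pair$a, pair$b, h,
                                costs)
    expect_equal(min(nc$cost, cb$cost, ca$cost),
                 lw_full_matrix(pair, costs = costs)$distance)
  }
})
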