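test_that("no-crossing combination equals the brute-force index sweep", {
  res <- combine_no_cc(c(0, 1, 2), c(2, 1, 0))
  expect_equal(res$cost, min(c(0, 1, 2) + c(2, 1, 0)))
  expect_equal(res$i, 0L)          # ties break to the smallest index
  set.seed(51)
  for (r in 1:30) {
    m <- sample(0:12, 1)
    rf <- sample(0:9, m + 1, replace = TRUE)
    rb <- sample(0:9, m + 1, replace = TRUE)
    brute <- min(vapply(0:m, function(i) rf[i + 1] + rb[i + 1], 0))
    expect_equal(combine_no_cc(rf, rb)$cost, brute)
  }
  # empty A: the single slot
  expect_equal(combine_no_cc(5, 7)$cost, 12)
  expect_error(combine_no_cc(1:3, 1:4), "length")
})

test_that("adjacent-in-B combination equals the double-loop enumeration", {
  # all-zero arrays, m = 3: minimum is u2 - u1 = 1
  expect_equal(combine_cc_adjacent_b(rep(0, 4), rep(0, 4))$cost, 1)
  # m < 2: no candidate
  expect_true(is.infinite(combine_cc_adjacent_b(c(0, 1), c(1, 0))$cost))
  set.seed(52)
  for (r in 1:30) {
    m <- sample(2:12, 1)
    r1f <- sample(0:9, m + 1, replace = TRUE)
    r1b <- sample(0:9, m + 1, replace = TRUE)
    costs <- if (r %% 2) dl_costs() else rand_refined_costs()
    brute <- Inf
    for (u1 in 1:(m - 1)) for (u2 in (u1 + 1):m)
      brute <- min(brute, r1f[u1] + r1b[u2 + 1] +
                     (u2 - u1 - 1) * costs$D + costs$T)
    res <- combine_cc_adjacent_b(r1f, r1b, costs)
    expect_equal(res$cost, brute)
    # the reported pair realizes the reported cost
    expect_equal(r1f[res$u1] + r1b[res$u2 + 1] +
                   (res$u2 - res$u1 - 1) * costs$D + costs$T, res$cost)
  }
})

test_that("character filtering restricts adjacent-in-B candidates to
           balanced lines", {
  a <- c(0L, 1L, 0L, 2L)
  r1f <- rep(0, 5); r1b <- rep(0, 5)
  # only u1 with a[u1] == 2 and u2 with a[u2] == 1 are allowed: none, since
  # the only 2 is at position 4 and the only 1 at position 2 (u1 < u2 fails)
  expect_true(is.infinite(
    combine_cc_adjacent_b(r1f, r1b, a = a, b_h = 1L, b_h1 = 2L)$cost))
  # u1 = 2 (code 1), u2 = 4 (code 2): cost (4 - 2 - 1)*1 + 1 = 2
  res <- combine_cc_adjacent_b(r1f, r1b, a = a, b_h = 2L, b_h1 = 1L)
  expect_equal(res[c("cost", "u1", "u2")], list(cost = 2, u1 = 2L, u2 = 4L))
})

test_that("adjacent-in-A combination agrees with the full-matrix
           center-crossing enumeration", {
  set.seed(53)
  tried <- 0L
  for (r in 1:120) {
    s <- sample(2:4, 1)
    a <- rand_string(10, s, min_len = 2L)
    b <- rand_string(10, s, min_len = 3L)
    costs <- if (r %% 2) dl_costs() else rand_refined_costs()
    pair <- encode_pair(a, b)
    h <- pair$n %/% 2L
    if (h < 1L) next
    # forward/backward linear-space passes as the trace algorithm runs them
    sw <- dl_costs(costs$S, costs$D, costs$I, costs$T)
    maxVal <- default_maxval(pair, costs)
    fwd <- ls_dl2(encode_pair(substr(b, 1, h), a), costs = sw,
                  maxVal = maxVal)
    bwd <- ls_dl2(encode_pair(reverse_chars(substr(b, h + 1, pair$n)),
                              reverse_chars(a)), costs = sw,
                  maxVal = maxVal)
    res <- combine_cc_adjacent_a(fwd$FR, rev(bwd$FR), pair$a, pair$b, h,
                                 costs)
    # brute force straight from full matrices: for each adjacent pair
    # u2 = u1 + 1, take v2 = rightmost occurrence of A[u2] in B[1:h] and
    # v1 = leftmost occurrence of A[u1] in B[h+1:n], and evaluate
    # H[u1-1, v2-1] + H'[u2+1, v1+1] + (v1 - v2 - 1)*I + T
    Hf <- lw_full_matrix(pair, costs = costs)$H
    Hb <- lw_full_matrix(encode_pair(reverse_chars(a), reverse_chars(b)),
                         costs = costs)$H
    suff <- function(i, j) Hb[pair$m - i + 2L, pair$n - j + 2L]
    brute <- Inf
    for (u1 in seq_len(pair$m - 1L)) {
      u2 <- u1 + 1L
      occ2 <- which(pair$b[seq_len(h)] == pair$a[u2])
      occ1 <- which(pair$b == pair$a[u1])
      occ1 <- occ1[occ1 > h]
      if (!length(occ2) || !length(occ1)) next
      v2 <- max(occ2); v1 <- min(occ1)
      brute <- min(brute, Hf[u1, v2] + suff(u2 + 1L, v1 + 1L) +
                     (v1 - v2 - 1L) * costs$I + costs$T)
    }
    if (is.finite(brute)) {
      tried <- tried + 1L
      expect_equal(res$cost, brute)
    } else {
      expect_true(is.infinite(res$cost) || res$cost >= maxVal)
    }
  }
  expect_gte(tried, 20L)   # the sweep actually exercised the combiner
})

test_that("adjacent-in-A sentinels fire when occurrences are missing", {
  # A's characters never appear in the right half of B
  pair <- encode_pair("aa", "aabb")
  maxVal <- default_maxval(pair, dl_costs())
  fwd <- ls_dl2(encode_pair("aa", "aa"), maxVal = maxVal)
  bwd <- ls_dl2(encode_pair("bb", "aa"), maxVal = maxVal)
  res <- combine_cc_adjacent_a(fwd$FR, rev(bwd$FR), pair$a, pair$b, 2L,
                               dl_costs())
  expect_true(is.infinite(res$cost))
  # n < 2: no bisection possible
  p2 <- encode_pair("ab", "a")
  expect_true(is.infinite(
    combine_cc_adjacent_a(rep(0, 3), rep(0, 3), p2$a, p2$b, 0L,
                          dl_costs())$cost))
})
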