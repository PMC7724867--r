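# shared generators and checkers for the property-style tests

rand_string <- function(max_len, alphabet_size, min_len = 0L) {
  len <- sample(min_len:max_len, 1L)
  if (len == 0L) return("")
  paste(sample(LETTERS[seq_len(alphabet_size)], len, replace = TRUE),
        collapse = "")
}

# integer-valued cost model satisfying 2S <= I + D <= 2T (sums of integer
# costs are exact in doubles, so distance comparisons can be exact)
rand_refined_costs <- function() {
  I <- sample(1:4, 1L)
  D <- sample(1:4, 1L)
  T <- ceiling((I + D) / 2) + sample(0:2, 1L)
  S <- sample(0:floor((I + D) / 2), 1L)
  dl_costs(S, I, D, T)
}

reverse_chars <- function(x) {
  if (nchar(x) == 0L) return(x)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

# run a trace algorithm and verify the full contract: valid trace, disjoint
# balanced crossings (trace_to_edit_script errors otherwise), script cost
# equal to the reference distance, script reproduces B
expect_optimal_trace <- function(a, b, costs = dl_costs(), q = NULL) {
  pair <- encode_pair(a, b)
  ref <- lw_full_matrix(pair, costs = costs)$distance
  res <- if (is.null(q)) ls_trace2(pair, costs = costs)
         else strip_trace2(pair, costs = costs, q = q)
  expect_true(is_valid_trace(res$trace))
  expect_equal(res$distance, ref)
  script <- trace_to_edit_script(res$trace, pair, costs)
  expect_equal(attr(script, "total_cost"), ref)
  expect_identical(apply_edit_script(script, pair), b)
  invisible(res)
}

# all distance implementations on one input; returns the vector of distances
all_distances <- function(a, b, costs = dl_costs(), q = 4L) {
  pair <- encode_pair(a, b)
  c(lw = lw_full_matrix(pair, costs = costs)$distance,
    refined = refined_full_matrix(pair, costs = costs)$distance,
    ls2 = ls_dl2(pair, costs = costs)$distance,
    strip2 = strip_dl2(pair, costs = costs, q = q)$distance,
    trace2 = ls_trace2(pair, costs = costs)$distance)
}
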