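#' Edit-operation cost model
#'
#' Bundles the four edit-operation costs: `S` (substitution of differing
#' characters; substituting a character for itself is always free), `I`
#' (insertion), `D` (deletion), and `T` (transposition of two adjacent
#' characters).  The classic unit DL distance is `dl_costs()`.
#'
#' Two validity regimes matter.  The full-matrix Lowrance-Wagner recurrence
#' is correct whenever `I + D <= 2T`.  The refined recurrence used by the
#' linear-space algorithms additionally needs `2S <= I + D`, i.e.
#' `2S <= I + D <= 2T`; unit costs satisfy both.
#'
#' @param S,I,D,T single non-negative finite numbers.
#' @return An object of class `dl_costs`.
#' @examples
#' dl_costs()                   # unit model
#' dl_costs(S = 1, I = 2, D = 2, T = 2)
#' @seealso [validate_cost_model()]
#' @export
dl_costs <- function(S = 1, I = 1, D = 1, T = 1) {
  vals <- list(S = S, I = I, D = D, T = T)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || !is.finite(v))
      stop("cost '", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("cost '", nm, "' must be non-negative", call. = FALSE)
  }
  structure(lapply(vals, as.numeric), class = "dl_costs")
}

as_dl_costs <- function(costs) {
  if (inherits(costs, "dl_costs")) return(costs)
  if (is.numeric(costs) && length(costs) == 4L)
    return(dl_costs(costs[[1]], costs[[2]], costs[[3]], costs[[4]]))
  stop("'costs' must be a dl_costs object or a numeric vector S, I, D, T",
       call. = FALSE)
}

#' Check a cost model against a recurrence's validity condition
#'
#' @param costs a [dl_costs()] object (or numeric vector `c(S, I, D, T)`).
#' @param mode `"lw"` checks `I + D <= 2T`, the condition under which the
#'   Lowrance-Wagner full-matrix recurrence computes the true minimum edit
#'   cost; `"refined"` checks `2S <= I + D <= 2T`, required by the refined
#'   recurrence and hence by all linear-space routines.
#' @return `TRUE` or `FALSE`.
#' @examples
#' validate_cost_model(dl_costs(), "refined")            # TRUE
#' validate_cost_model(dl_costs(S = 2), "refined")       # FALSE: 2S > I + D
#' @export
validate_cost_model <- function(costs, mode = c("refined", "lw")) {
  costs <- as_dl_costs(costs)
  mode <- match.arg(mode)
  sum_id <- costs$I + costs$D
  if (mode == "lw") sum_id <= 2 * costs$T
  else 2 * costs$S <= sum_id && sum_id <= 2 * costs$T
}

stop_unless_valid <- function(costs, mode) {
  if (!validate_cost_model(costs, mode)) {
    cond <- if (mode == "lw") "I + D <= 2T" else "2S <= I + D <= 2T"
    stop("cost model violates the requirement ", cond, call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.dl_costs <- function(x, ...) {
  cat(sprintf("<dl_costs> S=%g I=%g D=%g T=%g\n", x$S, x$I, x$D, x$T))
  invisible(x)
}

# swap insertion and deletion costs: d[S,I,D,T](A, B) == d[S,D,I,T](B, A)
swap_id <- function(costs) dl_costs(costs$S, costs$D, costs$I, costs$T)
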