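# the 19 kinetic constants subject to global sensitivity analysis
# (hill_n is structural and not sampled)
.sampled_params <- setdiff(.param_names, "hill_n")

#' Latin hypercube design for multi-parametric sensitivity analysis
#'
#' Draws a Latin hypercube sample of all 19 kinetic constants, each uniform
#' over `[baseline/range_factor, baseline * range_factor]` — one order of
#' magnitude around baseline at the default `range_factor = 10`. Each
#' parameter's `n_samples` values occupy exactly one equal-probability
#' stratum each, and the draw is reproducible under `seed`. Sampling is on
#' the linear scale by default; `log_uniform = TRUE` samples uniformly in
#' log-space instead.
#'
#' @param n_samples number of parameter sets (>= 2); the full analysis uses
#'   5000.
#' @param baselines a `meio_params` vector supplying the 19 baseline values
#'   (all must be positive and finite).
#' @param range_factor fold-range around baseline (> 1); default 10.
#' @param seed integer seed.
#' @param log_uniform sample uniformly on the log scale instead of linear.
#' @return `n_samples` x 19 numeric matrix with parameter-name columns.
#' @export
lhs_sample <- function(n_samples, baselines = default_parameters(),
                       range_factor = 10, seed = 1L, log_uniform = FALSE) {
  if (n_samples < 2L) stop("n_samples must be at least 2", call. = FALSE)
  if (!is.numeric(range_factor) || range_factor <= 1)
    stop("range_factor must be > 1", call. = FALSE)
  b <- unclass(validate_parameters(baselines))[.sampled_params]
  if (any(b <= 0) || any(!is.finite(b)))
    stop("all baseline parameters must be positive and finite to define ",
         "sampling strata", call. = FALSE)
  set.seed(seed)
  u <- lhs::randomLHS(as.integer(n_samples), length(b))
  lo <- b / range_factor; hi <- b * range_factor
  x <- if (log_uniform) {
    exp(sweep(sweep(u, 2L, log(hi) - log(lo), "*"), 2L, log(lo), "+"))
  } else {
    sweep(sweep(u, 2L, hi - lo, "*"), 2L, lo, "+")
  }
  colnames(x) <- .sampled_params
  x
}

#' Sum-of-squared-errors objective between two trajectories
#'
#' The sensitivity objective: the sum over shared grid points of the squared
#' difference of one model variable between a random-parameter trajectory and
#' the baseline trajectory. A diverged random trajectory scores `Inf` and is
#' therefore always classified unacceptable.
#'
#' @param traj_random,traj_baseline `meio_traj` objects on the same time
#'   grid.
#' @param variable model variable name.
#' @return non-negative number (possibly `Inf`).
#' @export
objective_sse <- function(traj_random, traj_baseline, variable) {
  stopifnot(inherits(traj_random, "meio_traj"),
            inherits(traj_baseline, "meio_traj"))
  if (!variable %in% .state_names)
    stop("unknown variable: ", variable, call. = FALSE)
  if (isTRUE(attr(traj_random, "diverged"))) return(Inf)
  if (nrow(traj_random) != nrow(traj_baseline) ||
      max(abs(traj_random$time_h - traj_baseline$time_h)) > 1e-9)
    stop("trajectories must share a time grid", call. = FALSE)
  sum((traj_random[[variable]] - traj_baseline[[variable]])^2)
}

#' Kolmogorov-Smirnov distance between two samples
#'
#' Sup-norm distance between the empirical cumulative distribution functions
#' of two samples — the per-parameter sensitivity score of the MPSA scheme,
#' bounded in `[0, 1]`.
#'
#' @param x,y non-empty numeric vectors.
#' @return number in `[0, 1]`.
#' @examples
#' ks_distance(c(1, 2, 3), c(2, 3, 4))  # 1/3
#' @export
ks_distance <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  grid <- sort(unique(c(x, y)))
  fx <- vapply(grid, function(g) mean(x <= g), 0)
  fy <- vapply(grid, function(g) mean(y <= g), 0)
  max(abs(fx - fy))
}

#' Multi-parametric sensitivity analysis
#'
#' The global sensitivity pipeline: draw a Latin hypercube sample of all 19
#' kinetic constants, integrate each sampled model from the mitotic state,
#' score each sample per variable by the sum-of-squared-errors objective
#' against the baseline time course, classify samples as acceptable
#' (objective below the mean objective of that variable) or unacceptable,
#' and report, for every (parameter, variable) pair, the Kolmogorov-Smirnov
#' distance between the parameter's values in the two classes. Sensitivities
#' lie in `[0, 1]`; larger means more influential.
#'
#' Divergent or failed integrations receive an infinite objective and are
#' classed unacceptable (the class-threshold mean is taken over finite
#' objectives). Per-sample failures never abort the run.
#'
#' @inheritParams integrate_model
#' @param n_samples number of Latin hypercube samples; the full analysis
#'   uses 5000 (reduced runs of 500-1000 preserve the qualitative ranking).
#' @param range_factor fold-range around baseline; default 10.
#' @param seed integer seed for the hypercube.
#' @param t_end,n_grid objective time grid; default 0-24 h, 97 points.
#' @param rtol,atol integration tolerances for the sampled runs.
#' @param log_uniform passed to [lhs_sample()].
#' @return object of class `meio_mpsa`: list with `sensitivity` (19 x 6
#'   matrix), `objectives` (n x 6), `acceptable` (n x 6 logical), `samples`
#'   (the design matrix) and the design settings.
#' @export
run_mpsa <- function(variant = wild_type(), params = default_parameters(),
                     n_samples = 5000L, range_factor = 10, seed = 1L,
                     t_end = 24, n_grid = 97L, rtol = 1e-8, atol = 1e-10,
                     log_uniform = FALSE) {
  params <- validate_parameters(params)
  x <- lhs_sample(n_samples, params, range_factor, seed, log_uniform)
  base_traj <- integrate_model(variant, params, t_end = t_end,
                               n_points = n_grid, rtol = rtol, atol = atol)
  base_mat <- as.matrix(base_traj[, .state_names])

  obj <- matrix(Inf, n_samples, 6L,
                dimnames = list(NULL, .state_names))
  for (i in seq_len(n_samples)) {
    p_i <- unclass(params)
    p_i[.sampled_params] <- x[i, ]
    tr <- tryCatch(
      integrate_model(variant, validate_parameters(p_i), t_end = t_end,
                      n_points = n_grid, rtol = rtol, atol = atol),
      error = function(e) NULL)
    if (is.null(tr) || isTRUE(attr(tr, "diverged"))) next
    obj[i, ] <- colSums((as.matrix(tr[, .state_names]) - base_mat)^2)
  }

  acc <- matrix(FALSE, n_samples, 6L, dimnames = list(NULL, .state_names))
  sens <- matrix(NA_real_, length(.sampled_params), 6L,
                 dimnames = list(.sampled_params, .state_names))
  for (v in .state_names) {
    finite <- is.finite(obj[, v])
    thr <- mean(obj[finite, v])
    acc[, v] <- finite & obj[, v] < thr
    if (!any(acc[, v]) || all(acc[, v])) {
      warning("degenerate acceptable/unacceptable split for ", v,
              "; sensitivities undefined", call. = FALSE)
      next
    }
    for (k in .sampled_params)
      sens[k, v] <- ks_distance(x[acc[, v], k], x[!acc[, v], k])
  }

  structure(list(sensitivity = sens, objectives = obj, acceptable = acc,
                 samples = x, n_samples = n_samples,
                 range_factor = range_factor, seed = seed,
                 t_end = t_end, n_grid = n_grid,
                 log_uniform = log_uniform),
            class = "meio_mpsa")
}

#' @export
print.meio_mpsa <- function(x, top = 3L, ...) {
  cat("Multi-parametric sensitivity analysis: n =", x$n_samples,
      ", range factor", x$range_factor, ", seed", x$seed, "\n")
  for (v in colnames(x$sensitivity)) {
    s <- sort(x$sensitivity[, v], decreasing = TRUE)
    cat(sprintf("  %-6s top %d: %s\n", v, top,
                paste(names(s)[seq_len(top)],
                      sprintf("(%.2f)", s[seq_len(top)]), collapse = " ")))
  }
  invisible(x)
}
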