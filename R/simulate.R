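# deSolve-facing wrapper around the resolved right-hand side
.desolve_rhs <- function(t, y, rp) {
  y <- pmax(y, 0)  # adaptive solvers may undershoot zero by ~atol
  list(rhs_resolved(y, rp))
}
.desolve_jac <- function(t, y, rp) jac_resolved(pmax(y, 0), rp)

#' Integrate the model forward in time
#'
#' Solves the model ODEs on a uniform time grid with adaptive error control
#' (default relative tolerance `1e-8`, absolute `1e-10`). If any component
#' exceeds the blow-up bound (default `1e3`; wild-type levels are O(1), and
#' the only unbounded regime is deletion of the Ime2-to-Ime1 negative
#' feedback), the trajectory is truncated at the first offending grid point
#' and flagged as diverged.
#'
#' @param variant a `meio_variant`; default [wild_type()].
#' @param params a `meio_params` vector.
#' @param init initial state; default [mitotic_initial_state()].
#' @param t_end end time in hours (> 0); default 24.
#' @param n_points number of grid points including t = 0; the default 961
#'   (0.025 h spacing over 24 h) resolves the ~6 h Ime1 peak.
#' @param method a [deSolve::ode()] method; default `"lsoda"`.
#' @param rtol,atol relative/absolute integration tolerances.
#' @param blowup divergence bound on any state component.
#' @return object of class `meio_traj`: a data frame with columns `time_h`,
#'   `rim11`, `pume6`, `psok2`, `ime1`, `pime1`, `ime2` and attributes
#'   `diverged` (logical) and `final_state`.
#' @examples
#' tr <- integrate_model(t_end = 24, n_points = 241)
#' attr(tr, "diverged")
#' @export
integrate_model <- function(variant = wild_type(), params = default_parameters(),
                            init = mitotic_initial_state(), t_end = 24,
                            n_points = 961, method = "lsoda",
                            rtol = 1e-8, atol = 1e-10, blowup = 1e3) {
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) || t_end <= 0)
    stop("t_end must be a single positive number of hours", call. = FALSE)
  if (n_points < 2L) stop("n_points must be at least 2", call. = FALSE)
  y0 <- validate_state(init)
  rp <- resolve_variant(variant, params)
  y0[rp$clamped] <- 0
  times <- seq(0, t_end, length.out = n_points)

  args <- list(y = as.numeric(y0), times = times, func = .desolve_rhs,
               parms = rp, method = method, rtol = rtol, atol = atol)
  if (is.character(method) &&
      method %in% c("lsoda", "lsode", "vode", "daspk", "radau", "bdf",
                    "adams", "impAdams")) {
    # stiff-capable solvers profit from the analytic Jacobian
    args$jacfunc <- .desolve_jac
    args$jactype <- "fullusr"
  }
  out <- tryCatch(do.call(deSolve::ode, args), error = function(e) e)
  if (inherits(out, "error"))
    stop("integration failed: ", conditionMessage(out), call. = FALSE)
  out <- unclass(out)
  colnames(out) <- c("time_h", .state_names)

  diverged <- FALSE
  bad <- which(apply(out[, -1L, drop = FALSE], 1L,
                     function(r) any(!is.finite(r)) || max(r) > blowup))
  if (length(bad) > 0) {
    diverged <- TRUE
    out <- out[seq_len(bad[1L]), , drop = FALSE]
  } else if (nrow(out) < n_points) {
    # solver stopped early without hitting the bound
    stop("integration error: solver stopped at t = ",
         signif(out[nrow(out), 1L], 4), " h of ", t_end,
         " h without divergence", call. = FALSE)
  }

  traj <- as.data.frame(out)
  attr(traj, "diverged") <- diverged
  attr(traj, "final_state") <- stats::setNames(
    as.numeric(out[nrow(out), -1L]), .state_names)
  attr(traj, "variant") <- variant
  attr(traj, "params") <- params
  class(traj) <- c("meio_traj", "data.frame")
  traj
}

#' Steady state of a model variant
#'
#' Integrates from `init` to `t = 500` h, then polishes the end point with a
#' damped Newton iteration using the analytic Jacobian (restricted to
#' non-clamped variables). Convergence requires the max-norm of the
#' right-hand side at the result to be below `tol` and all state invariants
#' to hold; if the Newton step leaves the admissible box the integrator end
#' point is kept.
#'
#' @inheritParams integrate_model
#' @param t_settle settling horizon in hours before polishing; default 500.
#' @param tol residual max-norm defining convergence; default `1e-10`.
#' @return list with `state` (named vector), `converged` (logical) and
#'   `diverged` (logical).
#' @examples
#' find_steady_state()$state  # wild-type fixed point, Ime2 ~ 0.27
#' @export
find_steady_state <- function(variant = wild_type(),
                              params = default_parameters(),
                              init = mitotic_initial_state(),
                              t_settle = 500, tol = 1e-10) {
  rp <- resolve_variant(variant, params)
  traj <- integrate_model(variant, params, init, t_end = t_settle,
                          n_points = 501L)
  if (attr(traj, "diverged"))
    return(list(state = attr(traj, "final_state"), converged = FALSE,
                diverged = TRUE))
  y <- attr(traj, "final_state")
  y_pol <- newton_polish(y, rp, tol = tol)
  if (!is.null(y_pol)) y <- y_pol
  res <- max(abs(rhs_resolved(as.numeric(y), rp)))
  list(state = stats::setNames(as.numeric(y), .state_names),
       converged = res < tol && state_admissible(y), diverged = FALSE)
}

# is a state inside the admissible box ([0,1]^3 x [0,Inf)^3), up to slack?
state_admissible <- function(y, slack = 1e-7) {
  all(is.finite(y)) && all(y >= -slack) &&
    all(y[1:3] <= 1 + slack)
}

# damped Newton on the free (non-clamped) coordinates; returns the polished
# state or NULL if the iteration fails or leaves the admissible box
newton_polish <- function(y, rp, tol = 1e-10, max_iter = 50L) {
  free <- !rp$clamped
  y <- as.numeric(y)
  y[rp$clamped] <- 0
  for (it in seq_len(max_iter)) {
    f <- rhs_resolved(y, rp)
    if (max(abs(f)) < tol * 1e-2) break
    J <- jac_resolved(y, rp)[free, free, drop = FALSE]
    step <- tryCatch(solve(J, -f[free]), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lambda <- 1
    repeat {
      y_new <- y
      y_new[free] <- y[free] + lambda * step
      if (state_admissible(y_new)) break
      lambda <- lambda / 2
      if (lambda < 1e-8) return(NULL)
    }
    if (max(abs(lambda * step)) < 1e-15) { y <- pmax(y_new, 0); break }
    y <- pmax(y_new, 0)
  }
  if (max(abs(rhs_resolved(y, rp))) > tol) return(NULL)
  y
}

#' @export
print.meio_traj <- function(x, ...) {
  cat("Model trajectory: ", nrow(x), " points over ",
      signif(x$time_h[nrow(x)], 4), " h",
      if (attr(x, "diverged")) " [DIVERGED]", "\n", sep = "")
  fs <- attr(x, "final_state")
  cat("final state:", paste(names(fs), signif(fs, 3), sep = "=",
                            collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.meio_traj <- function(x, vars = .state_names, ...) {
  graphics::matplot(x$time_h, as.matrix(x[, vars, drop = FALSE]),
                    type = "l", lty = 1, xlab = "time (h)",
                    ylab = "relative protein level", ...)
  graphics::legend("topright", legend = vars, col = seq_along(vars),
                   lty = 1, bty = "n")
  invisible(x)
}
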