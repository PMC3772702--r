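# Multi-start seed states: the three conserved-pool fractions at their
# quasi-steady values given Ime1, pIme1 at its quasi-steady value, and a
# coarse product grid over (Ime1, Ime2). The high-Ime2 branch can sit well
# above 1, hence the log grid up to 50.
.eq_seeds <- function(rp) {
  p <- rp$params
  R <- if (rp$clamped[["rim11"]]) 0 else
    p[["u_rim11"]] / (p[["u_rim11"]] + p[["p_rim11"]])
  ime1_grid <- c(0.01, 0.05, 0.2, 0.5, 1)
  ime2_grid <- exp(seq(log(1e-3), log(50), length.out = 12L))
  if (rp$clamped[["ime1"]]) ime1_grid <- 0
  if (rp$clamped[["ime2"]]) ime2_grid <- 0
  seeds <- list()
  for (i1 in ime1_grid) for (i2 in ime2_grid) {
    U <- if (rp$clamped[["pume6"]]) 0 else
      p[["p_ume6"]] * R / (p[["p_ume6"]] * R + p[["u_ume6"]])
    h <- if (is.finite(p[["c_sok2"]])) p[["c_sok2"]] / (p[["c_sok2"]] + i1) else 1
    S <- if (rp$clamped[["psok2"]]) 0 else
      p[["p_sok2"]] * h / (p[["p_sok2"]] * h + p[["u_sok2"]])
    P <- if (rp$clamped[["pime1"]]) 0 else p[["p_ime1"]] * R * i1 / p[["d_pime1"]]
    seeds[[length(seeds) + 1L]] <- c(R, U, S, i1, P, i2)
  }
  seeds
}

# all equilibria of a resolved model: multi-start damped Newton, dedup at
# max-norm 1e-6, stability from the analytic Jacobian's eigenvalues
.equilibria_resolved <- function(rp, extra_seeds = list(), tol = 1e-10,
                                 margin = 1e-8) {
  seeds <- c(.eq_seeds(rp), extra_seeds)
  found <- list()
  for (s in seeds) {
    y <- newton_polish(s, rp, tol = tol, max_iter = 60L)
    if (is.null(y)) next
    if (!state_admissible(y)) next
    dup <- any(vapply(found, function(e) max(abs(e$state - y)) < 1e-6, TRUE))
    if (dup) next
    ev <- eigen(jac_resolved(y, rp)[!rp$clamped, !rp$clamped, drop = FALSE],
                only.values = TRUE)$values
    lead <- max(Re(ev))
    stab <- if (lead < -margin) "stable"
            else if (lead > margin) "unstable"
            else "marginal"
    found[[length(found) + 1L]] <- list(
      state = stats::setNames(pmax(y, 0), .state_names),
      stability = stab, leading_real_eigenvalue = lead)
  }
  found[order(vapply(found, function(e) e$state[["ime2"]], 0))]
}

.set_param <- function(params, name, value) {
  if (!name %in% .param_names) stop("unknown parameter: ", name, call. = FALSE)
  p <- unclass(params)
  p[[name]] <- value
  p
}

#' Equilibria of the model at one parameter value
#'
#' Finds all equilibria by multi-start damped Newton iteration (seeds combine
#' quasi-steady closed forms for the conserved pools with a coarse grid over
#' Ime1 and a log grid over Ime2 up to 50), deduplicates them, and classifies
#' each as stable or unstable from the eigenvalues of the analytic Jacobian.
#' Every reported equilibrium satisfies a right-hand-side max-norm below
#' `1e-10`.
#'
#' @inheritParams integrate_model
#' @param param_name optional parameter to set (e.g. the bifurcation
#'   parameter); `NULL` evaluates at `params` as given.
#' @param value value for `param_name`.
#' @return list of equilibria, each a list with `state`, `stability`
#'   (`"stable"`/`"unstable"`) and `leading_real_eigenvalue` (per hour),
#'   ordered by increasing Ime2. Empty (with a warning) if no root is found.
#' @examples
#' eq <- equilibria_at()  # single stable equilibrium, Ime2 ~ 0.27
#' @export
equilibria_at <- function(variant = wild_type(), params = default_parameters(),
                          param_name = NULL, value = NULL) {
  if (!is.null(param_name)) {
    if (!is.numeric(value) || length(value) != 1L || is.na(value) || value < 0)
      stop("value must be a single non-negative number", call. = FALSE)
    params <- .set_param(params, param_name, value)
  }
  rp <- resolve_variant(variant, validate_parameters(params))
  eq <- .equilibria_resolved(rp)
  if (length(eq) == 0L)
    warning("no equilibrium found from any start", call. = FALSE)
  eq
}

.branch_df <- function(values, eq_list, param_name) {
  rows <- list()
  for (k in seq_along(values)) {
    for (j in seq_along(eq_list[[k]])) {
      e <- eq_list[[k]][[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter_value = values[k], equilibrium_index = j,
        stability = e$stability,
        leading_real_eigenvalue = e$leading_real_eigenvalue,
        as.list(e$state))
    }
  }
  br <- do.call(rbind, rows)
  attr(br, "parameter") <- param_name
  class(br) <- c("meio_branch", "data.frame")
  br
}

# parameters scanned on a logarithmic grid: the dimensionless half-maximum
# constants, which the analyses vary over orders of magnitude
.log_scan_params <- c("c_sok2", "c_ime1", "c1", "c2", "c3")

#' Equilibrium branches along one parameter
#'
#' Sweeps a parameter grid (logarithmic for the half-maximum constants,
#' linear for rates) in both directions, combining warm starts from the
#' previous grid point's equilibria with the fresh multi-start grid at every
#' step, so disconnected branches are found without arclength continuation.
#'
#' @inheritParams equilibria_at
#' @param param_name parameter to scan.
#' @param range length-2 numeric range (positive).
#' @param n_steps number of grid points (>= 2).
#' @param log_scale grid spacing; defaults to log for half-maximum constants.
#' @return object of class `meio_branch`: a data frame with columns
#'   `parameter_value`, `equilibrium_index`, `stability`,
#'   `leading_real_eigenvalue` and the six state variables.
#' @export
scan_1d <- function(variant = wild_type(), params = default_parameters(),
                    param_name, range, n_steps = 25L,
                    log_scale = param_name %in% .log_scan_params) {
  stopifnot(length(range) == 2L, all(range > 0), n_steps >= 2L)
  range <- sort(range)
  values <- if (log_scale)
    exp(seq(log(range[1L]), log(range[2L]), length.out = n_steps))
  else seq(range[1L], range[2L], length.out = n_steps)
  params <- validate_parameters(params)

  sweep_once <- function(vals) {
    eq_list <- vector("list", length(vals))
    warm <- list()
    for (k in seq_along(vals)) {
      rp <- resolve_variant(variant, .set_param(params, param_name, vals[k]))
      eq_list[[k]] <- .equilibria_resolved(rp, extra_seeds = warm)
      warm <- lapply(eq_list[[k]], function(e) as.numeric(e$state))
    }
    eq_list
  }
  up <- sweep_once(values)
  down <- rev(sweep_once(rev(values)))
  merged <- lapply(seq_along(values), function(k) {
    eq <- up[[k]]
    for (e in down[[k]]) {
      dup <- any(vapply(eq, function(o) max(abs(o$state - e$state)) < 1e-6, TRUE))
      if (!dup) eq[[length(eq) + 1L]] <- e
    }
    eq[order(vapply(eq, function(e) e$state[["ime2"]], 0))]
  })
  .branch_df(values, merged, param_name)
}

#' Equilibrium branches along a coupled PKA-activity scale
#'
#' PKA is not an explicit variable; its activity is represented by the
#' phosphorylation rates of Sok2 and Rim11. A single scale factor multiplies
#' both `p_sok2` and `p_rim11` (scale 1 = baseline); otherwise identical to
#' [scan_1d()]. Reducing the scale (lower PKA activity) lets a second stable
#' state of higher Ime2 appear.
#'
#' @inheritParams scan_1d
#' @param scale_range length-2 positive range of the common scale factor.
#' @return a `meio_branch` whose `parameter_value` column is the scale.
#' @export
scan_coupled_pka <- function(variant = wild_type(),
                             params = default_parameters(),
                             scale_range = c(0.001, 2), n_steps = 25L) {
  stopifnot(length(scale_range) == 2L, all(scale_range > 0), n_steps >= 2L)
  scale_range <- sort(scale_range)
  values <- exp(seq(log(scale_range[1L]), log(scale_range[2L]),
                    length.out = n_steps))
  params <- validate_parameters(params)
  p0_sok2 <- params[["p_sok2"]]; p0_rim11 <- params[["p_rim11"]]

  sweep_once <- function(vals) {
    eq_list <- vector("list", length(vals))
    warm <- list()
    for (k in seq_along(vals)) {
      p <- .set_param(params, "p_sok2", p0_sok2 * vals[k])
      p <- .set_param(p, "p_rim11", p0_rim11 * vals[k])
      rp <- resolve_variant(variant, p)
      eq_list[[k]] <- .equilibria_resolved(rp, extra_seeds = warm)
      warm <- lapply(eq_list[[k]], function(e) as.numeric(e$state))
    }
    eq_list
  }
  up <- sweep_once(values)
  down <- rev(sweep_once(rev(values)))
  merged <- lapply(seq_along(values), function(k) {
    eq <- up[[k]]
    for (e in down[[k]]) {
      dup <- any(vapply(eq, function(o) max(abs(o$state - e$state)) < 1e-6, TRUE))
      if (!dup) eq[[length(eq) + 1L]] <- e
    }
    eq[order(vapply(eq, function(e) e$state[["ime2"]], 0))]
  })
  .branch_df(values, merged, "pka_scale")
}

# number of stable equilibria at one parameter value
.n_stable_at <- function(variant, params, param_name, value) {
  rp <- resolve_variant(variant, .set_param(params, param_name, value))
  eq <- .equilibria_resolved(rp)
  sum(vapply(eq, function(e) e$stability == "stable", TRUE))
}

#' Bistable parameter interval
#'
#' Locates the interval of a bifurcation parameter over which at least two
#' stable equilibria coexist. A coarse grid (log-spaced for half-maximum
#' constants) locates the region; its two fold-point boundaries are then
#' refined by bisection on the stable-equilibrium count to parameter
#' tolerance `tol`. For the Ime2 auto-regulation constant `c2` with Hill
#' coefficient 5 the interval is roughly c2 in [0.5, 0.7]; coefficients 1
#' and 3 give no bistability and 7 widens the interval.
#'
#' @inheritParams scan_1d
#' @param hill_n optional Hill coefficient override.
#' @param n_steps coarse grid size; default 25.
#' @param tol bisection tolerance on the parameter; default `1e-3`.
#' @return list with `lower`, `upper` and `hill_n`, or `NULL` when no grid
#'   point has two stable equilibria.
#' @examples
#' \donttest{
#' bistable_interval(param_name = "c2", range = c(0.1, 2), hill_n = 5)
#' }
#' @export
bistable_interval <- function(variant = wild_type(),
                              params = default_parameters(),
                              param_name = "c2", range = c(0.1, 2),
                              hill_n = NULL, n_steps = 25L, tol = 1e-3,
                              log_scale = param_name %in% .log_scan_params) {
  stopifnot(length(range) == 2L, all(range > 0), n_steps >= 2L)
  range <- sort(range)
  params <- validate_parameters(params)
  if (!is.null(hill_n))
    params <- validate_parameters(.set_param(params, "hill_n", hill_n))
  values <- if (log_scale)
    exp(seq(log(range[1L]), log(range[2L]), length.out = n_steps))
  else seq(range[1L], range[2L], length.out = n_steps)

  counts <- vapply(values, function(v)
    .n_stable_at(variant, params, param_name, v), integer(1))
  bi <- which(counts >= 2L)
  if (length(bi) == 0L) return(NULL)

  bisect_edge <- function(lo, hi, inside_is_hi) {
    # invariant: exactly one of (lo, hi) has >= 2 stable equilibria
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      mid_in <- .n_stable_at(variant, params, param_name, mid) >= 2L
      if (mid_in == inside_is_hi) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (bi[1L] == 1L) values[1L] else
    bisect_edge(values[bi[1L] - 1L], values[bi[1L]], inside_is_hi = TRUE)
  last <- bi[length(bi)]
  upper <- if (last == length(values)) values[length(values)] else
    bisect_edge(values[last], values[last + 1L], inside_is_hi = FALSE)
  list(lower = lower, upper = upper, hill_n = params[["hill_n"]])
}

#' @export
print.meio_branch <- function(x, ...) {
  cat("Equilibrium branch over ", attr(x, "parameter"), ": ",
      length(unique(x$parameter_value)), " parameter values, ",
      nrow(x), " equilibria (", sum(x$stability == "stable"), " stable)\n",
      sep = "")
  invisible(x)
}

#' @export
plot.meio_branch <- function(x, variable = "ime2", log = "x", ...) {
  st <- x$stability == "stable"
  graphics::plot(x$parameter_value, x[[variable]], log = log, type = "n",
                 xlab = attr(x, "parameter"), ylab = paste(variable, "*"), ...)
  graphics::points(x$parameter_value[st], x[[variable]][st],
                   pch = 16, col = "red")
  graphics::points(x$parameter_value[!st], x[[variable]][!st],
                   pch = 1, col = "black")
  graphics::legend("topleft", legend = c("stable", "unstable"),
                   pch = c(16, 1), col = c("red", "black"), bty = "n")
  invisible(x)
}
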