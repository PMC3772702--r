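# canonical ordering used everywhere: rates first, then half-max constants,
# then the Hill coefficient
.param_names <- c(
  "s_ime1", "s_ime2", "s2_ime2",
  "d_ime1", "d2_ime1", "d_pime1", "d_ime2",
  "p_rim11", "u_rim11", "p_ume6", "u_ume6", "p_sok2", "u_sok2", "p_ime1",
  "c_sok2", "c_ime1", "c1", "c2", "c3",
  "hill_n"
)

# the four half-maximum constants that may take the value Inf (analytic limit)
.inf_capable <- c("c_ime1", "c_sok2", "c1", "c2")

.state_names <- c("rim11", "pume6", "psok2", "ime1", "pime1", "ime2")

#' Baseline kinetic parameters of the meiotic-initiation model
#'
#' Returns the baseline parameter set of the model: 19 kinetic constants
#' (synthesis, degradation, phosphorylation and dephosphorylation rates in
#' units of per hour, plus five dimensionless half-maximum constants) and the
#' Hill coefficient `hill_n` of Ime2 auto-regulation (default 5).
#'
#' Rates: `s_ime1`, `s_ime2` are synthesis rates of Ime1 and Ime2; `s2_ime2`
#' is the maximum rate of auto-regulation-dependent Ime2 synthesis; `d_ime1`,
#' `d_pime1`, `d_ime2` are basal degradation rates; `d2_ime1` is the maximum
#' Ime2-activated Ime1 degradation rate; `p_*`/`u_*` are phosphorylation and
#' dephosphorylation rates. Constants: `c_sok2` (half-maximum inhibition of
#' Sok2 phosphorylation by Ime1), `c_ime1` (half-maximum inhibition of Ime1
#' synthesis by pSok2), `c1` (half-maximum activation of Ime1 degradation by
#' Ime2), `c2` (half-maximum activation of Ime2 auto-regulation), `c3`
#' (half-maximum activation of Ime2 degradation).
#'
#' @param hill_n positive odd integer Hill coefficient of Ime2
#'   auto-regulation; the default 5 encodes the strong cooperativity of the
#'   auto-regulatory loop (which stands in for several interactions converging
#'   on Ime2).
#' @return a named numeric vector of class `meio_params` with the 19 kinetic
#'   constants plus `hill_n`.
#' @examples
#' p <- default_parameters()
#' p[["d_ime2"]]  # 8 per hour, from the ~5-minute Ime2 half-life
#' @export
default_parameters <- function(hill_n = 5) {
  p <- c(
    s_ime1 = 10, s_ime2 = 10, s2_ime2 = 3,
    d_ime1 = 1, d2_ime1 = 1, d_pime1 = 1, d_ime2 = 8,
    p_rim11 = 0.01, u_rim11 = 0.1,
    p_ume6 = 0.3, u_ume6 = 0.01,
    p_sok2 = 0.7, u_sok2 = 1,
    p_ime1 = 2,
    c_sok2 = 0.05, c_ime1 = 0.01, c1 = 0.01, c2 = 1.4, c3 = 2,
    hill_n = hill_n
  )
  validate_parameters(p)
}

#' Validate a parameter vector
#'
#' Checks names, non-negativity, that only the four limit-capable constants
#' (`c_ime1`, `c_sok2`, `c1`, `c2`) are infinite, and that `hill_n` is a
#' positive odd integer.
#'
#' @param p named numeric vector with the entries of [default_parameters()].
#' @return `p`, with class `meio_params`, invisibly usable downstream.
#' @export
validate_parameters <- function(p) {
  p <- unclass(p)
  if (!is.numeric(p)) stop("parameters must be numeric", call. = FALSE)
  missing <- setdiff(.param_names, names(p))
  if (length(missing) > 0)
    stop("missing parameters: ", paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(p), .param_names)
  if (length(extra) > 0)
    stop("unknown parameters: ", paste(extra, collapse = ", "), call. = FALSE)
  p <- p[.param_names]
  if (any(is.na(p))) stop("parameters must not be NA/NaN", call. = FALSE)
  if (any(p < 0)) stop("parameters must be non-negative", call. = FALSE)
  inf_bad <- names(p)[is.infinite(p) & !names(p) %in% .inf_capable]
  if (length(inf_bad) > 0)
    stop("only ", paste(.inf_capable, collapse = ", "),
         " may be infinite; got infinite ", paste(inf_bad, collapse = ", "),
         call. = FALSE)
  n <- p[["hill_n"]]
  if (!is.finite(n) || n <= 0 || n != round(n) || n %% 2 != 1)
    stop("hill_n must be a positive odd integer", call. = FALSE)
  structure(p, class = "meio_params")
}

#' Convert an exponential-decay half-life to a first-order rate
#'
#' Degradation in the model is first order, so a measured half-life `t½`
#' maps to the rate `ln(2)/t½`. The Table of baseline rates uses rounded
#' literature-derived values; this helper returns the exact conversion.
#'
#' @param half_life half-life in hours; must be positive.
#' @return degradation rate in per hour.
#' @examples
#' rate_from_half_life(1)       # ~0.693/h
#' rate_from_half_life(5 / 60)  # ~8.3/h; the 5-min Ime2 half-life, rounded
#'                              # to the baseline 8/h
#' @export
rate_from_half_life <- function(half_life) {
  if (!is.numeric(half_life) || length(half_life) != 1L ||
      !is.finite(half_life) || half_life <= 0)
    stop("half_life must be a single positive number (hours)", call. = FALSE)
  log(2) / half_life
}

#' Mitotic (pre-sporulation) initial condition
#'
#' All variables are zero except the repressive phosphorylated Sok2 pool,
#' which starts at its maximum of one: meiosis-specific proteins are absent
#' during vegetative growth while Sok2 is fully active as a repressor.
#'
#' @return named state vector (`rim11`, `pume6`, `psok2`, `ime1`, `pime1`,
#'   `ime2`), dimensionless relative protein levels.
#' @export
mitotic_initial_state <- function() {
  c(rim11 = 0, pume6 = 0, psok2 = 1, ime1 = 0, pime1 = 0, ime2 = 0)
}

# validate a state vector: named or positional, correct length, finite,
# fractions in [0,1], amounts >= 0 (small integrator undershoot clamped)
validate_state <- function(y, clamp_tol = 1e-9) {
  if (length(y) != 6L) stop("state must have 6 components", call. = FALSE)
  if (!is.null(names(y)) && !identical(names(y), .state_names)) {
    if (!all(.state_names %in% names(y)))
      stop("state names must be ", paste(.state_names, collapse = ", "),
           call. = FALSE)
    y <- y[.state_names]
  }
  names(y) <- .state_names
  if (any(!is.finite(y))) stop("state must be finite", call. = FALSE)
  if (any(y < -clamp_tol))
    stop("negative state component(s): ",
         paste(.state_names[y < -clamp_tol], collapse = ", "), call. = FALSE)
  pmax(y, 0)
}

#' Read or write a parameter file
#'
#' Parameter sets are stored as a flat key-value JSON or YAML file keyed by
#' the ASCII parameter names (`s_ime1`, `s2_ime2`, `d2_ime1`, ..., `hill_n`).
#' The string `"inf"` (any case, or `".inf"`) is accepted for the four
#' limit-capable constants `c_ime1`, `c_sok2`, `c1`, `c2`.
#'
#' @param path file path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return `read_parameters`: a validated `meio_params` vector.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  vals <- vapply(raw, function(v) {
    if (is.character(v)) {
      if (grepl("^\\.?inf(inity)?$", tolower(v))) Inf
      else suppressWarnings(as.numeric(v))
    } else as.numeric(v)
  }, numeric(1))
  validate_parameters(vals)
}

#' @rdname read_parameters
#' @param p parameter vector to write.
#' @export
write_parameters <- function(p, path) {
  p <- validate_parameters(p)
  out <- as.list(unclass(p))
  out[vapply(out, is.infinite, TRUE)] <- "inf"
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' @export
print.meio_params <- function(x, ...) {
  cat("Meiotic-initiation model parameters (rates per hour)\n")
  print(structure(unclass(x), class = NULL))
  invisible(x)
}
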