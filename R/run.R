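#' Write tabular artifacts
#'
#' Trajectories, equilibrium branches and key-value summaries are written as
#' tab-separated text with a header row.
#'
#' @param x object to write (`meio_traj`, `meio_branch`, or a named list for
#'   key-value output).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  if (is.data.frame(x)) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (is.matrix(x)) {
    utils::write.table(data.frame(parameter = rownames(x), x,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    kv <- data.frame(key = names(x),
                     value = vapply(x, function(v)
                       paste(format(v, digits = 12), collapse = ","), ""))
    utils::write.table(kv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

.experiments <- c("simulate", "knockout", "feedback", "scan", "pka_scan",
                  "mpsa", "validate")

# fill defaults and validate a run configuration; errors here occur before
# any artifact is written
.check_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config, call. = FALSE)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a file path", call. = FALSE)
  if (is.null(config$experiment) || !config$experiment %in% .experiments)
    stop("config$experiment must be one of ",
         paste(.experiments, collapse = ", "), call. = FALSE)
  defaults <- list(t_end = 24, n_points = 961L, seed = 1L,
                   hill_n = NULL, knockout = character(),
                   feedback = list(), override = list(),
                   n_samples = 1000L, range_factor = 10,
                   param = "c2", range = c(0.1, 2), n_steps = 25L,
                   scale_range = c(0.001, 2),
                   sigma = 0.2, a = 1, b = 0.1, screen_file = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (config$experiment == "knockout" && is.null(config$gene))
    stop("knockout experiment needs config$gene", call. = FALSE)
  if (config$experiment == "feedback" &&
      (is.null(config$loop) || is.null(config$mode)))
    stop("feedback experiment needs config$loop and config$mode", call. = FALSE)
  config
}

# assemble params and variant from a validated config (also validates names)
.config_model <- function(config) {
  params <- default_parameters()
  if (!is.null(config$hill_n))
    params <- validate_parameters(.set_param(params, "hill_n", config$hill_n))
  variant <- model_variant(knockouts = config$knockout,
                           feedback = config$feedback,
                           overrides = config$override)
  if (config$experiment == "knockout") variant <- knockout(variant, config$gene)
  if (config$experiment == "feedback") {
    arm <- if (is.null(config$arm)) "both" else config$arm
    variant <- set_feedback(variant, config$loop, config$mode, arm = arm)
  }
  list(params = params, variant = variant)
}

#' Run a configured experiment
#'
#' Executes one of the package's experiment kinds — `simulate`, `knockout`,
#' `feedback` (time courses), `scan`, `pka_scan` (equilibrium branches plus
#' bistable interval), `mpsa` (global sensitivity) or `validate` (synthetic
#' screen correlation) — and writes its TSV artifacts plus a provenance
#' sidecar (resolved parameters, seed, package version) to `out_dir`.
#' Deterministic given the seed. The configuration is fully validated before
#' anything is written, so a malformed config produces no partial outputs.
#'
#' @param config named list, or path to a YAML/JSON file mirroring the list.
#'   Fields: `experiment` (required), and depending on the kind: `gene`,
#'   `loop`/`mode`/`arm`, `param`/`range`/`n_steps`, `scale_range`,
#'   `n_samples`/`range_factor`, `sigma`/`a`/`b`/`screen_file`, plus common
#'   `t_end`, `n_points`, `hill_n`, `knockout`, `feedback`, `override`,
#'   `seed`.
#' @param out_dir output directory, created if needed.
#' @return invisible character vector of written file paths.
#' @export
run_experiment <- function(config, out_dir) {
  config <- .check_config(config)
  mdl <- .config_model(config)
  params <- mdl$params; variant <- mdl$variant
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    write_tsv(x, p)
    written <<- c(written, p)
  }

  kind <- config$experiment
  if (kind %in% c("simulate", "knockout", "feedback")) {
    traj <- integrate_model(variant, params, t_end = config$t_end,
                            n_points = config$n_points)
    emit(traj, "trajectory.tsv")
    feats <- list()
    for (v in .state_names) {
      f <- transient_features(traj, v)
      for (nm in setdiff(names(f), "diverged"))
        feats[[paste(v, nm, sep = ".")]] <- f[[nm]]
    }
    emit(feats, "features.tsv")
    ss <- find_steady_state(variant, params)
    emit(c(as.list(ss$state), converged = ss$converged,
           diverged = ss$diverged), "steady_state.tsv")
  } else if (kind == "scan") {
    br <- scan_1d(variant, params, config$param, config$range,
                  n_steps = config$n_steps)
    emit(br, "branch.tsv")
    bi <- bistable_interval(variant, params, config$param, config$range,
                            n_steps = config$n_steps)
    emit(if (is.null(bi)) list(bistable = FALSE)
         else c(bistable = TRUE, bi), "bistable_interval.tsv")
  } else if (kind == "pka_scan") {
    br <- scan_coupled_pka(variant, params, config$scale_range,
                           n_steps = config$n_steps)
    emit(br, "branch.tsv")
  } else if (kind == "mpsa") {
    rep <- run_mpsa(variant, params, n_samples = config$n_samples,
                    range_factor = config$range_factor, seed = config$seed)
    emit(rep$sensitivity, "sensitivity.tsv")
    emit(list(n_samples = rep$n_samples, range_factor = rep$range_factor,
              seed = rep$seed, t_end = rep$t_end, n_grid = rep$n_grid),
         "mpsa_meta.tsv")
  } else if (kind == "validate") {
    panel <- genotype_panel(params)
    emit(panel, "panel.tsv")
    screen <- if (!is.null(config$screen_file)) read_screen(config$screen_file)
      else synth_screen(panel, a = config$a, b = config$b,
                        sigma = config$sigma, seed = config$seed)
    emit(screen, "screen.tsv")
    val <- validate_against(screen, panel)
    emit(list(r = val$r, p = val$p, meets_reported = val$meets_reported),
         "correlation.tsv")
  }

  prov <- c(list(experiment = kind, seed = config$seed,
                 package_version = as.character(utils::packageVersion("meioticODE")),
                 knockouts = paste(variant$knockouts, collapse = ",")),
            as.list(unclass(resolve_variant(variant, params)$params)))
  emit(prov, "provenance.tsv")
  invisible(written)
}

#' Summarize the artifacts of a run directory
#'
#' Produces a short human-readable summary of whatever artifacts a
#' [run_experiment()] call left in a directory: steady states, peak
#' features, bistable intervals, top sensitivities, validation correlation.
#'
#' @param dir run output directory.
#' @return the summary lines, invisibly; also printed.
#' @export
report_run <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  lines <- character()
  kv <- function(f) {
    d <- utils::read.delim(file.path(dir, f), stringsAsFactors = FALSE)
    stats::setNames(d$value, d$key)
  }
  have <- function(f) file.exists(file.path(dir, f))

  if (have("steady_state.tsv")) {
    ss <- kv("steady_state.tsv")
    lines <- c(lines, "Steady state:",
               paste(" ", paste(names(ss)[1:6],
                                signif(as.numeric(ss[1:6]), 3),
                                sep = "=", collapse = ", ")))
  }
  if (have("features.tsv")) {
    f <- kv("features.tsv")
    pt <- suppressWarnings(as.numeric(f["ime1.peak_time"]))
    if (is.finite(pt))
      lines <- c(lines, sprintf("Ime1 peak at %.2f h (value %.3f)",
                                pt, as.numeric(f["ime1.peak_value"])))
  }
  if (have("bistable_interval.tsv")) {
    b <- kv("bistable_interval.tsv")
    lines <- c(lines, if (identical(b[["bistable"]], "TRUE"))
      sprintf("Bistable interval: [%.3f, %.3f]",
              as.numeric(b[["lower"]]), as.numeric(b[["upper"]]))
      else "No bistable interval on the scanned range")
  }
  if (have("branch.tsv")) {
    br <- utils::read.delim(file.path(dir, "branch.tsv"))
    lines <- c(lines, sprintf("Branch: %d equilibria (%d stable) over %d values",
                              nrow(br), sum(br$stability == "stable"),
                              length(unique(br$parameter_value))))
  }
  if (have("sensitivity.tsv")) {
    s <- utils::read.delim(file.path(dir, "sensitivity.tsv"),
                           check.names = FALSE)
    lines <- c(lines, "Top-3 sensitivities per variable:")
    for (v in .state_names) {
      o <- order(-s[[v]])[1:3]
      lines <- c(lines, sprintf("  %-6s %s", v,
                                paste(s$parameter[o],
                                      sprintf("(%.2f)", s[[v]][o]),
                                      collapse = " ")))
    }
  }
  if (have("correlation.tsv")) {
    cr <- kv("correlation.tsv")
    lines <- c(lines, sprintf("Validation: Pearson r = %.3f, p = %.3g",
                              as.numeric(cr[["r"]]), as.numeric(cr[["p"]])))
  }
  if (length(lines) == 0L) lines <- "no artifacts found"
  cat(lines, sep = "\n")
  invisible(lines)
}
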