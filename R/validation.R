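.genotypes <- c("WT", "rim11", "ume6", "sok2", "ime1", "ime2")

#' Steady-state Ime2 across the knockout genotype panel
#'
#' Runs the steady-state solver for the wild type and each of the five
#' single-gene deletions from the mitotic initial state and collects the
#' Ime2 readout — the most downstream protein, used as the model's proxy
#' for sporulation efficiency. Deletions of the sporulation-deficient genes
#' (`rim11`, `ume6`, `ime1`, `ime2`) give Ime2 = 0; the `sok2` deletion
#' (sporulation-proficient) gives Ime2 above wild type.
#'
#' @param params a `meio_params` vector.
#' @return object of class `meio_panel`: data frame with columns `genotype`
#'   (`WT`, `rim11`, `ume6`, `sok2`, `ime1`, `ime2`) and `ime2_steady`.
#' @export
genotype_panel <- function(params = default_parameters()) {
  variants <- c(list(wild_type()),
                lapply(toupper(.genotypes[-1L]),
                       function(g) knockout(wild_type(), g)))
  ime2 <- vapply(variants, function(v)
    find_steady_state(v, params)$state[["ime2"]], 0)
  panel <- data.frame(genotype = .genotypes, ime2_steady = ime2)
  class(panel) <- c("meio_panel", "data.frame")
  panel
}

#' Synthetic sporulation-efficiency screen
#'
#' Generates a synthetic stand-in for an experimental deletion-screen table
#' of sporulation/pre-sporulation ratios, one positive ratio per genotype,
#' monotonically linked to simulated steady-state Ime2 through an affine
#' link with multiplicative lognormal noise:
#' `ratio = (a * Ime2 + b) * exp(eps)`, `eps ~ Normal(0, sigma^2)`.
#' Multiplicative noise keeps ratios positive, matching the fold-type
#' nature of the experimental quantity. With `sigma = 0` the ratios are an
#' exact monotone transform of the panel.
#'
#' @param panel a `meio_panel` from [genotype_panel()].
#' @param a positive link scale.
#' @param b non-negative link offset (keeps zero-Ime2 genotypes at a
#'   positive baseline ratio).
#' @param sigma lognormal noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return data frame with columns `genotype` and `ratio`; generator
#'   settings stored as attributes.
#' @export
synth_screen <- function(panel, a = 1, b = 0.1, sigma = 0.2, seed = 1L) {
  stopifnot(inherits(panel, "meio_panel"))
  if (!is.numeric(a) || a <= 0) stop("a must be positive", call. = FALSE)
  if (!is.numeric(b) || b < 0) stop("b must be non-negative", call. = FALSE)
  if (!is.numeric(sigma) || is.na(sigma) || sigma < 0)
    stop("sigma must be a non-negative number", call. = FALSE)
  set.seed(seed)
  eps <- stats::rnorm(nrow(panel), 0, sigma)
  screen <- data.frame(genotype = panel$genotype,
                       ratio = (a * panel$ime2_steady + b) * exp(eps))
  attr(screen, "settings") <- list(a = a, b = b, sigma = sigma, seed = seed)
  screen
}

#' Pearson correlation with t-test p-value
#'
#' Product-moment correlation between two sequences with the two-sided
#' p-value from the t-transform on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return list with `r` and `p`.
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))$r  # 0.6
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Correlate a screen table with the simulated genotype panel
#'
#' Joins a (synthetic or experimental) sporulation/pre-sporulation ratio
#' table with simulated steady-state Ime2 by genotype id and reports the
#' Pearson correlation, its p-value, and whether the correlation reaches
#' the strength reported against the published deletion screen
#' (r >= 0.85, p <= 0.05) — meaningful only when real screen data are
#' supplied.
#'
#' @param screen data frame with columns `genotype` and `ratio` covering all
#'   six genotypes (e.g. from [synth_screen()] or [read_screen()]).
#' @param panel a `meio_panel`.
#' @return list with `r`, `p`, `meets_reported` and the joined `table`.
#' @export
validate_against <- function(screen, panel) {
  stopifnot(inherits(panel, "meio_panel"))
  if (!all(c("genotype", "ratio") %in% names(screen)))
    stop("screen must have columns genotype, ratio", call. = FALSE)
  missing <- setdiff(panel$genotype, screen$genotype)
  if (length(missing) > 0)
    stop("screen is missing genotypes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  joined <- merge(panel, screen, by = "genotype")
  cr <- pearson_cor(joined$ime2_steady, joined$ratio)
  list(r = cr$r, p = cr$p,
       meets_reported = cr$r >= 0.85 && cr$p <= 0.05,
       table = joined)
}

#' Read an experimental screen table
#'
#' Loads a two-column TSV (`genotype`, `ratio`) of experimental
#' sporulation/pre-sporulation ratios, so a comparison against real
#' deletion-screen data is one [validate_against()] call for users who have
#' the external dataset.
#'
#' @param path path to a tab-separated file with a header row.
#' @return data frame with columns `genotype` and `ratio`.
#' @export
read_screen <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  screen <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("genotype", "ratio") %in% names(screen)))
    stop("screen file must have columns genotype, ratio", call. = FALSE)
  if (any(!is.finite(screen$ratio)) || any(screen$ratio <= 0))
    stop("ratios must be positive numbers", call. = FALSE)
  screen
}
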