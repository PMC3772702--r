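.genes <- c("RIM11", "UME6", "SOK2", "IME1", "IME2")
.loops <- c("SOK2_IME1_double_negative", "IME2_IME1_negative",
            "IME2_auto_positive")
.modes <- c("baseline", "increased", "decreased", "deleted")

# figure-legend parameter values realizing each feedback mode, per loop arm
.feedback_values <- list(
  SOK2_IME1_double_negative = list(
    c_ime1 = c(increased = 0.001, decreased = 0.1, deleted = Inf),
    c_sok2 = c(increased = 0.005, decreased = 0.5, deleted = Inf)
  ),
  IME2_IME1_negative = list(
    d2_ime1 = c(increased = 10, decreased = 0.1, deleted = 0),
    c1      = c(increased = 0.001, decreased = 0.1, deleted = Inf)
  ),
  IME2_auto_positive = list(
    s2_ime2 = c(increased = 30, decreased = 0.3, deleted = 0),
    c2      = c(increased = 0.14, decreased = 14, deleted = Inf)
  )
)

#' Construct a model variant
#'
#' A variant is a structural edit of the wild-type model: a set of knocked-out
#' genes, feedback-loop modes, and explicit parameter overrides. The wild type
#' is the empty variant. Variants are built incrementally with [knockout()],
#' [set_feedback()] and [override_param()].
#'
#' @param knockouts character vector of gene ids among
#'   `RIM11, UME6, SOK2, IME1, IME2`.
#' @param feedback named list mapping loop ids
#'   (`SOK2_IME1_double_negative`, `IME2_IME1_negative`, `IME2_auto_positive`)
#'   to a mode (`baseline`, `increased`, `decreased`, `deleted`), or to a list
#'   `list(mode =, arm =)` to address one arm of a loop.
#' @param overrides named list of explicit parameter overrides (values may be
#'   `Inf` for the limit-capable constants).
#' @return object of class `meio_variant`.
#' @examples
#' wild_type()
#' knockout(wild_type(), "SOK2")
#' set_feedback(wild_type(), "IME2_auto_positive", "increased")
#' @export
model_variant <- function(knockouts = character(), feedback = list(),
                          overrides = list()) {
  v <- structure(
    list(knockouts = character(), feedback = list(), overrides = list()),
    class = "meio_variant"
  )
  for (g in knockouts) v <- knockout(v, g)
  for (loop in names(feedback)) {
    f <- feedback[[loop]]
    if (is.list(f)) {
      v <- set_feedback(v, loop, f$mode, arm = if (is.null(f$arm)) "both" else f$arm)
    } else {
      v <- set_feedback(v, loop, f)
    }
  }
  for (nm in names(overrides)) v <- override_param(v, nm, overrides[[nm]])
  v
}

#' @rdname model_variant
#' @export
wild_type <- function() model_variant()

#' Knock a gene out of the model
#'
#' A deletion removes the gene product permanently: the protein's variables
#' are clamped to zero (with zero derivative) and its synthesis terms are
#' removed. `RIM11`, `UME6`, `SOK2` clamp the corresponding pool fraction;
#' `IME1` zeroes `s_ime1` and clamps both Ime1 forms; `IME2` zeroes `s_ime2`
#' and `s2_ime2` and clamps Ime2.
#'
#' @param variant a `meio_variant`.
#' @param gene one of `RIM11, UME6, SOK2, IME1, IME2` (case-insensitive).
#' @return the edited variant.
#' @export
knockout <- function(variant, gene) {
  stopifnot(inherits(variant, "meio_variant"))
  gene <- toupper(gene)
  if (length(gene) != 1L || !gene %in% .genes)
    stop("unknown gene: must be one of ", paste(.genes, collapse = ", "),
         call. = FALSE)
  variant$knockouts <- union(variant$knockouts, gene)
  variant
}

#' Set a feedback-loop mode
#'
#' Applies the parameter values that up-regulate, down-regulate or delete one
#' of the three feedback loops (mutual inhibition between pSok2 and Ime1;
#' negative feedback from Ime2 to Ime1 via degradation; positive
#' auto-regulation of Ime2). The values are those used in the perturbation
#' experiments: e.g. the double-negative loop deleted sets
#' `c_ime1 = Inf, c_sok2 = Inf`; increased sets `c_ime1 = 0.001,
#' c_sok2 = 0.005`. Each loop has two addressable arms
#' (e.g. `c_ime1` vs `c_sok2`), selectable via `arm`.
#'
#' @param variant a `meio_variant`.
#' @param loop loop id, one of `SOK2_IME1_double_negative`,
#'   `IME2_IME1_negative`, `IME2_auto_positive`.
#' @param mode `baseline`, `increased`, `decreased` or `deleted`.
#' @param arm `"both"` (default) or the name of a single parameter arm of the
#'   loop (e.g. `"c_ime1"`).
#' @return the edited variant; conflicting explicit overrides of the same
#'   parameter raise an error.
#' @export
set_feedback <- function(variant, loop, mode, arm = "both") {
  stopifnot(inherits(variant, "meio_variant"))
  if (!loop %in% .loops)
    stop("unknown loop: must be one of ", paste(.loops, collapse = ", "),
         call. = FALSE)
  if (!mode %in% .modes)
    stop("unknown mode: must be one of ", paste(.modes, collapse = ", "),
         call. = FALSE)
  arms <- .feedback_values[[loop]]
  use <- if (identical(arm, "both")) names(arms) else arm
  if (!all(use %in% names(arms)))
    stop("loop ", loop, " has arms ", paste(names(arms), collapse = ", "),
         call. = FALSE)
  variant$feedback[[loop]] <- list(mode = mode, arm = arm)
  if (mode == "baseline") return(variant)
  for (pn in use) {
    val <- arms[[pn]][[mode]]
    if (pn %in% names(variant$overrides) &&
        !isTRUE(variant$overrides[[pn]] == val))
      stop("conflicting override of ", pn, ": already set to ",
           variant$overrides[[pn]], call. = FALSE)
    variant$overrides[[pn]] <- val
  }
  variant
}

#' Override a single parameter in a variant
#'
#' Records an explicit parameter override; later overrides of the same
#' parameter shadow earlier ones. `Inf` is allowed for the limit-capable
#' half-maximum constants and is evaluated as the analytic limit of the
#' corresponding regulatory term.
#'
#' @param variant a `meio_variant`.
#' @param name parameter name (see [default_parameters()]).
#' @param value non-negative number, or `Inf` where allowed.
#' @return the edited variant.
#' @export
override_param <- function(variant, name, value) {
  stopifnot(inherits(variant, "meio_variant"))
  if (!name %in% .param_names)
    stop("unknown parameter: ", name, call. = FALSE)
  if (is.character(value) && grepl("^\\.?inf(inity)?$", tolower(value)))
    value <- Inf
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value < 0)
    stop("override value must be a single non-negative number", call. = FALSE)
  if (is.infinite(value) && !name %in% .inf_capable)
    stop(name, " cannot be infinite", call. = FALSE)
  variant$overrides[[name]] <- value
  variant
}

#' Resolve a variant against a parameter set
#'
#' Applies knockout synthesis edits and overrides to the parameter vector and
#' computes which state variables are clamped to zero. Internal workhorse
#' shared by the right-hand side, Jacobian and all downstream analyses.
#'
#' @param variant a `meio_variant`.
#' @param params a `meio_params` vector.
#' @return list with `params` (edited numeric vector) and `clamped`
#'   (named logical over the six state variables).
#' @keywords internal
#' @export
resolve_variant <- function(variant, params) {
  stopifnot(inherits(variant, "meio_variant"))
  p <- unclass(validate_parameters(params))
  clamped <- stats::setNames(rep(FALSE, 6L), .state_names)
  for (nm in names(variant$overrides)) p[[nm]] <- variant$overrides[[nm]]
  for (g in variant$knockouts) {
    switch(g,
      RIM11 = clamped["rim11"] <- TRUE,
      UME6  = clamped["pume6"] <- TRUE,
      SOK2  = clamped["psok2"] <- TRUE,
      IME1  = { p[["s_ime1"]] <- 0; clamped[c("ime1", "pime1")] <- TRUE },
      IME2  = { p[["s_ime2"]] <- 0; p[["s2_ime2"]] <- 0
                clamped["ime2"] <- TRUE }
    )
  }
  if (any(p < 0) || any(is.na(p)))
    stop("resolved parameters invalid", call. = FALSE)
  list(params = p, clamped = clamped)
}

#' @export
print.meio_variant <- function(x, ...) {
  if (length(x$knockouts) == 0 && length(x$overrides) == 0) {
    cat("Model variant: wild type\n")
    return(invisible(x))
  }
  cat("Model variant\n")
  if (length(x$knockouts) > 0)
    cat("  knockouts:", paste(x$knockouts, collapse = ", "), "\n")
  for (loop in names(x$feedback))
    cat("  feedback:", loop, "->", x$feedback[[loop]]$mode,
        if (!identical(x$feedback[[loop]]$arm, "both"))
          paste0("(arm ", x$feedback[[loop]]$arm, ")") else "", "\n")
  if (length(x$overrides) > 0)
    cat("  overrides:",
        paste(names(x$overrides), unlist(x$overrides), sep = "=",
              collapse = ", "), "\n")
  invisible(x)
}
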