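# Internal right-hand side on a resolved variant. `y` is the unnamed state
# in canonical order, `rp` the list from resolve_variant(). Infinite
# half-maximum constants are evaluated as their analytic limits:
#   c_ime1 = Inf => c_ime1/(c_ime1+pSok2) -> 1   (inhibition removed)
#   c_sok2 = Inf => c_sok2/(c_sok2+Ime1)  -> 1
#   c1     = Inf => Ime1/(c1+Ime1)        -> 0   (Ime2-activated decay off)
#   c2     = Inf => Ime2^n/(c2^n+Ime2^n)  -> 0   (auto-regulation off)
rhs_resolved <- function(y, rp) {
  p <- rp$params
  y[rp$clamped] <- 0
  rim11 <- y[1L]; pume6 <- y[2L]; psok2 <- y[3L]
  ime1 <- y[4L]; pime1 <- y[5L]; ime2 <- y[6L]
  n <- p[["hill_n"]]

  f_sok2 <- if (is.finite(p[["c_sok2"]])) p[["c_sok2"]] / (p[["c_sok2"]] + ime1) else 1
  f_ime1 <- if (is.finite(p[["c_ime1"]])) p[["c_ime1"]] / (p[["c_ime1"]] + psok2) else 1
  f_c1   <- if (is.finite(p[["c1"]]))     ime1 / (p[["c1"]] + ime1)               else 0
  f_c2   <- if (is.finite(p[["c2"]])) {
    if (ime2 > 0) ime2^n / (p[["c2"]]^n + ime2^n) else 0
  } else 0

  d <- c(
    p[["u_rim11"]] * (1 - rim11) - p[["p_rim11"]] * rim11,
    p[["p_ume6"]] * rim11 * (1 - pume6) - p[["u_ume6"]] * pume6,
    p[["p_sok2"]] * f_sok2 * (1 - psok2) - p[["u_sok2"]] * psok2,
    p[["s_ime1"]] * f_ime1 - p[["p_ime1"]] * rim11 * ime1 -
      p[["d_ime1"]] * ime1 - p[["d2_ime1"]] * ime2 * f_c1,
    p[["p_ime1"]] * rim11 * ime1 - p[["d_pime1"]] * pime1,
    p[["s_ime2"]] * pume6 * pime1 + p[["s2_ime2"]] * f_c2 -
      p[["d_ime2"]] * ime2 / (p[["c3"]] + ime2)
  )
  d[rp$clamped] <- 0
  d
}

# Analytic Jacobian of rhs_resolved. Rows/columns of clamped variables are 0.
jac_resolved <- function(y, rp) {
  p <- rp$params
  y[rp$clamped] <- 0
  rim11 <- y[1L]; pume6 <- y[2L]; psok2 <- y[3L]
  ime1 <- y[4L]; pime1 <- y[5L]; ime2 <- y[6L]
  n <- p[["hill_n"]]
  J <- matrix(0, 6L, 6L, dimnames = list(.state_names, .state_names))

  J[1L, 1L] <- -(p[["u_rim11"]] + p[["p_rim11"]])

  J[2L, 1L] <- p[["p_ume6"]] * (1 - pume6)
  J[2L, 2L] <- -(p[["p_ume6"]] * rim11 + p[["u_ume6"]])

  if (is.finite(p[["c_sok2"]])) {
    f_sok2 <- p[["c_sok2"]] / (p[["c_sok2"]] + ime1)
    df_sok2 <- -p[["c_sok2"]] / (p[["c_sok2"]] + ime1)^2
  } else {
    f_sok2 <- 1; df_sok2 <- 0
  }
  J[3L, 3L] <- -(p[["p_sok2"]] * f_sok2 + p[["u_sok2"]])
  J[3L, 4L] <- p[["p_sok2"]] * (1 - psok2) * df_sok2

  if (is.finite(p[["c_ime1"]])) {
    df_ime1 <- -p[["c_ime1"]] / (p[["c_ime1"]] + psok2)^2
  } else df_ime1 <- 0
  if (is.finite(p[["c1"]])) {
    f_c1 <- ime1 / (p[["c1"]] + ime1)
    df_c1 <- p[["c1"]] / (p[["c1"]] + ime1)^2
  } else {
    f_c1 <- 0; df_c1 <- 0
  }
  J[4L, 1L] <- -p[["p_ime1"]] * ime1
  J[4L, 3L] <- p[["s_ime1"]] * df_ime1
  J[4L, 4L] <- -p[["p_ime1"]] * rim11 - p[["d_ime1"]] -
    p[["d2_ime1"]] * ime2 * df_c1
  J[4L, 6L] <- -p[["d2_ime1"]] * f_c1

  J[5L, 1L] <- p[["p_ime1"]] * ime1
  J[5L, 4L] <- p[["p_ime1"]] * rim11
  J[5L, 5L] <- -p[["d_pime1"]]

  J[6L, 2L] <- p[["s_ime2"]] * pime1
  J[6L, 5L] <- p[["s_ime2"]] * pume6
  dhill <- if (is.finite(p[["c2"]])) {
    cn <- p[["c2"]]^n
    if (ime2 > 0) n * cn * ime2^(n - 1) / (cn + ime2^n)^2
    else if (n == 1) 1 / p[["c2"]] else 0
  } else 0
  J[6L, 6L] <- p[["s2_ime2"]] * dhill -
    p[["d_ime2"]] * p[["c3"]] / (p[["c3"]] + ime2)^2

  J[rp$clamped, ] <- 0
  J[, rp$clamped] <- 0
  J
}

#' Time derivatives of the meiotic-initiation model
#'
#' Evaluates the right-hand side of the six coupled ordinary differential
#' equations describing Rim11, pUme6, pSok2, Ime1, pIme1 and Ime2 dynamics:
#' Rim11, Ume6 and Sok2 are conserved one-unit pools that interconvert
#' between phosphorylated and unphosphorylated forms; Ime1 is synthesized
#' under inhibitory Hill control by pSok2, phosphorylated by Rim11, and
#' degraded both basally and through Ime2-activated (saturating) decay; Ime2
#' is synthesized by pUme6 together with pIme1, amplified by cooperative
#' (Hill) auto-regulation, and degraded in a density-dependent manner.
#'
#' @param state state vector (see [mitotic_initial_state()]); components must
#'   be finite and non-negative (values above `-1e-9`, as produced by
#'   adaptive integrators, are clamped to zero).
#' @param params a `meio_params` vector; default [default_parameters()].
#' @param variant a `meio_variant`; default [wild_type()].
#' @return named derivative vector, units per hour.
#' @examples
#' meiosis_rhs(mitotic_initial_state())
#' @export
meiosis_rhs <- function(state, params = default_parameters(),
                        variant = wild_type()) {
  y <- validate_state(state)
  rp <- resolve_variant(variant, params)
  stats::setNames(rhs_resolved(as.numeric(y), rp), .state_names)
}

#' Analytic Jacobian of the model right-hand side
#'
#' Partial derivatives of [meiosis_rhs()] with respect to the state, used for
#' stability classification of equilibria and Newton polishing of steady
#' states. Agrees with central finite differences to relative tolerance
#' `1e-5` on admissible states.
#'
#' @inheritParams meiosis_rhs
#' @return 6 x 6 matrix with rows/columns in state order.
#' @export
meiosis_jacobian <- function(state, params = default_parameters(),
                             variant = wild_type()) {
  y <- validate_state(state)
  rp <- resolve_variant(variant, params)
  jac_resolved(as.numeric(y), rp)
}
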