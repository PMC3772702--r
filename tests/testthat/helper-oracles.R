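# independent oracles shared across test files

state_names <- c("rim11", "pume6", "psok2", "ime1", "pime1", "ime2")

# central finite-difference Jacobian of meiosis_rhs
fd_jacobian <- function(state, params = default_parameters(),
                        variant = wild_type(), h = 1e-6) {
  J <- matrix(0, 6, 6)
  for (j in 1:6) {
    e <- rep(0, 6)
    e[j] <- h * max(1, abs(state[j]))
    up <- meiosis_rhs(state + e, params, variant)
    dn <- meiosis_rhs(pmax(state - e, 0), params, variant)
    J[, j] <- (up - dn) / (state[j] + e[j] - max(state[j] - e[j], 0))
  }
  J
}

# hand-written replica of the model equations, kept independent of the
# package internals
rhs_replica <- function(y, p) {
  n <- p[["hill_n"]]
  c(p[["u_rim11"]] * (1 - y[1]) - p[["p_rim11"]] * y[1],
    p[["p_ume6"]] * y[1] * (1 - y[2]) - p[["u_ume6"]] * y[2],
    p[["p_sok2"]] * (p[["c_sok2"]] / (p[["c_sok2"]] + y[4])) * (1 - y[3]) -
      p[["u_sok2"]] * y[3],
    p[["s_ime1"]] * (p[["c_ime1"]] / (p[["c_ime1"]] + y[3])) -
      p[["p_ime1"]] * y[1] * y[4] - p[["d_ime1"]] * y[4] -
      p[["d2_ime1"]] * y[6] * y[4] / (p[["c1"]] + y[4]),
    p[["p_ime1"]] * y[1] * y[4] - p[["d_pime1"]] * y[5],
    p[["s_ime2"]] * y[2] * y[5] +
      p[["s2_ime2"]] * y[6]^n / (p[["c2"]]^n + y[6]^n) -
      p[["d_ime2"]] * y[6] / (p[["c3"]] + y[6]))
}

# reduced-system equilibrium counter: with Rim11, pUme6, pSok2, pIme1 at
# their closed-form quasi-steady values and Ime1 solved from its balance by
# a scalar root find, equilibria of the full system are sign changes of the
# remaining Ime2 residual on a dense log grid
reduced_residual <- function(ime2, p) {
  R <- p[["u_rim11"]] / (p[["u_rim11"]] + p[["p_rim11"]])
  U <- p[["p_ume6"]] * R / (p[["p_ume6"]] * R + p[["u_ume6"]])
  f_ime1 <- function(i1) {
    h <- p[["c_sok2"]] / (p[["c_sok2"]] + i1)
    S <- p[["p_sok2"]] * h / (p[["p_sok2"]] * h + p[["u_sok2"]])
    p[["s_ime1"]] * p[["c_ime1"]] / (p[["c_ime1"]] + S) -
      p[["p_ime1"]] * R * i1 - p[["d_ime1"]] * i1 -
      p[["d2_ime1"]] * ime2 * i1 / (p[["c1"]] + i1)
  }
  i1 <- uniroot(f_ime1, c(0, 60), tol = 1e-13)$root
  pI <- p[["p_ime1"]] * R * i1 / p[["d_pime1"]]
  n <- p[["hill_n"]]
  p[["s_ime2"]] * U * pI + p[["s2_ime2"]] * ime2^n / (p[["c2"]]^n + ime2^n) -
    p[["d_ime2"]] * ime2 / (p[["c3"]] + ime2)
}

count_equilibria_oracle <- function(p, m = 600) {
  grid <- exp(seq(log(1e-4), log(60), length.out = m))
  v <- vapply(grid, reduced_residual, 0, p = p)
  sum(diff(sign(v)) != 0)
}

# random admissible state under a fixed RNG state
random_state <- function() {
  c(runif(3), runif(3, 0, 2))
}

table3_state <- c(rim11 = 0.91, pume6 = 0.96, psok2 = 0.25,
                  ime1 = 0.05, pime1 = 0.10, ime2 = 0.27)
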