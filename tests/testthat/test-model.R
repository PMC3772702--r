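test_that("derivatives vanish (to rounding) at the published steady state", {
  d <- meiosis_rhs(table3_state)
  # the published state is rounded to 2 decimals, so the residual is small
  # but not zero
  expect_true(all(abs(d) <= 0.1))
})

test_that("derivatives at reference states match direct substitution", {
  d0 <- meiosis_rhs(mitotic_initial_state())
  expect_equal(d0[["rim11"]], 0.1)          # u_rim11 * (1 - 0)
  expect_equal(d0[["psok2"]], -1)           # (1 - pSok2) factor is 0 at 1
  expect_equal(d0[["ime2"]], 0)

  z <- meiosis_rhs(rep(0, 6))
  expect_equal(z[["psok2"]], 0.7)           # p_sok2, no Ime1 inhibition
  expect_equal(z[["ime2"]], 0)              # auto-regulation is 0 at Ime2=0
  expect_equal(z[["ime1"]], 10)             # full synthesis, no pSok2
})

test_that("wild-type variant leaves the equations untouched", {
  p <- default_parameters()
  set.seed(7)
  for (i in 1:10) {
    y <- random_state()
    expect_equal(unname(meiosis_rhs(y, p, wild_type())),
                 rhs_replica(y, p), tolerance = 1e-14)
  }
})

test_that("rhs is linear in each synthesis rate", {
  p <- unclass(default_parameters())
  y <- c(0.5, 0.5, 0.3, 0.2, 0.1, 0.4)
  base <- meiosis_rhs(y, validate_parameters(p))
  p2 <- validate_parameters(replace(p, "s_ime1", 2 * p[["s_ime1"]]))
  d2 <- meiosis_rhs(y, p2)
  synth <- p[["s_ime1"]] * p[["c_ime1"]] / (p[["c_ime1"]] + y[3])
  expect_equal(d2[["ime1"]] - base[["ime1"]], synth, tolerance = 1e-12)
})

test_that("rhs rejects invalid states and parameters", {
  expect_error(meiosis_rhs(c(-0.5, 0, 0, 0, 0, 0)), "negative")
  expect_error(meiosis_rhs(c(NA, 0, 0, 0, 0, 0)), "finite")
  p <- unclass(default_parameters())
  expect_error(meiosis_rhs(rep(0, 6), replace(p, "c2", NaN)), "NA")
  # integrator-scale undershoot is clamped, not rejected
  expect_silent(meiosis_rhs(c(-1e-10, 0, 0.5, 0, 0, 0)))
})

test_that("derivatives point inward at the faces of the unit box", {
  p <- default_parameters()
  at <- function(...) {
    y <- c(rim11 = 0.5, pume6 = 0.5, psok2 = 0.5,
           ime1 = 0.2, pime1 = 0.1, ime2 = 0.3)
    y[names(list(...))] <- unlist(list(...))
    meiosis_rhs(y, p)
  }
  expect_gt(at(rim11 = 0)[["rim11"]], 0)
  expect_lt(at(rim11 = 1)[["rim11"]], 0)
  expect_gt(at(pume6 = 0)[["pume6"]], 0)
  expect_lt(at(pume6 = 1)[["pume6"]], 0)
  expect_gt(at(psok2 = 0)[["psok2"]], 0)
  expect_lt(at(psok2 = 1)[["psok2"]], 0)
  # amounts cannot go negative: sources only at zero
  expect_gte(at(ime1 = 0)[["ime1"]], 0)
  expect_gte(at(ime2 = 0)[["ime2"]], 0)
})

test_that("analytic Jacobian matches finite differences on random states", {
  set.seed(11)
  for (i in 1:20) {
    y <- random_state()
    J <- meiosis_jacobian(y)
    Jfd <- fd_jacobian(y)
    scale <- pmax(abs(Jfd), 1)
    expect_lt(max(abs(J - Jfd) / scale), 1e-5)
  }
})

test_that("Jacobian structure follows the equations", {
  J <- meiosis_jacobian(mitotic_initial_state())
  p <- default_parameters()
  expect_equal(J["rim11", "rim11"], -(p[["u_rim11"]] + p[["p_rim11"]]))
  # at the all-zero state the Ime2 synthesis term has no pIme1 leverage
  J0 <- meiosis_jacobian(rep(0, 6))
  expect_equal(J0["ime2", "pime1"], 0)
})

test_that("infinite half-maximum constants evaluate as analytic limits", {
  y <- c(0.5, 0.5, 0.3, 0.2, 0.1, 0.4)
  p <- unclass(default_parameters())
  # c_ime1 = Inf: inhibition of Ime1 synthesis removed entirely
  pi <- validate_parameters(replace(p, "c_ime1", Inf))
  d <- meiosis_rhs(y, pi)
  expect_equal(d[["ime1"]] - meiosis_rhs(y, validate_parameters(p))[["ime1"]],
               p[["s_ime1"]] * (1 - p[["c_ime1"]] / (p[["c_ime1"]] + y[3])),
               tolerance = 1e-12)
  # c1 = Inf: Ime2-activated degradation term is exactly 0
  pc1 <- validate_parameters(replace(p, "c1", Inf))
  expect_equal(meiosis_rhs(y, pc1)[["ime1"]],
               p[["s_ime1"]] * p[["c_ime1"]] / (p[["c_ime1"]] + y[3]) -
                 p[["p_ime1"]] * y[1] * y[4] - p[["d_ime1"]] * y[4],
               tolerance = 1e-12)
  # c2 = Inf: auto-regulation term is exactly 0
  pc2 <- validate_parameters(replace(p, "c2", Inf))
  expect_equal(meiosis_rhs(y, pc2)[["ime2"]],
               p[["s_ime2"]] * y[2] * y[5] - p[["d_ime2"]] * y[6] / (p[["c3"]] + y[6]),
               tolerance = 1e-12)
  # Jacobians stay finite and match finite differences in the limits
  for (q in list(pi, pc1, pc2)) {
    J <- meiosis_jacobian(y, q)
    expect_true(all(is.finite(J)))
    expect_lt(max(abs(J - fd_jacobian(y, q)) / pmax(abs(J), 1)), 1e-5)
  }
})

test_that("integration keeps the state in the admissible box", {
  tr <- integrate_model(t_end = 48, n_points = 481)
  m <- as.matrix(tr[, state_names])
  expect_true(all(m >= -1e-8))
  expect_true(all(m[, 1:3] <= 1 + 1e-8))
})
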