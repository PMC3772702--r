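test_that("knockouts clamp the deleted product and silence its synthesis", {
  rp <- resolve_variant(knockout(wild_type(), "RIM11"), default_parameters())
  expect_true(rp$clamped[["rim11"]])
  rp <- resolve_variant(knockout(wild_type(), "IME1"), default_parameters())
  expect_identical(rp$params[["s_ime1"]], 0)
  expect_true(all(rp$clamped[c("ime1", "pime1")]))
  rp <- resolve_variant(knockout(wild_type(), "IME2"), default_parameters())
  expect_identical(rp$params[["s_ime2"]], 0)
  expect_identical(rp$params[["s2_ime2"]], 0)
  expect_true(rp$clamped[["ime2"]])
  expect_error(knockout(wild_type(), "NDT80"), "unknown gene")
})

test_that("deleting any Ime2 source gene pins ime2 at exactly zero", {
  for (g in c("RIM11", "UME6", "IME1", "IME2")) {
    tr <- integrate_model(knockout(wild_type(), g), t_end = 48,
                          n_points = 97)
    expect_identical(unique(tr$ime2), 0)
    ss <- find_steady_state(knockout(wild_type(), g))
    expect_identical(ss$state[["ime2"]], 0)
  }
})

test_that("feedback modes apply the perturbation-experiment parameter values", {
  p <- default_parameters()
  v <- set_feedback(wild_type(), "SOK2_IME1_double_negative", "deleted")
  rp <- resolve_variant(v, p)
  expect_identical(rp$params[["c_ime1"]], Inf)
  expect_identical(rp$params[["c_sok2"]], Inf)

  v <- set_feedback(wild_type(), "SOK2_IME1_double_negative", "increased")
  rp <- resolve_variant(v, p)
  expect_identical(rp$params[["c_ime1"]], 0.001)
  expect_identical(rp$params[["c_sok2"]], 0.005)

  v <- set_feedback(wild_type(), "IME2_IME1_negative", "decreased")
  rp <- resolve_variant(v, p)
  expect_identical(rp$params[["d2_ime1"]], 0.1)
  expect_identical(rp$params[["c1"]], 0.1)

  v <- set_feedback(wild_type(), "IME2_auto_positive", "increased")
  rp <- resolve_variant(v, p)
  expect_identical(rp$params[["s2_ime2"]], 30)
  expect_identical(rp$params[["c2"]], 0.14)

  # single-arm addressing
  v <- set_feedback(wild_type(), "SOK2_IME1_double_negative", "decreased",
                    arm = "c_ime1")
  rp <- resolve_variant(v, p)
  expect_identical(rp$params[["c_ime1"]], 0.1)
  expect_identical(rp$params[["c_sok2"]], p[["c_sok2"]])

  expect_error(set_feedback(wild_type(), "bogus", "deleted"), "unknown loop")
  expect_error(set_feedback(wild_type(), "IME2_auto_positive", "bogus"),
               "unknown mode")
})

test_that("overrides shadow earlier values and validate their input", {
  v <- override_param(wild_type(), "c2", 0.5)
  v <- override_param(v, "c2", 0.14)
  rp <- resolve_variant(v, default_parameters())
  expect_identical(rp$params[["c2"]], 0.14)
  # equivalent to the increased auto-positive c2 arm
  v2 <- set_feedback(wild_type(), "IME2_auto_positive", "increased",
                     arm = "c2")
  rp2 <- resolve_variant(v2, default_parameters())
  expect_identical(rp$params[["c2"]], rp2$params[["c2"]])

  expect_error(override_param(wild_type(), "bogus", 1), "unknown parameter")
  expect_error(override_param(wild_type(), "c2", -1), "non-negative")
  expect_error(override_param(wild_type(), "d_ime2", Inf), "cannot be infinite")
  # "inf" strings accepted for the limit-capable constants
  v3 <- override_param(wild_type(), "c1", "inf")
  expect_identical(resolve_variant(v3, default_parameters())$params[["c1"]], Inf)
})

test_that("c1 = Inf removes Ime2-activated Ime1 degradation at any state", {
  v <- override_param(wild_type(), "c1", Inf)
  p <- unclass(default_parameters())
  set.seed(3)
  for (i in 1:5) {
    y <- random_state()
    with_term <- meiosis_rhs(y)
    without <- meiosis_rhs(y, variant = v)
    expect_equal(with_term[["ime1"]] - without[["ime1"]],
                 -p[["d2_ime1"]] * y[6] * y[4] / (p[["c1"]] + y[4]),
                 tolerance = 1e-12)
  }
})

test_that("conflicting feedback edits of one parameter are rejected", {
  v <- override_param(wild_type(), "c2", 0.5)
  expect_error(set_feedback(v, "IME2_auto_positive", "increased", arm = "c2"),
               "conflicting")
})

test_that("variant edits are order-independent when non-conflicting", {
  a <- override_param(knockout(wild_type(), "SOK2"), "c2", 0.6)
  b <- knockout(override_param(wild_type(), "c2", 0.6), "SOK2")
  pa <- resolve_variant(a, default_parameters())
  pb <- resolve_variant(b, default_parameters())
  expect_identical(pa$params, pb$params)
  expect_identical(pa$clamped, pb$clamped)
})
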