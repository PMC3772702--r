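test_that("baseline model has a single stable equilibrium at the published level", {
  eq <- equilibria_at()
  expect_length(eq, 1L)
  expect_identical(eq[[1]]$stability, "stable")
  expect_equal(eq[[1]]$state[["ime2"]], 0.27, tolerance = 0.01)
  expect_lt(max(abs(meiosis_rhs(eq[[1]]$state))), 1e-10)
})

test_that("lowering c2 into the bistable window yields two stable states", {
  eq <- equilibria_at(param_name = "c2", value = 0.6)
  expect_length(eq, 3L)
  stab <- vapply(eq, function(e) e$stability, "")
  expect_identical(stab, c("stable", "unstable", "stable"))
  # every reported equilibrium is a genuine root
  p6 <- validate_parameters(replace(unclass(default_parameters()), "c2", 0.6))
  for (e in eq) expect_lt(max(abs(meiosis_rhs(e$state, p6))), 1e-10)
})

test_that("equilibrium counts match the reduced-system sign-change oracle", {
  p <- unclass(default_parameters())
  for (c2 in c(0.3, 0.6, 1.0, 1.4)) {
    pc <- replace(p, "c2", c2)
    n_oracle <- count_equilibria_oracle(pc)
    eq <- equilibria_at(params = validate_parameters(pc))
    expect_identical(length(eq), n_oracle)
  }
})

test_that("stability labels are confirmed by perturb-and-integrate", {
  eq <- equilibria_at(param_name = "c2", value = 0.6)
  p6 <- validate_parameters(replace(unclass(default_parameters()), "c2", 0.6))
  for (e in eq) {
    y0 <- pmin(pmax(e$state + 1e-3, 0), c(1, 1, 1, Inf, Inf, Inf))
    tr <- integrate_model(params = p6, init = y0, t_end = 200,
                          n_points = 201)
    dist <- max(abs(attr(tr, "final_state") - e$state))
    if (e$stability == "stable") expect_lt(dist, 1e-4)
    else expect_gt(dist, 1e-3)
  }
})

test_that("knocked-out Ime2 leaves a single zero-Ime2 equilibrium at any c2", {
  v <- knockout(wild_type(), "IME2")
  for (c2 in c(0.14, 0.6, 1.4)) {
    eq <- equilibria_at(v, param_name = "c2", value = c2)
    expect_length(eq, 1L)
    expect_identical(eq[[1]]$state[["ime2"]], 0)
  }
})

test_that("relieving pSok2 inhibition of Ime1 opens a high-Ime2 stable branch", {
  br <- as.data.frame(scan_1d(param_name = "c_ime1", range = c(1e-3, 10),
                              n_steps = 17))
  stable <- br[br$stability == "stable", ]
  unstable <- br[br$stability == "unstable", ]
  expect_gt(nrow(unstable), 0)
  low <- stable[stable$ime2 < 0.7, ]
  high <- stable[stable$ime2 > 5, ]
  expect_gt(nrow(low), 0)
  expect_gt(nrow(high), 0)
  # high branch sits at larger c_ime1 than the low branch, with the
  # unstable segment in between
  expect_gt(min(high$parameter_value), max(low$parameter_value))
  expect_true(all(unstable$parameter_value > max(low$parameter_value) &
                  unstable$parameter_value < min(high$parameter_value)))
  # the wild-type baseline point lies on the stable low branch
  expect_true(any(abs(low$ime2 - 0.27) < 0.15))
})

test_that("strengthening Ime1 inhibition of Sok2 opens the high branch downward", {
  br <- as.data.frame(scan_1d(param_name = "c_sok2", range = c(1e-5, 1),
                              n_steps = 17))
  stable <- br[br$stability == "stable", ]
  low <- stable[stable$ime2 < 0.7, ]
  high <- stable[stable$ime2 > 5, ]
  expect_gt(nrow(low), 0)
  expect_gt(nrow(high), 0)
  # high-Ime2 branch appears as c_sok2 decreases
  expect_lt(max(high$parameter_value), min(low$parameter_value))
})

test_that("weakening the negative feedback (c1 up) raises the stable Ime2 branch", {
  br <- as.data.frame(scan_1d(param_name = "c1", range = c(1e-3, 10),
                              n_steps = 17))
  stable <- br[br$stability == "stable", ]
  unstable <- br[br$stability == "unstable", ]
  low <- stable[stable$ime2 < 0.7, ]
  high <- stable[stable$ime2 > 1, ]
  expect_gt(nrow(low), 0)
  expect_gt(nrow(high), 0)
  expect_gt(nrow(unstable), 0)
  expect_gt(min(high$parameter_value), max(low$parameter_value))
})

test_that("reducing PKA-coupled phosphorylation opens a high-Ime2 stable state", {
  br <- as.data.frame(scan_coupled_pka(scale_range = c(1e-3, 2), n_steps = 17))
  stable <- br[br$stability == "stable", ]
  low <- stable[stable$ime2 < 0.7, ]
  high <- stable[stable$ime2 > 5, ]
  expect_gt(nrow(low), 0)
  expect_gt(nrow(high), 0)
  expect_lt(max(high$parameter_value), min(low$parameter_value))
  # scale 1 sits on the default branch: close to the baseline equilibrium
  near1 <- low[which.min(abs(low$parameter_value - 1)), ]
  expect_lt(abs(near1$ime2 - 0.27), 0.15)
})

test_that("scan grids are deterministic and direction-independent", {
  b1 <- scan_1d(param_name = "c2", range = c(0.4, 0.8), n_steps = 7)
  b2 <- scan_1d(param_name = "c2", range = c(0.4, 0.8), n_steps = 7)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
})
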