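test_that("no signal is produced below all heat thresholds", {
  prof <- temperature_profile(0, 22, duration = 50)
  sig <- compute_signals(prof)
  expect_true(all(sig$J == 0))
  expect_true(all(sig$S == 0))
  expect_true(all(sig$D == 1))
})

test_that("signal build-up and decay follow the linear-ODE closed forms", {
  p <- model_params()
  prof <- temperature_profile(c(0, 10, 11), c(22, 37, 22), duration = 20)
  sig <- compute_signals(prof, p)
  at <- function(t, col) sig[[col]][match(t, sig$time_h)]
  # during the 37 degC pulse both J (T >= 30) and S (T >= 35) charge up
  J_end <- p$sigma_J / p$lambda_J * (1 - exp(-p$lambda_J * 1))
  S_end <- p$sigma_S / p$lambda_S * (1 - exp(-p$lambda_S * 1))
  expect_equal(at(11, "J"), J_end, tolerance = 1e-8)
  expect_equal(at(11, "S"), S_end, tolerance = 1e-8)
  # pure exponential decay after the pulse
  expect_equal(at(15, "J"), J_end * exp(-p$lambda_J * 4), tolerance = 1e-8)
  expect_equal(at(15, "S"), S_end * exp(-p$lambda_S * 4), tolerance = 1e-8)
  # 37 degC is below the damage threshold
  expect_true(all(sig$D == 1))
})

test_that("damage factor after a two-hour lethal pulse matches closed form", {
  p <- model_params()
  prof <- temperature_profile(c(0, 5, 7), c(22, 43.5, 22), duration = 30)
  sig <- compute_signals(prof, p)
  D_end <- p$D_min + (1 - p$D_min) * exp(-p$kappa_D * 2)
  expect_equal(sig$D[match(7, sig$time_h)], D_end, tolerance = 1e-6)
  # recovery toward 1 afterwards: dD/dt = rho_D (1 - D)
  D_later <- 1 - (1 - D_end) * exp(-p$rho_D * 13)
  expect_equal(sig$D[match(20, sig$time_h)], D_later, tolerance = 1e-6)
})

test_that("a step too coarse for the shortest heat window is refused", {
  prof <- build_lab_profile(lab_protocol())  # 20-min acclimation window
  expect_error(compute_signals(prof, dt = 0.5), "shortest profile step")
  expect_error(simulate_mean_field(profile = prof, dt = 0.5),
               "shortest profile step")
  expect_error(compute_signals(prof, dt = 0), "dt must be > 0")
})

test_that("mean-field right-hand side reproduces its single-term limits", {
  # absorbing all-R corner: no conversion pathway active
  p0 <- model_params(k_noise = 0, v0 = 0)
  expect_equal(mean_field_rhs(1, 0, J = 0, S = 0, params = p0),
               c(dr = 0, da = 0))
  # pure basal derepression: dr/dt = -v0 at r = 1
  p1 <- model_params(k_noise = 0, v0 = 0.01)
  expect_equal(mean_field_rhs(1, 0, J = 0, S = 0, params = p1)[["dr"]],
               -0.01)
  # symmetric recruited rates without signals: the equal-fractions point
  # r = a = u = 1/3 is stationary, so dr = -da there
  ps <- model_params(k_act = 0.3, k_rep = 0.3, v0 = 0)
  d <- mean_field_rhs(1 / 3, 1 / 3, J = 0, S = 0, params = ps)
  expect_equal(d[["dr"]], 0)
  expect_equal(d[["da"]], 0)
  expect_equal(d[["dr"]], -d[["da"]])
})

test_that("mean-field right-hand side rejects states off the simplex", {
  expect_error(mean_field_rhs(0.7, 0.5, 0, 0), "simplex")
  expect_error(mean_field_rhs(-0.1, 0.2, 0, 0), "simplex")
})

test_that("zero-signal run settles at a stationary point of the flow", {
  prof <- temperature_profile(0, 22, duration = 4000)
  traj <- simulate_mean_field(profile = prof, dt = 0.5)
  n <- nrow(traj)
  d <- mean_field_rhs(traj$r[n], traj$a[n], J = 0, S = 0)
  expect_lt(max(abs(d)), 1e-6)
})

test_that("trajectories stay on the simplex with non-negative mRNA", {
  prof <- build_lab_profile(lab_protocol())
  for (traj in list(simulate_mean_field(profile = prof),
                    simulate_ssa(profile = prof, n_runs = 50, seed = 3))) {
    expect_true(all(traj$r >= 0 & traj$a >= 0))
    expect_true(all(traj$r + traj$a <= 1 + 1e-12))
    expect_true(all(traj$m >= 0))
  }
})

test_that("reduced demethylase activity keeps the locus more repressed", {
  prof <- build_lab_profile(lab_protocol())
  wt <- simulate_mean_field(profile = prof, genotype = "WT")
  mut <- simulate_mean_field(profile = prof, genotype = "jmjq")
  expect_true(all(wt$r <= mut$r + 1e-9))
  # and acclimation-primed expression at HS+4 h is higher in the wild type
  at <- function(tr, t) approx(tr$time_h, tr$m, t)$y
  expect_gt(at(wt, 173), at(mut, 173))
})

test_that("observation maps are affine in the state variables", {
  prof <- temperature_profile(0, 22, duration = 10)
  traj <- simulate_mean_field(profile = prof)
  obs <- observation_params(c27 = 10, b27 = 1)
  pred <- observe(traj, obs)
  k27 <- pred$value[pred$assay == "K27"]
  expect_equal(k27, 10 * traj$r + 1)
  expect_equal(pred$value[pred$assay == "K4"], 10 * traj$a + 0.5)
  expect_equal(pred$value[pred$assay == "expr"], traj$m)
  # c27 = 10, b27 = 1, r = 0.35 -> K27 = 4.5
  tr35 <- traj[1:2, , drop = FALSE]
  tr35$r <- 0.35
  expect_equal(observe(tr35, obs, assays = "K27")$value, c(4.5, 4.5))
})

test_that("doubling the expression scale only rescales expression", {
  prof <- temperature_profile(0, 22, duration = 10)
  traj <- simulate_mean_field(profile = prof)
  p1 <- observe(traj, observation_params(cm = 1))
  p2 <- observe(traj, observation_params(cm = 2))
  expect_equal(p2$value[p2$assay == "expr"],
               2 * p1$value[p1$assay == "expr"])
  expect_equal(p2$value[p2$assay == "K27"], p1$value[p1$assay == "K27"])
  expect_equal(p2$value[p2$assay == "K4"], p1$value[p1$assay == "K4"])
})

test_that("stochastic ensembles are reproducible and seed-sensitive", {
  prof <- temperature_profile(c(0, 5, 6), c(22, 37, 22), duration = 30)
  a <- simulate_ssa(profile = prof, n_runs = 40, seed = 11)
  b <- simulate_ssa(profile = prof, n_runs = 40, seed = 11)
  c <- simulate_ssa(profile = prof, n_runs = 40, seed = 12)
  expect_identical(a$r, b$r)
  expect_identical(a$m, b$m)
  expect_false(identical(a$r, c$r))
})

test_that("zero total propensity freezes the stochastic state", {
  p <- model_params(k_act = 0, k_rep = 0, k_noise = 0, v0 = 0, vUA_S = 0,
                    r_init = 0)
  prof <- temperature_profile(0, 22, duration = 50)
  traj <- simulate_ssa(p, prof, n_runs = 20, seed = 1)
  expect_true(all(traj$r == 0))
  expect_true(all(traj$a == 0))
})

test_that("parameter validation enforces domain constraints", {
  expect_error(model_params(k_act = -1), ">= 0")
  expect_error(model_params(N = 2.5), "integer")
  expect_error(model_params(phi_jmj = 1.2), "phi_jmj")
  expect_error(model_params(D_min = -0.1), "D_min")
  expect_error(model_params(r_init = 2), "r_init")
  expect_error(observation_params(c27 = -1), "slopes")
  expect_error(simulate_ssa(model_params(N = 600),
                            temperature_profile(0, 22, duration = 1),
                            n_runs = 2e4), "cost")
})
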