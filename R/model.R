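#' Model parameters for the nucleosome-state heat-memory model
#'
#' The locus is modelled as `N` nucleosomes, each in one of three states:
#' R (H3K27me3, repressive), U (unmodified), or A (H3K4me3, active).
#' Conversions are two-step (R <-> U <-> A) and combine recruited ("read-write")
#' feedback, uniform noisy conversions, and three temperature-driven signals:
#'
#' * `J` — JMJ demethylase activity, produced while `T >= T_J`, decaying at
#'   `lambda_J`; drives R -> U at rate `vJ * phi * J` on top of the basal `v0`
#'   (together the R -> U derepression rate). The genotype multiplier `phi` is
#'   1 in the wild type and `phi_jmj` (< 1) in the demethylase quadruple
#'   mutant.
#' * `S` — heat-shock-factor-like activation, produced while `T >= T_S`;
#'   drives U -> A at `vUA_S * S` and gates transcription.
#' * `D` — cellular capacity in `[D_min, 1]`; heat above `T_D` damages it at
#'   `kappa_D` and it recovers at `rho_D`, which produces the gradual (rather
#'   than immediate) transcriptional upregulation after a severe heat shock.
#'
#' mRNA follows `dm/dt = D * (alpha0 + alpha * S * a * (1 - r)) - delta * m`,
#' i.e. transcription requires the activating signal, active marks, and loss
#' of repressive marks (the poised-state balance of the two marks).
#'
#' Rates are per hour, temperatures in degrees C, thresholds chosen so that an
#' acclimation pulse (37 degC) activates J and S but not damage, while a heat
#' shock (43.5 degC) activates all three.
#'
#' @param N nucleosome count (integer >= 1).
#' @param k_act recruited conversion strength toward A (per hour).
#' @param k_rep recruited strength toward R (per hour).
#' @param k_noise basal noisy rate for every allowed single-step conversion.
#' @param v0 basal R -> U demethylation rate.
#' @param vJ JMJ-dependent R -> U rate coefficient (per hour per unit J).
#' @param phi_jmj genotype multiplier on `vJ` in the mutant (0..1).
#' @param sigma_J,lambda_J,T_J JMJ signal production, decay, and heat
#'   threshold.
#' @param sigma_S,lambda_S,T_S activation signal production, decay, threshold.
#' @param T_D,kappa_D,rho_D,D_min damage threshold, damage rate, recovery
#'   rate, damage floor.
#' @param vUA_S S-driven U -> A coefficient.
#' @param alpha,alpha0,delta maximal and basal transcription rates and mRNA
#'   decay.
#' @param r_init initial repressed fraction (locus Polycomb-repressed before
#'   any heat).
#' @return An object of class `heatmem_params` (named list).
#' @export
model_params <- function(N = 20,
                         k_act = 0.1, k_rep = 0.2, k_noise = 0.02,
                         v0 = 0.002, vJ = 0.1, phi_jmj = 0.2,
                         sigma_J = 3, lambda_J = 0.01, T_J = 30,
                         sigma_S = 6, lambda_S = 0.05, T_S = 35,
                         T_D = 42, kappa_D = 2, rho_D = 0.02, D_min = 0.1,
                         vUA_S = 0.05,
                         alpha = 20, alpha0 = 0.02, delta = 0.5,
                         r_init = 0.9) {
  p <- list(N = N, k_act = k_act, k_rep = k_rep, k_noise = k_noise, v0 = v0,
            vJ = vJ, phi_jmj = phi_jmj, sigma_J = sigma_J,
            lambda_J = lambda_J, T_J = T_J, sigma_S = sigma_S,
            lambda_S = lambda_S, T_S = T_S, T_D = T_D, kappa_D = kappa_D,
            rho_D = rho_D, D_min = D_min, vUA_S = vUA_S, alpha = alpha,
            alpha0 = alpha0, delta = delta, r_init = r_init)
  rates <- c("k_act", "k_rep", "k_noise", "v0", "vJ", "sigma_J", "lambda_J",
             "sigma_S", "lambda_S", "kappa_D", "rho_D", "vUA_S", "alpha",
             "alpha0", "delta")
  if (any(unlist(p[rates]) < 0)) stop("all rates must be >= 0")
  if (p$N < 1 || p$N != round(p$N)) stop("N must be an integer >= 1")
  if (p$D_min < 0 || p$D_min > 1) stop("D_min must lie in [0, 1]")
  if (p$phi_jmj < 0 || p$phi_jmj > 1) stop("phi_jmj must lie in [0, 1]")
  if (p$r_init < 0 || p$r_init > 1) stop("r_init must lie in [0, 1]")
  structure(p, class = "heatmem_params")
}

#' Observation parameters
#'
#' Affine maps from model state to assay scale: mean repressed fraction to
#' H3K27me3 ChIP percent-input, mean active fraction to H3K4me3 percent-input,
#' and mRNA level to relative expression (versus a reference gene).
#'
#' @param c27,b27 slope and intercept for H3K27me3 percent-input.
#' @param c4,b4 slope and intercept for H3K4me3 percent-input.
#' @param cm scale for relative expression.
#' @return An object of class `heatmem_obs`.
#' @export
observation_params <- function(c27 = 10, b27 = 0.5, c4 = 10, b4 = 0.5,
                               cm = 1) {
  if (any(c(c27, c4, cm) < 0)) stop("slopes must be >= 0")
  if (any(c(b27, b4) < 0)) stop("intercepts must be >= 0")
  structure(list(c27 = c27, b27 = b27, c4 = c4, b4 = b4, cm = cm),
            class = "heatmem_obs")
}

# flatten params to the positional vector the C++ core expects
.param_vector <- function(params, genotype = c("WT", "jmjq")) {
  genotype <- match.arg(genotype)
  phi <- if (genotype == "WT") 1 else params$phi_jmj
  c(params$N, params$k_act, params$k_rep, params$k_noise, params$v0,
    params$vJ, phi, params$sigma_J, params$lambda_J, params$T_J,
    params$sigma_S, params$lambda_S, params$T_S, params$T_D, params$kappa_D,
    params$rho_D, params$D_min, params$alpha, params$alpha0, params$delta,
    params$vUA_S, params$r_init)
}

.check_dt <- function(profile, dt) {
  if (dt <= 0) stop("dt must be > 0")
  if (length(profile$times) > 1) {
    widths <- diff(c(profile$times, profile$duration))
    if (dt > min(widths) + 1e-9)
      stop(sprintf(
        "dt = %g h exceeds the shortest profile step (%g h); a heat window would be skipped",
        dt, min(widths)))
  }
}

#' Integrate the temperature-driven signals
#'
#' Solves the linear signal ODEs `dJ/dt = sigma_J 1[T >= T_J] - lambda_J J`
#' (and likewise for S) from zero initial conditions, and the damage factor
#' `dD/dt = -kappa_D (D - D_min)` while `T >= T_D`, `+rho_D (1 - D)`
#' otherwise, from `D(0) = 1`, with fixed-step RK4 on a grid aligned to the
#' profile breakpoints.
#'
#' @param profile a [temperature_profile()].
#' @param params a [model_params()].
#' @param dt integration/output step in hours.
#' @return data.frame with columns `time_h`, `J`, `S`, `D`.
#' @export
compute_signals <- function(profile, params = model_params(), dt = 0.05) {
  stopifnot(inherits(profile, "temp_profile"))
  .check_dt(profile, dt)
  out <- cpp_simulate(profile$times, profile$temps, profile$duration,
                      .param_vector(params, "WT"), dt)
  data.frame(time_h = out[, "time_h"], J = out[, "J"], S = out[, "S"],
             D = out[, "D"])
}

#' Mean-field right-hand side
#'
#' Deterministic (locus-average) limit of the recruited-conversion scheme:
#' with `u = 1 - r - a`,
#' `dr/dt = (k_rep r + k_noise) u - (k_act a + k_noise + v0 + vJ phi J) r` and
#' `da/dt = (k_act a + k_noise + vUA_S S) u - (k_rep r + k_noise) a`.
#'
#' @param r,a repressed and active mean fractions, non-negative with sum at
#'   most 1.
#' @param J,S,D signal levels (D unused here; kept for a uniform signature).
#' @param params a [model_params()].
#' @param genotype `"WT"` (phi = 1) or `"jmjq"` (phi = `phi_jmj`).
#' @return Named numeric vector `c(dr, da)`.
#' @export
mean_field_rhs <- function(r, a, J, S, D = 1, params = model_params(),
                           genotype = c("WT", "jmjq")) {
  genotype <- match.arg(genotype)
  if (r < 0 || a < 0 || r + a > 1 + 1e-12)
    stop("fractions outside the simplex: need r, a >= 0 and r + a <= 1")
  phi <- if (genotype == "WT") 1 else params$phi_jmj
  u <- 1 - r - a
  dr <- (params$k_rep * r + params$k_noise) * u -
    (params$k_act * a + params$k_noise + params$v0 +
       params$vJ * phi * J) * r
  da <- (params$k_act * a + params$k_noise + params$vUA_S * S) * u -
    (params$k_rep * r + params$k_noise) * a
  c(dr = dr, da = da)
}

.as_trajectory <- function(df, genotype, engine, n_runs) {
  structure(df, genotype = genotype, engine = engine, n_runs = n_runs,
            class = c("heatmem_traj", "data.frame"))
}

#' Simulate the deterministic mean-field model
#'
#' Integrates the coupled fraction and mRNA ODEs (see [model_params()]) with
#' fixed-step RK4 from `r(0) = r_init`, `a(0) = 0`, `m(0) = alpha0 / delta`.
#'
#' @param params a [model_params()].
#' @param profile a [temperature_profile()].
#' @param genotype `"WT"` or `"jmjq"`.
#' @param dt integration/output step (hours).
#' @return A trajectory data.frame (`heatmem_traj`) with columns `time_h`,
#'   `r`, `a`, `m`, `sem_r`, `sem_m` (the SEM columns are zero for this
#'   deterministic engine) plus the signals `J`, `S`, `D`.
#' @export
simulate_mean_field <- function(params = model_params(), profile,
                                genotype = c("WT", "jmjq"), dt = 0.05) {
  genotype <- match.arg(genotype)
  stopifnot(inherits(profile, "temp_profile"))
  .check_dt(profile, dt)
  out <- cpp_simulate(profile$times, profile$temps, profile$duration,
                      .param_vector(params, genotype), dt)
  r <- out[, "r"]; a <- out[, "a"]
  viol <- max(0, -min(r), -min(a), max(r + a) - 1)
  if (viol > 1e-6)
    stop(sprintf("integrator left the simplex by %.3g; reduce dt", viol))
  df <- data.frame(time_h = out[, "time_h"],
                   r = pmin(pmax(r, 0), 1), a = pmin(pmax(a, 0), 1),
                   m = out[, "m"], sem_r = 0, sem_m = 0,
                   J = out[, "J"], S = out[, "S"], D = out[, "D"])
  .as_trajectory(df, genotype, "ode", 1L)
}

#' Simulate the stochastic nucleosome-state model (exact SSA)
#'
#' Gillespie simulation of the `N`-nucleosome locus with per-nucleosome
#' propensities (recruitment uses fractions over all `N` nucleosomes) and
#' rates held piecewise-constant on the signal grid; waiting times that cross
#' a grid boundary are re-drawn with the new propensities, so the algorithm is
#' exact within cells. Per-run mRNA is integrated in closed form between state
#' changes. Runs are seeded independently as `seed + run index`, so ensembles
#' are reproducible.
#'
#' @param params a [model_params()].
#' @param profile a [temperature_profile()].
#' @param genotype `"WT"` or `"jmjq"`.
#' @param n_runs ensemble size (>= 1).
#' @param seed integer seed.
#' @param dt_signal signal-grid step (hours).
#' @param force bypass the cost guard for very large `N * n_runs`.
#' @return A trajectory data.frame (`heatmem_traj`) with ensemble mean `r`,
#'   `a`, `m` and standard errors `sem_r`, `sem_m`.
#' @export
simulate_ssa <- function(params = model_params(), profile,
                         genotype = c("WT", "jmjq"), n_runs = 200,
                         seed = 1, dt_signal = 0.05, force = FALSE) {
  genotype <- match.arg(genotype)
  stopifnot(inherits(profile, "temp_profile"), n_runs >= 1)
  .check_dt(profile, dt_signal)
  if (!force && params$N > 500 && n_runs > 1e4)
    stop("N > 500 with n_runs > 10^4: prohibitive cost; set force = TRUE to override")
  res <- cpp_ssa(profile$times, profile$temps, profile$duration,
                 .param_vector(params, genotype), as.integer(n_runs),
                 as.numeric(seed), dt_signal)
  df <- data.frame(time_h = res$time_h, r = res$r, a = res$a, m = res$m,
                   sem_r = res$sem_r, sem_m = res$sem_m,
                   J = res$J, S = res$S, D = res$D)
  .as_trajectory(df, genotype, "ssa", as.integer(n_runs))
}

#' Map a model trajectory to predicted assay measurements
#'
#' @param traj a trajectory from one of the simulation engines.
#' @param obs an [observation_params()].
#' @param times optional times (hours) at which to predict (linear
#'   interpolation on the trajectory grid); defaults to the full grid.
#' @param assays subset of `c("K27", "K4", "expr")`.
#' @return data.frame with columns `time_h`, `assay`, `value`: H3K27me3
#'   percent-input `c27 * r + b27`, H3K4me3 percent-input `c4 * a + b4`,
#'   relative expression `cm * m`.
#' @export
observe <- function(traj, obs = observation_params(), times = NULL,
                    assays = c("K27", "K4", "expr")) {
  assays <- match.arg(assays, several.ok = TRUE)
  if (is.null(times)) times <- traj$time_h
  at <- function(col) stats::approx(traj$time_h, traj[[col]], xout = times,
                                    rule = 2)$y
  pieces <- list()
  if ("K27" %in% assays)
    pieces$K27 <- data.frame(time_h = times, assay = "K27",
                             value = obs$c27 * at("r") + obs$b27)
  if ("K4" %in% assays)
    pieces$K4 <- data.frame(time_h = times, assay = "K4",
                            value = obs$c4 * at("a") + obs$b4)
  if ("expr" %in% assays)
    pieces$expr <- data.frame(time_h = times, assay = "expr",
                              value = obs$cm * at("m"))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
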