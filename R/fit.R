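# default box bounds (natural scale) and log-scale flags for fittable
# parameters; phi_jmj is genotype-specific by construction (it only enters the
# mutant simulation, the wild type always uses phi = 1)
.default_bounds <- function() {
  tab <- rbind(
    k_act   = c(1e-2, 10,   1), k_rep   = c(1e-2, 10,   1),
    k_noise = c(1e-4, 1,    1), v0      = c(1e-5, 1,    1),
    vJ      = c(1e-2, 100,  1), phi_jmj = c(1e-2, 1,    1),
    sigma_J = c(1e-2, 100,  1), lambda_J = c(1e-4, 10,  1),
    sigma_S = c(1e-2, 100,  1), lambda_S = c(1e-4, 10,  1),
    kappa_D = c(1e-3, 20,   1), rho_D   = c(1e-4, 10,   1),
    D_min   = c(1e-3, 1,    1), vUA_S   = c(1e-2, 100,  1),
    alpha   = c(1e-2, 1e3,  1), alpha0  = c(1e-4, 10,   1),
    delta   = c(1e-2, 10,   1), r_init  = c(1e-2, 0.999, 0),
    c27     = c(0.1,  100,  1), b27     = c(1e-3, 10,   1),
    c4      = c(0.1,  100,  1), b4      = c(1e-3, 10,   1),
    cm      = c(1e-2, 100,  1))
  data.frame(name = rownames(tab), lower = tab[, 1], upper = tab[, 2],
             log = tab[, 3] == 1, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Specify free parameters for fitting
#'
#' @param names character vector of parameter names to free (model parameters
#'   and/or observation parameters `c27`, `b27`, `c4`, `b4`, `cm`).
#' @param lower,upper optional named overrides of the default box bounds.
#' @param log optional named logical overrides of the log-scale flags.
#' @return data.frame of class `heatmem_free_spec` with columns `name`,
#'   `lower`, `upper`, `log`.
#' @export
free_param_spec <- function(names, lower = NULL, upper = NULL, log = NULL) {
  def <- .default_bounds()
  unknown <- setdiff(names, def$name)
  if (length(unknown))
    stop("unknown free parameter(s): ", paste(unknown, collapse = ", "))
  spec <- def[match(names, def$name), , drop = FALSE]
  rownames(spec) <- NULL
  for (nm in names(lower)) spec$lower[spec$name == nm] <- lower[[nm]]
  for (nm in names(upper)) spec$upper[spec$name == nm] <- upper[[nm]]
  for (nm in names(log)) spec$log[spec$name == nm] <- isTRUE(log[[nm]])
  if (any(spec$lower >= spec$upper)) stop("bounds must satisfy lower < upper")
  class(spec) <- c("heatmem_free_spec", "data.frame")
  spec
}

.obs_names <- c("c27", "b27", "c4", "b4", "cm")

.apply_theta <- function(theta, params, obs) {
  for (nm in names(theta)) {
    if (nm %in% .obs_names) obs[[nm]] <- theta[[nm]]
    else params[[nm]] <- theta[[nm]]
  }
  list(params = params, obs = obs)
}

.validate_timecourse <- function(data, profile = NULL) {
  need <- c("time_h", "assay", "genotype", "replicate", "value")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("time-course data lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(data$assay %in% c("K27", "K4", "expr")))
    stop("assay must be one of K27, K4, expr")
  if (!all(data$genotype %in% c("WT", "jmjq")))
    stop("genotype must be WT or jmjq")
  if (any(!is.finite(data$value)) || any(data$value < 0))
    stop("values must be finite and >= 0")
  if (!is.null(profile) &&
      any(data$time_h < 0 | data$time_h > profile$duration))
    stop("measurement times fall outside the profile duration")
  invisible(data)
}

#' Weighted log-scale sum-of-squares objective
#'
#' For each genotype present in the data, simulates the deterministic
#' mean-field model with the candidate parameters, maps it through the
#' observation model, and accumulates
#' `sum w_assay * (log(value + eps) - log(pred + eps))^2` with `eps = 1e-3`
#' (log residuals because qPCR/ChIP errors are multiplicative). Simulation
#' failures yield `Inf` rather than an error.
#'
#' @param theta named numeric vector of candidate values for the free
#'   parameters (natural scale).
#' @param data observed time course: data.frame with columns `time_h`,
#'   `assay`, `genotype`, `replicate`, `value`.
#' @param profile a [temperature_profile()].
#' @param fixed a [model_params()] supplying every non-free parameter.
#' @param obs an [observation_params()].
#' @param weights named per-assay weights.
#' @param dt integration step (hours).
#' @return Non-negative scalar (or `Inf` on simulation failure).
#' @export
sse_objective <- function(theta, data, profile, fixed = model_params(),
                          obs = observation_params(),
                          weights = c(K27 = 1, K4 = 1, expr = 1), dt = 0.05) {
  .validate_timecourse(data, profile)
  ap <- .apply_theta(theta, fixed, obs)
  eps <- 1e-3
  total <- 0
  for (g in unique(data$genotype)) {
    dg <- data[data$genotype == g, , drop = FALSE]
    traj <- tryCatch(
      simulate_mean_field(ap$params, profile, genotype = g, dt = dt),
      error = function(e) NULL)
    if (is.null(traj)) return(Inf)
    pred <- observe(traj, ap$obs, times = sort(unique(dg$time_h)),
                    assays = unique(dg$assay))
    key <- paste(pred$time_h, pred$assay)
    pv <- pred$value[match(paste(dg$time_h, dg$assay), key)]
    w <- weights[dg$assay]
    w[is.na(w)] <- 1
    total <- total + sum(w * (log(dg$value + eps) - log(pv + eps))^2)
  }
  if (!is.finite(total)) return(Inf)
  total
}

# bounded reparameterisation: unconstrained z -> natural-scale parameter
.z_to_theta <- function(z, spec) {
  u <- stats::plogis(z)
  th <- ifelse(spec$log,
               exp(log(spec$lower) + u * (log(spec$upper) - log(spec$lower))),
               spec$lower + u * (spec$upper - spec$lower))
  names(th) <- spec$name
  th
}

.theta_to_z <- function(theta, spec) {
  u <- ifelse(spec$log,
              (log(theta) - log(spec$lower)) /
                (log(spec$upper) - log(spec$lower)),
              (theta - spec$lower) / (spec$upper - spec$lower))
  stats::qlogis(pmin(pmax(u, 1e-6), 1 - 1e-6))
}

.optim_one <- function(z0, fn, maxit = 600) {
  # Nelder-Mead also handles the 1-parameter case here (the transformed
  # space is unbounded, so Brent's required box does not apply); silence
  # optim's advisory about it
  withCallingHandlers(
    stats::optim(z0, fn, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-9)),
    warning = function(w) {
      if (grepl("Nelder-Mead", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Fit the heat-memory model to observed time courses
#'
#' The central model-fitting routine. Minimises [sse_objective()] over the
#' free parameters by multi-start Nelder-Mead (starts drawn by Latin-hypercube
#' sampling in the transformed bound space, seeded and therefore
#' reproducible). When the data contain both genotypes the fit is joint: all
#' free parameters are shared across genotypes except `phi_jmj`, which by
#' construction only scales the JMJ-dependent derepression rate of the mutant
#' — the model-level encoding of the mutant's lower R -> U transition rate.
#'
#' @param data observed time course (columns `time_h`, `assay`, `genotype`,
#'   `replicate`, `value`).
#' @param profile a [temperature_profile()].
#' @param free character vector of free parameter names, or a
#'   [free_param_spec()].
#' @param fixed a [model_params()] supplying the non-free parameters.
#' @param obs an [observation_params()].
#' @param weights named per-assay weights for the objective.
#' @param n_starts number of Latin-hypercube multistarts.
#' @param seed integer seed controlling starts and bootstrap.
#' @param bootstrap number of replicate-resampling bootstrap refits (0 = no
#'   bootstrap); each refit restarts Nelder-Mead from the point estimate.
#' @param dt integration step (hours).
#' @return An object of class `heatmem_fit` with methods [print()],
#'   [summary()], [coef()], [predict()], [fitted()], [residuals()], [plot()]
#'   and [simulate()].
#' @export
fit_heat_memory <- function(data, profile, free = c("vJ", "phi_jmj"),
                            fixed = model_params(),
                            obs = observation_params(),
                            weights = c(K27 = 1, K4 = 1, expr = 1),
                            n_starts = 20, seed = 1, bootstrap = 0,
                            dt = 0.05) {
  .validate_timecourse(data, profile)
  spec <- if (inherits(free, "heatmem_free_spec")) free
          else free_param_spec(free)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  npar <- nrow(spec)
  fn <- function(z) sse_objective(.z_to_theta(z, spec), data, profile,
                                  fixed, obs, weights, dt)
  u0 <- lhs::randomLHS(n_starts, npar) * 0.96 + 0.02
  z0 <- stats::qlogis(u0)
  fits <- vector("list", n_starts)
  objs <- rep(Inf, n_starts)
  conv <- logical(n_starts)
  for (s in seq_len(n_starts)) {
    res <- tryCatch(.optim_one(z0[s, ], fn), error = function(e) NULL)
    if (is.null(res)) next
    fits[[s]] <- res
    objs[s] <- res$value
    conv[s] <- res$convergence == 0 && is.finite(res$value)
  }
  if (!any(is.finite(objs)))
    stop("no start converged; per-start objectives: ",
         paste(signif(objs, 3), collapse = ", "))
  best <- which.min(objs)
  z_hat <- fits[[best]]$par
  theta_hat <- .z_to_theta(z_hat, spec)
  ap <- .apply_theta(theta_hat, fixed, obs)

  boot <- NULL
  if (bootstrap > 0) {
    draws <- matrix(NA_real_, bootstrap, npar,
                    dimnames = list(NULL, spec$name))
    grp <- interaction(data$genotype, data$time_h, data$assay, drop = TRUE)
    for (b in seq_len(bootstrap)) {
      idx <- unlist(lapply(split(seq_len(nrow(data)), grp), function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]),
        use.names = FALSE)
      db <- data[idx, , drop = FALSE]
      fnb <- function(z) sse_objective(.z_to_theta(z, spec), db, profile,
                                       fixed, obs, weights, dt)
      rb <- tryCatch(.optim_one(z_hat, fnb, maxit = 400),
                     error = function(e) NULL)
      if (!is.null(rb)) draws[b, ] <- .z_to_theta(rb$par, spec)
    }
    boot <- draws
  }

  structure(list(coefficients = theta_hat, objective = objs[best],
                 params = ap$params, obs = ap$obs, free = spec,
                 data = data, profile = profile, weights = weights,
                 genotypes = sort(unique(data$genotype)),
                 n_starts = n_starts, n_converged = sum(conv),
                 start_objectives = objs, bootstrap = boot,
                 seed = seed, dt = dt, call = match.call()),
            class = "heatmem_fit")
}

#' @method print heatmem_fit
#' @export
print.heatmem_fit <- function(x, ...) {
  cat("Heat-memory model fit\n")
  cat(sprintf("  genotypes: %s;  %d observations;  objective = %.6g\n",
              paste(x$genotypes, collapse = " + "), nrow(x$data),
              x$objective))
  cat(sprintf("  %d/%d starts converged (seed %d)\n", x$n_converged,
              x$n_starts, x$seed))
  cat("  coefficients:\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.heatmem_fit <- function(object, ...) object$coefficients

#' Bootstrap percentile confidence intervals of a fit
#'
#' @param object a [fit_heat_memory()] result fitted with `bootstrap > 0`.
#' @param parm parameter names (default: all free parameters).
#' @param level confidence level.
#' @param ... unused.
#' @return Matrix of lower/upper percentile bounds.
#' @export
confint.heatmem_fit <- function(object, parm = NULL, level = 0.95, ...) {
  if (is.null(object$bootstrap))
    stop("fit was run without bootstrap; refit with bootstrap > 0")
  if (is.null(parm)) parm <- colnames(object$bootstrap)
  a <- (1 - level) / 2
  t(apply(object$bootstrap[, parm, drop = FALSE], 2, stats::quantile,
          probs = c(a, 1 - a), na.rm = TRUE))
}

#' @export
predict.heatmem_fit <- function(object, times = NULL,
                                assays = c("K27", "K4", "expr"),
                                genotype = NULL, ...) {
  if (is.null(genotype)) genotype <- object$genotypes
  out <- lapply(genotype, function(g) {
    traj <- simulate_mean_field(object$params, object$profile, genotype = g,
                                dt = object$dt)
    p <- observe(traj, object$obs, times = times, assays = assays)
    p$genotype <- g
    p
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
fitted.heatmem_fit <- function(object, ...) {
  d <- object$data
  pred <- numeric(nrow(d))
  for (g in object$genotypes) {
    sel <- d$genotype == g
    p <- predict(object, times = sort(unique(d$time_h[sel])),
                 assays = unique(d$assay[sel]), genotype = g)
    pred[sel] <- p$value[match(paste(d$time_h[sel], d$assay[sel]),
                               paste(p$time_h, p$assay))]
  }
  pred
}

#' @export
residuals.heatmem_fit <- function(object, ...) {
  eps <- 1e-3
  log(object$data$value + eps) - log(fitted(object) + eps)
}

#' @method summary heatmem_fit
#' @export
summary.heatmem_fit <- function(object, level = 0.95, ...) {
  res <- residuals(object)
  by_assay <- tapply(res, object$data$assay, function(r)
    c(n = length(r), rmse = sqrt(mean(r^2))))
  ci <- if (!is.null(object$bootstrap)) confint(object, level = level)
  structure(list(fit = object, resid_by_assay = by_assay, ci = ci,
                 level = level),
            class = "summary.heatmem_fit")
}

#' @method print summary.heatmem_fit
#' @export
print.summary.heatmem_fit <- function(x, ...) {
  print(x$fit)
  cat("  log-residual RMSE by assay:\n")
  for (nm in names(x$resid_by_assay))
    cat(sprintf("    %-4s n = %3d  rmse = %.3f\n", nm,
                x$resid_by_assay[[nm]]["n"], x$resid_by_assay[[nm]]["rmse"]))
  if (!is.null(x$ci)) {
    cat(sprintf("  %g%% bootstrap percentile intervals:\n", 100 * x$level))
    print(signif(x$ci, 4))
  }
  invisible(x)
}

#' @export
plot.heatmem_fit <- function(x, assays = NULL, ...) {
  d <- x$data
  if (is.null(assays)) assays <- unique(d$assay)
  old <- graphics::par(mfrow = c(length(assays), 1),
                       mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(old))
  cols <- c(WT = "black", jmjq = "firebrick")
  for (as_ in assays) {
    da <- d[d$assay == as_, , drop = FALSE]
    pr <- predict(x, assays = as_)
    ylim <- range(c(da$value, pr$value))
    graphics::plot(NA, xlim = c(0, x$profile$duration), ylim = ylim,
                   xlab = "time (h since germination)", ylab = as_, ...)
    for (g in x$genotypes) {
      pg <- pr[pr$genotype == g, ]
      graphics::lines(pg$time_h, pg$value, col = cols[[g]])
      dg <- da[da$genotype == g, ]
      graphics::points(dg$time_h, dg$value, col = cols[[g]], pch = 1)
    }
    graphics::legend("topleft", legend = x$genotypes, bty = "n",
                     col = cols[x$genotypes], lty = 1)
  }
  invisible(x)
}

#' Simulate replicate datasets from a fitted model
#'
#' Parametric simulation: regenerates noisy time courses at the fitted
#' parameters with the same sampling design (times, assays, genotypes,
#' replicate counts) as the fitted data.
#'
#' @param object a `heatmem_fit`.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param noise_sd lognormal measurement noise SD; default is the RMSE of the
#'   fit's log residuals.
#' @param ... unused.
#' @return A list of `nsim` data.frames in the fitted-data format.
#' @export
simulate.heatmem_fit <- function(object, nsim = 1, seed = 1,
                                 noise_sd = NULL, ...) {
  if (is.null(noise_sd)) noise_sd <- sqrt(mean(residuals(object)^2))
  d <- object$data
  n_rep <- max(as.integer(as.factor(d$replicate)))
  times <- sort(unique(d$time_h))
  lapply(seq_len(nsim), function(i) {
    gen_timecourse(object$params, object$obs, object$profile,
                   genotypes = object$genotypes, sample_times = times,
                   assays = unique(d$assay),
                   noise = assay_noise(sd_expr = noise_sd, sd_chip = noise_sd,
                                       replicates = n_rep),
                   seed = seed + i - 1)$data
  })
}
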