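.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification of a synthetic fluctuating-field temperature series
#'
#' Stylised field conditions: a diurnal sinusoid between night and day
#' temperatures plus Gaussian-shaped midday heat spikes and measurement noise.
#' The defaults encode the fluctuating-condition design used for field
#' experiments: at least two spikes above 30 degC whose onsets are separated
#' by a 2-day gap, so that the first spike acts as the acclimation event and
#' the second as the heat shock.
#'
#' @param days length of the series in days (hourly sampling).
#' @param day_temp,night_temp diurnal extremes (degC).
#' @param spike_days days (0-based) on which spikes occur; default the first
#'   spike on day 5 and the second `gap_days` later.
#' @param spike_peaks peak temperatures, one per spike, all > 30 degC.
#' @param gap_days gap between the first two spikes (days).
#' @param noise_sd hourly Gaussian noise SD (degC).
#' @param seed integer seed.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(days = 14, day_temp = 26, night_temp = 18,
                       spike_days = NULL, spike_peaks = c(36, 38),
                       gap_days = 2, noise_sd = 0.3, seed = 1) {
  if (is.null(spike_days)) spike_days <- c(5, 5 + gap_days)
  if (length(spike_days) < 2) stop("need at least two spikes")
  if (length(spike_peaks) != length(spike_days))
    stop("one peak temperature per spike day")
  if (any(spike_peaks <= 30)) stop("spike peaks must exceed 30 degC")
  if (gap_days <= 0) stop("gap must be > 0")
  if (max(spike_days) >= days) stop("spike days must fall within the series")
  structure(list(days = days, day_temp = day_temp, night_temp = night_temp,
                 spike_days = spike_days, spike_peaks = spike_peaks,
                 gap_days = gap_days, noise_sd = noise_sd, seed = seed),
            class = "field_spec")
}

#' Generate an hourly fluctuating-field temperature profile
#'
#' @param spec a [field_spec()].
#' @return A [temperature_profile()] with hourly breakpoints; temperatures are
#'   rounded to 0.001 degC so that writing and re-reading the CSV form is an
#'   exact round trip.
#' @export
gen_field_profile <- function(spec = field_spec()) {
  stopifnot(inherits(spec, "field_spec"))
  h <- 0:(24 * spec$days - 1)
  mid <- (spec$day_temp + spec$night_temp) / 2
  amp <- (spec$day_temp - spec$night_temp) / 2
  base <- mid + amp * cos(2 * pi * (h %% 24 - 14) / 24)  # warmest at 14:00
  temp <- base
  for (i in seq_along(spec$spike_days)) {
    centre <- 24 * spec$spike_days[i] + 13
    height <- spec$spike_peaks[i] - base[centre + 1]
    temp <- temp + height * exp(-((h - centre) / 1.5)^2)
  }
  temp <- .with_seed(spec$seed,
                     temp + stats::rnorm(length(h), 0, spec$noise_sd))
  temperature_profile(h, round(temp, 3), duration = max(h) + 1,
                      label = "field:synthetic")
}

#' Assay noise settings for synthetic time courses
#'
#' @param sd_expr lognormal SD of relative-expression measurements.
#' @param sd_chip lognormal SD of ChIP percent-input measurements.
#' @param replicates replicates per (genotype, time, assay) point.
#' @return An object of class `assay_noise`.
#' @export
assay_noise <- function(sd_expr = 0.2, sd_chip = 0.2, replicates = 3) {
  if (sd_expr < 0 || sd_chip < 0) stop("noise SDs must be >= 0")
  if (replicates < 1) stop("need at least one replicate")
  structure(list(sd_expr = sd_expr, sd_chip = sd_chip,
                 replicates = as.integer(replicates)),
            class = "assay_noise")
}

#' Generate a noisy synthetic assay time course with known truth
#'
#' Simulates the deterministic model per genotype, maps it through the
#' observation model, and multiplies each replicate by lognormal measurement
#' noise (multiplicative error, as appropriate for qPCR/ChIP).
#'
#' @param params a [model_params()] (the ground truth).
#' @param obs an [observation_params()].
#' @param profile a [temperature_profile()].
#' @param genotypes subset of `c("WT", "jmjq")`.
#' @param sample_times measurement times (hours); the default covers the lab
#'   +ACC+HS design (before/after each heat window and the following days).
#' @param assays subset of `c("expr", "K27", "K4")`.
#' @param noise an [assay_noise()].
#' @param seed integer seed.
#' @param dt integration step.
#' @return list with `data` (columns `time_h`, `assay`, `genotype`,
#'   `replicate`, `value`) and `truth` (the generating parameters and seed).
#' @export
gen_timecourse <- function(params = model_params(),
                           obs = observation_params(), profile,
                           genotypes = c("WT", "jmjq"),
                           sample_times = c(95, 96.5, 100, 120, 144, 167,
                                            169.5, 173, 193, 217),
                           assays = c("expr", "K27"),
                           noise = assay_noise(), seed = 1, dt = 0.05) {
  stopifnot(inherits(profile, "temp_profile"), inherits(noise, "assay_noise"))
  genotypes <- match.arg(genotypes, several.ok = TRUE)
  assays <- match.arg(assays, c("expr", "K27", "K4"), several.ok = TRUE)
  if (any(sample_times < 0 | sample_times > profile$duration))
    stop("sample times outside the profile")
  rows <- .with_seed(seed, {
    out <- list()
    for (g in genotypes) {
      traj <- simulate_mean_field(params, profile, genotype = g, dt = dt)
      pred <- observe(traj, obs, times = sample_times, assays = assays)
      for (rep_i in seq_len(noise$replicates)) {
        sd <- ifelse(pred$assay == "expr", noise$sd_expr, noise$sd_chip)
        fac <- exp(stats::rnorm(nrow(pred), 0, sd))
        out[[length(out) + 1]] <- data.frame(
          time_h = pred$time_h, assay = pred$assay, genotype = g,
          replicate = rep_i, value = pred$value * fac,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  rownames(rows) <- NULL
  list(data = rows,
       truth = list(params = params, obs = obs, noise = noise, seed = seed))
}

#' Generate a synthetic RNA-seq count matrix with planted memory genes
#'
#' Negative-binomial counts with a log-link genotype-by-time effect. Planted
#' "memory" genes have no expression difference between genotypes immediately
#' after heat shock (0 h) but a `+/- effect` log2 fold change (mutant versus
#' wild type) at 4 and 24 h — the signature the 0/4/24-h screen is designed to
#' detect. All other genes are null at every time.
#'
#' @param n_genes total genes.
#' @param n_memory planted memory genes.
#' @param design data.frame with columns `sample`, `genotype`, `time_h`,
#'   `replicate`; default 2 genotypes x (0, 4, 24) h x 3 replicates.
#' @param effect absolute log2 fold change planted at 4 and 24 h.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param baseline_meanlog,baseline_sdlog lognormal distribution of per-gene
#'   baseline abundance (CPM scale).
#' @param seed integer seed.
#' @return list with `counts` (genes x samples integer matrix), `design`,
#'   `libsizes`, and `truth` (per-gene `is_memory`, `direction`,
#'   `lfc_4h`, `lfc_24h`).
#' @export
gen_count_matrix <- function(n_genes = 5000, n_memory = 200, design = NULL,
                             effect = 2, dispersion = 0.1,
                             baseline_meanlog = log(30), baseline_sdlog = 1,
                             seed = 1) {
  if (n_memory > n_genes) stop("n_memory must not exceed n_genes")
  if (is.null(design)) {
    design <- expand.grid(replicate = 1:3, time_h = c(0, 4, 24),
                          genotype = c("WT", "jmjq"),
                          stringsAsFactors = FALSE)[, 3:1]
    design$sample <- sprintf("%s_t%g_r%d", design$genotype, design$time_h,
                             design$replicate)
  }
  grp <- table(design$genotype, design$time_h)
  if (!all(c("WT", "jmjq") %in% rownames(grp)) ||
      !all(c(0, 4, 24) %in% as.numeric(colnames(grp))) || any(grp < 2))
    stop("design must cover both genotypes at 0/4/24 h with >= 2 replicates")
  .with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    base_cpm <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    libsizes <- stats::runif(nrow(design), 0.8, 1.2) * 1e7
    names(libsizes) <- design$sample
    memory <- rep(FALSE, n_genes)
    memory[sample.int(n_genes, n_memory)] <- TRUE
    direction <- ifelse(memory,
                        ifelse(stats::runif(n_genes) < 0.5, "up", "down"),
                        NA)
    lfc <- matrix(0, n_genes, 3, dimnames = list(genes, c("0", "4", "24")))
    sgn <- ifelse(direction == "up", 1, -1)
    lfc[memory, "4"] <- effect * sgn[memory]
    lfc[memory, "24"] <- effect * sgn[memory]
    counts <- matrix(0L, n_genes, nrow(design),
                     dimnames = list(genes, design$sample))
    for (j in seq_len(nrow(design))) {
      l2 <- if (design$genotype[j] == "jmjq")
        lfc[, as.character(design$time_h[j])] else 0
      mu <- base_cpm / 1e6 * libsizes[j] * 2^l2
      counts[, j] <- if (dispersion > 0)
        stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
      else stats::rpois(n_genes, mu)
    }
    truth <- data.frame(gene = genes, is_memory = memory,
                        direction = direction,
                        lfc_4h = lfc[, "4"], lfc_24h = lfc[, "24"],
                        row.names = NULL, stringsAsFactors = FALSE)
    list(counts = counts, design = design, libsizes = libsizes, truth = truth,
         seed = seed)
  })
}

#' Generate synthetic per-region ChIP coverage counts
#'
#' Poisson counts for wild type and mutant over a set of regions; a planted
#' fraction of regions has mutant mean coverage `fc_true` times the wild-type
#' mean (scaled by library size), emulating hypermethylated regions.
#'
#' @param n_regions number of regions.
#' @param planted_hyper_fraction fraction of regions planted as hyper.
#' @param fc_true true mutant/wild-type fold change of planted regions.
#' @param libsizes length-2 vector `c(wt, mut)` of library sizes.
#' @param base_mean mean wild-type coverage per region (at the wt library
#'   size).
#' @param seed integer seed.
#' @return list with `regions` (data.frame `region`, `count_wt`, `count_mut`),
#'   `libsizes`, and `truth` (per-region `planted_hyper`).
#' @export
gen_region_counts <- function(n_regions = 1000, planted_hyper_fraction = 0.1,
                              fc_true = 2, libsizes = c(wt = 2e6, mut = 2e6),
                              base_mean = 1000, seed = 1) {
  if (planted_hyper_fraction < 0 || planted_hyper_fraction > 1)
    stop("planted fraction must lie in [0, 1]")
  .with_seed(seed, {
    planted <- rep(FALSE, n_regions)
    n_pl <- round(planted_hyper_fraction * n_regions)
    if (n_pl > 0) planted[sample.int(n_regions, n_pl)] <- TRUE
    rate <- stats::rlnorm(n_regions, log(base_mean), 0.3) / libsizes[[1]]
    mu_wt <- rate * libsizes[[1]]
    mu_mut <- rate * libsizes[[2]] * ifelse(planted, fc_true, 1)
    df <- data.frame(region = sprintf("R%05d", seq_len(n_regions)),
                     count_wt = stats::rpois(n_regions, mu_wt),
                     count_mut = stats::rpois(n_regions, mu_mut),
                     stringsAsFactors = FALSE)
    list(regions = df, libsizes = libsizes,
         truth = data.frame(region = df$region, planted_hyper = planted,
                            stringsAsFactors = FALSE),
         seed = seed)
  })
}

#' Total chlorophyll from DMF-extract absorbances
#'
#' Chl a + b (micromolar) = 19.43 * A646.8 + 8.05 * A663.8.
#'
#' @param A646_8,A663_8 absorbances at 646.8 and 663.8 nm (>= 0).
#' @return Chlorophyll a + b concentration in micromolar.
#' @export
chlorophyll_content <- function(A646_8, A663_8) {
  if (any(A646_8 < 0) || any(A663_8 < 0))
    stop("absorbances must be >= 0")
  19.43 * A646_8 + 8.05 * A663_8
}
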