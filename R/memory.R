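# +ACC+HS / +HS-only profile pair for a given ACC->HS gap; ACC always starts
# at 96 h after germination, HS follows after the gap, and the profile runs
# for another 48 h so post-HS readouts are available.
.gap_profiles <- function(gap) {
  hs_time <- 96 + 1 / 3 + gap
  total <- hs_time + 1 + 48
  with_acc <- build_lab_profile(lab_protocol(hs_time = hs_time,
                                             total_duration = total))
  without_acc <- build_lab_profile(lab_protocol(acc_enabled = FALSE,
                                                hs_time = hs_time,
                                                total_duration = total))
  list(with_acc = with_acc, without_acc = without_acc, hs_end = hs_time + 1)
}

#' Acclimation memory ratio
#'
#' Quantifies priming: the ratio of predicted mRNA at a readout time after
#' heat shock between a run with an acclimation pulse `gap` hours before the
#' heat shock and an otherwise identical run without acclimation. A ratio of 1
#' means acclimation left no trace; acclimatized loci responding faster or
#' more strongly give ratios above 1.
#'
#' @param params a [model_params()].
#' @param gap hours between the end of the acclimation pulse and the heat
#'   shock (>= 0).
#' @param genotype `"WT"` or `"jmjq"`.
#' @param engine `"ode"` (mean-field) or `"ssa"` (ensemble mean).
#' @param n_runs ensemble size for the SSA engine.
#' @param seed integer seed (shared by both runs).
#' @param readout hours after the end of the heat shock at which mRNA is read
#'   (default 4 h, the time at which expression and phenotype contrasts are
#'   scored).
#' @param dt integration / signal-grid step.
#' @return Scalar memory ratio.
#' @export
memory_ratio <- function(params = model_params(), gap = 72,
                         genotype = c("WT", "jmjq"),
                         engine = c("ode", "ssa"), n_runs = 300, seed = 1,
                         readout = 4, dt = 0.05) {
  genotype <- match.arg(genotype)
  engine <- match.arg(engine)
  if (gap < 0) stop("gap must be >= 0")
  pr <- .gap_profiles(gap)
  sim <- function(profile) {
    traj <- if (engine == "ode")
      simulate_mean_field(params, profile, genotype, dt = dt)
    else simulate_ssa(params, profile, genotype, n_runs = n_runs,
                      seed = seed, dt_signal = dt)
    stats::approx(traj$time_h, traj$m, xout = pr$hs_end + readout,
                  rule = 2)$y
  }
  m_acc <- sim(pr$with_acc)
  m_no <- sim(pr$without_acc)
  if (m_no < 1e-12)
    stop("non-acclimatized expression is numerically zero; degenerate transcription parameters")
  m_acc / m_no
}

#' Scan memory duration against nucleosome number
#'
#' For each nucleosome count `N`, computes the memory ratio over a grid of
#' ACC-to-HS gaps (all other parameters identical) and reports the memory
#' duration: the largest scanned gap whose ratio still meets the threshold
#' (no interpolation; 0 when no gap qualifies). Restates, as a scan, the
#' model result that multiple modified nucleosomes lengthen the memory
#' effect.
#'
#' @param params a [model_params()]; its `N` is overridden per scan.
#' @param N_values nucleosome counts to scan.
#' @param gap_grid increasing grid of gaps (hours).
#' @param threshold memory-ratio threshold defining "remembered" (default 2).
#' @param engine `"ssa"` (default, ensemble means) or `"ode"`.
#' @param n_runs SSA ensemble size.
#' @param seed integer seed.
#' @param genotype `"WT"` or `"jmjq"`.
#' @param dt signal-grid step.
#' @return data.frame of class `memory_scan` with columns `N`, `gap_h`,
#'   `ratio`; attribute `durations` (named by N) and `threshold`.
#' @export
memory_duration_scan <- function(params = model_params(),
                                 N_values = c(2, 5, 20),
                                 gap_grid = seq(48, 336, by = 48),
                                 threshold = 2, engine = c("ssa", "ode"),
                                 n_runs = 300, seed = 1,
                                 genotype = "WT", dt = 0.05) {
  engine <- match.arg(engine)
  if (length(N_values) == 0) stop("N_values must be non-empty")
  if (any(diff(gap_grid) <= 0)) stop("gap_grid must be increasing")
  rows <- list()
  durations <- stats::setNames(numeric(length(N_values)),
                               as.character(N_values))
  for (N in N_values) {
    p <- params
    p$N <- N
    ratios <- vapply(gap_grid, function(g)
      memory_ratio(p, gap = g, genotype = genotype, engine = engine,
                   n_runs = n_runs, seed = seed, dt = dt), numeric(1))
    ok <- gap_grid[ratios >= threshold]
    durations[as.character(N)] <- if (length(ok)) max(ok) else 0
    rows[[length(rows) + 1]] <- data.frame(N = N, gap_h = gap_grid,
                                           ratio = ratios)
  }
  out <- do.call(rbind, rows)
  attr(out, "durations") <- durations
  attr(out, "threshold") <- threshold
  class(out) <- c("memory_scan", "data.frame")
  out
}
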