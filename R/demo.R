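.write_tsv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' End-to-end lab-protocol demo
#'
#' Simulates wild type and the demethylase mutant under the memory condition
#' (+ACC +HS) and the basal condition (+HS only), and summarises predicted
#' expression right after acclimation, right after heat shock, and 4 and 24 h
#' into recovery.
#'
#' @param params a [model_params()].
#' @param obs an [observation_params()].
#' @param dt integration step.
#' @param out_dir optional directory for trajectory/summary TSV files.
#' @return list with `trajectories` (named list of 4 trajectory data.frames)
#'   and `summary` (scenario x genotype table of mRNA at ACC+0 h, HS+0 h,
#'   HS+4 h, HS+24 h).
#' @export
run_demo_lab <- function(params = model_params(),
                         obs = observation_params(), dt = 0.05,
                         out_dir = NULL) {
  protos <- list(`+ACC+HS` = lab_protocol(),
                 `+HS` = lab_protocol(acc_enabled = FALSE))
  acc_end <- 96 + 1 / 3
  hs_end <- 169
  readouts <- c(`ACC+0h` = acc_end, `HS+0h` = hs_end, `HS+4h` = hs_end + 4,
                `HS+24h` = hs_end + 24)
  trajs <- list()
  rows <- list()
  for (sc in names(protos)) {
    profile <- build_lab_profile(protos[[sc]])
    for (g in c("WT", "jmjq")) {
      traj <- simulate_mean_field(params, profile, genotype = g, dt = dt)
      key <- paste0(sc, ":", g)
      trajs[[key]] <- traj
      .write_tsv(traj[, c("time_h", "r", "a", "m", "sem_r", "sem_m")],
                 out_dir, paste0("traj_", gsub("[+:]", "_", key), ".tsv"))
      m_at <- stats::approx(traj$time_h, traj$m, xout = readouts, rule = 2)$y
      rows[[key]] <- data.frame(scenario = sc, genotype = g,
                                t(stats::setNames(m_at, names(readouts))),
                                check.names = FALSE)
    }
  }
  summary_tab <- do.call(rbind, rows)
  rownames(summary_tab) <- NULL
  .write_tsv(summary_tab, out_dir, "summary_lab.tsv")
  list(trajectories = trajs, summary = summary_tab)
}

#' End-to-end fluctuating-field demo
#'
#' Generates (or accepts) a fluctuating field temperature series, annotates
#' its heat spikes (first = ACC, second = HS), and simulates both genotypes
#' across it.
#'
#' @param params a [model_params()].
#' @param spec a [field_spec()] used when no profile is given.
#' @param profile optional [temperature_profile()] (e.g. from
#'   [read_temperature_csv()]).
#' @param dt integration step.
#' @param out_dir optional output directory.
#' @return list with `profile`, `spikes`, `trajectories` (per genotype), and
#'   `peak_summary` (per spike and genotype: mRNA maximum within a day after
#'   the spike).
#' @export
run_demo_field <- function(params = model_params(), spec = field_spec(),
                           profile = NULL, dt = 0.05, out_dir = NULL) {
  if (is.null(profile)) profile <- gen_field_profile(spec)
  spikes <- detect_spikes(profile)
  if (nrow(spikes) == 0)
    warning("no heat spikes above 30 degC detected in the field profile")
  trajs <- list()
  peak_rows <- list()
  for (g in c("WT", "jmjq")) {
    traj <- simulate_mean_field(params, profile, genotype = g, dt = dt)
    trajs[[g]] <- traj
    .write_tsv(traj[, c("time_h", "r", "a", "m", "sem_r", "sem_m")],
               out_dir, paste0("traj_field_", g, ".tsv"))
    for (i in seq_len(nrow(spikes))) {
      win <- traj$time_h >= spikes$end_h[i] - 1 &
        traj$time_h <= spikes$end_h[i] + 24
      peak_rows[[paste(g, i)]] <- data.frame(
        genotype = g, spike = spikes$role[i], spike_end_h = spikes$end_h[i],
        peak_m = max(traj$m[win]),
        peak_time_h = traj$time_h[win][which.max(traj$m[win])])
    }
  }
  peak_summary <- do.call(rbind, peak_rows)
  rownames(peak_summary) <- NULL
  .write_tsv(peak_summary, out_dir, "summary_field.tsv")
  list(profile = profile, spikes = spikes, trajectories = trajs,
       peak_summary = peak_summary)
}

#' End-to-end screening demo on synthetic counts
#'
#' Generates a count matrix with planted memory genes, runs the full
#' differential-expression screen (common dispersion, NB LRT at 0/4/24 h, the
#' 0/4/24-h memory criterion), clusters the selected genes' expression
#' profiles, plants hypermethylated region calls on a fraction of the true
#' down-regulated memory genes, and tests the overlap between screened-down
#' genes and hyper regions.
#'
#' @param n_genes,n_memory,effect,dispersion passed to [gen_count_matrix()].
#' @param alpha FDR threshold for the screen.
#' @param k number of expression clusters.
#' @param hyper_on_down fraction of planted down-memory genes that also carry
#'   a planted hypermethylated region.
#' @param hyper_background fraction of all other genes with a planted hyper
#'   region.
#' @param seed integer seed.
#' @param out_dir optional output directory.
#' @return list with `screen` (selected genes), `confusion` (sensitivity,
#'   FDR, counts vs the planted truth), `clusters`, `overlap_p`, and the
#'   generated `truth`.
#' @export
run_screen_demo <- function(n_genes = 5000, n_memory = 200, effect = 2,
                            dispersion = 0.1, alpha = 0.05, k = 6,
                            hyper_on_down = 0.55, hyper_background = 0.05,
                            seed = 1, out_dir = NULL) {
  gen <- gen_count_matrix(n_genes = n_genes, n_memory = n_memory,
                          effect = effect, dispersion = dispersion,
                          seed = seed)
  phi <- estimate_common_dispersion(gen$counts, gen$design, gen$libsizes)
  de <- lapply(c(0, 4, 24), function(tt)
    nb_lrt(gen$counts, gen$design, tt, phi, gen$libsizes))
  screen <- screen_memory_genes(de[[1]], de[[2]], de[[3]], alpha = alpha)

  truth <- gen$truth
  is_mem <- truth$is_memory
  sel <- truth$gene %in% screen$gene
  tp <- sum(sel & is_mem)
  confusion <- data.frame(selected = sum(sel), true_memory = sum(is_mem),
                          tp = tp, fp = sum(sel & !is_mem),
                          sensitivity = tp / sum(is_mem),
                          fdr = if (sum(sel)) sum(sel & !is_mem) / sum(sel)
                                else 0)

  # cluster selected genes' mean log2 CPM profiles over genotype x time
  clusters <- NULL
  if (nrow(screen) >= k) {
    cpm <- cpm_normalize(gen$counts, gen$libsizes)
    grp <- interaction(gen$design$genotype, gen$design$time_h, drop = TRUE)
    prof <- sapply(levels(grp), function(g)
      rowMeans(log2(cpm[screen$gene, gen$design$sample[grp == g],
                        drop = FALSE] + 1)))
    clusters <- cluster_profiles(prof, k = k, seed = seed)
  }

  # plant hyper regions: hyper_on_down of the true down-memory genes,
  # hyper_background elsewhere, then test the screened-down overlap
  hyper <- .with_seed(seed + 1, {
    down_mem <- truth$gene[is_mem & truth$direction == "down"]
    others <- setdiff(truth$gene, down_mem)
    c(sample(down_mem, round(hyper_on_down * length(down_mem))),
      sample(others, round(hyper_background * length(others))))
  })
  screened_down <- screen$gene[screen$direction == "down"]
  overlap_p <- hypergeom_overlap(
    n_A = length(screened_down), n_B = length(hyper),
    n_overlap = length(intersect(screened_down, hyper)),
    n_universe = n_genes)

  .write_tsv(screen, out_dir, "screen.tsv")
  .write_tsv(confusion, out_dir, "confusion.tsv")
  if (!is.null(clusters))
    .write_tsv(data.frame(gene = names(clusters), cluster = clusters),
               out_dir, "clusters.tsv")
  list(screen = screen, confusion = confusion, clusters = clusters,
       overlap_p = overlap_p, dispersion_hat = phi, truth = truth)
}
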