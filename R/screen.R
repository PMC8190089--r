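.validate_counts <- function(counts, design = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (genes x samples)")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (!is.null(design)) {
    need <- c("sample", "genotype", "time_h", "replicate")
    miss <- setdiff(need, names(design))
    if (length(miss))
      stop("design lacks column(s): ", paste(miss, collapse = ", "))
    if (!all(colnames(counts) %in% design$sample))
      stop("every count column must appear in the design table")
  }
  invisible(counts)
}

#' Counts-per-million normalization
#'
#' @param counts genes x samples integer matrix.
#' @param libsizes per-sample library sizes; defaults to column sums.
#' @return Matrix of CPM values.
#' @export
cpm_normalize <- function(counts, libsizes = colSums(counts)) {
  .validate_counts(counts)
  if (any(libsizes <= 0)) stop("library sizes must be > 0")
  sweep(counts, 2, libsizes, "/") * 1e6
}

#' Method-of-moments common NB dispersion
#'
#' Pools the negative-binomial mean-variance relation `var = mu + phi mu^2`
#' over all genes within replicate groups (same genotype and time). Counts are
#' first rescaled to each group's mean library size so that library-size
#' variation does not inflate the estimate. The estimate is clipped at 0.
#'
#' @param counts genes x samples integer matrix.
#' @param design design table (`sample`, `genotype`, `time_h`, `replicate`).
#' @param libsizes per-sample library sizes; defaults to column sums.
#' @return Scalar dispersion `phi >= 0`.
#' @export
estimate_common_dispersion <- function(counts, design,
                                       libsizes = colSums(counts)) {
  .validate_counts(counts, design)
  grp <- interaction(design$genotype, design$time_h, drop = TRUE)
  names(libsizes) <- design$sample[match(colnames(counts), design$sample)]
  ms <- numeric(0); vs <- numeric(0); ns <- numeric(0)
  for (g in levels(grp)) {
    cols <- design$sample[grp == g]
    cols <- intersect(colnames(counts), cols)
    if (length(cols) < 2) next
    l <- libsizes[cols]
    y <- sweep(counts[, cols, drop = FALSE], 2, mean(l) / l, "*")
    m <- rowMeans(y)
    v <- apply(y, 1, stats::var)
    keep <- m > 0
    ms <- c(ms, m[keep]); vs <- c(vs, v[keep])
    ns <- c(ns, rep(length(cols), sum(keep)))
  }
  if (length(ms) == 0)
    stop("no replicated (genotype, time) group in the design")
  # per gene-group moment equations E[v - m] = phi mu^2 and
  # E[m^2 - v/n] = mu^2 (the v/n correction removes the upward bias of m^2),
  # pooled with inverse-variance weights w = 1/(m + phi m^2)^2 since
  # Var(v) scales with (mu + phi mu^2)^2; iterated to a fixed point
  phi <- 0
  for (it in 1:25) {
    w <- 1 / pmax(ms + phi * ms^2, 1e-12)^2
    phi_new <- max(0, sum(w * (vs - ms)) / sum(w * (ms^2 - vs / ns)))
    if (abs(phi_new - phi) < 1e-12) { phi <- phi_new; break }
    phi <- phi_new
  }
  phi
}

# NB log-likelihood at per-library rate lambda (mu_i = lambda * L_i),
# phi = 0 reduces to Poisson; constants in y are kept (they cancel in LRTs)
.nb_loglik <- function(y, L, lambda, phi) {
  mu <- outer(lambda, L)
  if (phi == 0) {
    rowSums(y * log(pmax(mu, 1e-300)) - mu - lgamma(y + 1))
  } else {
    k <- 1 / phi
    rowSums(lgamma(y + k) - lgamma(k) - lgamma(y + 1) +
              y * log(mu / (mu + k) + (mu == 0)) + k * log(k / (k + mu)))
  }
}

# MLE of the per-library rate for NB counts with library-size offsets
.nb_rate_mle <- function(y, L, phi) {
  lambda <- pmax(rowSums(y) / sum(L), 1e-12)
  if (phi > 0) {
    k <- 1 / phi
    for (it in 1:25) {
      denom <- sweep(1 / (outer(lambda, L) + k), 2, L, "*") *
        (y + k)  # (y+k) L / (k + lambda L)
      lam_new <- pmax(rowSums(y), 1e-12) / pmax(rowSums(denom), 1e-300)
      if (max(abs(lam_new - lambda) / pmax(lambda, 1e-12)) < 1e-10) {
        lambda <- lam_new; break
      }
      lambda <- lam_new
    }
  }
  lambda
}

#' Negative-binomial likelihood-ratio test, mutant vs wild type
#'
#' Per-gene two-group comparison at one time point with a common dispersion:
#' the full model fits one mean per genotype (with library-size offsets), the
#' null a shared mean; twice the log-likelihood difference is referred to a
#' chi-square with 1 degree of freedom. At `dispersion = 0` this is exactly
#' the Poisson likelihood-ratio test.
#'
#' @param counts genes x samples integer matrix.
#' @param design design table.
#' @param contrast_time the time (h) at which to compare genotypes.
#' @param dispersion common NB dispersion `phi >= 0`.
#' @param libsizes per-sample library sizes; defaults to column sums over all
#'   samples (so normalization is consistent across contrasts).
#' @return data.frame of class `heatmem_de` with columns `gene`, `log2FC`
#'   (mutant vs wild type, with a small pseudo-rate to guard zeros), `stat`,
#'   `pvalue`, `qvalue` (Benjamini-Hochberg); attribute `contrast_time`.
#' @export
nb_lrt <- function(counts, design, contrast_time, dispersion,
                   libsizes = colSums(counts)) {
  .validate_counts(counts, design)
  if (dispersion < 0) stop("dispersion must be >= 0")
  names(libsizes) <- colnames(counts)
  sel <- design$time_h == contrast_time
  cols_wt <- design$sample[sel & design$genotype == "WT"]
  cols_mut <- design$sample[sel & design$genotype == "jmjq"]
  if (length(cols_wt) < 2 || length(cols_mut) < 2)
    stop("both genotypes need >= 2 replicates at the contrast time")
  y_wt <- counts[, cols_wt, drop = FALSE]
  y_mut <- counts[, cols_mut, drop = FALSE]
  L_wt <- libsizes[cols_wt]; L_mut <- libsizes[cols_mut]

  lam_wt <- .nb_rate_mle(y_wt, L_wt, dispersion)
  lam_mut <- .nb_rate_mle(y_mut, L_mut, dispersion)
  lam_0 <- .nb_rate_mle(cbind(y_wt, y_mut), c(L_wt, L_mut), dispersion)

  l_full <- .nb_loglik(y_wt, L_wt, lam_wt, dispersion) +
    .nb_loglik(y_mut, L_mut, lam_mut, dispersion)
  l_null <- .nb_loglik(cbind(y_wt, y_mut), c(L_wt, L_mut), lam_0, dispersion)
  stat <- pmax(0, 2 * (l_full - l_null))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  pseudo <- 0.5 / mean(c(L_wt, L_mut))
  out <- data.frame(gene = rownames(counts),
                    log2FC = log2((lam_mut + pseudo) / (lam_wt + pseudo)),
                    stat = stat, pvalue = p, qvalue = bh_adjust(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast_time") <- contrast_time
  class(out) <- c("heatmem_de", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()], method `"BH"`).
#'
#' @param pvalues numeric vector in `[0, 1]`, no missing values.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues))) stop("p-values must not contain NA/NaN")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Screen for memory genes from three differential-expression results
#'
#' Implements the acclimation-memory screening criterion: a gene qualifies
#' when it shows no genotype difference immediately after heat shock
#' (`q_0h >= alpha`) but a significant difference after either 4 or 24 h
#' (`q_4h < alpha` or `q_24h < alpha`). The reported direction is the sign of
#' the mutant-vs-wild-type log2 fold change at the earliest qualifying time.
#'
#' @param de_0h,de_4h,de_24h [nb_lrt()] results over the same gene universe.
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame of class `screen_result` with one row per selected gene:
#'   `gene`, `direction` (`up`/`down` in the mutant), `qualifies_4h`,
#'   `qualifies_24h`; attributes `alpha` and `universe` (all tested genes).
#' @export
screen_memory_genes <- function(de_0h, de_4h, de_24h, alpha = 0.05) {
  g0 <- de_0h$gene
  for (de in list(de_4h, de_24h)) {
    if (!identical(sort(de$gene), sort(g0))) {
      diffs <- c(setdiff(g0, de$gene), setdiff(de$gene, g0))
      stop("gene universes differ between contrasts: ",
           paste(utils::head(diffs, 10), collapse = ", "))
    }
  }
  q0 <- de_0h$qvalue
  q4 <- de_4h$qvalue[match(g0, de_4h$gene)]
  q24 <- de_24h$qvalue[match(g0, de_24h$gene)]
  sel <- q0 >= alpha & (q4 < alpha | q24 < alpha)
  first_lfc <- ifelse(q4 < alpha, de_4h$log2FC[match(g0, de_4h$gene)],
                      de_24h$log2FC[match(g0, de_24h$gene)])
  out <- data.frame(gene = g0[sel],
                    direction = ifelse(first_lfc[sel] > 0, "up", "down"),
                    qualifies_4h = (q4 < alpha)[sel],
                    qualifies_24h = (q24 < alpha)[sel],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "universe") <- g0
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Cluster expression profiles
#'
#' Rows (genes) are z-scored and clustered with Lloyd k-means over seeded
#' restarts; on z-scored rows squared Euclidean distance is a monotone
#' transform of one minus the Pearson correlation, so this is the standard
#' correlation-based profile clustering. Constant rows cannot be z-scored and
#' are dropped with a warning. The default `k = 6` follows the six-cluster
#' partition of the memory-gene screen.
#'
#' @param expr numeric matrix: genes x (genotype-by-time) mean expression
#'   columns (e.g. mean log2 CPM).
#' @param k number of clusters.
#' @param seed integer seed (assignments are deterministic given the seed).
#' @param restarts number of random restarts; the best within-cluster sum of
#'   squares wins.
#' @return Named integer vector of cluster assignments (1..k) for the
#'   non-constant rows.
#' @export
cluster_profiles <- function(expr, k = 6, seed = 1, restarts = 100) {
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant row(s) dropped before clustering")
    expr <- expr[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (k > nrow(expr)) stop("k exceeds the number of usable genes")
  z <- (expr - rowMeans(expr)) / sds
  .with_seed(seed, {
    # Lloyd restarts routinely produce transient empty clusters; only the
    # best restart is kept, so muffle that specific warning
    km <- withCallingHandlers(
      stats::kmeans(z, centers = k, nstart = restarts,
                    algorithm = "Lloyd", iter.max = 500),
      warning = function(w) {
        if (grepl("empty cluster", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    stats::setNames(km$cluster, rownames(expr))
  })
}

#' Hypergeometric overlap test
#'
#' Upper-tail probability that two gene sets drawn from a common universe
#' share at least the observed number of genes:
#' `P[X >= n_overlap]` with `X ~ Hypergeometric(n_universe, n_B, n_A)`.
#'
#' @param n_A size of set A (draws).
#' @param n_B size of set B (successes in the universe).
#' @param n_overlap observed overlap.
#' @param n_universe universe size.
#' @return Upper-tail p-value.
#' @export
hypergeom_overlap <- function(n_A, n_B, n_overlap, n_universe) {
  if (n_overlap > min(n_A, n_B) || max(n_A, n_B) > n_universe ||
      n_overlap < 0 || n_A + n_B - n_overlap > n_universe)
    stop("inconsistent overlap counts")
  stats::phyper(n_overlap - 1, n_B, n_universe - n_B, n_A,
                lower.tail = FALSE)
}

#' Read a BED file of gene-body regions
#'
#' Minimal three-plus-column BED reader (0-based, half-open intervals) with
#' per-line validation.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end`, and `name` (from column 4
#'   when present, otherwise `chrom:start-end`).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty BED file: ", path)
  parse_line <- function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed BED line %d: fewer than 3 fields", i))
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || start < 0 || end <= start ||
        start != round(start) || end != round(end))
      stop(sprintf("malformed BED line %d: bad coordinates", i))
    data.frame(chrom = f[1], start = start, end = end,
               name = if (length(f) >= 4) f[4]
                      else sprintf("%s:%d-%d", f[1], start, end),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(lines), parse_line))
  rownames(out) <- NULL
  out
}

#' Call hyper-/hypomethylated regions by fold enrichment
#'
#' Compares library-size-normalized coverage between mutant and wild type per
#' region: `ratio = CPM_mut / CPM_wt` with a pseudocount of 0.5 added to each
#' count. A region is called `hyper` when `ratio >= fc`, `hypo` when
#' `ratio <= 1/fc`, otherwise `none` (default threshold 1.5-fold).
#'
#' @param cov_wt,cov_mut per-region counts (equal length; names or the
#'   `regions` argument give region ids).
#' @param lib_wt,lib_mut library sizes (> 0).
#' @param fc fold-enrichment threshold.
#' @param regions optional region ids, a data.frame from [read_bed()], or a
#'   BED file path.
#' @return data.frame of class `region_calls`: `region`, `cpm_wt`, `cpm_mut`,
#'   `ratio`, `call`.
#' @export
call_fold_change_regions <- function(cov_wt, cov_mut, lib_wt, lib_mut,
                                     fc = 1.5, regions = NULL) {
  if (length(cov_wt) != length(cov_mut))
    stop("coverage vectors must have equal length")
  if (lib_wt <= 0 || lib_mut <= 0) stop("library sizes must be > 0")
  if (fc <= 1) stop("fold-change threshold must exceed 1")
  ids <- if (is.null(regions)) {
    if (!is.null(names(cov_wt))) names(cov_wt)
    else sprintf("R%05d", seq_along(cov_wt))
  } else if (is.character(regions) && length(regions) == 1 &&
             file.exists(regions)) {
    read_bed(regions)$name
  } else if (is.data.frame(regions)) regions$name
  else as.character(regions)
  if (length(ids) != length(cov_wt))
    stop("number of regions does not match coverage length")
  cpm_wt <- (cov_wt + 0.5) / lib_wt * 1e6
  cpm_mut <- (cov_mut + 0.5) / lib_mut * 1e6
  ratio <- cpm_mut / cpm_wt
  call <- ifelse(ratio >= fc, "hyper", ifelse(ratio <= 1 / fc, "hypo",
                                              "none"))
  out <- data.frame(region = ids, cpm_wt = cpm_wt, cpm_mut = cpm_mut,
                    ratio = ratio, call = call, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("region_calls", "data.frame")
  out
}
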