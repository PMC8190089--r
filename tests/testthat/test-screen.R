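toy_design <- function(reps = 2, times = 0) {
  d <- expand.grid(replicate = seq_len(reps), time_h = times,
                   genotype = c("WT", "jmjq"), stringsAsFactors = FALSE)[, 3:1]
  d$sample <- sprintf("%s_t%g_r%d", d$genotype, d$time_h, d$replicate)
  d
}

test_that("CPM normalization is a per-column rescaling", {
  m <- matrix(c(5L, 0L, 10L, 0L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cpm <- cpm_normalize(m, libsizes = c(1e6, 2e6))
  expect_equal(cpm["g1", "s1"], 5)
  expect_equal(cpm["g2", ], c(s1 = 0, s2 = 0))
  # doubling all counts in a sample leaves its CPM unchanged (column sums)
  m2 <- m
  m2[, 2] <- m2[, 2] * 2L
  expect_equal(cpm_normalize(m2)[, 2], cpm_normalize(m)[, 2])
  expect_error(cpm_normalize(m, libsizes = c(0, 1)), "> 0")
  expect_error(cpm_normalize(matrix(-1, 1, 1)), "non-negative")
})

test_that("dispersion estimate is near zero for Poisson counts", {
  gen <- gen_count_matrix(n_genes = 2000, n_memory = 0, dispersion = 0,
                          seed = 4)
  phi <- estimate_common_dispersion(gen$counts, gen$design, gen$libsizes)
  expect_lte(phi, 0.01)
})

test_that("dispersion estimate recovers the generating value", {
  des <- toy_design(reps = 4, times = c(0, 4, 24))
  gen <- gen_count_matrix(n_genes = 2000, n_memory = 0, design = des,
                          dispersion = 0.1, seed = 9)
  phi <- estimate_common_dispersion(gen$counts, gen$design, gen$libsizes)
  expect_gte(phi, 0.05)
  expect_lte(phi, 0.2)
})

test_that("constant counts within groups give zero dispersion", {
  des <- toy_design(reps = 3)
  m <- matrix(50L, 4, 6, dimnames = list(paste0("g", 1:4), des$sample))
  expect_equal(estimate_common_dispersion(m, des, rep(1e6, 6)), 0)
})

test_that("unreplicated designs are rejected for dispersion estimation", {
  des <- toy_design(reps = 1)
  m <- matrix(5L, 2, 2, dimnames = list(c("g1", "g2"), des$sample))
  expect_error(estimate_common_dispersion(m, des, c(1e6, 1e6)),
               "no replicated")
})

test_that("Poisson-limit likelihood ratio matches the closed form", {
  des <- toy_design(reps = 2)
  counts <- matrix(c(10L, 10L, 20L, 20L), 1, 4,
                   dimnames = list("g1", des$sample))
  libs <- rep(1e6, 4)
  names(libs) <- des$sample
  de <- nb_lrt(counts, des, contrast_time = 0, dispersion = 0,
               libsizes = libs)
  stat_exact <- 2 * (20 * log(2 / 3) + 40 * log(4 / 3))
  expect_equal(de$stat, stat_exact, tolerance = 1e-9)
  expect_equal(de$pvalue, pchisq(stat_exact, 1, lower.tail = FALSE))
  expect_equal(de$pvalue, 0.0091, tolerance = 1e-2)
  expect_gt(de$log2FC, 0)  # mutant higher
})

test_that("identical groups give a null test result", {
  des <- toy_design(reps = 2)
  counts <- matrix(c(15L, 15L, 15L, 15L), 1, 4,
                   dimnames = list("g1", des$sample))
  de <- nb_lrt(counts, des, 0, dispersion = 0.1, libsizes = rep(1e6, 4))
  expect_equal(de$stat, 0, tolerance = 1e-10)
  expect_equal(de$pvalue, 1)
  expect_equal(de$log2FC, 0)
})

test_that("swapping genotype labels mirrors the fold change only", {
  des <- toy_design(reps = 3)
  set.seed(2)
  counts <- matrix(rpois(30, 40), 5, 6,
                   dimnames = list(paste0("g", 1:5), des$sample))
  libs <- rep(1e6, 6)
  de1 <- nb_lrt(counts, des, 0, dispersion = 0.05, libsizes = libs)
  des_swapped <- des
  des_swapped$genotype <- ifelse(des$genotype == "WT", "jmjq", "WT")
  de2 <- nb_lrt(counts, des_swapped, 0, dispersion = 0.05, libsizes = libs)
  expect_equal(de2$log2FC, -de1$log2FC, tolerance = 1e-6)
  expect_equal(de2$pvalue, de1$pvalue, tolerance = 1e-8)
})

test_that("the negative-binomial test respects its preconditions", {
  des <- toy_design(reps = 2)
  counts <- matrix(1L, 1, 4, dimnames = list("g", des$sample))
  expect_error(nb_lrt(counts, des, 0, dispersion = -1), ">= 0")
  expect_error(nb_lrt(counts, des, 99, dispersion = 0.1), "replicates")
})

test_that("BH adjustment matches the hand step-up computation", {
  bh_hand <- function(p) {
    n <- length(p)
    o <- order(p)
    q_sorted <- p[o] * n / seq_len(n)
    q_sorted <- rev(cummin(rev(q_sorted)))
    out <- numeric(n)
    out[o] <- pmin(q_sorted, 1)
    out
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  for (p in list(c(0.005, 0.04, 0.03, 0.02), c(0.5, 0.001, 0.9, 0.25),
                 runif(25))) {
    expect_equal(bh_adjust(p), bh_hand(p))
  }
  expect_equal(bh_adjust(0.123), 0.123)
  # order preservation
  p <- c(0.001, 0.3, 0.04, 0.7)
  expect_equal(order(bh_adjust(p)), order(p))
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("screen criterion keeps only late-diverging genes", {
  mk <- function(q, lfc, t) {
    d <- data.frame(gene = paste0("g", seq_along(q)), log2FC = lfc,
                    stat = 1, pvalue = q, qvalue = q,
                    stringsAsFactors = FALSE)
    attr(d, "contrast_time") <- t
    class(d) <- c("heatmem_de", "data.frame")
    d
  }
  # g1: selected via 4 h; g2: differs already at 0 h; g3: never differs;
  # g4: selected via 24 h only, downward
  de0 <- mk(c(0.50, 0.01, 0.50, 0.30), c(0.1, 2.0, 0.0, -0.1), 0)
  de4 <- mk(c(0.01, 0.001, 0.20, 0.40), c(1.5, 2.0, 0.2, -0.5), 4)
  de24 <- mk(c(0.20, 0.001, 0.30, 0.01), c(1.0, 2.0, 0.1, -2.0), 24)
  sel <- screen_memory_genes(de0, de4, de24, alpha = 0.05)
  expect_equal(sel$gene, c("g1", "g4"))
  expect_equal(sel$direction, c("up", "down"))
  expect_equal(sel$qualifies_4h, c(TRUE, FALSE))
  expect_equal(sel$qualifies_24h, c(FALSE, TRUE))
  # mismatched universes are rejected with the offending genes listed
  de24_bad <- de24
  de24_bad$gene[4] <- "g99"
  expect_error(screen_memory_genes(de0, de4, de24_bad, alpha = 0.05), "g99")
})

test_that("planted profile groups are separated perfectly at k = 2", {
  set.seed(1)
  up <- matrix(rep(c(0, 2, 4), each = 20), 20, 3) + rnorm(60, sd = 0.05)
  down <- matrix(rep(c(4, 2, 0), each = 20), 20, 3) + rnorm(60, sd = 0.05)
  expr <- rbind(up, down)
  rownames(expr) <- paste0("g", 1:40)
  cl <- cluster_profiles(expr, k = 2, seed = 3)
  expect_length(unique(cl[1:20]), 1)
  expect_length(unique(cl[21:40]), 1)
  expect_false(cl[[1]] == cl[[21]])
})

test_that("clustering is deterministic and groups duplicated rows together", {
  set.seed(8)
  expr <- matrix(rnorm(120), 20, 6)
  rownames(expr) <- paste0("g", 1:20)
  expr[20, ] <- expr[1, ]  # duplicate row
  c1 <- cluster_profiles(expr, k = 4, seed = 5)
  c2 <- cluster_profiles(expr, k = 4, seed = 5)
  expect_identical(c1, c2)
  expect_equal(c1[["g1"]], c1[["g20"]])
})

test_that("constant expression rows are dropped with a warning", {
  expr <- matrix(rnorm(30), 10, 3)
  rownames(expr) <- paste0("g", 1:10)
  expr[3, ] <- 7
  expect_warning(cl <- cluster_profiles(expr, k = 2, seed = 1), "constant")
  expect_false("g3" %in% names(cl))
  expect_error(suppressWarnings(cluster_profiles(expr[1:3, ], k = 5)),
               "k exceeds")
})

test_that("hypergeometric overlap matches full enumeration up to size 12", {
  enum_p <- function(n_A, n_B, ov, U) {
    ks <- ov:min(n_A, n_B)
    sum(choose(n_B, ks) * choose(U - n_B, n_A - ks)) / choose(U, n_A)
  }
  for (U in 1:12) {
    for (n_B in 0:U) {
      for (n_A in 0:U) {
        lo <- max(0, n_A + n_B - U)
        for (ov in lo:min(n_A, n_B)) {
          expect_equal(hypergeom_overlap(n_A, n_B, ov, U),
                       enum_p(n_A, n_B, ov, U), tolerance = 1e-12)
        }
      }
    }
  }
  expect_equal(hypergeom_overlap(4, 5, 3, 10), 55 / 210)
  expect_equal(hypergeom_overlap(4, 5, 0, 10), 1)
  expect_equal(hypergeom_overlap(10, 10, 10, 10), 1)
  expect_error(hypergeom_overlap(4, 5, 6, 10), "inconsistent")
  expect_error(hypergeom_overlap(8, 8, 2, 10), "inconsistent")
})

test_that("overlap significance sharpens as the universe grows", {
  ps <- vapply(c(200, 500, 1000, 5000), function(U)
    hypergeom_overlap(50, 40, 20, U), numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("BED reader validates coordinates line by line", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tgeneA", "chr1\t200\t300", "chr2\t5\t50\tgeneB"),
             path)
  bed <- read_bed(path)
  expect_equal(bed$name, c("geneA", "chr1:200-300", "geneB"))
  expect_equal(bed$start, c(0, 200, 5))
  writeLines(c("chr1\t0\t100\tok", "chr1\t50"), path)
  expect_error(read_bed(path), "line 2")
  writeLines(c("chr1\t100\t40\tbad"), path)
  expect_error(read_bed(path), "line 1")
  writeLines(character(0), path)
  expect_error(read_bed(path), "empty")
})

test_that("fold-enrichment caller reproduces the hyper/none/hypo triple", {
  calls <- call_fold_change_regions(cov_wt = c(100, 100, 200),
                                    cov_mut = c(160, 100, 100),
                                    lib_wt = 1e6, lib_mut = 1e6)
  expect_equal(calls$call, c("hyper", "none", "hypo"))
  expect_equal(calls$cpm_wt, c(100.5, 100.5, 200.5))
  expect_equal(calls$cpm_mut, c(160.5, 100.5, 100.5))
  expect_equal(calls$ratio, c(160.5 / 100.5, 1, 100.5 / 200.5))
  expect_error(call_fold_change_regions(1, c(1, 2), 1e6, 1e6), "equal length")
  expect_error(call_fold_change_regions(1, 1, 0, 1e6), "> 0")
  expect_error(call_fold_change_regions(1, 1, 1e6, 1e6, fc = 1), "exceed 1")
})

test_that("region calls can take their identifiers from a BED file", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tr1", "chr1\t100\t200\tr2"), path)
  calls <- call_fold_change_regions(c(10, 10), c(30, 10), 1e6, 1e6,
                                    regions = path)
  expect_equal(calls$region, c("r1", "r2"))
})

test_that("planted hyper regions are recovered by the 1.5-fold caller", {
  gen <- gen_region_counts(seed = 2)
  calls <- call_fold_change_regions(gen$regions$count_wt,
                                    gen$regions$count_mut,
                                    gen$libsizes[["wt"]],
                                    gen$libsizes[["mut"]])
  planted <- gen$truth$planted_hyper
  expect_gte(mean(calls$call[planted] == "hyper"), 0.95)
  # and near-pure noise does not trigger calls
  gen0 <- gen_region_counts(planted_hyper_fraction = 0, seed = 3)
  calls0 <- call_fold_change_regions(gen0$regions$count_wt,
                                     gen0$regions$count_mut,
                                     gen0$libsizes[["wt"]],
                                     gen0$libsizes[["mut"]])
  expect_lte(mean(calls0$call == "hyper"), 0.05)
})
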