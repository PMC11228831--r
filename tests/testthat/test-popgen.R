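test_that("SFS construction handles monomorphic, singleton and missing data", {
  D <- matrix(0L, nrow = 10, ncol = 5)
  G <- genotype_matrix(D, 1:5 * 100, "c", rep("A", 5), rep("T", 5),
                       sprintf("s%d", 1:10))
  sfs <- sfs_from_genotypes(G)
  expect_identical(sum(sfs$counts), 0)
  # one singleton among 10 diploids, folded
  D[1, 3] <- 1L
  Gs <- genotype_matrix(D, 1:5 * 100, "c", rep("A", 5), rep("T", 5),
                        sprintf("s%d", 1:10))
  f <- sfs_from_genotypes(Gs, folded = TRUE)
  expect_identical(f$counts[1], 1)
  expect_identical(sum(f$counts), 1)
  expect_length(f$counts, 10)
  # hypergeometric projection conserves mass for sites above the floor
  D[2, 3] <- NA
  Gm <- genotype_matrix(D, 1:5 * 100, "c", rep("A", 5), rep("T", 5),
                        sprintf("s%d", 1:10))
  u <- sfs_from_genotypes(Gm)
  expect_identical(u$n_chromosomes, 18)
  expect_equal(sum(u$counts), 1, tolerance = 1e-12)
  expect_error(sfs_from_genotypes(genotype_matrix(
    matrix(NA_integer_, 4, 2), c(1, 2), "c", c("A", "A"), c("T", "T"),
    sprintf("s%d", 1:4))), "missing")
})

test_that("Watterson's theta and Tajima's D match independent formulas", {
  expect_identical(watterson_theta(0, 10), 0)
  expect_equal(watterson_theta(10, 10), 10 / sum(1 / 1:9), tolerance = 1e-12)
  expect_error(watterson_theta(3, 1), "chromosomes")
  # frozen oracle value for a fixed unfolded spectrum (independent script)
  cnt <- c(5, 3, 2, 1, 1, 0, 1, 0, 2)
  sfs <- make_sfs(cnt, 10)
  expect_equal(pi_from_sfs(sfs), 4.955555555555556, tolerance = 1e-12)
  expect_equal(tajimas_d(sfs), -0.3011997592918769, tolerance = 1e-10)
  expect_equal(tajimas_d(sfs), tajima_oracle(cnt, 10), tolerance = 1e-12)
  # undefined cases are missing with a reason
  expect_true(is.na(tajimas_d(make_sfs(numeric(9), 10))))
  expect_identical(attr(tajimas_d(make_sfs(numeric(9), 10)), "reason"),
                   "no segregating sites")
  # all-singleton spectrum: strongly negative D
  expect_lt(tajimas_d(make_sfs(c(20, rep(0, 8)), 10)), 0)
})

test_that("pi and theta_w from one SFS satisfy the D numerator identity", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(4:40, 1)
    counts <- stats::rpois(n - 1, 30 / seq_len(n - 1))
    if (sum(counts) == 0) counts[1] <- 1
    sfs <- make_sfs(counts, n)
    S <- sum(counts)
    a1 <- sum(1 / seq_len(n - 1))
    D <- tajimas_d(sfs)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    a2 <- sum(1 / seq_len(n - 1)^2)
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    denom <- sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
    expect_equal(D * denom, pi_from_sfs(sfs) - watterson_theta(S, n),
                 tolerance = 1e-9)
  }
})

test_that("window tiling is half-open, fully contained, and filter-flagged", {
  D <- matrix(rep(c(0L, 1L, 2L, 1L), 5), nrow = 4)
  G <- genotype_matrix(D, c(10, 25000, 50000, 50001, 99999), "c",
                       rep("A", 5), rep("T", 5), sprintf("s%d", 1:4))
  w <- sliding_window_stats(G, window = 50000, step = 10000, min_S = 2,
                            chrom_length = 1e5)
  expect_identical(w$start, c(1, 10001, 20001, 30001, 40001, 50001))
  expect_identical(w$end, w$start + 50000)
  # pos 50000 belongs to [1,50001); pos 50001 starts the window at 50001
  expect_identical(w$n_sites[1], 3L)
  expect_equal(w$S[1], 3)
  expect_true(w$passes_filter[1])
  expect_identical(w$n_sites[6], 2L)
  # empty window
  wempty <- sliding_window_stats(G, window = 10000, step = 10000,
                                 chrom_length = 1e5)
  expect_identical(wempty$S[4], 0)
  expect_false(wempty$passes_filter[4])
  expect_true(is.na(wempty$tajima_d[4]))
  expect_error(sliding_window_stats(G, window = 100, step = 500), "window")
  # region masking keeps or drops overlapping windows
  wonly <- sliding_window_stats(G, window = 50000, step = 10000,
                                chrom_length = 1e5,
                                region = list(start = 60000, end = 70000),
                                region_mode = "only")
  expect_true(all(wonly$start <= 70000 & wonly$end - 1 >= 60000))
  wex <- sliding_window_stats(G, window = 50000, step = 10000,
                              chrom_length = 1e5,
                              region = list(start = 60000, end = 70000),
                              region_mode = "exclude")
  expect_identical(nrow(wonly) + nrow(wex), 6L)
})

test_that("windowed Watterson theta recovers the generating rate", {
  # one homokaryotype group over a panmictic chromosome
  co <- simulate_inversion_cohort(cohort_sim_params(
    n_samples_per_pop = 20, pop_labels = "one", pop_latitudes = 40,
    p_inverted_per_pop = 0, t_div_ci = 0, chrom_length = 2e6,
    ci_start = 9e5, ci_end = 11e5, theta_per_site = 4e-4,
    n_ci_blocks = 2, n_background_blocks = 18, seed = 31))
  w <- sliding_window_stats(co$genotypes, window = 50000, step = 50000,
                            min_S = 1, chrom_length = 2e6)
  est <- w$theta_w_per_bp
  target <- 4e-4
  expect_lt(abs(mean(est) - target),
            3 * stats::sd(est) / sqrt(length(est)) + 0.05 * target)
})

test_that("pooled diversity is elevated inside a diverged inversion", {
  co <- small_cohort(seed = 9)
  G <- co$genotypes
  w <- sliding_window_stats(G, window = 50000, step = 50000, min_S = 1,
                            chrom_length = co$params$chrom_length)
  inside <- w$start >= co$truth_region[1] & w$end <= co$truth_region[2]
  expect_gt(mean(w$pi_per_bp[inside]), mean(w$pi_per_bp[!inside]))
})

test_that("Weir-Cockerham FST matches the component oracle and edge cases", {
  # fixed difference, no heterozygotes: fst = 1
  d_anc <- rep(0L, 20)
  d_inv <- rep(2L, 20)
  G <- genotype_matrix(cbind(c(d_anc, d_inv)), 100, "c", "A", "T",
                       sprintf("s%d", 1:40))
  f <- weir_cockerham_fst(G, sprintf("s%d", 1:20), sprintf("s%d", 21:40))
  expect_equal(f$fst, 1, tolerance = 1e-12)
  # identical genotype columns across groups: oracle value, expected <= 0
  g <- c(0L, 0L, 1L, 0L, 1L, 0L, 2L, 0L, 0L, 1L)
  G2 <- genotype_matrix(cbind(c(g, g)), 100, "c", "A", "T",
                        sprintf("s%d", 1:20))
  f2 <- weir_cockerham_fst(G2, sprintf("s%d", 1:10), sprintf("s%d", 11:20))
  expect_equal(f2$fst, wc_fst_oracle(g, g), tolerance = 1e-12)
  expect_lte(f2$fst, 0)
  # frozen mixed fixture (independent script): 0.5061728395061729
  d1 <- c(0L, 0L, 1L, 0L, 1L, 0L, 2L, 0L, 0L, 1L)
  d2 <- c(2L, 1L, 2L, 2L, 1L, 2L, 2L, 1L, 2L, 2L)
  G3 <- genotype_matrix(cbind(c(d1, d2)), 100, "c", "A", "T",
                        sprintf("s%d", 1:20))
  f3 <- weir_cockerham_fst(G3, sprintf("s%d", 1:10), sprintf("s%d", 11:20))
  expect_equal(f3$fst, 0.5061728395061729, tolerance = 1e-12)
  expect_error(weir_cockerham_fst(G3, sprintf("s%d", 1:10),
                                  sprintf("s%d", 10:20)), "overlap")
})

test_that("FST is invariant to group swap and allele relabeling, null-centred", {
  co <- small_cohort(seed = 10)
  G <- co$genotypes
  truth <- co$truth_karyotypes
  anc <- names(truth)[truth == "ANC_HOM"]
  inv <- names(truth)[truth == "INV_HOM"]
  f12 <- weir_cockerham_fst(G, anc, inv)
  f21 <- weir_cockerham_fst(G, inv, anc)
  expect_equal(f12$fst, f21$fst, tolerance = 1e-12)
  Gf <- G
  Gf$dosages <- 2L - Gf$dosages
  ff <- weir_cockerham_fst(Gf, anc, inv)
  expect_equal(f12$fst, ff$fst, tolerance = 1e-12)
  # random halves of one panmictic population: mean FST near 0; sites within
  # a block share a genealogy, so the Monte-Carlo SE is taken across
  # independent cohorts, one mean per cohort
  set.seed(12)
  means <- vapply(1:12, function(sd) {
    null_co <- simulate_inversion_cohort(cohort_sim_params(
      n_samples_per_pop = 30, pop_labels = "one", pop_latitudes = 40,
      p_inverted_per_pop = 0, t_div_ci = 0, chrom_length = 3e6,
      ci_start = 1e6, ci_end = 2e6, theta_per_site = 4e-5,
      n_ci_blocks = 4, n_background_blocks = 8, seed = 400 + sd))
    ids <- null_co$genotypes$sample_ids
    half <- sample(ids, 15)
    fn <- weir_cockerham_fst(null_co$genotypes, half, setdiff(ids, half))
    mean(fn$fst)
  }, numeric(1))
  expect_lt(abs(mean(means)), 3 * stats::sd(means) / sqrt(length(means)))
})

test_that("inversion FST rises monotonically with class divergence time", {
  mean_ci_fst <- function(t_div) {
    vals <- vapply(1:4, function(sd) {
      co <- simulate_inversion_cohort(cohort_sim_params(
        n_samples_per_pop = 15, pop_labels = c("a", "b"),
        pop_latitudes = c(34, 44), p_inverted_per_pop = c(0.5, 0.5),
        t_div_ci = t_div, chrom_length = 3e6, ci_start = 1e6, ci_end = 2e6,
        theta_per_site = 3e-5, n_ci_blocks = 4, n_background_blocks = 6,
        seed = 100 * t_div + sd))
      truth <- co$truth_karyotypes
      anc <- names(truth)[truth == "ANC_HOM"]
      inv <- names(truth)[truth == "INV_HOM"]
      f <- weir_cockerham_fst(co$genotypes, anc, inv)
      keep <- f$pos >= 1e6 & f$pos <= 2e6
      mean(f$fst[keep])
    }, numeric(1))
    mean(vals)
  }
  ladder <- vapply(c(0.5, 1, 2, 4), mean_ci_fst, numeric(1))
  expect_true(all(diff(ladder) > 0))
})

test_that("per-sample heterozygosity separates heterokaryotypes", {
  D <- rbind(rep(1L, 6), c(0L, 2L, 0L, 2L, 0L, 2L), c(1L, NA, 1L, NA, 1L, NA))
  G <- genotype_matrix(D, 1:6 * 10, "c", rep("A", 6), rep("T", 6),
                       c("het", "hom", "missingy"))
  h <- per_sample_heterozygosity(G)
  expect_identical(unname(h), c(1, 0, 1))
  expect_error(per_sample_heterozygosity(genotype_matrix(
    matrix(2L, 3, 2), c(1, 2), "c", c("A", "A"), c("T", "T"),
    sprintf("s%d", 1:3))), "polymorphic")
  co <- small_cohort(seed = 14)
  truth <- co$truth_karyotypes
  ci <- which(co$genotypes$positions >= co$truth_region[1] &
                co$genotypes$positions <= co$truth_region[2])
  het <- per_sample_heterozygosity(co$genotypes, ci)
  m <- tapply(het, truth[names(het)], mean)
  expect_gt(m[["HET"]], m[["ANC_HOM"]])
  expect_gt(m[["HET"]], m[["INV_HOM"]])
})

test_that("Welch t and one-way F match their direct-formula oracles", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 4, 6, 8, 10)
  w <- welch_t_test(x, y)
  expect_equal(w$statistic, -1.897366596101028, tolerance = 1e-10)
  expect_equal(w$df, 5.882352941176471, tolerance = 1e-10)
  expect_equal(w$p_two_tailed, 0.1075311949306272, tolerance = 1e-10)
  identicals <- welch_t_test(x, x)
  expect_identical(c(identicals$statistic, identicals$p_two_tailed), c(0, 1))
  expect_error(welch_t_test(c(1, 1, 1), c(2, 2)), "degenerate")
  expect_identical(welch_t_test(c(1, 1), c(1, 1))$p_two_tailed, 1)
  # two-group pooled ANOVA equals squared pooled t
  a <- anova_oneway(list(x, y))
  tp <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(a$statistic, unname(tp$statistic)^2, tolerance = 1e-9)
  expect_equal(a$df, c(1, 8))
  expect_equal(a$p_two_tailed, tp$p.value, tolerance = 1e-9)
  flat <- anova_oneway(list(c(3, 3), c(3, 3), c(3, 3)))
  expect_identical(c(flat$statistic, flat$p_two_tailed), c(0, 1))
})

test_that("pooled neutral spectra follow the 1/i expectation", {
  # near-one mutation per genealogy so pooled sites are effectively
  # independent draws from the exact neutral SFS; chi-square GOF is then
  # valid at its nominal level
  set.seed(61)
  n_chrom <- 10
  cols <- vector("list", 4000)
  k <- 0L
  total <- 0L
  for (b in seq_len(200000)) {
    H <- simulate_neutral_block(n_chrom, 0.02)
    if (ncol(H) == 0) next
    k <- k + 1L
    cols[[k]] <- H
    total <- total + ncol(H)
    if (total >= 10500) break
  }
  Hp <- do.call(cbind, cols[seq_len(k)])
  dos <- Hp[seq(1, n_chrom, 2), ] + Hp[seq(2, n_chrom, 2), ]
  G <- genotype_matrix(dos, seq_len(ncol(dos)), "c",
                       rep("A", ncol(dos)), rep("T", ncol(dos)),
                       sprintf("s%d", seq_len(n_chrom / 2)))
  sfs <- sfs_from_genotypes(G)
  expect_gte(sum(sfs$counts), 10000)
  expp <- (1 / seq_len(n_chrom - 1)) / sum(1 / seq_len(n_chrom - 1))
  gof <- suppressWarnings(stats::chisq.test(sfs$counts, p = expp))
  expect_gt(gof$p.value, 0.01)
})
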