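# Shared fixtures, built in code.

# Small deterministic genotype matrix: 6 samples x 4 sites, two populations.
tiny_genotypes <- function() {
  dos <- rbind(c(0L, 0L, 1L, 2L),
               c(0L, 1L, 1L, 2L),
               c(1L, 1L, 0L, 1L),
               c(2L, 2L, 0L, 0L),
               c(2L, 2L, NA, 0L),
               c(1L, 1L, 1L, 1L))
  ids <- sprintf("s%02d", 1:6)
  genotype_matrix(dos, positions = c(100, 5000, 250000, 900000),
                  chrom = "chr1",
                  ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"),
                  sample_ids = ids,
                  population_of = stats::setNames(rep(c("north", "south"),
                                                      each = 3), ids),
                  latitude_of = c(north = 48, south = 34))
}

# A small cohort with strong class divergence, cheap enough for unit tests.
small_cohort <- function(seed = 1, ...) {
  simulate_inversion_cohort(cohort_sim_params(
    n_samples_per_pop = 8,
    pop_labels = c("southPop", "midPop", "northPop"),
    pop_latitudes = c(34, 41, 48),
    p_inverted_per_pop = c(0.25, 0.6, 0.95),
    chrom_length = 8e6, ci_start = 2e6, ci_end = 6e6,
    theta_per_site = 1e-5, t_div_ci = 4,
    n_ci_blocks = 8, n_background_blocks = 12,
    seed = seed, ...))
}

# Unfolded SFS object without going through genotypes.
make_sfs <- function(counts, n) {
  structure(list(n_chromosomes = n, counts = counts, folded = FALSE),
            class = "SFS")
}

# Independent brute-force two-sided Fisher p: full hypergeometric enumeration
# over tables with the observed margins (point-probability convention, with
# the same relative slack the production convention uses).
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Independent Tajima's D from an unfolded SFS, formulas written out directly.
tajima_oracle <- function(counts, n) {
  S <- sum(counts)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  pi <- sum(seq_len(n - 1) * (n - seq_len(n - 1)) * counts) / choose(n, 2)
  (pi - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# Independent Weir-Cockerham theta-hat for one biallelic site, two groups of
# diploid dosages, written directly from the variance components.
wc_fst_oracle <- function(d1, d2) {
  n1 <- sum(!is.na(d1)); n2 <- sum(!is.na(d2)); r <- 2
  p1 <- sum(d1, na.rm = TRUE) / (2 * n1)
  p2 <- sum(d2, na.rm = TRUE) / (2 * n2)
  h1 <- sum(d1 == 1, na.rm = TRUE) / n1
  h2 <- sum(d2 == 1, na.rm = TRUE) / n2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}
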