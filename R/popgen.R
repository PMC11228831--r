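# Diversity and divergence statistics contrasting homokaryotype groups:
# site frequency spectra, Watterson's theta, nucleotide diversity and
# Tajima's D in sliding windows, per-SNP Weir-Cockerham FST, per-sample
# heterozygosity, and the associated significance tests.

#' Site frequency spectrum from genotype dosages
#'
#' Counts alternate (treated as derived) alleles over non-missing chromosomes
#' per site. Sites with missing genotypes are down-projected to a common
#' chromosome count by the expected hypergeometric projection; sites with
#' fewer complete chromosomes than `proj_floor * 2n` are dropped. With no
#' missing data the spectrum is an exact integer count vector.
#'
#' @param G a [genotype_matrix()].
#' @param sites optional site (column) indices to restrict to.
#' @param folded fold the spectrum to minor-allele counts.
#' @param proj_floor minimum fraction of `2n` chromosomes a site must have
#'   (default 0.8).
#' @return an `SFS`: `list(n_chromosomes, counts, folded)`; `counts` is
#'   indexed by allele count `1 .. n-1` (unfolded) or `1 .. floor(n/2)`
#'   (folded) and sums to the (projected) number of segregating sites.
#' @export
sfs_from_genotypes <- function(G, sites = NULL, folded = FALSE,
                               proj_floor = 0.8) {
  .assert(length(G$sample_ids) >= 2, "need at least 2 samples")
  D <- G$dosages
  if (!is.null(sites)) D <- D[, sites, drop = FALSE]
  m <- 2 * colSums(!is.na(D))
  .assert(any(m > 0), "all sites are missing")
  n_full <- 2L * nrow(D)
  floor_c <- ceiling(proj_floor * n_full)
  keep <- m >= floor_c
  .assert(any(keep), "all sites fall below the projection floor")
  d <- colSums(D, na.rm = TRUE)[keep]
  m <- m[keep]
  n_proj <- min(m)
  counts <- numeric(n_proj - 1L)
  complete <- m == n_proj
  if (any(complete)) {
    dc <- d[complete]
    seg <- dc > 0 & dc < n_proj
    if (any(seg)) {
      tab <- tabulate(dc[seg], nbins = n_proj - 1L)
      counts <- counts + tab
    }
  }
  if (any(!complete)) {
    for (s in which(!complete)) {
      j <- seq_len(n_proj - 1L)
      counts <- counts + stats::dhyper(j, d[s], m[s] - d[s], n_proj)
    }
  }
  if (folded) {
    half <- floor(n_proj / 2)
    fc <- vapply(seq_len(half), function(i) {
      if (i == n_proj - i) counts[i] else counts[i] + counts[n_proj - i]
    }, numeric(1))
    return(structure(list(n_chromosomes = n_proj, counts = fc, folded = TRUE),
                     class = "SFS"))
  }
  structure(list(n_chromosomes = n_proj, counts = counts, folded = FALSE),
            class = "SFS")
}

#' Watterson's theta estimator
#'
#' `S / a1` with `a1 = sum(1/i, i = 1..n-1)`.
#'
#' @param S number of segregating sites.
#' @param n_chromosomes sample size in chromosomes (>= 2).
#' @return the Watterson estimate.
#' @export
watterson_theta <- function(S, n_chromosomes) {
  .assert(n_chromosomes >= 2, "need at least 2 chromosomes")
  .assert(S >= 0, "S must be non-negative")
  S / .harmonic(n_chromosomes - 1L)
}

#' Mean pairwise differences from an SFS
#'
#' `pi = sum(i (n - i) counts[i]) / choose(n, 2)`; valid for folded spectra
#' too because folding merges classes with equal `i (n - i)`.
#'
#' @param sfs an `SFS`.
#' @return the per-window (not per-bp) pi.
#' @export
pi_from_sfs <- function(sfs) {
  n <- sfs$n_chromosomes
  i <- seq_along(sfs$counts)
  sum(i * (n - i) * sfs$counts) / choose(n, 2)
}

#' Tajima's D from an SFS
#'
#' Standardized difference between pi and Watterson's theta using the
#' constants `a1, a2, b1, b2, c1, c2, e1, e2` of the original formulation.
#' Undefined (returned as `NA` with attribute `reason`) when `S = 0` or
#' `n < 4`.
#'
#' @param sfs an `SFS`.
#' @return Tajima's D (scalar) or `NA`.
#' @export
tajimas_d <- function(sfs) {
  n <- sfs$n_chromosomes
  S <- sum(sfs$counts)
  if (S <= 0) return(structure(NA_real_, reason = "no segregating sites"))
  if (n < 4) return(structure(NA_real_, reason = "fewer than 4 chromosomes"))
  a1 <- .harmonic(n - 1L)
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  pi <- pi_from_sfs(sfs)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Sliding-window diversity statistics
#'
#' Tiles the chromosome with half-open windows `[start, start + window)`
#' beginning at `1 + k * step`, keeping only fully contained windows, and
#' reports per-window segregating sites, Watterson's theta, pi (both raw per
#' window and per bp) and Tajima's D. `passes_filter` flags windows with at
#' least `min_S` segregating sites. A region can be excluded or exclusively
#' kept, matching analyses restricted to (or purged of) the inversion.
#'
#' @param G a [genotype_matrix()].
#' @param samples optional sample ids to restrict to (e.g. one homokaryotype
#'   group).
#' @param window,step window and slide size in bp (defaults 50000 / 10000).
#' @param min_S segregating-site filter (default 100).
#' @param chrom_length chromosome length; defaults to the last site position.
#' @param region optional `list(start =, end =)` 1-based inclusive mask.
#' @param region_mode `"all"`, `"exclude"` (drop windows overlapping the
#'   region) or `"only"` (keep only those).
#' @param folded fold spectra before computing D (no effect on the value).
#' @return data frame of `WindowStat` rows: `chrom, start, end, n_sites, S,
#'   theta_w, theta_w_per_bp, pi, pi_per_bp, tajima_d, passes_filter`.
#' @export
sliding_window_stats <- function(G, samples = NULL, window = 50000,
                                 step = 10000, min_S = 100,
                                 chrom_length = NULL, region = NULL,
                                 region_mode = c("all", "exclude", "only"),
                                 folded = TRUE) {
  .assert(window >= step, "window must be at least as large as step")
  region_mode <- match.arg(region_mode)
  D <- G$dosages
  if (!is.null(samples)) {
    idx <- match(samples, G$sample_ids)
    .assert(all(!is.na(idx)), "unknown sample id in samples")
    D <- D[idx, , drop = FALSE]
  }
  .assert(nrow(D) >= 2, "need at least 2 samples")
  chrom_length <- chrom_length %||% max(G$positions)
  starts <- seq(1, chrom_length - window + 1, by = step)
  if (!is.null(region) && region_mode != "all") {
    overlaps <- starts <= region$end & (starts + window - 1) >= region$start
    starts <- if (region_mode == "exclude") starts[!overlaps] else
      starts[overlaps]
  }
  n <- 2L * nrow(D)
  no_missing <- !anyNA(D)
  d_all <- colSums(D, na.rm = TRUE)
  idx_lo <- findInterval(starts - 1, G$positions) + 1L
  idx_hi <- findInterval(starts + window - 1, G$positions)
  rows <- lapply(seq_along(starts), function(w) {
    sites <- if (idx_hi[w] >= idx_lo[w]) seq(idx_lo[w], idx_hi[w]) else
      integer(0)
    # half-open window: keep pos in [start, start+window)
    sites <- sites[G$positions[sites] >= starts[w] &
                     G$positions[sites] < starts[w] + window]
    if (length(sites) == 0L) {
      sfs <- structure(list(n_chromosomes = n, counts = numeric(max(n - 1, 1)),
                            folded = FALSE), class = "SFS")
    } else if (no_missing) {
      d <- d_all[sites]
      seg <- d > 0 & d < n
      counts <- if (any(seg)) tabulate(d[seg], nbins = n - 1L) else
        numeric(n - 1L)
      sfs <- structure(list(n_chromosomes = n, counts = counts,
                            folded = FALSE), class = "SFS")
    } else {
      sfs <- sfs_from_genotypes(
        genotype_matrix(D[, sites, drop = FALSE], G$positions[sites], G$chrom,
                        G$ref_allele[sites], G$alt_allele[sites],
                        rownames(D)),
        folded = folded)
    }
    S <- sum(sfs$counts)
    tw <- watterson_theta(S, sfs$n_chromosomes)
    pi <- pi_from_sfs(sfs)
    data.frame(chrom = G$chrom, start = starts[w], end = starts[w] + window,
               n_sites = length(sites), S = S, theta_w = tw,
               theta_w_per_bp = tw / window, pi = pi, pi_per_bp = pi / window,
               tajima_d = as.numeric(tajimas_d(sfs)),
               passes_filter = S >= min_S)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-SNP Weir-Cockerham FST between two groups
#'
#' Two-population biallelic theta-hat from the variance components (a, b, c)
#' computed from allele frequencies, diploid sample sizes and observed
#' heterozygote proportions. Sites monomorphic across both groups, or with
#' fewer than 2 genotyped samples in either group, are skipped. Negative
#' estimates are reported as computed (flagged, not clamped).
#'
#' @param G a [genotype_matrix()].
#' @param group1,group2 disjoint vectors of sample ids.
#' @return data frame `site, pos, fst, n1, n2, negative`.
#' @export
weir_cockerham_fst <- function(G, group1, group2) {
  .assert(length(intersect(group1, group2)) == 0L,
          "groups must not overlap")
  i1 <- match(group1, G$sample_ids)
  i2 <- match(group2, G$sample_ids)
  .assert(all(!is.na(c(i1, i2))), "unknown sample id in groups")
  D1 <- G$dosages[i1, , drop = FALSE]
  D2 <- G$dosages[i2, , drop = FALSE]
  n1 <- colSums(!is.na(D1))
  n2 <- colSums(!is.na(D2))
  p1 <- colSums(D1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(D2, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(D1 == 1, na.rm = TRUE) / n1
  h2 <- colSums(D2 == 1, na.rm = TRUE) / n2
  ok <- n1 >= 2 & n2 >= 2
  poly <- ok & !((p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1))
  r <- 2
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
  fst <- a / (a + b + cc)
  keep <- which(poly & is.finite(fst))
  data.frame(site = keep, pos = G$positions[keep], fst = fst[keep],
             n1 = n1[keep], n2 = n2[keep], negative = fst[keep] < 0)
}

#' Per-sample heterozygosity over polymorphic sites
#'
#' Fraction of heterozygous genotypes among non-missing genotypes per sample,
#' over the polymorphic sites of the chosen subset (e.g. the inversion
#' interval).
#'
#' @param G a [genotype_matrix()].
#' @param sites optional site indices to restrict to.
#' @return named numeric vector, `NA` for samples with no data.
#' @export
per_sample_heterozygosity <- function(G, sites = NULL) {
  D <- G$dosages
  if (!is.null(sites)) D <- D[, sites, drop = FALSE]
  sds <- apply(D, 2, stats::sd, na.rm = TRUE)
  poly <- !is.na(sds) & sds > 0
  .assert(any(poly), "no polymorphic sites in subset")
  D <- D[, poly, drop = FALSE]
  het <- rowSums(D == 1, na.rm = TRUE)
  tot <- rowSums(!is.na(D))
  out <- ifelse(tot > 0, het / tot, NA_real_)
  stats::setNames(out, G$sample_ids)
}

#' Welch's two-sample t test (unequal variances)
#'
#' Two-tailed t test with the Satterthwaite degrees of freedom. When both
#' groups have zero variance: equal means give `t = 0, p = 1`; unequal means
#' are a degenerate-variance error.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return `list(statistic, df, p_two_tailed, test_name = "welch_t")`.
#' @export
welch_t_test <- function(x, y) {
  .assert(length(x) >= 2 && length(y) >= 2, "need >= 2 values per group")
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, df = length(x) + length(y) - 2,
                  p_two_tailed = 1, test_name = "welch_t"))
    stop("degenerate variance: both groups constant with different means",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_two_tailed = tt$p.value, test_name = "welch_t")
}

#' One-way analysis of variance
#'
#' Classic pooled-variance F test across k groups; zero total variance gives
#' `F = 0, p = 1`.
#'
#' @param groups list of numeric vectors (>= 2 groups, >= 2 values each).
#' @return `list(statistic, df = c(k - 1, N - k), p_two_tailed,
#'   test_name = "anova_oneway")`.
#' @export
anova_oneway <- function(groups) {
  .assert(length(groups) >= 2, "need at least 2 groups")
  .assert(all(lengths(groups) >= 2), "need at least 2 values per group")
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  k <- length(groups)
  N <- length(values)
  if (stats::var(values) == 0)
    return(list(statistic = 0, df = c(k - 1, N - k), p_two_tailed = 1,
                test_name = "anova_oneway"))
  ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(statistic = unname(ow$statistic),
       df = unname(ow$parameter), p_two_tailed = ow$p.value,
       test_name = "anova_oneway")
}
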