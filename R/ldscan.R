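# Pairwise LD along a chromosome, detection of the long-range high-LD block
# produced by a segregating inversion, and selection of karyotype-diagnostic
# loci within it.

#' Pairwise r-squared between dosage vectors
#'
#' Computes composite (Rogers-Huff) linkage disequilibrium as the squared
#' Pearson correlation of genotype dosage vectors, pairwise-complete over
#' non-missing samples. This phase-free estimator requires no haplotype
#' phasing and is deterministic. Sites are filtered to minor allele frequency
#' `>= maf_min` first; monomorphic sites never enter a pair. Pairs with fewer
#' than `min_joint` jointly non-missing samples are skipped.
#'
#' @param G a [genotype_matrix()].
#' @param maf_min minimum minor-allele frequency (default 0.05).
#' @param r2_min only pairs with `r^2 >= r2_min` are returned (default 0.8).
#' @param min_joint minimum jointly non-missing sample count per pair.
#' @return data frame with columns `i, j, pos_i, pos_j, r2` (`i < j`, site
#'   indices refer to columns of `G`); attribute `sites_used` lists the site
#'   indices that survived the MAF filter. Empty (with a warning) when fewer
#'   than two sites survive filtering.
#' @export
compute_r2 <- function(G, maf_min = 0.05, r2_min = 0.8, min_joint = 10) {
  D <- G$dosages
  p <- colMeans(D, na.rm = TRUE) / 2
  sds <- apply(D, 2, stats::sd, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  keep <- which(!is.na(maf) & maf >= maf_min & !is.na(sds) & sds > 0)
  empty <- data.frame(i = integer(0), j = integer(0), pos_i = numeric(0),
                      pos_j = numeric(0), r2 = numeric(0))
  attr(empty, "sites_used") <- keep
  attr(empty, "chrom") <- G$chrom
  if (length(keep) < 2L) {
    warning("fewer than 2 polymorphic sites after MAF filter; no LD pairs")
    return(empty)
  }
  Dk <- D[, keep, drop = FALSE]
  r2 <- suppressWarnings(stats::cor(Dk, use = "pairwise.complete.obs"))^2
  joint <- crossprod(!is.na(Dk))
  sel <- which(upper.tri(r2) & !is.na(r2) & r2 >= r2_min & joint >= min_joint,
               arr.ind = TRUE)
  if (nrow(sel) == 0L) return(empty)
  i <- keep[sel[, 1L]]
  j <- keep[sel[, 2L]]
  out <- data.frame(i = i, j = j,
                    pos_i = G$positions[i], pos_j = G$positions[j],
                    r2 = r2[sel])
  out <- out[order(out$i, out$j), ]
  rownames(out) <- NULL
  attr(out, "sites_used") <- keep
  attr(out, "chrom") <- G$chrom
  out
}

#' Detect the inversion region from long-range LD pairs
#'
#' Builds a graph whose vertices are sites and whose edges are LD pairs at
#' least `min_distance` apart (distance gating isolates the inversion's
#' long-range signal from ordinary short-range LD). Suppressed recombination
#' produces several mutually unlinked high-LD site sets spanning the same
#' interval -- the karyotype-tagging sites plus haplotype clusters within
#' each karyotype class -- so every connected component supported by at least
#' `min_pairs` qualifying pairs is kept and components whose genomic spans
#' overlap are merged, starting from the best-supported one. The region spans
#' the minimum to maximum position of the merged sites. Absence of a
#' qualifying component is a valid result (`NULL`), not an error.
#'
#' @param pairs output of [compute_r2()].
#' @param min_distance minimum pair separation in bp (default 1 Mb).
#' @param min_pairs minimum number of supporting pairs (default 50).
#' @return an `InversionRegion` (`chrom, start, end, span, n_support_pairs,
#'   member_sites`) or `NULL`.
#' @export
detect_inversion_region <- function(pairs, min_distance = 1e6,
                                    min_pairs = 50) {
  long <- pairs[pairs$pos_j - pairs$pos_i >= min_distance, , drop = FALSE]
  if (nrow(long) == 0L) return(NULL)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(long$i), to = as.character(long$j)),
    directed = FALSE)
  comp <- igraph::components(g)
  edge_comp <- comp$membership[as.character(long$i)]
  edge_pop <- tabulate(edge_comp, comp$no)
  qual <- which(edge_pop >= min_pairs)
  if (length(qual) == 0L) return(NULL)
  site_of <- as.integer(names(comp$membership))
  span_of <- t(vapply(qual, function(k) {
    pos <- G_pos <- c(long$pos_i[edge_comp == k], long$pos_j[edge_comp == k])
    range(pos)
  }, numeric(2)))
  # merge overlapping qualifying components, starting from the best supported
  ord <- qual[order(edge_pop[qual], decreasing = TRUE)]
  ord_span <- span_of[order(edge_pop[qual], decreasing = TRUE), , drop = FALSE]
  merged <- 1L
  lo <- ord_span[1, 1]
  hi <- ord_span[1, 2]
  repeat {
    add <- which(!(seq_along(ord) %in% merged) &
                   ord_span[, 1] <= hi & ord_span[, 2] >= lo)
    if (length(add) == 0L) break
    merged <- c(merged, add)
    lo <- min(lo, ord_span[add, 1])
    hi <- max(hi, ord_span[add, 2])
  }
  keep <- ord[merged]
  members <- sort(site_of[comp$membership %in% keep])
  n_support <- sum(edge_pop[keep])
  structure(list(chrom = attr(pairs, "chrom") %||% NA_character_,
                 start = lo, end = hi,
                 span = hi - lo + 1,
                 n_support_pairs = n_support,
                 member_sites = members),
            class = "InversionRegion")
}

#' @export
print.InversionRegion <- function(x, ...) {
  cat(sprintf(
    "InversionRegion: %s:%.0f-%.0f (span %.2f Mb), %d sites, %d supporting pairs\n",
    x$chrom, x$start, x$end, x$span / 1e6, length(x$member_sites),
    x$n_support_pairs))
  invisible(x)
}

#' Select karyotype-diagnostic loci within a detected inversion
#'
#' Samples are clustered into at most three karyotype groups by k-means on a
#' per-sample region score, with deterministic initialization (centres at the
#' score minimum, midpoint and maximum, matching the equal spacing of the
#' three genotype clusters on a dosage axis; ties broken by sample order).
#' The score is the leading principal component of the centered dosages over
#' all polymorphic sites spanned by the region -- a sign-aligned mean dosage
#' in which each site is weighted by its variance, so the deep
#' karyotype split (many intermediate-frequency, perfectly correlated sites)
#' dominates any within-class haplotype structure. Because residual
#' within-class variation can blur the k-means boundaries, the clustering is
#' refined once: loci that already match the provisional clusters in at least
#' 80\% of samples re-score every sample as a mean oriented dosage, and
#' samples are reassigned to the karyotype group nearest that score. A locus
#' is diagnostic when, in one allele orientation, its observed genotypes
#' match the 0/1/2 pattern implied by the refined cluster identity in at
#' least `concordance_min` of non-missing samples.
#'
#' Orientation of the "inverted" label: inversion orientation cannot be read
#' from genotypes alone, so either supply `ancestral_samples` (samples known
#' to be ancestral homozygotes, e.g. from cross-species synteny) or accept
#' the default of labelling the globally commoner haplotype class "inverted".
#' The chosen orientation is recorded in attribute `orientation`.
#'
#' @param G a [genotype_matrix()].
#' @param region an `InversionRegion` from [detect_inversion_region()]; a
#'   hand-built `list(start =, end =)` is accepted, in which case all
#'   polymorphic sites in the interval are considered.
#' @param concordance_min minimum concordance to keep a locus (default 0.95).
#' @param ancestral_samples optional sample ids anchoring the ancestral
#'   cluster.
#' @return data frame with columns `site, pos, inverted_allele` (`"ref"` or
#'   `"alt"`), `concordance`; attributes `clusters` (per-sample karyotype
#'   group as oriented dosage 0/1/2) and `orientation`.
#' @export
select_diagnostic_loci <- function(G, region, concordance_min = 0.95,
                                   ancestral_samples = NULL) {
  .assert(length(G$sample_ids) >= 3, "need at least 3 samples")
  sites <- which(G$positions >= region$start & G$positions <= region$end)
  .assert(length(sites) > 0, "region contains no sites")
  D <- G$dosages[, sites, drop = FALSE]
  sds <- apply(D, 2, stats::sd, na.rm = TRUE)
  poly <- !is.na(sds) & sds > 0
  if (!any(poly)) stop("region not karyotypically variable", call. = FALSE)
  sites <- sites[poly]
  D <- D[, poly, drop = FALSE]
  Z <- scale(D, center = TRUE, scale = FALSE)
  Z[is.na(Z)] <- 0 # missing genotypes contribute the site mean to the score
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE, rank. = 1)
  score <- pc$x[, 1L] / sqrt(ncol(Z)) # PC1, scaled like a mean dosage
  lo <- min(score)
  hi <- max(score)
  centers <- unique(c(lo, (lo + hi) / 2, hi))
  if (length(centers) < 2L)
    stop("region not karyotypically variable", call. = FALSE)
  km <- stats::kmeans(score, centers = matrix(centers, ncol = 1))
  if (length(unique(km$cluster)) < 2L)
    stop("region not karyotypically variable", call. = FALSE)
  # order clusters by centre; expected dosage of the high-score haplotype
  ord <- order(km$centers[, 1L])
  rank_of <- match(km$cluster, ord)                    # 1 = low .. k = high
  k <- length(ord)
  exp_high <- if (k == 3L) c(0L, 1L, 2L) else c(0L, 2L)
  e_high <- exp_high[rank_of]                          # dosage of high-score allele
  # per-locus best orientation and concordance against an expected pattern
  best_fit <- function(e) {
    res <- vapply(seq_len(ncol(D)), function(s) {
      obs <- D[, s]
      ok <- !is.na(obs) & !is.na(e)
      if (!any(ok)) return(c(NA_real_, NA_real_))
      c_dir <- mean(obs[ok] == e[ok])
      c_flip <- mean(obs[ok] == 2L - e[ok])
      if (c_dir >= c_flip) c(c_dir, 1) else c(c_flip, 0)
    }, numeric(2))
    list(conc = res[1, ], direct = res[2, ] == 1)
  }
  # refinement pass: loci already fitting the provisional clusters in >= 80%
  # of samples define a clean mean oriented dosage; samples are reassigned to
  # the nearest karyotype group on that axis
  prov <- best_fit(e_high)
  sel <- which(!is.na(prov$conc) & prov$conc >= 0.8)
  if (length(sel) == 0L)
    stop("region not karyotypically variable", call. = FALSE)
  Dh <- D[, sel, drop = FALSE]
  flip <- !prov$direct[sel]
  Dh[, flip] <- 2L - Dh[, flip, drop = FALSE]
  score2 <- rowMeans(Dh, na.rm = TRUE)
  e_high <- pmin(pmax(as.integer(round(score2)), 0L), 2L)
  if (length(unique(e_high[!is.na(e_high)])) < 2L)
    stop("region not karyotypically variable", call. = FALSE)
  # which extreme is "inverted"
  if (!is.null(ancestral_samples)) {
    anc_idx <- match(ancestral_samples, G$sample_ids)
    .assert(all(!is.na(anc_idx)), "unknown sample in ancestral_samples")
    anc_is_high <- mean(e_high[anc_idx], na.rm = TRUE) > 1
    inverted_is_high <- !anc_is_high
  } else {
    freq_high <- sum(e_high, na.rm = TRUE) / (2 * sum(!is.na(e_high)))
    inverted_is_high <- freq_high >= 0.5
  }
  e_inv <- if (inverted_is_high) e_high else 2L - e_high  # inverted dosage / sample
  fin <- best_fit(e_inv)   # direct = TRUE means alt tags the inverted class
  keep <- which(!is.na(fin$conc) & fin$conc >= concordance_min)
  out <- data.frame(site = sites[keep], pos = G$positions[sites[keep]],
                    inverted_allele = ifelse(fin$direct[keep], "alt", "ref"),
                    concordance = fin$conc[keep])
  rownames(out) <- NULL
  attr(out, "clusters") <- stats::setNames(e_inv, G$sample_ids)
  attr(out, "orientation") <- if (inverted_is_high)
    "high_score_class_labelled_inverted" else "low_score_class_labelled_inverted"
  out
}
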