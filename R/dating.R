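# Topology validation of duplicated ortholog families and calibrated
# strict-clock estimation of the inversion's divergence time.
#
# The estimator is a distance-based strict clock: within the focal homeolog
# clade, the substitution rate is anchored by the Salmo-Oncorhynchus split,
# and the ancestral-inverted trout divergence is converted to million years
# by proportionality. Per-family ages are summarized by their median and
# mean over topology-validated, variant families.

#' Jukes-Cantor (JC69) distance between two aligned sequences
#'
#' `d = -(3/4) log(1 - (4/3) p)` with `p` the proportion of differing sites
#' among comparable positions (sites with `N` or `-` in either sequence are
#' excluded). Requires at least `min_sites` comparable sites; `p >= 0.75` is
#' a saturation error.
#'
#' @param seq_a,seq_b equal-length nucleotide strings.
#' @param min_sites minimum comparable sites (default 100).
#' @return the JC69 distance (substitutions/site).
#' @export
jc69_distance <- function(seq_a, seq_b, min_sites = 100) {
  .assert(nchar(seq_a) == nchar(seq_b), "sequences must have equal length")
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  nt <- c("A", "C", "G", "T")
  comparable <- a %in% nt & b %in% nt
  .assert(sum(comparable) >= min_sites,
          sprintf("fewer than %d comparable sites", min_sites))
  p <- mean(a[comparable] != b[comparable])
  if (p >= 0.75)
    stop("saturated distance: p >= 0.75, JC69 correction undefined",
         call. = FALSE)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise JC69 distance matrix for a family
#'
#' @param family an `OrthologFamily`.
#' @param min_sites minimum comparable sites per pair.
#' @return symmetric labelled distance matrix.
#' @export
family_distances <- function(family, min_sites = 100) {
  labs <- names(family$sequences)
  k <- length(labs)
  D <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    D[i, j] <- D[j, i] <- jc69_distance(family$sequences[[i]],
                                        family$sequences[[j]], min_sites)
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \pkg{ape}); tie-breaking follows the label
#' order of the input matrix, so the result is deterministic.
#'
#' @param D symmetric non-negative distance matrix with row/column labels.
#' @param labels optional label vector overriding the matrix dimnames.
#' @return an unrooted `phylo` tree (Newick-serializable).
#' @export
nj_tree <- function(D, labels = NULL) {
  .assert(is.matrix(D) && nrow(D) == ncol(D), "D must be a square matrix")
  .assert(isTRUE(all.equal(D, t(D))), "distance matrix must be symmetric")
  .assert(all(D >= 0), "distances must be non-negative")
  .assert(nrow(D) >= 3, "need at least 3 taxa")
  if (!is.null(labels)) dimnames(D) <- list(labels, labels)
  ape::nj(stats::as.dist(D))
}

# Clade definitions for the fixed taxon token set.
.clade_sets <- function() {
  list(outgroup = c("pike", "mudminnow"),
       clade1 = c("whitefish1", "grayling1", "atlantic1", "trout_anc",
                  "trout_inv"),
       clade2 = c("whitefish2", "grayling2", "atlantic2", "trout_homeo2"),
       salmo_onc1 = c("atlantic1", "trout_anc", "trout_inv"),
       salmo_onc2 = c("atlantic2", "trout_homeo2"),
       inv_pair = c("trout_anc", "trout_inv"))
}

#' Check the required ortholog topology
#'
#' Roots the gene tree on the esociform outgroup pair and tests, as
#' bipartition (monophyly) statements: (i) the two homeolog clades created by
#' the whole-genome duplication are each monophyletic; (ii) Atlantic salmon
#' and rainbow trout are sisters within each clade; (iii) the ancestral and
#' inverted trout sequences are sisters. A family passes when all three hold
#' and the two inversion-haplotype sequences are not identical (an identical
#' pair carries no dating signal).
#'
#' @param tree an unrooted `phylo` containing all labels of
#'   [ortholog_taxa()].
#' @param inversion_pair_identical logical: are the trout_anc / trout_inv
#'   sequence strings identical? (Sequence identity cannot be read from a
#'   tree; supply it, or use [ortholog_topology_report()].)
#' @param family_id optional identifier copied into the report.
#' @return a one-row `TopologyReport` data frame with flags
#'   `two_homeolog_clades, salmo_oncorhynchus_sister_in_each,
#'   inversion_pair_sister, inversion_pair_identical, passes`.
#' @export
check_ortholog_topology <- function(tree, inversion_pair_identical = FALSE,
                                    family_id = NA_character_) {
  cs <- .clade_sets()
  need <- ortholog_taxa()
  missing <- setdiff(need, tree$tip.label)
  .assert(length(missing) == 0L,
          paste0("tree is missing required label(s): ",
                 paste(missing, collapse = ", ")))
  rooted <- tryCatch(
    ape::root(tree, outgroup = cs$outgroup, resolve.root = TRUE),
    error = function(e) ape::root(tree, outgroup = cs$outgroup[1],
                                  resolve.root = TRUE))
  mono <- function(tips) ape::is.monophyletic(rooted, tips)
  two <- mono(cs$clade1) && mono(cs$clade2)
  sis <- mono(cs$salmo_onc1) && mono(cs$salmo_onc2)
  pair <- mono(cs$inv_pair)
  passes <- two && sis && pair && !inversion_pair_identical
  data.frame(family_id = family_id,
             two_homeolog_clades = two,
             salmo_oncorhynchus_sister_in_each = sis,
             inversion_pair_sister = pair,
             inversion_pair_identical = inversion_pair_identical,
             passes = passes)
}

#' Topology report for one family (distances, NJ tree, identity check)
#'
#' @param family an `OrthologFamily`.
#' @param min_sites minimum comparable sites for distances.
#' @return the `TopologyReport` row of [check_ortholog_topology()], with the
#'   NJ tree attached as attribute `tree`.
#' @export
ortholog_topology_report <- function(family, min_sites = 100) {
  D <- family_distances(family, min_sites)
  tree <- nj_tree(D)
  identical_pair <- family$sequences[["trout_anc"]] ==
    family$sequences[["trout_inv"]]
  rep <- check_ortholog_topology(tree, identical_pair, family$family_id)
  attr(rep, "tree") <- tree
  rep
}

#' Filter families on their topology reports
#'
#' Keeps families whose report passes; the rejection tally attributes each
#' failing family to its first violated criterion, in the order homeolog
#' clades, Salmo-Oncorhynchus sisterhood, inversion-pair sisterhood,
#' invariant inversion pair.
#'
#' @param families list of `OrthologFamily` objects.
#' @param reports data frame of stacked `TopologyReport` rows aligned with
#'   `families`.
#' @return `list(families, n_kept, rejected)` where `rejected` is a named
#'   count vector.
#' @export
filter_families <- function(families, reports) {
  .assert(length(families) == nrow(reports),
          "families and reports must align")
  reasons <- c("homeolog_clades", "salmo_oncorhynchus_sister",
               "inversion_pair_not_sister", "invariant_pair")
  tally <- stats::setNames(integer(4), reasons)
  keep <- logical(length(families))
  for (i in seq_along(families)) {
    r <- reports[i, ]
    if (r$passes) {
      keep[i] <- TRUE
    } else if (!r$two_homeolog_clades) {
      tally["homeolog_clades"] <- tally["homeolog_clades"] + 1L
    } else if (!r$salmo_oncorhynchus_sister_in_each) {
      tally["salmo_oncorhynchus_sister"] <-
        tally["salmo_oncorhynchus_sister"] + 1L
    } else if (!r$inversion_pair_sister) {
      tally["inversion_pair_not_sister"] <-
        tally["inversion_pair_not_sister"] + 1L
    } else {
      tally["invariant_pair"] <- tally["invariant_pair"] + 1L
    }
  }
  list(families = families[keep], n_kept = sum(keep), rejected = tally)
}

#' A calibration point for the strict clock
#'
#' @param node calibrated node label; the estimator uses the
#'   Salmo-Oncorhynchus split within the focal homeolog clade.
#' @param age_my calibration age in million years (> 0); default 27.3.
#' @return a `Calibration` list.
#' @export
calibration <- function(node = "salmo_oncorhynchus_split", age_my = 27.3) {
  .assert(age_my > 0, "calibration age must be > 0")
  structure(list(node = node, age_my = age_my), class = "Calibration")
}

#' Strict-clock TMRCA of the inversion haplotypes for one family
#'
#' The local substitution rate is `d_cal / (2 * age_my)` where `d_cal` is the
#' mean of the two trout-to-Atlantic-salmon JC distances within the focal
#' clade (which trout copy anchors the calibration is not identifiable, so
#' both are averaged); the inversion age is then
#' `d(trout_anc, trout_inv) / (2 * rate)`. Ages scale exactly linearly in the
#' calibration age.
#'
#' @param family an `OrthologFamily` (should have passed the topology
#'   filter).
#' @param cal a [calibration()].
#' @param min_sites minimum comparable sites for distances.
#' @return one-row data frame `family_id, d_inv_pair, d_cal_pair, tmrca_my`.
#' @export
estimate_tmrca <- function(family, cal = calibration(), min_sites = 100) {
  s <- family$sequences
  d_anc <- jc69_distance(s[["trout_anc"]], s[["atlantic1"]], min_sites)
  d_inv <- jc69_distance(s[["trout_inv"]], s[["atlantic1"]], min_sites)
  d_cal <- (d_anc + d_inv) / 2
  if (d_cal <= 0)
    stop("no signal for rate: calibration distance is zero", call. = FALSE)
  d_pair <- jc69_distance(s[["trout_anc"]], s[["trout_inv"]], min_sites)
  rate <- d_cal / (2 * cal$age_my)
  data.frame(family_id = family$family_id, d_inv_pair = d_pair,
             d_cal_pair = d_cal, tmrca_my = d_pair / (2 * rate))
}

#' Summarize per-family age estimates
#'
#' @param estimates stacked rows from [estimate_tmrca()].
#' @return `list(median_my, mean_my, n_families, table)`.
#' @export
summarize_ages <- function(estimates) {
  .assert(!is.null(estimates) && nrow(estimates) >= 1,
          "no age estimates to summarize")
  list(median_my = stats::median(estimates$tmrca_my),
       mean_my = mean(estimates$tmrca_my),
       n_families = nrow(estimates),
       table = estimates)
}

#' Date an inversion from a batch of ortholog families
#'
#' Convenience wrapper: topology reports, filtering, per-family TMRCA and the
#' cohort summary in one call.
#'
#' @param families list of `OrthologFamily` objects.
#' @param cal a [calibration()].
#' @param min_sites minimum comparable sites for distances.
#' @return `list(reports, rejected, estimates, summary)`.
#' @export
date_inversion <- function(families, cal = calibration(), min_sites = 100) {
  reports <- do.call(rbind, lapply(families, ortholog_topology_report,
                                   min_sites = min_sites))
  filt <- filter_families(families, reports)
  estimates <- do.call(rbind, lapply(filt$families, estimate_tmrca,
                                     cal = cal, min_sites = min_sites))
  list(reports = reports, rejected = filt$rejected, estimates = estimates,
       summary = summarize_ages(estimates))
}
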