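# Coalescent-based simulators supplying truth-labelled inputs for every
# downstream stage: diploid inversion cohorts, ortholog sequence families
# evolved on a fixed species tree with a whole-genome duplication, and
# gene-annotation tables with planted enrichment.

#' Parameters for a simulated inversion cohort
#'
#' Defaults describe a desk-scale analogue of a RAD-seq survey of a species
#' carrying a ~13.6-Mb inversion: five populations of diploids sampled along
#' a latitudinal gradient, with the inverted haplotype's frequency rising to
#' fixation northwards, two deeply diverged non-recombining haplotype classes
#' inside the inversion, and independent neutral blocks elsewhere on the
#' chromosome.
#'
#' @param n_samples_per_pop diploid samples per population (>= 2).
#' @param pop_labels population identifiers.
#' @param pop_latitudes decimal-degree latitude per population.
#' @param p_inverted_per_pop frequency of the inverted haplotype per
#'   population, each in `[0, 1]`.
#' @param chrom_length chromosome length (bp).
#' @param ci_start,ci_end inversion bounds, 1-based inclusive.
#' @param theta_per_site population-scaled mutation rate per site
#'   (`4 N mu`); the default gives a marker density comparable to a
#'   reduced-representation dataset (a few hundred SNPs on the chromosome).
#' @param t_div_ci divergence time of the two inversion haplotype classes, in
#'   units of `2N` generations.
#' @param n_ci_blocks number of sub-blocks inside the inversion. All
#'   sub-blocks share one class assignment per chromosome (the orientation
#'   split is inherited as a single locus), but their within-class
#'   genealogies are independent, reflecting that homokaryotypes recombine
#'   freely within their own class while recombination between classes is
#'   suppressed.
#' @param n_background_blocks number of independent non-recombining neutral
#'   blocks outside the inversion; blocks are assigned contiguous intervals so
#'   that background linkage stays short-range.
#' @param seed integer seed.
#' @return a validated `CohortSimParams` list.
#' @export
cohort_sim_params <- function(n_samples_per_pop = 10,
                              pop_labels = c("pop33N", "pop37N", "pop41N",
                                             "pop45N", "pop49N"),
                              pop_latitudes = c(33, 37, 41, 45, 49),
                              p_inverted_per_pop = c(0.2, 0.5, 0.8, 1, 1),
                              chrom_length = 30e6,
                              ci_start = 5.6e6, ci_end = 19.2e6,
                              theta_per_site = 3e-6,
                              t_div_ci = 4,
                              n_ci_blocks = 16,
                              n_background_blocks = 40,
                              seed = 1) {
  .assert(n_samples_per_pop >= 2, "n_samples_per_pop must be >= 2")
  k <- length(pop_labels)
  .assert(length(pop_latitudes) == k && length(p_inverted_per_pop) == k,
          "pop_labels, pop_latitudes and p_inverted_per_pop must align")
  .assert(all(p_inverted_per_pop >= 0 & p_inverted_per_pop <= 1),
          "p_inverted_per_pop must lie in [0, 1]")
  .assert(1 <= ci_start && ci_start < ci_end && ci_end <= chrom_length,
          "require 1 <= ci_start < ci_end <= chrom_length")
  .assert(theta_per_site > 0, "theta_per_site must be > 0")
  .assert(t_div_ci >= 0, "t_div_ci must be >= 0")
  .assert(n_ci_blocks >= 1, "n_ci_blocks must be >= 1")
  .assert(n_background_blocks >= 1, "n_background_blocks must be >= 1")
  structure(list(n_samples_per_pop = as.integer(n_samples_per_pop),
                 pop_labels = as.character(pop_labels),
                 pop_latitudes = as.numeric(pop_latitudes),
                 p_inverted_per_pop = as.numeric(p_inverted_per_pop),
                 chrom_length = chrom_length, ci_start = ci_start,
                 ci_end = ci_end, theta_per_site = theta_per_site,
                 t_div_ci = t_div_ci,
                 n_ci_blocks = as.integer(n_ci_blocks),
                 n_background_blocks = as.integer(n_background_blocks),
                 seed = as.integer(seed)),
            class = "CohortSimParams")
}

# Kingman coalescent branches for n lineages, optionally structured into two
# demes that merge (looking backwards) at time t_div. Returns all branches as
# carrier sets plus branch lengths, in units of 2N generations.
.coal_branches <- function(n, deme = rep(1L, n), t_div = 0) {
  members <- as.list(seq_len(n))
  open_len <- numeric(n)
  dem <- as.integer(deme)
  merged <- length(unique(dem)) <= 1L
  time <- 0
  # every coalescence closes two branches; the root edge is never created
  out_members <- vector("list", 2L * (n - 1L))
  out_len <- numeric(2L * (n - 1L))
  closed <- 0L
  while (length(members) > 1L) {
    k <- length(members)
    if (!merged) {
      kd <- tabulate(dem)
      rate_d <- kd * (kd - 1) / 2
      tot <- sum(rate_d)
      if (tot == 0) {
        open_len <- open_len + (t_div - time)
        time <- t_div
        merged <- TRUE
        dem[] <- 1L
        next
      }
      w <- stats::rexp(1, tot)
      if (time + w >= t_div) {
        open_len <- open_len + (t_div - time)
        time <- t_div
        merged <- TRUE
        dem[] <- 1L
        next
      }
      time <- time + w
      open_len <- open_len + w
      d <- sample.int(length(rate_d), 1L, prob = rate_d)
      idx <- which(dem == d)
      pair <- idx[sample.int(length(idx), 2L)]
    } else {
      w <- stats::rexp(1, k * (k - 1) / 2)
      time <- time + w
      open_len <- open_len + w
      pair <- sample.int(k, 2L)
    }
    for (p in pair) {
      closed <- closed + 1L
      out_members[[closed]] <- members[[p]]
      out_len[closed] <- open_len[p]
    }
    members[[pair[1L]]] <- sort(c(members[[pair[1L]]], members[[pair[2L]]]))
    open_len[pair[1L]] <- 0
    members <- members[-pair[2L]]
    open_len <- open_len[-pair[2L]]
    dem <- dem[-pair[2L]]
  }
  # each coalescence closes 2 branches: total closed = 2(n-1)
  list(members = out_members[seq_len(closed)], len = out_len[seq_len(closed)])
}

# Poisson mutations on a branch set under the infinite-sites model; mutation
# rate is theta/2 per unit branch length. Returns an n x S binary matrix.
.drop_mutations <- function(branches, n, theta) {
  total <- sum(branches$len)
  s <- stats::rpois(1, theta / 2 * total)
  H <- matrix(0L, nrow = n, ncol = s)
  if (s > 0) {
    b <- sample.int(length(branches$len), s, replace = TRUE,
                    prob = branches$len)
    for (j in seq_len(s)) H[branches$members[[b[j]]], j] <- 1L
  }
  H
}

#' Simulate one neutral non-recombining block
#'
#' Haplotypes arise from a standard Kingman coalescent with Poisson
#' (infinite-sites) mutation: the expected number of segregating sites is
#' `theta_block * a1` with `a1 = sum(1/i, i = 1..n-1)`.
#'
#' Uses the current RNG state; seed the global RNG for reproducibility.
#'
#' @param n_chromosomes number of haploid chromosomes (>= 2).
#' @param theta_block population-scaled mutation rate for the whole block.
#' @return binary haplotype matrix, `n_chromosomes` rows, one column per
#'   segregating site (derived allele = 1).
#' @export
simulate_neutral_block <- function(n_chromosomes, theta_block) {
  .assert(n_chromosomes >= 2, "n_chromosomes must be >= 2")
  .assert(theta_block > 0, "theta_block must be > 0")
  br <- .coal_branches(n_chromosomes)
  .drop_mutations(br, n_chromosomes, theta_block)
}

#' Simulate a diploid cohort segregating for a chromosomal inversion
#'
#' Inside the inversion the two haplotype classes descend from clean-split
#' two-deme coalescents with divergence `t_div_ci` and no exchange (modelling
#' complete recombination suppression between orientations); each diploid
#' draws its two class labels once, by Hardy-Weinberg sampling from its
#' population's inverted-haplotype frequency, and the labels are shared by
#' all `n_ci_blocks` sub-blocks of the inversion while within-class
#' genealogies stay independent between sub-blocks. Outside the inversion,
#' independent panmictic neutral blocks are simulated and placed in
#' contiguous intervals. Site positions are uniform within their interval,
#' 1-based; alleles are random distinct nucleotides with the derived state as
#' ALT.
#'
#' @param params a [cohort_sim_params()] object.
#' @return a `SimulatedCohort`: `list(genotypes, truth_karyotypes,
#'   truth_region, params)` where `truth_karyotypes` is a named vector in
#'   `{ANC_HOM, HET, INV_HOM}` and `truth_region = c(ci_start, ci_end)`.
#' @export
simulate_inversion_cohort <- function(params) {
  .assert(inherits(params, "CohortSimParams"),
          "params must come from cohort_sim_params()")
  set.seed(params$seed)
  npop <- length(params$pop_labels)
  n <- params$n_samples_per_pop * npop
  pop <- rep(params$pop_labels, each = params$n_samples_per_pop)
  sample_ids <- sprintf("s%03d_%s", seq_len(n), pop)
  # haplotype class per chromosome (TRUE = inverted), Hardy-Weinberg draws
  p_inv <- rep(params$p_inverted_per_pop, each = params$n_samples_per_pop)
  hap_inv <- matrix(stats::runif(2L * n) < rep(p_inv, each = 2L), nrow = 2L)
  truth <- c("ANC_HOM", "HET", "INV_HOM")[colSums(hap_inv) + 1L]
  names(truth) <- sample_ids

  chrom_class <- as.integer(as.vector(hap_inv)) + 1L # per chromosome: 1=anc, 2=inv
  n_chrom <- 2L * n

  ci_len <- params$ci_end - params$ci_start + 1
  nc <- min(params$n_ci_blocks, ci_len)
  ci_bounds <- round(seq(0, ci_len, length.out = nc + 1L))
  ci_parts <- list()
  for (b in seq_len(nc)) {
    blen <- ci_bounds[b + 1L] - ci_bounds[b]
    if (blen < 1) next
    br <- .coal_branches(n_chrom, deme = chrom_class,
                         t_div = params$t_div_ci)
    Hb <- .drop_mutations(br, n_chrom, params$theta_per_site * blen)
    if (ncol(Hb) == 0) next
    pb <- sort(sample.int(blen, min(ncol(Hb), blen))) + ci_bounds[b]
    ci_parts[[length(ci_parts) + 1L]] <-
      list(H = Hb[, seq_along(pb), drop = FALSE], pos = pb)
  }
  H_ci <- do.call(cbind, lapply(ci_parts, `[[`, "H"))
  pos_ci <- unlist(lapply(ci_parts, `[[`, "pos")) + params$ci_start - 1

  # background: contiguous chunks tiling the outside coordinate space
  left_len <- params$ci_start - 1
  right_len <- params$chrom_length - params$ci_end
  out_len <- left_len + right_len
  H_bg <- NULL
  pos_bg <- numeric(0)
  if (out_len > 0) {
    nb <- min(params$n_background_blocks, out_len)
    bounds <- round(seq(0, out_len, length.out = nb + 1L))
    blocks <- list()
    for (b in seq_len(nb)) {
      blen <- bounds[b + 1L] - bounds[b]
      if (blen < 1) next
      Hb <- simulate_neutral_block(n_chrom, params$theta_per_site * blen)
      if (ncol(Hb) == 0) next
      pb <- sort(sample.int(blen, min(ncol(Hb), blen))) + bounds[b]
      Hb <- Hb[, seq_along(pb), drop = FALSE]
      blocks[[length(blocks) + 1L]] <- list(H = Hb, pos = pb)
    }
    if (length(blocks) > 0) {
      H_bg <- do.call(cbind, lapply(blocks, `[[`, "H"))
      pos_bg <- unlist(lapply(blocks, `[[`, "pos"))
      # map outside coordinate (1..out_len) to genome coordinate
      pos_bg <- ifelse(pos_bg <= left_len, pos_bg,
                       pos_bg - left_len + params$ci_end)
    }
  }

  H <- cbind(H_ci, H_bg)
  pos <- c(pos_ci, pos_bg)
  ord <- order(pos)
  H <- H[, ord, drop = FALSE]
  pos <- pos[ord]
  .assert(!anyDuplicated(pos), "duplicate site positions")  # blocks are disjoint

  dos <- H[seq(1, n_chrom, by = 2L), , drop = FALSE] +
    H[seq(2, n_chrom, by = 2L), , drop = FALSE]
  nt <- c("A", "C", "G", "T")
  ref <- nt[sample.int(4L, length(pos), replace = TRUE)]
  shift <- sample.int(3L, length(pos), replace = TRUE)
  alt <- nt[(match(ref, nt) - 1L + shift) %% 4L + 1L]
  G <- genotype_matrix(dos, pos, "chrInv", ref, alt, sample_ids,
                       population_of = stats::setNames(pop, sample_ids),
                       latitude_of = stats::setNames(params$pop_latitudes,
                                                     params$pop_labels))
  structure(list(genotypes = G,
                 truth_karyotypes = truth,
                 truth_region = c(params$ci_start, params$ci_end),
                 params = params),
            class = "SimulatedCohort")
}

#' Write a simulated cohort to disk
#'
#' Emits `cohort.vcf` (VCF 4.2, unphased GT), `samples.tsv`
#' (sample/population/latitude) and `truth.tsv` (sample/karyotype).
#'
#' @param cohort a `SimulatedCohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  G <- cohort$genotypes
  vcf <- file.path(dir, "cohort.vcf")
  write_vcf(G, vcf)
  st <- file.path(dir, "samples.tsv")
  write_tsv(data.frame(sample = G$sample_ids,
                       population = unname(G$population_of),
                       latitude = unname(G$latitude_of[G$population_of])), st)
  tt <- file.path(dir, "truth.tsv")
  write_tsv(data.frame(sample = names(cohort$truth_karyotypes),
                       karyotype = unname(cohort$truth_karyotypes)), tt)
  invisible(c(vcf, st, tt))
}

#' Parameters for simulated ortholog families
#'
#' The species tree holds two esociform outgroups (pike, mudminnow) and two
#' homeolog clades created by the salmonid whole-genome duplication, each
#' containing whitefish, grayling, Atlantic salmon and rainbow trout tips;
#' the focal clade carries two trout sequences (ancestral and inverted
#' haplotype) that diverged `t_inv` million years ago. Sequences evolve under
#' single-rate JC69 with no indels.
#'
#' @param n_families number of families to simulate.
#' @param seq_length alignment length (bp).
#' @param species_tree_ages named ages (MY) of the divergence events: `root`
#'   (esociform-salmonid split), `esociform` (pike-mudminnow),
#'   `wgd` (homeolog duplication), `salmonidae` (crown of each homeolog
#'   clade), `whitefish_grayling`, `salmo_oncorhynchus`, and `t_inv`
#'   (ancestral vs inverted trout haplotypes). Child events must be younger
#'   than their parents.
#' @param subst_rate substitutions/site/MY.
#' @param seed integer seed.
#' @return a validated `OrthologSimParams` list.
#' @export
ortholog_sim_params <- function(n_families = 200,
                                seq_length = 10000,
                                species_tree_ages = c(root = 112,
                                                      esociform = 85,
                                                      wgd = 95,
                                                      salmonidae = 51.8,
                                                      whitefish_grayling = 35,
                                                      salmo_oncorhynchus = 27.3,
                                                      t_inv = 1.0),
                                subst_rate = 1e-3,
                                seed = 1) {
  a <- species_tree_ages
  need <- c("root", "esociform", "wgd", "salmonidae", "whitefish_grayling",
            "salmo_oncorhynchus", "t_inv")
  .assert(all(need %in% names(a)),
          paste0("species_tree_ages must name: ", paste(need, collapse = ", ")))
  nested <- a["esociform"] < a["root"] && a["wgd"] < a["root"] &&
    a["salmonidae"] < a["wgd"] &&
    a["whitefish_grayling"] < a["salmonidae"] &&
    a["salmo_oncorhynchus"] < a["salmonidae"] &&
    a["t_inv"] < a["salmo_oncorhynchus"] && a["t_inv"] >= 0
  .assert(isTRUE(nested), "species tree ages are not strictly nested")
  .assert(subst_rate > 0, "subst_rate must be > 0")
  .assert(n_families >= 1 && seq_length >= 1, "need n_families, seq_length >= 1")
  structure(list(n_families = as.integer(n_families),
                 seq_length = as.integer(seq_length),
                 species_tree_ages = a, subst_rate = subst_rate,
                 seed = as.integer(seed)),
            class = "OrthologSimParams")
}

#' The fixed taxon tokens used by the ortholog simulator
#' @return character vector of the 11 tip labels.
#' @export
ortholog_taxa <- function() {
  c("pike", "mudminnow",
    "whitefish1", "grayling1", "atlantic1", "trout_anc", "trout_inv",
    "whitefish2", "grayling2", "atlantic2", "trout_homeo2")
}

# Species tree as a Newick string with branch lengths in MY.
.species_tree_newick <- function(a) {
  clade <- function(idx, trout) {
    sprintf("((whitefish%d:%g,grayling%d:%g):%g,(atlantic%d:%g,%s):%g):%g",
            idx, a["whitefish_grayling"], idx, a["whitefish_grayling"],
            a["salmonidae"] - a["whitefish_grayling"],
            idx, a["salmo_oncorhynchus"], trout,
            a["salmonidae"] - a["salmo_oncorhynchus"],
            a["wgd"] - a["salmonidae"])
  }
  trout1 <- sprintf("(trout_anc:%g,trout_inv:%g):%g",
                    a["t_inv"], a["t_inv"], a["salmo_oncorhynchus"] - a["t_inv"])
  trout2 <- sprintf("trout_homeo2:%g", a["salmo_oncorhynchus"])
  sprintf("((pike:%g,mudminnow:%g):%g,(%s,%s):%g);",
          a["esociform"], a["esociform"], a["root"] - a["esociform"],
          clade(1L, trout1), clade(2L, trout2), a["root"] - a["wgd"])
}

#' Simulate aligned ortholog families along the duplicated species tree
#'
#' Each family is an equal-length alignment of the 11 taxa returned by
#' [ortholog_taxa()], evolved by single-rate JC69 substitution (via
#' \pkg{phangorn}) along the fixed species tree; there are no indels. The
#' expected uncorrected distance between the ancestral and inverted trout
#' haplotypes is approximately `2 * subst_rate * t_inv` for small values.
#'
#' @param params an [ortholog_sim_params()] object.
#' @return list of `OrthologFamily` objects; the true `t_inv` (MY) is
#'   attached as attribute `t_inv`.
#' @export
simulate_ortholog_families <- function(params) {
  .assert(inherits(params, "OrthologSimParams"),
          "params must come from ortholog_sim_params()")
  set.seed(params$seed)
  tree <- ape::read.tree(text = .species_tree_newick(params$species_tree_ages))
  fams <- vector("list", params$n_families)
  for (i in seq_len(params$n_families)) {
    sim <- phangorn::simSeq(tree, l = params$seq_length,
                            rate = params$subst_rate, type = "DNA")
    m <- toupper(as.character(sim))
    seqs <- stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
    fams[[i]] <- ortholog_family(sprintf("fam%04d", i), seqs[ortholog_taxa()])
  }
  attr(fams, "t_inv") <- unname(params$species_tree_ages["t_inv"])
  fams
}

#' Write ortholog families as one FASTA per family
#'
#' @param families list of `OrthologFamily` objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
write_families <- function(families, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(families, function(f) {
    p <- file.path(dir, paste0(f$family_id, ".fasta"))
    write_family_fasta(f, p)
    p
  }, character(1))
  invisible(paths)
}

#' Parameters for a simulated gene-annotation table
#'
#' Genes are placed on one chromosome, a fixed fraction inside the inversion
#' interval; every gene receives each functional term by an independent
#' Bernoulli draw at `baseline_term_prob`, except that inside the inversion
#' the probability of each enriched term is multiplied by its multiplier
#' (clipped to 1 with a warning).
#'
#' @param n_genes total genes.
#' @param n_terms number of functional terms (`TERM0001`, ...).
#' @param ci_gene_fraction fraction of genes inside the inversion.
#' @param baseline_term_prob per-gene, per-term assignment probability.
#' @param enriched_terms named numeric vector: term id -> inside-inversion
#'   probability multiplier (>= 1).
#' @param chrom,chrom_length,ci_start,ci_end gene coordinate scaffold.
#' @param seed integer seed.
#' @return a validated `AnnotationSimParams` list.
#' @export
annotation_sim_params <- function(n_genes = 30300,
                                  n_terms = 20,
                                  ci_gene_fraction = 300 / 30300,
                                  baseline_term_prob = 0.02,
                                  enriched_terms = c(TERM0001 = 8,
                                                     TERM0002 = 8,
                                                     TERM0003 = 8),
                                  chrom = "chrInv",
                                  chrom_length = 30e6,
                                  ci_start = 5.6e6, ci_end = 19.2e6,
                                  seed = 1) {
  .assert(baseline_term_prob >= 0 && baseline_term_prob <= 1,
          "baseline_term_prob must be in [0, 1]")
  .assert(ci_gene_fraction >= 0 && ci_gene_fraction <= 1,
          "ci_gene_fraction must be in [0, 1]")
  .assert(all(enriched_terms >= 1), "enrichment multipliers must be >= 1")
  term_ids <- sprintf("TERM%04d", seq_len(n_terms))
  .assert(all(names(enriched_terms) %in% term_ids) ||
            length(enriched_terms) == 0,
          "enriched_terms must name terms among the simulated term ids")
  structure(list(n_genes = as.integer(n_genes), n_terms = as.integer(n_terms),
                 ci_gene_fraction = ci_gene_fraction,
                 baseline_term_prob = baseline_term_prob,
                 enriched_terms = enriched_terms,
                 chrom = chrom, chrom_length = chrom_length,
                 ci_start = ci_start, ci_end = ci_end,
                 seed = as.integer(seed)),
            class = "AnnotationSimParams")
}

#' Simulate a gene -> term annotation table with planted enrichment
#'
#' @param params an [annotation_sim_params()] object.
#' @return `list(annotations, genes, ci_genes, truth_enriched)`:
#'   `annotations` has one row per gene-term assignment with columns
#'   `gene_id, chrom, start, end, term_id, category`; `genes` lists all gene
#'   coordinates (the term universe); `ci_genes` the gene ids inside the
#'   inversion; `truth_enriched` the term ids planted with multiplier > 1.
#' @export
simulate_annotation <- function(params) {
  .assert(inherits(params, "AnnotationSimParams"),
          "params must come from annotation_sim_params()")
  set.seed(params$seed)
  n_ci <- round(params$ci_gene_fraction * params$n_genes)
  n_bg <- params$n_genes - n_ci
  gene_len <- 1000
  ci_span <- params$ci_end - params$ci_start + 1 - gene_len
  start_ci <- sort(sample.int(ci_span, n_ci, replace = TRUE)) +
    params$ci_start - 1
  # background genes uniform on the outside coordinate space
  left_len <- params$ci_start - 1 - gene_len
  out_len <- left_len + (params$chrom_length - params$ci_end - gene_len)
  s_out <- sort(sample.int(out_len, n_bg, replace = TRUE))
  start_bg <- ifelse(s_out <= left_len, s_out, s_out - left_len + params$ci_end)
  genes <- data.frame(
    gene_id = sprintf("g%06d", seq_len(params$n_genes)),
    chrom = params$chrom,
    start = c(start_ci, start_bg),
    end = c(start_ci, start_bg) + gene_len - 1)
  in_ci <- c(rep(TRUE, n_ci), rep(FALSE, n_bg))
  term_ids <- sprintf("TERM%04d", seq_len(params$n_terms))
  category <- stats::setNames(rep(c("BP", "MF", "CC"),
                                  length.out = params$n_terms), term_ids)
  mult <- stats::setNames(rep(1, params$n_terms), term_ids)
  mult[names(params$enriched_terms)] <- params$enriched_terms
  rows <- vector("list", params$n_terms)
  for (t in seq_len(params$n_terms)) {
    p_in <- params$baseline_term_prob * mult[t]
    if (p_in > 1) {
      warning(sprintf("probability for %s clipped to 1", term_ids[t]))
      p_in <- 1
    }
    p <- ifelse(in_ci, p_in, params$baseline_term_prob)
    has <- stats::runif(params$n_genes) < p
    if (any(has))
      rows[[t]] <- data.frame(gene_id = genes$gene_id[has],
                              chrom = genes$chrom[has],
                              start = genes$start[has], end = genes$end[has],
                              term_id = term_ids[t],
                              category = unname(category[t]))
  }
  ann <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  ann <- ann[order(ann$gene_id, ann$term_id), ]
  rownames(ann) <- NULL
  list(annotations = ann,
       genes = genes,
       ci_genes = genes$gene_id[in_ci],
       truth_enriched = names(params$enriched_terms)[params$enriched_terms > 1])
}

#' Write a simulated annotation set
#'
#' @param sim output of [simulate_annotation()].
#' @param dir output directory.
#' @return invisibly, the file paths.
#' @export
write_annotation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- file.path(dir, "annotations.tsv")
  g <- file.path(dir, "genes.tsv")
  write_tsv(sim$annotations, a)
  write_tsv(sim$genes, g)
  invisible(c(a, g))
}
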