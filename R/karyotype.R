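# Per-sample inversion karyotype calls from diagnostic loci, and frequency
# summaries by population and latitude.

#' Call per-sample inversion karyotypes
#'
#' Each sample's dosage at every diagnostic locus is oriented so that 2 means
#' two copies of the inverted-tagged allele, then averaged over non-missing
#' loci. Calls use fixed score thresholds with dead zones guarding mosaic or
#' erroneous samples: `ANC_HOM` below `anc_max`, `HET` within
#' `[het_lo, het_hi]`, `INV_HOM` above `inv_min`, otherwise `UNRESOLVED`.
#' Samples missing more than `max_missing` of the loci are `UNRESOLVED`.
#'
#' @param G a [genotype_matrix()].
#' @param loci diagnostic loci from [select_diagnostic_loci()] (columns
#'   `site`, `inverted_allele`).
#' @param max_missing maximum tolerated missing fraction per sample (0.5).
#' @param anc_max,het_lo,het_hi,inv_min score thresholds (defaults 0.5,
#'   0.75, 1.25, 1.5).
#' @return data frame with columns `sample_id, call, mean_score, n_loci_used,
#'   missing_fraction`; `call` is one of `ANC_HOM, HET, INV_HOM, UNRESOLVED`.
#' @export
call_karyotypes <- function(G, loci, max_missing = 0.5,
                            anc_max = 0.5, het_lo = 0.75, het_hi = 1.25,
                            inv_min = 1.5) {
  .assert(!is.null(loci) && nrow(loci) >= 1, "need at least one diagnostic locus")
  D <- G$dosages[, loci$site, drop = FALSE]
  flip <- loci$inverted_allele == "ref"
  D[, flip] <- 2L - D[, flip, drop = FALSE]
  n_used <- rowSums(!is.na(D))
  miss <- 1 - n_used / nrow(loci)
  score <- rowMeans(D, na.rm = TRUE)
  call <- rep("UNRESOLVED", length(score))
  call[score < anc_max] <- "ANC_HOM"
  call[score >= het_lo & score <= het_hi] <- "HET"
  call[score > inv_min] <- "INV_HOM"
  call[miss > max_missing | is.nan(score)] <- "UNRESOLVED"
  data.frame(sample_id = G$sample_ids, call = call,
             mean_score = ifelse(is.nan(score), NA_real_, score),
             n_loci_used = n_used, missing_fraction = miss)
}

#' Per-population karyotype counts and frequencies
#'
#' `UNRESOLVED` samples are excluded from `n`. A cohort-total row
#' (`population = "TOTAL"`) is appended. Frequencies are reported both as
#' fractions and as percentages rounded to one decimal;
#' `freq_ancestral_allele` is the allele-counting estimate
#' `(2 * anc_hom + het) / (2 n)`.
#'
#' @param calls output of [call_karyotypes()].
#' @param population_of named vector sample -> population (defaults to the
#'   map attached to the genotype matrix that produced `calls`).
#' @param latitude_of optional named vector population -> latitude.
#' @return data frame with one row per population plus the total row.
#' @export
population_frequencies <- function(calls, population_of, latitude_of = NULL) {
  unmapped <- setdiff(calls$sample_id, names(population_of))
  .assert(length(unmapped) == 0L,
          paste0("samples without a population: ",
                 paste(unmapped, collapse = ", ")))
  pop <- as.character(population_of[calls$sample_id])
  pops <- unique(pop)
  one <- function(idx, label) {
    cc <- calls$call[idx]
    cc <- cc[cc != "UNRESOLVED"]
    n <- length(cc)
    counts <- c(anc_hom = sum(cc == "ANC_HOM"), het = sum(cc == "HET"),
                inv_hom = sum(cc == "INV_HOM"))
    if (n == 0L) {
      warning(sprintf("population %s has no resolved calls", label))
      fr <- c(NA_real_, NA_real_, NA_real_)
      fa <- NA_real_
    } else {
      fr <- counts / n
      fa <- (2 * counts[["anc_hom"]] + counts[["het"]]) / (2 * n)
    }
    data.frame(population = label,
               latitude = if (is.null(latitude_of)) NA_real_ else
                 unname(latitude_of[label]),
               n = n,
               count_anc_hom = counts[["anc_hom"]], count_het = counts[["het"]],
               count_inv_hom = counts[["inv_hom"]],
               freq_anc_hom = fr[1], freq_het = fr[2], freq_inv_hom = fr[3],
               pct_anc_hom = .pct1(fr[1]), pct_het = .pct1(fr[2]),
               pct_inv_hom = .pct1(fr[3]),
               freq_ancestral_allele = fa)
  }
  rows <- lapply(pops, function(p) one(which(pop == p), p))
  total <- one(seq_len(nrow(calls)), "TOTAL")
  total$latitude <- NA_real_
  out <- rbind(do.call(rbind, rows), total)
  rownames(out) <- NULL
  out
}

#' Ancestral-haplotype frequency against latitude
#'
#' Orders the per-population records by ascending latitude; populations with
#' no latitude are appended and flagged.
#'
#' @param records output of [population_frequencies()] (the `TOTAL` row is
#'   dropped).
#' @return data frame `population, latitude, n, freq_ancestral_allele,
#'   missing_latitude`, sorted by latitude.
#' @export
latitude_cline <- function(records) {
  rec <- records[records$population != "TOTAL",
                 c("population", "latitude", "n", "freq_ancestral_allele")]
  rec$missing_latitude <- is.na(rec$latitude)
  out <- rbind(rec[!rec$missing_latitude, ][order(rec$latitude[!rec$missing_latitude]), ],
               rec[rec$missing_latitude, ])
  rownames(out) <- NULL
  out
}

#' Ancestral allele frequency from a single diagnostic locus
#'
#' Allele-counting estimate with a Wilson 95\% confidence interval, for
#' amplicon-style data where one locus tags the two inversion orientations.
#'
#' @param hom_anc,het,hom_inv genotype counts at the locus.
#' @param conf confidence level (default 0.95).
#' @return `list(freq, lower, upper, n)` where `freq = (2 hom_anc + het) /
#'   (2 n)`.
#' @export
single_locus_frequency <- function(hom_anc, het, hom_inv, conf = 0.95) {
  .assert(all(c(hom_anc, het, hom_inv) >= 0), "counts must be non-negative")
  n <- hom_anc + het + hom_inv
  .assert(n >= 1, "need at least one genotyped sample")
  x <- 2 * hom_anc + het
  m <- 2 * n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ph <- x / m
  denom <- 1 + z^2 / m
  centre <- (ph + z^2 / (2 * m)) / denom
  half <- z * sqrt(ph * (1 - ph) / m + z^2 / (4 * m^2)) / denom
  list(freq = ph, lower = max(0, centre - half), upper = min(1, centre + half),
       n = n)
}
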