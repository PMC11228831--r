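#' Construct a genotype matrix
#'
#' The shared genotype container for the whole pipeline: a diploid dosage
#' matrix (samples x sites) counting copies of the alternate allele, with
#' 1-based site positions on a single chromosome and optional sample ->
#' population and population -> latitude metadata. Missing genotypes are
#' `NA`, never 0.
#'
#' @param dosages integer matrix, samples in rows, sites in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param positions 1-based, strictly increasing site positions (bp).
#' @param chrom chromosome identifier (single string).
#' @param ref,alt per-site single-character alleles.
#' @param sample_ids sample identifiers (row names).
#' @param population_of named character vector mapping sample id -> population;
#'   when supplied, every sample must be present.
#' @param latitude_of named numeric vector mapping population -> decimal
#'   degrees latitude (optional).
#' @return an object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(dosages, positions, chrom, ref, alt, sample_ids,
                            population_of = NULL, latitude_of = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  .assert(length(chrom) == 1L, "chrom must be a single identifier")
  .assert(nrow(dosages) == length(sample_ids),
          "dosage rows must match sample_ids")
  .assert(ncol(dosages) == length(positions),
          "dosage columns must match positions")
  .assert(length(ref) == length(positions) && length(alt) == length(positions),
          "ref/alt must have one allele per site")
  .assert(!is.unsorted(positions, strictly = TRUE),
          "positions must be strictly increasing")
  ok <- dosages %in% c(0L, 1L, 2L) | is.na(dosages)
  .assert(all(ok), "dosages must be 0, 1, 2 or NA")
  if (!is.null(population_of)) {
    missing_pop <- setdiff(sample_ids, names(population_of))
    .assert(length(missing_pop) == 0L,
            paste0("samples without a population: ",
                   paste(missing_pop, collapse = ", ")))
    population_of <- population_of[sample_ids]
  }
  rownames(dosages) <- sample_ids
  structure(list(
    sample_ids = as.character(sample_ids),
    chrom = as.character(chrom),
    positions = as.numeric(positions),
    ref_allele = as.character(ref),
    alt_allele = as.character(alt),
    dosages = dosages,
    population_of = population_of,
    latitude_of = latitude_of
  ), class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d samples x %d sites on %s (%.0f-%.0f bp)\n",
              length(x$sample_ids), length(x$positions), x$chrom,
              min(x$positions), max(x$positions)))
  if (!is.null(x$population_of))
    cat("populations:", paste(unique(x$population_of), collapse = ", "), "\n")
  invisible(x)
}

#' Subset the sites of a genotype matrix
#'
#' @param G a `GenotypeMatrix`.
#' @param sites integer site indices (columns) to keep, in increasing order.
#' @return a `GenotypeMatrix` restricted to those sites.
#' @export
subset_sites <- function(G, sites) {
  sites <- sort(unique(as.integer(sites)))
  genotype_matrix(G$dosages[, sites, drop = FALSE], G$positions[sites],
                  G$chrom, G$ref_allele[sites], G$alt_allele[sites],
                  G$sample_ids, G$population_of, G$latitude_of)
}

#' Read a VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}), keeping biallelic SNP records
#' only; multiallelic sites and indels are skipped with a message giving the
#' count. Dosages are computed from the GT field regardless of the phasing
#' separator; `./.` becomes `NA`.
#'
#' @param path path to a VCF file.
#' @param region optional `list(chrom =, start =, end =)` filter, 1-based
#'   inclusive coordinates.
#' @param chrom optional chromosome to extract when the file holds several;
#'   required in that case unless `region` names one.
#' @param samples_tsv optional path to a samples TSV (see
#'   [read_samples_tsv()]) used to attach population/latitude metadata.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, region = NULL, chrom = NULL, samples_tsv = NULL) {
  .assert(file.exists(path), paste0("cannot read VCF: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped > 0)
    message(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)",
                    n_skipped))
  .assert(any(snp), "no biallelic SNP records in VCF")
  keep_chrom <- region$chrom %||% chrom
  chroms <- fix[, "CHROM"]
  if (is.null(keep_chrom)) {
    .assert(length(unique(chroms[snp])) == 1L,
            "VCF holds several chromosomes; supply chrom or region")
    keep_chrom <- unique(chroms[snp])
  }
  pos <- as.numeric(fix[, "POS"])
  keep <- snp & chroms == keep_chrom
  if (!is.null(region))
    keep <- keep & pos >= region$start & pos <= region$end
  .assert(any(keep), "no biallelic SNP records after region filter")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  ord <- order(pos[keep])
  gt <- gt[ord, , drop = FALSE]
  d <- .gt_to_dosage(gt)          # variants x samples
  pop <- lat <- NULL
  if (!is.null(samples_tsv)) {
    maps <- read_samples_tsv(samples_tsv)
    pop <- maps$population_of
    lat <- maps$latitude_of
  }
  genotype_matrix(t(d), pos[keep][ord], keep_chrom,
                  ref[keep][ord], alt[keep][ord],
                  colnames(gt), population_of = pop, latitude_of = lat)
}

# GT string -> alt-allele dosage; tolerant of / and | separators.
.gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  val <- vapply(u, function(s) {
    if (is.na(s)) return(NA_integer_)
    a <- strsplit(s, "[/|]")[[1]]
    if (length(a) != 2L || any(!a %in% c("0", "1"))) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
  m <- matrix(val[match(as.vector(gt), u)], nrow = nrow(gt),
              dimnames = dimnames(gt))
  m
}

#' Write a genotype matrix as VCF 4.2
#'
#' One record per site with an unphased diploid GT field; missing dosages are
#' written as `./.`. The file ends with a newline.
#'
#' @param G a `GenotypeMatrix`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(G, path) {
  gt_codes <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_along(G$positions), function(j) {
    d <- G$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_codes[d + 1L])
    paste(c(G$chrom, format(G$positions[j], scientific = FALSE, trim = TRUE),
            sprintf("site%06d", j), G$ref_allele[j], G$alt_allele[j],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=invkaryo",
    sprintf("##contig=<ID=%s>", G$chrom),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$sample_ids), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Convert a 1-based inclusive interval to BED convention
#'
#' BED uses 0-based, half-open coordinates, so `bed_start = start - 1` and
#' `bed_end = end`; the interval width is preserved.
#'
#' @param chrom chromosome identifier.
#' @param start_1based,end_1based 1-based inclusive interval bounds.
#' @return a one-row data frame with columns `chrom`, `start`, `end`.
#' @export
region_to_bed <- function(chrom, start_1based, end_1based) {
  .assert(start_1based >= 1, "start must be >= 1")
  .assert(start_1based <= end_1based, "start must not exceed end")
  data.frame(chrom = chrom, start = start_1based - 1, end = end_1based)
}

#' Read a samples TSV (sample, population, latitude)
#'
#' @param path TSV with header columns `sample`, `population`, and optionally
#'   `latitude` (decimal degrees per population).
#' @return `list(population_of =, latitude_of =, table =)`.
#' @export
read_samples_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  for (col in c("sample", "population"))
    .assert(col %in% names(tab),
            paste0("samples table is missing required column: ", col))
  pop <- stats::setNames(as.character(tab$population), tab$sample)
  lat <- NULL
  if ("latitude" %in% names(tab)) {
    u <- !duplicated(tab$population)
    lat <- stats::setNames(as.numeric(tab$latitude[u]), tab$population[u])
  }
  list(population_of = pop, latitude_of = lat, table = tab)
}

#' Read a gene annotation TSV
#'
#' @param path TSV with header columns `gene_id`, `chrom`, `start`, `end`,
#'   `term_id`, `category`; one row per gene-term assignment.
#' @return the annotation data frame.
#' @export
read_annotation_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  for (col in c("gene_id", "chrom", "start", "end", "term_id", "category"))
    .assert(col %in% names(tab),
            paste0("annotation table is missing required column: ", col))
  tab
}

#' Read one aligned ortholog family from FASTA
#'
#' All sequences in a family must have equal length (the families are
#' alignments); a deviating sequence raises an error naming its header.
#'
#' @param path FASTA file, one family per file, taxon-labelled headers.
#' @param family_id optional identifier; defaults to the file name without
#'   extension.
#' @return an `OrthologFamily`: `list(family_id =, sequences =)` with
#'   `sequences` a named character vector of uppercase nucleotide strings.
#' @export
read_family_fasta <- function(path, family_id = NULL) {
  seqs <- ape::read.FASTA(path)
  .assert(length(seqs) > 0L, paste0("empty FASTA: ", path))
  chars <- as.character(seqs)
  lens <- lengths(chars)
  if (length(unique(lens)) != 1L) {
    # first sequence sets the reference length; name the first deviator
    bad <- which(lens != lens[1])[1]
    stop(sprintf("unequal sequence length in %s: '%s' has %d sites",
                 path, names(chars)[bad], lens[bad]), call. = FALSE)
  }
  strings <- vapply(chars, function(x) toupper(paste(x, collapse = "")),
                    character(1))
  ortholog_family(family_id %||% sub("\\.[^.]*$", "", basename(path)),
                  strings)
}

#' Construct an ortholog family
#'
#' @param family_id identifier.
#' @param sequences named character vector of equal-length uppercase
#'   nucleotide strings (alphabet A/C/G/T/N/-).
#' @return an object of class `OrthologFamily`.
#' @export
ortholog_family <- function(family_id, sequences) {
  .assert(length(unique(nchar(sequences))) == 1L,
          "family sequences must have equal length")
  .assert(!is.null(names(sequences)) && all(nzchar(names(sequences))),
          "family sequences must be named by taxon")
  bad <- grepl("[^ACGTN-]", sequences)
  .assert(!any(bad), "sequences may contain only A, C, G, T, N, -")
  structure(list(family_id = family_id, sequences = sequences),
            class = "OrthologFamily")
}

#' Write an ortholog family to FASTA
#'
#' @param family an `OrthologFamily`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_family_fasta <- function(family, path) {
  lines <- as.vector(rbind(paste0(">", names(family$sequences)),
                           unname(family$sequences)))
  writeLines(lines, path)
  invisible(path)
}

# Tab-only TSV writer; files always end with a newline.
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
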