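# End-to-end orchestration: simulate -> ldscan -> karyotype -> popgen ->
# (dating, enrich), with a machine-readable run manifest.

#' Default pipeline configuration
#'
#' Stage parameters mirror the analysis defaults used throughout the package
#' (`r2_min = 0.8`, `maf_min = 0.05`, 50 kb windows sliding by 10 kb, at
#' least 100 segregating sites per window, `alpha = 0.05`). The default run
#' is simulation-backed; supply `inputs` paths and disable `stages$simulate`
#' to analyse real files.
#'
#' @param seed integer seed used for every stochastic stage.
#' @param out_dir output directory.
#' @return a nested configuration list.
#' @export
default_config <- function(seed = 1, out_dir = "invkaryo_run") {
  list(
    seed = seed,
    out_dir = out_dir,
    stages = list(simulate = TRUE, ldscan = TRUE, karyotype = TRUE,
                  popgen = TRUE, dating = TRUE, enrich = TRUE),
    inputs = list(vcf = NULL, samples = NULL, loci = NULL,
                  annotations = NULL, genes = NULL, families_dir = NULL),
    simulate = list(cohort = list(),
                    orthologs = list(n_families = 40, seq_length = 2000),
                    annotation = list(n_genes = 3000,
                                      ci_gene_fraction = 0.05,
                                      n_terms = 12)),
    ldscan = list(r2_min = 0.8, maf_min = 0.05, min_distance = 1e6,
                  min_pairs = 50),
    karyotype = list(concordance_min = 0.95),
    popgen = list(window = 50000, step = 10000, min_S = 100),
    dating = list(calibration_age = 27.3),
    enrich = list(alpha = 0.05)
  )
}

.merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]) && !is.null(names(user[[k]])))
      base[[k]] <- .merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

.validate_config <- function(cfg) {
  st <- cfg$stages
  if (!isTRUE(st$simulate)) {
    if (isTRUE(st$ldscan) || isTRUE(st$karyotype) || isTRUE(st$popgen))
      .assert(!is.null(cfg$inputs$vcf) && file.exists(cfg$inputs$vcf),
              "config error: simulation disabled and inputs$vcf missing")
    if (isTRUE(st$dating))
      .assert(!is.null(cfg$inputs$families_dir) &&
                dir.exists(cfg$inputs$families_dir),
              "config error: dating enabled but inputs$families_dir missing")
    if (isTRUE(st$enrich))
      .assert(!is.null(cfg$inputs$annotations) &&
                file.exists(cfg$inputs$annotations),
              "config error: enrich enabled but inputs$annotations missing")
  }
  if (!isTRUE(st$ldscan) && isTRUE(st$karyotype))
    .assert(!is.null(cfg$inputs$loci),
            "config error: karyotype enabled without ldscan or a loci file")
  invisible(cfg)
}

#' Run the full inversion-characterization pipeline
#'
#' Executes the enabled stages in dependency order, writes every stage output
#' under `out_dir`, and returns (and writes) a manifest listing each output
#' file with its MD5 checksum, the resolved configuration, the seed and stage
#' timings. Reruns with the same configuration and seed yield identical
#' checksums for all deterministic stages. A stage failure aborts the run
#' with the failing stage named, leaving a `.partial` marker beside the
#' outputs already written.
#'
#' @param config a configuration list (see [default_config()]) or the path to
#'   a JSON file holding one; partial configurations are merged over the
#'   defaults.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- .merge_config(default_config(), config)
  .validate_config(cfg)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  partial <- file.path(out, ".partial")
  file.create(partial)
  log_path <- file.path(out, "run.log")
  logf <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  files <- character(0)
  timings <- list()
  stage_env <- new.env()
  run_stage <- function(name, enabled, fun) {
    if (!isTRUE(enabled)) {
      logf("stage %s: skipped", name)
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    logf("stage %s: done in %.2fs", name, timings[[name]])
    res
  }
  add_file <- function(...) files <<- c(files, c(...))

  run_stage("simulate", cfg$stages$simulate, function() {
    set.seed(cfg$seed)
    seeds <- .child_seeds(3)
    cp <- do.call(cohort_sim_params,
                  c(cfg$simulate$cohort, list(seed = seeds[1])))
    stage_env$cohort <- simulate_inversion_cohort(cp)
    add_file(write_cohort(stage_env$cohort, out))
    op <- do.call(ortholog_sim_params,
                  c(cfg$simulate$orthologs, list(seed = seeds[2])))
    stage_env$families <- simulate_ortholog_families(op)
    add_file(write_families(stage_env$families, file.path(out, "families")))
    ap <- do.call(annotation_sim_params,
                  c(cfg$simulate$annotation, list(seed = seeds[3])))
    stage_env$annotation <- simulate_annotation(ap)
    add_file(write_annotation(stage_env$annotation, out))
  })

  if (!isTRUE(cfg$stages$simulate)) {
    if (!is.null(cfg$inputs$vcf))
      stage_env$cohort <- list(genotypes = read_vcf(
        cfg$inputs$vcf, samples_tsv = cfg$inputs$samples))
    if (!is.null(cfg$inputs$families_dir))
      stage_env$families <- lapply(
        list.files(cfg$inputs$families_dir, pattern = "\\.fa(sta)?$",
                   full.names = TRUE), read_family_fasta)
    if (!is.null(cfg$inputs$annotations))
      stage_env$annotation <- list(
        annotations = read_annotation_tsv(cfg$inputs$annotations),
        genes = if (!is.null(cfg$inputs$genes))
          utils::read.table(cfg$inputs$genes, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE) else NULL)
  }

  run_stage("ldscan", cfg$stages$ldscan, function() {
    G <- stage_env$cohort$genotypes
    pairs <- compute_r2(G, maf_min = cfg$ldscan$maf_min,
                        r2_min = cfg$ldscan$r2_min)
    p <- file.path(out, "ld_pairs.tsv"); write_tsv(pairs, p); add_file(p)
    region <- detect_inversion_region(pairs,
                                      min_distance = cfg$ldscan$min_distance,
                                      min_pairs = cfg$ldscan$min_pairs)
    stage_env$region <- region
    if (is.null(region)) {
      logf("ldscan: no inversion region detected")
      return(invisible(NULL))
    }
    rb <- file.path(out, "region.bed")
    utils::write.table(region_to_bed(region$chrom, region$start, region$end),
                       rb, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    add_file(rb)
    loci <- select_diagnostic_loci(G, region,
                                   concordance_min =
                                     cfg$karyotype$concordance_min)
    stage_env$loci <- loci
    lp <- file.path(out, "diagnostic_loci.tsv"); write_tsv(loci, lp)
    add_file(lp)
  })

  run_stage("karyotype", cfg$stages$karyotype && !is.null(stage_env$loci) ||
              (cfg$stages$karyotype && !is.null(cfg$inputs$loci)), function() {
    G <- stage_env$cohort$genotypes
    loci <- stage_env$loci %||%
      utils::read.table(cfg$inputs$loci, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    calls <- call_karyotypes(G, loci)
    stage_env$calls <- calls
    cp <- file.path(out, "calls.tsv"); write_tsv(calls, cp); add_file(cp)
    freqs <- population_frequencies(calls, G$population_of, G$latitude_of)
    fp <- file.path(out, "pop_frequencies.tsv"); write_tsv(freqs, fp)
    add_file(fp)
    cl <- latitude_cline(freqs)
    lp <- file.path(out, "cline.tsv"); write_tsv(cl, lp); add_file(lp)
  })

  run_stage("popgen", cfg$stages$popgen && !is.null(stage_env$calls),
            function() {
    G <- stage_env$cohort$genotypes
    calls <- stage_env$calls
    region <- stage_env$region
    anc <- calls$sample_id[calls$call == "ANC_HOM"]
    inv <- calls$sample_id[calls$call == "INV_HOM"]
    mask <- if (!is.null(region)) list(start = region$start,
                                       end = region$end) else NULL
    for (grp in list(list(id = "anc", s = anc), list(id = "inv", s = inv))) {
      if (length(grp$s) < 2) {
        logf("popgen: fewer than 2 %s homokaryotypes; windows skipped",
             grp$id)
        next
      }
      w <- sliding_window_stats(G, samples = grp$s,
                                window = cfg$popgen$window,
                                step = cfg$popgen$step,
                                min_S = cfg$popgen$min_S,
                                region = mask,
                                region_mode = if (is.null(mask)) "all" else
                                  "only")
      p <- file.path(out, sprintf("windows_%s.tsv", grp$id))
      write_tsv(w, p); add_file(p)
      stage_env[[paste0("windows_", grp$id)]] <- w
    }
    if (length(anc) >= 2 && length(inv) >= 2) {
      fst <- weir_cockerham_fst(G, anc, inv)
      p <- file.path(out, "fst.tsv"); write_tsv(fst, p); add_file(p)
      ci_sites <- if (!is.null(region))
        which(G$positions >= region$start & G$positions <= region$end) else
          NULL
      het <- per_sample_heterozygosity(G, ci_sites)
      hd <- data.frame(sample_id = names(het), heterozygosity = unname(het),
                       call = calls$call[match(names(het), calls$sample_id)])
      p <- file.path(out, "heterozygosity.tsv"); write_tsv(hd, p); add_file(p)
      tests <- list()
      tests$het_anc_vs_inv <- welch_t_test(het[anc], het[inv])
      wa <- stage_env$windows_anc
      wi <- stage_env$windows_inv
      if (!is.null(wa) && !is.null(wi)) {
        fa <- wa$theta_w[wa$passes_filter]
        fi <- wi$theta_w[wi$passes_filter]
        if (length(fa) >= 2 && length(fi) >= 2)
          tests$theta_anc_vs_inv <- welch_t_test(fa, fi)
      }
      td <- do.call(rbind, lapply(names(tests), function(nm)
        data.frame(comparison = nm, test = tests[[nm]]$test_name,
                   statistic = tests[[nm]]$statistic,
                   df = paste(round(tests[[nm]]$df, 3), collapse = ","),
                   p_two_tailed = tests[[nm]]$p_two_tailed)))
      p <- file.path(out, "tests.tsv"); write_tsv(td, p); add_file(p)
    } else {
      logf("popgen: need >= 2 samples per homokaryotype for contrasts")
    }
  })

  run_stage("dating", cfg$stages$dating && !is.null(stage_env$families),
            function() {
    res <- date_inversion(stage_env$families,
                          calibration(age_my = cfg$dating$calibration_age))
    p <- file.path(out, "topology_reports.tsv")
    write_tsv(res$reports, p); add_file(p)
    p <- file.path(out, "ages.tsv"); write_tsv(res$estimates, p); add_file(p)
    p <- file.path(out, "age_summary.json")
    jsonlite::write_json(list(median_my = res$summary$median_my,
                              mean_my = res$summary$mean_my,
                              n_families = res$summary$n_families,
                              rejected = as.list(res$rejected)),
                         p, auto_unbox = TRUE, digits = NA)
    add_file(p)
  })

  run_stage("enrich", cfg$stages$enrich && !is.null(stage_env$annotation),
            function() {
    ann <- stage_env$annotation
    genes <- ann$genes
    region <- stage_env$region
    ci_genes <- if (!is.null(ann$ci_genes) && is.null(region)) ann$ci_genes
      else {
        .assert(!is.null(genes), "enrich: no gene coordinate table")
        lo <- if (!is.null(region)) region$start else
          min(genes$start[genes$gene_id %in% ann$ci_genes])
        hi <- if (!is.null(region)) region$end else
          max(genes$end[genes$gene_id %in% ann$ci_genes])
        genes$gene_id[genes$start >= lo & genes$end <= hi]
      }
    res <- term_enrichment(ann$annotations, ci_genes,
                           universe = if (!is.null(genes)) genes$gene_id else
                             NULL,
                           alpha = cfg$enrich$alpha)
    p <- file.path(out, "enrichment.tsv"); write_tsv(res$records, p)
    add_file(p)
  })

  resolved <- file.path(out, "run_config_resolved.json")
  jsonlite::write_json(cfg, resolved, auto_unbox = TRUE, null = "null",
                       digits = NA)
  add_file(resolved)
  files <- unique(normalizePath(files))
  manifest <- list(
    package_version = as.character(utils::packageVersion("invkaryo")),
    seed = cfg$seed,
    timings_s = timings,
    outputs = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  file.remove(partial)
  logf("pipeline complete: %d output files", length(files))
  invisible(manifest)
}
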