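test_that("JC69 distance matches the closed form and guards its domain", {
  a <- strrep("A", 1000)
  expect_identical(jc69_distance(a, a), 0)
  # p = 0.1 over 1,000 sites; frozen from the closed-form script
  b <- paste0(strrep("C", 100), strrep("A", 900))
  expect_equal(jc69_distance(a, b), 0.107325632730505, tolerance = 1e-12)
  # ambiguous and gap sites are excluded from the comparison
  a2 <- paste0(strrep("N", 50), strrep("A", 950))
  b2 <- paste0(strrep("-", 25), strrep("C", 120), strrep("A", 855))
  p <- 95 / 950 # 95 mismatches among 950 comparable sites
  expect_equal(jc69_distance(a2, b2), -0.75 * log(1 - 4 * p / 3),
               tolerance = 1e-12)
  expect_error(jc69_distance(paste0(strrep("C", 750), strrep("A", 250)), a),
               "saturated")
  expect_error(jc69_distance(strrep("A", 50), strrep("C", 50)),
               "comparable")
  expect_error(jc69_distance("ACGT", "ACG"), "equal length")
})

test_that("neighbor joining recovers additive four-taxon topologies", {
  # additive distances on ((t1,t2),(t3,t4)) with internal edge 3
  D <- matrix(c(0, 2, 7, 8,
                2, 0, 7, 8,
                7, 7, 0, 3,
                8, 8, 3, 0), 4, 4,
              dimnames = list(c("t1", "t2", "t3", "t4"),
                              c("t1", "t2", "t3", "t4")))
  tr <- nj_tree(D)
  expect_true(ape::is.monophyletic(ape::root(tr, "t4"), c("t1", "t2")))
  # three taxa have a single unrooted resolution
  tr3 <- nj_tree(D[1:3, 1:3])
  expect_identical(sort(tr3$tip.label), c("t1", "t2", "t3"))
  D2 <- D
  D2[1, 2] <- 5
  expect_error(nj_tree(D2), "symmetric")
})

test_that("topology checks validate clades and reject planted violations", {
  fams <- simulate_ortholog_families(ortholog_sim_params(
    n_families = 3, seq_length = 3000, seed = 19))
  rep1 <- ortholog_topology_report(fams[[1]])
  expect_true(rep1$passes)
  expect_true(rep1$two_homeolog_clades)
  expect_true(rep1$salmo_oncorhynchus_sister_in_each)
  expect_true(rep1$inversion_pair_sister)
  expect_false(rep1$inversion_pair_identical)
  # identical inversion pair is flagged and fails
  fam_id <- fams[[2]]
  fam_id$sequences[["trout_inv"]] <- fam_id$sequences[["trout_anc"]]
  rep2 <- ortholog_topology_report(fam_id)
  expect_true(rep2$inversion_pair_identical)
  expect_false(rep2$passes)
  # swapping homeolog tips between clades breaks clade monophyly
  fam_sw <- fams[[3]]
  tmp <- fam_sw$sequences[["whitefish1"]]
  fam_sw$sequences[["whitefish1"]] <- fam_sw$sequences[["whitefish2"]]
  fam_sw$sequences[["whitefish2"]] <- tmp
  rep3 <- ortholog_topology_report(fam_sw)
  expect_false(rep3$two_homeolog_clades)
  expect_false(rep3$passes)
  # missing label is named
  tr <- attr(rep1, "tree")
  tr <- ape::drop.tip(tr, "grayling2")
  expect_error(check_ortholog_topology(tr), "grayling2")
})

test_that("family filtering tallies rejection reasons", {
  fams <- simulate_ortholog_families(ortholog_sim_params(
    n_families = 4, seq_length = 2000, seed = 23))
  fams[[2]]$sequences[["trout_inv"]] <- fams[[2]]$sequences[["trout_anc"]]
  reports <- do.call(rbind, lapply(fams, ortholog_topology_report))
  filt <- filter_families(fams, reports)
  expect_identical(filt$n_kept, 3L)
  expect_identical(unname(filt$rejected["invariant_pair"]), 1L)
  expect_identical(sum(filt$rejected), 1L)
  # all passing: identity
  ok <- filter_families(fams[-2], reports[-2, ])
  expect_identical(ok$n_kept, 3L)
})

test_that("TMRCA estimation is proportional, calibrated, and label-symmetric", {
  fams <- simulate_ortholog_families(ortholog_sim_params(
    n_families = 6, seq_length = 8000, seed = 29))
  est <- estimate_tmrca(fams[[1]])
  expect_gt(est$tmrca_my, 0)
  # d_inv_pair = 0 gives age 0
  fam0 <- fams[[2]]
  fam0$sequences[["trout_inv"]] <- fam0$sequences[["trout_anc"]]
  expect_identical(estimate_tmrca(fam0)$tmrca_my, 0)
  # d_inv = d_cal gives exactly the calibration age
  filler <- stats::setNames(
    rep(strrep("T", 1000),
        length(setdiff(ortholog_taxa(),
                       c("atlantic1", "trout_anc", "trout_inv")))),
    setdiff(ortholog_taxa(), c("atlantic1", "trout_anc", "trout_inv")))
  syn <- ortholog_family("syn", c(
    filler,
    atlantic1 = strrep("A", 1000),
    trout_anc = paste0(strrep("C", 50), strrep("A", 950)),
    trout_inv = paste0(strrep("G", 50), strrep("A", 950))))
  e <- estimate_tmrca(syn, calibration(age_my = 27.3))
  expect_equal(e$d_inv_pair, e$d_cal_pair, tolerance = 1e-12)
  expect_equal(e$tmrca_my, 27.3, tolerance = 1e-9)
  # doubling the calibration age doubles every estimate exactly
  e1 <- do.call(rbind, lapply(fams, estimate_tmrca,
                              cal = calibration(age_my = 27.3)))
  e2 <- do.call(rbind, lapply(fams, estimate_tmrca,
                              cal = calibration(age_my = 54.6)))
  expect_equal(e2$tmrca_my, 2 * e1$tmrca_my, tolerance = 1e-12)
  # swapping the anc/inv labels leaves the estimate unchanged
  fam_sw <- fams[[4]]
  tmp <- fam_sw$sequences[["trout_anc"]]
  fam_sw$sequences[["trout_anc"]] <- fam_sw$sequences[["trout_inv"]]
  fam_sw$sequences[["trout_inv"]] <- tmp
  expect_equal(estimate_tmrca(fam_sw)$tmrca_my,
               estimate_tmrca(fams[[4]])$tmrca_my, tolerance = 1e-12)
  # zero calibration distance has no rate signal
  broken <- fams[[5]]
  broken$sequences[["atlantic1"]] <- broken$sequences[["trout_anc"]]
  broken$sequences[["trout_inv"]] <- broken$sequences[["trout_anc"]]
  expect_error(estimate_tmrca(broken), "no signal")
  expect_error(calibration(age_my = 0), "age")
})

test_that("age summaries aggregate and order divergence scenarios correctly", {
  est <- data.frame(family_id = c("a", "b", "c"),
                    d_inv_pair = 0, d_cal_pair = 1, tmrca_my = c(1, 2, 3))
  s <- summarize_ages(est)
  expect_identical(c(s$median_my, s$mean_my, s$n_families), c(2, 2, 3))
  one <- summarize_ages(est[1, ])
  expect_identical(c(one$median_my, one$mean_my), c(1, 1))
  expect_error(summarize_ages(est[0, ]), "no age")
  # batches at t_inv 0.5 vs 1.0 MY order their medians correctly
  ords <- vapply(1:10, function(sd) {
    ages <- c(0.5, 1.0)
    meds <- vapply(ages, function(tv) {
      prm <- ortholog_sim_params(
        n_families = 12, seq_length = 6000,
        species_tree_ages = c(root = 112, esociform = 85, wgd = 95,
                              salmonidae = 51.8, whitefish_grayling = 35,
                              salmo_oncorhynchus = 27.3, t_inv = tv),
        seed = 1000 * tv + sd)
      res <- date_inversion(simulate_ortholog_families(prm))
      res$summary$median_my
    }, numeric(1))
    meds[1] < meds[2]
  }, logical(1))
  expect_gte(mean(ords), 0.9)
})

test_that("estimation error shrinks with alignment length", {
  med_err <- vapply(c(2000, 20000), function(len) {
    errs <- vapply(1:6, function(sd) {
      fams <- simulate_ortholog_families(ortholog_sim_params(
        n_families = 10, seq_length = len, seed = 7000 + 13 * sd + len))
      res <- date_inversion(fams)
      abs(res$estimates$tmrca_my - 1.0)
    }, numeric(10))
    stats::median(errs)
  }, numeric(1))
  expect_lt(med_err[2], med_err[1])
})
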