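test_that("all-zero mutation parameters give the perfect blunt fusion", {
  set.seed(41)
  quiet <- simulation_params(p_deletion_per_end = 0, p_p_nucleotides = 0,
                             n_mean = 0, sj_imprecision_prob = 0)
  cl <- demo_coding_locus()
  refs <- vdjoin:::joint_refs(cl)
  sim <- simulate_coding_joint(cl, quiet)
  expect_identical(sim$read$sequence, paste0(refs$left, refs$right))
  expect_identical(sim$truth$del_left, 0L)
  expect_identical(sim$truth$n_insertion, "")
  sl <- demo_signal_locus()
  srefs <- vdjoin:::joint_refs(sl)
  ssim <- simulate_signal_joint(sl, quiet)
  expect_identical(ssim$read$sequence, paste0(srefs$left, srefs$right))
  expect_true(ssim$truth$precise)
})

test_that("identical parameters and seed give byte-identical cohort files", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  loci <- list(demoCJ = demo_coding_locus(), demoSJ = demo_signal_locus())
  params <- list(WT = simulation_params(seed = 99, n_junctions = 30,
                                        joint_kind = "signal"),
                 FS = cohort_preset(seed = 99)$FS)
  simulate_cohort(loci["demoSJ"], params, dir = dir1)
  simulate_cohort(loci["demoSJ"], params, dir = dir2)
  for (f in c("reads.fasta", "truth.tsv", "metadata.tsv", "params.json"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  # n_junctions = 0 produces empty but valid outputs
  dir0 <- withr::local_tempdir()
  res0 <- simulate_cohort(loci["demoSJ"],
                          list(WT = simulation_params(n_junctions = 0)),
                          dir = dir0)
  expect_identical(nrow(res0$reads), 0L)
  expect_true(file.exists(file.path(dir0, "truth.tsv")))
})

test_that("fully precise regimes annotate as 100% precise and ApaL1-positive", {
  sl <- demo_signal_locus()
  sim <- simulate_cohort(sl, list(WT = simulation_params(
    seed = 5, n_junctions = 60, joint_kind = "signal",
    sj_imprecision_prob = 0)))
  ann <- annotate_junctions(sim$reads, sl)
  expect_true(all(ann$precise))
  expect_true(all(ann$apal1_site_present))
})

test_that("miscleavage-only imprecision is flagged by the annotator", {
  sl <- demo_signal_locus()
  params <- simulation_params(seed = 6, n_junctions = 80,
                              joint_kind = "signal",
                              sj_imprecision_prob = 1,
                              sj_p_deletion_per_end = 0, p_miscleavage = 1,
                              n_mean = 0)
  sim <- simulate_cohort(sl, list(FS = params))
  expect_true(all(sim$truth$miscleavage))
  ann <- annotate_junctions(sim$reads, sl)
  expect_true(all(!ann$precise))
  expect_true(all(ann$miscleavage))
})

test_that("a deletion-heavy signal regime reproduces the geometric over-cutoff tail", {
  sl <- demo_signal_locus()
  params <- simulation_params(seed = 8, n_junctions = 500,
                              joint_kind = "signal",
                              sj_imprecision_prob = 1,
                              sj_p_deletion_per_end = 0.9,
                              deletion_mean = 6, n_mean = 0,
                              p_miscleavage = 0)
  sim <- simulate_cohort(sl, list(FS = params))
  ann <- annotate_junctions(sim$reads, sl)
  s <- summarize_signal_joints(ann)
  pooled <- s[s$locus == "pooled", ]
  # P(deletion > 5 | deleted) = (5/6)^5 ~ 40% for the 1+geometric model
  theory <- 100 * (5 / 6)^5
  expect_lt(abs(pooled$pct_deleted_ends_gt_cutoff - theory), 10)
})

test_that("simulation parameters are recovered within 3 standard errors at n = 1000", {
  set.seed(44)
  # deletion mean, unambiguous deletion-only regime
  locus <- disjoint_alphabet_locus(45)
  params <- simulation_params(seed = 45, n_junctions = 1000,
                              p_deletion_per_end = 0.7, deletion_mean = 4,
                              n_mean = 0, p_p_nucleotides = 0)
  sim <- simulate_cohort(locus, list(WT = params))
  ann <- annotate_junctions(sim$reads, locus)
  dels <- c(ann$del_left[ann$del_left > 0], ann$del_right[ann$del_right > 0])
  se <- stats::sd(dels) / sqrt(length(dels))
  expect_lt(abs(mean(dels) - 4), 3 * se)
  # N-length mean, insertion-only regime with P-proof flank ends
  locus2 <- pproof_insertion_locus()
  params2 <- simulation_params(seed = 46, n_junctions = 1000,
                               p_deletion_per_end = 0, p_p_nucleotides = 0,
                               n_mean = 3,
                               n_base_composition = pproof_n_composition)
  sim2 <- simulate_cohort(locus2, list(WT = params2))
  ann2 <- annotate_junctions(sim2$reads, locus2)
  lens <- nchar(ann2$n_insertion)
  se2 <- stats::sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 3), 3 * se2)
  # imprecision fraction of a signal regime
  sl <- demo_signal_locus()
  params3 <- simulation_params(seed = 47, n_junctions = 1000,
                               joint_kind = "signal",
                               sj_imprecision_prob = 0.25)
  sim3 <- simulate_cohort(sl, list(WT = params3))
  ann3 <- annotate_junctions(sim3$reads, sl)
  frac <- mean(!ann3$precise)
  se3 <- sqrt(0.25 * 0.75 / 1000)
  expect_lt(abs(frac - 0.25), 3 * se3)
})

test_that("the bundled two-genotype preset separates the regimes end to end", {
  sl <- demo_signal_locus()
  sim <- simulate_cohort(sl, cohort_preset(n_junctions = 150, seed = 48))
  ann <- annotate_junctions(sim$reads, sl)
  s <- summarize_signal_joints(ann)
  pooled <- s[s$locus == "pooled", ]
  fs <- pooled[pooled$genotype == "FS", ]
  wt <- pooled[pooled$genotype == "WT", ]
  expect_gt(fs$pct_imprecise, wt$pct_imprecise)
  res <- chi_squared_independence(rbind(c(fs$n_imprecise, fs$n_precise),
                                        c(wt$n_imprecise, wt$n_precise)))
  expect_lt(res$p_value, 0.05)
})

test_that("identical regimes give uniform chi-squared p-values (type-I control)", {
  sl <- demo_signal_locus()
  pvals <- vapply(1:500, function(i) {
    pair <- list(
      A = simulation_params(seed = 1000 + i, n_junctions = 200,
                            joint_kind = "signal"),
      B = simulation_params(seed = 501000 + i, n_junctions = 200,
                            joint_kind = "signal"))
    sim <- simulate_cohort(sl, pair)
    prec <- tapply(sim$truth$precise, sim$reads$genotype, sum)
    tab <- rbind(c(200 - prec[["A"]], prec[["A"]]),
                 c(200 - prec[["B"]], prec[["B"]]))
    chi_squared_independence(tab)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("microhomology joins use existing overlaps or fall back flagged", {
  set.seed(49)
  # flanks engineered with a shared junction-proximal trimer
  locus <- toy_coding_locus(paste0(random_dna(10, c("A", "C")), "GTTGG"),
                            paste0("TGGCA", random_dna(10, c("A", "C"))))
  params <- simulation_params(p_microhomology_join = 1, mh_min = 2)
  sims <- lapply(1:50, function(i)
    simulate_coding_joint(locus, params, paste0("m", i)))
  mh <- vapply(sims, function(s) s$truth$microhomology_len, integer(1))
  fallback <- vapply(sims, function(s) s$truth$mh_fallback, logical(1))
  expect_true(all(mh >= 2 | fallback))
  expect_gt(mean(mh >= 2), 0.9)  # overlaps exist for these flanks
  # annotation reports a decomposition that reconstructs every MH read
  for (s in sims) {
    a <- annotate_coding_joint(s$read$sequence, locus)
    expect_identical(reconstruct_junction(a, locus), s$read$sequence)
  }
  # flanks with disjoint alphabets can never satisfy the request
  locus2 <- disjoint_alphabet_locus()
  sim2 <- simulate_coding_joint(locus2, params, "f")
  expect_true(sim2$truth$mh_fallback)
})
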