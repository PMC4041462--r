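test_that("coding-joint decomposition matches hand-worked cases", {
  locus <- toy_coding_locus("TACTTC", "GGAACA")
  # perfect blunt join
  a <- annotate_coding_joint("TACTTCGGAACA", locus)
  expect_identical(
    c(a$del_left, a$del_right, nchar(a$n_insertion), a$microhomology_len),
    c(0L, 0L, 0L, 0L))
  # 2 nt resected from the left coding end
  a <- annotate_coding_joint("TACTGGAACA", locus)
  expect_identical(c(a$del_left, a$del_right), c(2L, 0L))
  expect_identical(a$n_insertion, "")
  # P nucleotides: GA extends the unresected left end ...TC as a
  # reverse-complement palindrome
  a <- annotate_coding_joint("TACTTCGAGGAACA", locus)
  expect_identical(a$p_left, "GA")
  expect_identical(a$n_insertion, "")
  expect_identical(a$del_left, 0L)
  # P on the right end: CC complements the right flank start GG
  a <- annotate_coding_joint("TACTTCCCGGAACA", locus)
  expect_identical(a$p_right, "CC")
  # microhomology: flanks share the 2-mer TC at the junction
  mh_locus <- toy_coding_locus("TACTTC", "TCGGAACA")
  a <- annotate_coding_joint("TACTTCGGAACA", mh_locus)
  expect_identical(a$microhomology_len, 2L)
  expect_identical(a$microhomology_seq, "TC")
  expect_identical(c(a$del_left, a$del_right), c(0L, 0L))
  # the same overlap below the reporting threshold folds into the left end
  a <- annotate_coding_joint("TACTTCGGAACA", mh_locus,
                             annotation_config(microhomology_min = 3))
  expect_identical(a$microhomology_len, 0L)
  expect_identical(c(a$del_left, a$del_right), c(0L, 2L))
  # unalignable read errors with the read id
  expect_error(annotate_coding_joint("GGGGGGGG", locus, read_id = "r9"),
               "r9")
  # wrong joint kind is a usage error
  expect_error(annotate_signal_joint("TACTTCGGAACA", locus), "not a signal")
})

test_that("greedy decomposition equals exhaustive minimal-edit search on short windows", {
  set.seed(101)
  cfg <- annotation_config()
  for (i in 1:300) {
    lf <- random_dna(sample(4:12, 1))
    rf <- random_dna(sample(4:12, 1))
    locus <- toy_coding_locus(lf, rf)
    # mix of structured junctions and arbitrary windows <= 30 nt
    seqn <- if (runif(1) < 0.5) {
      dl <- sample(0:3, 1); dr <- sample(0:3, 1)
      paste0(substr(lf, 1, nchar(lf) - dl), random_dna(sample(0:4, 1)),
             substr(rf, dr + 1, nchar(rf)))
    } else random_dna(sample(2:30, 1))
    o <- oracle_decompose(seqn, lf, rf, cfg$microhomology_min)
    if (o$left_retained == 0 && o$right_retained == 0) next
    a <- annotate_coding_joint(seqn, locus, cfg)
    expect_identical(a$del_left, o$del_left)
    expect_identical(a$del_right, o$del_right)
    expect_identical(a$microhomology_len, o$microhomology_len)
    expect_identical(paste0(a$p_left, a$n_insertion, a$p_right), o$middle)
  }
})

test_that("P assignment equals brute-force palindromic extension and respects resection", {
  set.seed(202)
  for (i in 1:150) {
    lf <- random_dna(10)
    rf <- random_dna(10, c("G", "T"))  # right flank cannot absorb the middle
    middle <- random_dna(sample(1:6, 1), c("A", "C"))
    locus <- toy_coding_locus(lf, rf)
    a <- annotate_coding_joint(paste0(lf, middle, rf), locus)
    if (a$del_left != 0L || a$microhomology_len != 0L) next
    expect_identical(nchar(a$p_left), oracle_p_left(middle, lf, 4L))
  }
  # P is never called on a resected end
  locus <- toy_coding_locus("TACTTC", "GGGGGG")
  a <- annotate_coding_joint("TACTGAGGGGGG", locus)  # del_left = 2
  expect_identical(a$del_left, 2L)
  expect_identical(a$p_left, "")
  expect_identical(a$n_insertion, "GA")
})

test_that("signal joints are classified precise/imprecise with the ApaL1 check", {
  locus <- toy_signal_locus()
  refs <- vdjoin:::joint_refs(locus)
  precise <- paste0(refs$left, refs$right)
  a <- annotate_signal_joint(precise, locus)
  expect_true(a$precise)
  expect_true(a$apal1_site_present)
  # 3 nt removed from one heptamer
  a <- annotate_signal_joint(
    paste0(substr(refs$left, 1, nchar(refs$left) - 3), refs$right), locus)
  expect_false(a$precise)
  expect_identical(a$del_left_rss, 3L)
  expect_false(a$apal1_site_present)
  # intact heptamers separated by an inserted CC
  a <- annotate_signal_joint(paste0(refs$left, "CC", refs$right), locus)
  expect_false(a$precise)
  expect_identical(a$insertion, "CC")
  expect_false(a$apal1_site_present)
})

test_that("miscleavage is called when inserted bases carry coding flank onto a signal end", {
  locus <- toy_signal_locus()
  refs <- vdjoin:::joint_refs(locus)
  lf <- locus$left_segment$coding_flank
  rf <- locus$right_segment$coding_flank
  # left side of the joint is inverted: carried coding bases read as the
  # reverse complement of the flank's RSS-proximal bases
  carried_l <- revcomp(substr(lf, nchar(lf) - 1, nchar(lf)))
  a <- annotate_signal_joint(paste0(refs$left, carried_l, refs$right), locus)
  expect_true(a$miscleavage)
  expect_identical(a$miscleavage_seq, carried_l)
  # right side carries flank bases in direct orientation
  carried_r <- substr(rf, nchar(rf) - 2, nchar(rf))
  a <- annotate_signal_joint(paste0(refs$left, carried_r, refs$right), locus)
  expect_true(a$miscleavage)
  # insertion matching neither flank is not miscleavage
  probe <- "AAAA"
  stopifnot(revcomp(substr(lf, nchar(lf) - 3, nchar(lf))) != probe,
            substr(rf, nchar(rf) - 3, nchar(rf)) != probe)
  a <- annotate_signal_joint(paste0(refs$left, probe, refs$right), locus)
  expect_false(a$miscleavage)
  # empty insertion: nothing to flag
  a <- annotate_signal_joint(paste0(refs$left, refs$right), locus)
  expect_false(a$miscleavage)
})

test_that("frame classification follows net length change mod 3", {
  locus <- toy_coding_locus("TACTTC", "GGAACA", frame_left = 0L,
                            frame_right = 1L)
  expect_identical(annotate_coding_joint("TACTTCGGAACA", locus)$in_frame,
                   "in")                               # net 0
  expect_identical(annotate_coding_joint("TACTTCCGGGAACA", locus)$in_frame,
                   "out")                              # net +2
  expect_identical(annotate_coding_joint("TACGGAACA", locus)$in_frame,
                   "in")                               # net -3
  no_anchor <- toy_coding_locus("TACTTC", "GGAACA")
  expect_identical(annotate_coding_joint("TACTTCGGAACA", no_anchor)$in_frame,
                   "unknown")
})

test_that("reconstruction reproduces the observed window for every annotation", {
  set.seed(303)
  cl <- demo_coding_locus()
  sl <- demo_signal_locus()
  params <- simulation_params(p_microhomology_join = 0.15,
                              p_adr_mechanism = 0.15,
                              sj_imprecision_prob = 0.5)
  for (i in 1:300) {
    sim <- simulate_coding_joint(cl, params, paste0("c", i))
    a <- annotate_coding_joint(sim$read$sequence, cl)
    expect_identical(reconstruct_junction(a, cl), sim$read$sequence)
    sim <- simulate_signal_joint(sl, params, paste0("s", i))
    a <- annotate_signal_joint(sim$read$sequence, sl)
    expect_identical(reconstruct_junction(a, sl), sim$read$sequence)
  }
})

test_that("annotation recovers simulator truth under unambiguous regimes", {
  set.seed(404)
  # deletions only, left/right flanks on disjoint alphabets
  params_del <- simulation_params(p_deletion_per_end = 0.9,
                                  deletion_mean = 4, n_mean = 0,
                                  p_p_nucleotides = 0)
  locus <- disjoint_alphabet_locus()
  for (i in 1:200) {
    sim <- simulate_coding_joint(locus, params_del, paste0("d", i))
    a <- annotate_coding_joint(sim$read$sequence, locus)
    expect_identical(a$del_left, sim$truth$del_left)
    expect_identical(a$del_right, sim$truth$del_right)
    expect_identical(a$n_insertion, "")
  }
  # insertions only: flank ends chosen so no N base can read as P
  locus2 <- pproof_insertion_locus()
  params_ins <- simulation_params(p_deletion_per_end = 0,
                                  p_p_nucleotides = 0, n_mean = 3,
                                  n_base_composition = pproof_n_composition)
  for (i in 1:200) {
    sim <- simulate_coding_joint(locus2, params_ins, paste0("i", i))
    a <- annotate_coding_joint(sim$read$sequence, locus2)
    expect_identical(a$n_insertion, sim$truth$n_insertion)
    expect_identical(c(a$del_left, a$del_right), c(0L, 0L))
  }
})

test_that("the junction pretty-printer shows germline, deletions and insertions", {
  locus <- toy_coding_locus("TACTTC", "GGAACA")
  txt <- format_junction(annotate_coding_joint("TACTGAGGAACA", locus), locus)
  expect_match(txt, "germline: TACTTC / GGAACA", fixed = TRUE)
  expect_match(txt, "(-2)", fixed = TRUE)   # left deletion
  expect_match(txt, "GA")                   # N bases uppercase
  sl <- toy_signal_locus()
  refs <- vdjoin:::joint_refs(sl)
  txt <- format_junction(
    annotate_signal_joint(paste0(refs$left, refs$right), sl), sl)
  expect_match(txt, "precise")
})

test_that("annotate_junctions routes reads by joint kind", {
  set.seed(7)
  loci <- list(demoCJ = demo_coding_locus(), demoSJ = demo_signal_locus())
  sim <- simulate_cohort(loci["demoCJ"],
                         list(WT = simulation_params(seed = 7, n_junctions = 5)))
  refs <- vdjoin:::joint_refs(loci$demoSJ)
  reads <- rbind(sim$reads,
                 data.frame(read_id = "sj1",
                            sequence = paste0(refs$left, refs$right),
                            locus = "demoSJ", genotype = "WT",
                            stringsAsFactors = FALSE))
  ann <- annotate_junctions(reads, loci)
  expect_identical(nrow(ann), 6L)
  expect_identical(ann$joint_kind, c(rep("coding", 5), "signal"))
  expect_true(ann$precise[6])
  expect_true(all(is.na(ann$precise[1:5])))
  expect_error(annotate_junctions(
    data.frame(read_id = "x", sequence = "ACGT", locus = "nope"), loci),
    "unknown locus")
})
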