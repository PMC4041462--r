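#' Simulation parameters for junction cohorts
#'
#' Defines one end-joining regime.  Defaults describe a wild-type-like
#' classical-NHEJ regime loosely calibrated to the bundled reference cohort
#' marginals: most coding ends resected with short (mean 4 nt) geometric
#' deletions, occasional P nucleotides on unresected ends, short
#' TdT-like GC-biased N additions, about one signal joint in four imprecise
#' with rare RSS deletions.  See the methods vignette for the rationale
#' behind each default.
#'
#' @param seed Integer seed; together with the parameters it fully
#'   determines the simulated cohort.
#' @param n_junctions Junctions per locus.
#' @param joint_kind `"coding"` or `"signal"`.
#' @param p_deletion_per_end Probability a coding end is resected.
#' @param deletion_mean Mean deletion length (nt) among deleted ends
#'   (1 + geometric).
#' @param p_p_nucleotides Probability an unresected coding end acquires P
#'   nucleotides.
#' @param max_p_length Maximum simulated P length (uniform 1..max).
#' @param n_mean Mean N-insertion length (geometric on 0, 1, 2, ...).
#' @param n_base_composition Named probabilities over `A,C,G,T` for N bases.
#' @param p_microhomology_join Probability a coding joint is forced through
#'   an existing sequence overlap (microhomology-mediated join).
#' @param mh_min,mh_max Microhomology length range searched for such joins.
#' @param p_adr_mechanism Probability a coding joint forms through
#'   annealing of a complementary 3' extension followed by
#'   strand-displacement fill-in, leaving an adjacent direct repeat with one
#'   inserted copy.
#' @param adr_k_range Repeat lengths the ADR mechanism produces (3-5 nt).
#' @param sj_imprecision_prob Probability a signal joint is imprecise.
#' @param sj_p_deletion_per_end Probability an imprecise signal end carries
#'   an RSS deletion.
#' @param p_miscleavage Probability an undeleted imprecise signal end
#'   carries miscleaved coding bases.
#' @param miscleavage_mean Mean miscleavage slip length (1 + geometric).
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(seed = 1L, n_junctions = 100L,
                              joint_kind = c("coding", "signal"),
                              p_deletion_per_end = 0.8,
                              deletion_mean = 4,
                              p_p_nucleotides = 0.25,
                              max_p_length = 2L,
                              n_mean = 3,
                              n_base_composition = c(A = 0.2, C = 0.3,
                                                     G = 0.3, T = 0.2),
                              p_microhomology_join = 0,
                              mh_min = 2L, mh_max = 5L,
                              p_adr_mechanism = 0,
                              adr_k_range = 3:5,
                              sj_imprecision_prob = 0.25,
                              sj_p_deletion_per_end = 0.1,
                              p_miscleavage = 0.15,
                              miscleavage_mean = 2) {
  joint_kind <- match.arg(joint_kind)
  probs <- c(p_deletion_per_end, p_p_nucleotides, p_microhomology_join,
             p_adr_mechanism, sj_imprecision_prob, sj_p_deletion_per_end,
             p_miscleavage)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (abs(sum(n_base_composition) - 1) > 1e-9 || any(n_base_composition < 0))
    stop("n_base_composition must be nonnegative and sum to 1")
  if (!setequal(names(n_base_composition), c("A", "C", "G", "T")))
    stop("n_base_composition must be named over A, C, G, T")
  structure(list(
    seed = as.integer(seed), n_junctions = as.integer(n_junctions),
    joint_kind = joint_kind,
    p_deletion_per_end = p_deletion_per_end, deletion_mean = deletion_mean,
    p_p_nucleotides = p_p_nucleotides, max_p_length = as.integer(max_p_length),
    n_mean = n_mean, n_base_composition = n_base_composition[c("A","C","G","T")],
    p_microhomology_join = p_microhomology_join,
    mh_min = as.integer(mh_min), mh_max = as.integer(mh_max),
    p_adr_mechanism = p_adr_mechanism, adr_k_range = adr_k_range,
    sj_imprecision_prob = sj_imprecision_prob,
    sj_p_deletion_per_end = sj_p_deletion_per_end,
    p_miscleavage = p_miscleavage, miscleavage_mean = miscleavage_mean),
    class = "simulation_params")
}

empty_truth <- function(read_id) {
  list(read_id = read_id, del_left = 0L, del_right = 0L,
       p_left = "", p_right = "", n_insertion = "",
       microhomology_len = 0L, adr = NA_character_,
       miscleavage = FALSE, precise = NA, mh_fallback = FALSE)
}

truth_df <- function(truths) {
  do.call(rbind, lapply(truths, function(t)
    data.frame(t, stringsAsFactors = FALSE)))
}

# search deletion combinations (0..max_scan per end) for an existing
# suffix/prefix overlap of length mh_min..mh_max; NULL when none exists
find_mh_join <- function(lf, rf, mh_min, mh_max, max_scan = 6L) {
  hits <- list()
  for (dl in 0:min(max_scan, nchar(lf) - 1L)) {
    tl <- substr(lf, 1L, nchar(lf) - dl)
    for (dr in 0:min(max_scan, nchar(rf) - 1L)) {
      tr <- substr(rf, dr + 1L, nchar(rf))
      for (m in min(mh_max, nchar(tl), nchar(tr)):mh_min) {
        if (m < mh_min) break
        if (substr(tl, nchar(tl) - m + 1L, nchar(tl)) == substr(tr, 1L, m)) {
          hits[[length(hits) + 1L]] <- list(dl = dl, dr = dr, m = m)
          break
        }
      }
    }
  }
  if (!length(hits)) return(NULL)
  hits[[sample.int(length(hits), 1L)]]
}

#' Simulate one coding joint
#'
#' Draws per-end resection (or optional P-nucleotide palindromes from the
#' unopened hairpin), N addition, and optionally a microhomology-mediated
#' join or the adjacent-direct-repeat mechanism (a 3-5 nt complementary
#' extension annealed to the partner end and filled by strand displacement,
#' duplicating the terminal k-mer with one inserted copy).  Consumes the
#' ambient RNG stream; seed via [simulate_cohort()] or `set.seed()`.
#'
#' @param locus A coding [locus_reference()].
#' @param params A [simulation_params()].
#' @param read_id Identifier for the emitted read.
#' @return List with `read` (data frame row: read_id, sequence, locus,
#'   genotype placeholder) and `truth` (ground-truth list).
#' @export
simulate_coding_joint <- function(locus, params, read_id = "sim") {
  stopifnot(locus$joint_kind == "coding")
  refs <- joint_refs(locus)
  lf <- refs$left
  rf <- refs$right
  truth <- empty_truth(read_id)

  if (stats::runif(1) < params$p_adr_mechanism) {
    # complementary-extension + strand-displacement fill-in: duplicate the
    # terminal k-mer of one (possibly resected) end as inserted sequence
    dl <- if (stats::runif(1) < params$p_deletion_per_end)
      rlen_geom1(1, params$deletion_mean, nchar(lf) - 1L) else 0L
    dr <- if (stats::runif(1) < params$p_deletion_per_end)
      rlen_geom1(1, params$deletion_mean, nchar(rf) - 1L) else 0L
    tl <- substr(lf, 1L, nchar(lf) - dl)
    tr <- substr(rf, dr + 1L, nchar(rf))
    k <- sample(params$adr_k_range, 1L)
    k <- min(k, nchar(tl), nchar(tr))
    dup <- if (stats::runif(1) < 0.5)
      substr(tl, nchar(tl) - k + 1L, nchar(tl))
    else substr(tr, 1L, k)
    truth$del_left <- dl
    truth$del_right <- dr
    truth$n_insertion <- dup
    truth$adr <- dup
    seqn <- paste0(tl, dup, tr)
    return(list(read = data.frame(read_id = read_id, sequence = seqn,
                                  locus = locus$locus_name,
                                  stringsAsFactors = FALSE),
                truth = truth))
  }

  if (stats::runif(1) < params$p_microhomology_join) {
    hit <- find_mh_join(lf, rf, params$mh_min, params$mh_max)
    if (!is.null(hit)) {
      tl <- substr(lf, 1L, nchar(lf) - hit$dl)
      tr <- substr(rf, hit$dr + 1L, nchar(rf))
      truth$del_left <- hit$dl
      truth$del_right <- hit$dr
      truth$microhomology_len <- hit$m
      seqn <- paste0(tl, substr(tr, hit$m + 1L, nchar(tr)))
      return(list(read = data.frame(read_id = read_id, sequence = seqn,
                                    locus = locus$locus_name,
                                    stringsAsFactors = FALSE),
                  truth = truth))
    }
    truth$mh_fallback <- TRUE  # no overlap available: plain join, flagged
  }

  dl <- if (stats::runif(1) < params$p_deletion_per_end)
    rlen_geom1(1, params$deletion_mean, nchar(lf) - 1L) else 0L
  dr <- if (stats::runif(1) < params$p_deletion_per_end)
    rlen_geom1(1, params$deletion_mean, nchar(rf) - 1L) else 0L
  p_left <- p_right <- ""
  if (dl == 0L && stats::runif(1) < params$p_p_nucleotides) {
    j <- sample.int(params$max_p_length, 1L)
    p_left <- revcomp(substr(lf, nchar(lf) - j + 1L, nchar(lf)))
  }
  if (dr == 0L && stats::runif(1) < params$p_p_nucleotides) {
    j <- sample.int(params$max_p_length, 1L)
    p_right <- revcomp(substr(rf, 1L, j))
  }
  nbases <- sample_bases(rlen_geom0(1, params$n_mean),
                         params$n_base_composition)
  truth$del_left <- dl
  truth$del_right <- dr
  truth$p_left <- p_left
  truth$p_right <- p_right
  truth$n_insertion <- nbases
  seqn <- paste0(substr(lf, 1L, nchar(lf) - dl), p_left, nbases, p_right,
                 substr(rf, dr + 1L, nchar(rf)))
  list(read = data.frame(read_id = read_id, sequence = seqn,
                         locus = locus$locus_name, stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate one signal joint
#'
#' With probability `1 - sj_imprecision_prob` emits the precise
#' heptamer-to-heptamer fusion; otherwise samples RSS deletions,
#' miscleavage (coding-flank bases carried onto an undeleted end, in the
#' orientation the joint geometry dictates) and N insertion.  An imprecise
#' draw that samples no alteration receives a single N base.
#'
#' @inheritParams simulate_coding_joint
#' @param locus A signal [locus_reference()].
#' @return As [simulate_coding_joint()]; the truth record's `precise` field
#'   is set.
#' @export
simulate_signal_joint <- function(locus, params, read_id = "sim") {
  stopifnot(locus$joint_kind == "signal")
  refs <- joint_refs(locus)
  truth <- empty_truth(read_id)
  if (stats::runif(1) >= params$sj_imprecision_prob) {
    truth$precise <- TRUE
    seqn <- paste0(refs$left, refs$right)
    return(list(read = data.frame(read_id = read_id, sequence = seqn,
                                  locus = locus$locus_name,
                                  stringsAsFactors = FALSE),
                truth = truth))
  }
  truth$precise <- FALSE
  dl <- if (stats::runif(1) < params$sj_p_deletion_per_end)
    rlen_geom1(1, params$deletion_mean, nchar(refs$left) - 1L) else 0L
  dr <- if (stats::runif(1) < params$sj_p_deletion_per_end)
    rlen_geom1(1, params$deletion_mean, nchar(refs$right) - 1L) else 0L
  misc_l <- misc_r <- ""
  lf <- locus$left_segment$coding_flank
  rf <- locus$right_segment$coding_flank
  if (dl == 0L && stats::runif(1) < params$p_miscleavage) {
    j <- rlen_geom1(1, params$miscleavage_mean, nchar(lf))
    misc_l <- revcomp(substr(lf, nchar(lf) - j + 1L, nchar(lf)))
  }
  if (dr == 0L && stats::runif(1) < params$p_miscleavage) {
    j <- rlen_geom1(1, params$miscleavage_mean, nchar(rf))
    misc_r <- substr(rf, nchar(rf) - j + 1L, nchar(rf))
  }
  nbases <- sample_bases(rlen_geom0(1, params$n_mean),
                         params$n_base_composition)
  if (dl == 0L && dr == 0L && !nzchar(misc_l) && !nzchar(misc_r) &&
      !nzchar(nbases))
    nbases <- sample_bases(1L, params$n_base_composition)
  truth$del_left <- dl
  truth$del_right <- dr
  truth$n_insertion <- nbases
  truth$miscleavage <- nzchar(misc_l) || nzchar(misc_r)
  seqn <- paste0(substr(refs$left, 1L, nchar(refs$left) - dl),
                 misc_l, nbases, misc_r,
                 substr(refs$right, dr + 1L, nchar(refs$right)))
  list(read = data.frame(read_id = read_id, sequence = seqn,
                         locus = locus$locus_name, stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate a multi-locus, multi-genotype junction cohort
#'
#' For each genotype, seeds the RNG from its parameter set and draws
#' `n_junctions` reads per locus.  Identical `(loci, params, dir)` inputs
#' produce byte-identical outputs.
#'
#' @param loci Named list of [locus_reference()] objects.
#' @param params_by_genotype Named list of [simulation_params()], one per
#'   genotype label.
#' @param dir Optional output directory; when given, writes `reads.fasta`,
#'   `truth.tsv`, `metadata.tsv` and `params.json` there.
#' @return Invisibly, a list with `reads` (data frame: read_id, sequence,
#'   locus, genotype), `truth` (data frame of truth records) and `files`
#'   (output paths, or `NULL`).
#' @export
simulate_cohort <- function(loci, params_by_genotype, dir = NULL) {
  if (inherits(loci, "locus_reference"))
    loci <- setNames(list(loci), loci$locus_name)
  all_reads <- list()
  all_truth <- list()
  for (genotype in names(params_by_genotype)) {
    params <- params_by_genotype[[genotype]]
    set.seed(params$seed)
    for (locus in loci) {
      n <- params$n_junctions
      if (n < 1L) next
      for (i in seq_len(n)) {
        id <- sprintf("%s_%s_%05d", genotype, locus$locus_name, i)
        sim <- if (params$joint_kind == "coding")
          simulate_coding_joint(locus, params, id)
        else simulate_signal_joint(locus, params, id)
        sim$read$genotype <- genotype
        all_reads[[length(all_reads) + 1L]] <- sim$read
        all_truth[[length(all_truth) + 1L]] <- sim$truth
      }
    }
  }
  reads <- if (length(all_reads)) do.call(rbind, all_reads)
  else data.frame(read_id = character(0), sequence = character(0),
                  locus = character(0), genotype = character(0),
                  stringsAsFactors = FALSE)
  truth <- if (length(all_truth)) truth_df(all_truth)
  else data.frame(read_id = character(0), stringsAsFactors = FALSE)
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(fasta = file.path(dir, "reads.fasta"),
                  truth = file.path(dir, "truth.tsv"),
                  metadata = file.path(dir, "metadata.tsv"),
                  params = file.path(dir, "params.json"))
    seqs <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
    Biostrings::writeXStringSet(seqs, files$fasta)
    utils::write.table(truth, files$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(reads[c("read_id", "locus", "genotype")],
                       files$metadata, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(lapply(params_by_genotype, unclass), files$params,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(reads = reads, truth = truth, files = files))
}

#' Built-in cohort presets
#'
#' `"table1_like"` returns a two-genotype signal-joint regime pair for the
#' bundled demonstration pipeline: a `WT`-like regime (low imprecision,
#' short rare deletions) and an `FS`-like regime (high imprecision, longer
#' and more frequent deletions, occasional microhomology-scale insertions),
#' chosen so the two genotypes differ detectably in imprecise fraction at
#' moderate cohort sizes.
#'
#' @param name Preset name (currently only `"table1_like"`).
#' @param n_junctions Junctions per locus and genotype.
#' @param seed Base seed; the second genotype uses `seed + 1`.
#' @return Named list of [simulation_params()].
#' @export
cohort_preset <- function(name = "table1_like", n_junctions = 150L,
                          seed = 1L) {
  name <- match.arg(name)
  list(
    WT = simulation_params(seed = seed, n_junctions = n_junctions,
                           joint_kind = "signal",
                           sj_imprecision_prob = 0.21,
                           sj_p_deletion_per_end = 0.1,
                           deletion_mean = 2, n_mean = 2,
                           p_miscleavage = 0.03),
    FS = simulation_params(seed = seed + 1L, n_junctions = n_junctions,
                           joint_kind = "signal",
                           sj_imprecision_prob = 0.45,
                           sj_p_deletion_per_end = 0.3,
                           deletion_mean = 6, n_mean = 3,
                           p_miscleavage = 0.12))
}
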