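#' Cohort summary configuration
#'
#' @param sj_deletion_cutoff Signal-joint deletion cutoff (nt): the
#'   summaries report the fraction of deleted ends exceeding it.  Default 5
#'   (the longest deletion observed in the wild-type reference cohort).
#' @param cj_deletion_cutoff Coding-joint deletion cutoff (nt): fraction of
#'   deleted events exceeding it.  Default 4 (the average deleted length in
#'   wild-type junctions).
#' @param microhomology_min Minimum microhomology length (nt) counted in the
#'   summaries.  Default 2.
#' @return An object of class `summary_config`.
#' @export
summary_config <- function(sj_deletion_cutoff = 5L, cj_deletion_cutoff = 4L,
                           microhomology_min = 2L) {
  vals <- c(sj_deletion_cutoff, cj_deletion_cutoff, microhomology_min)
  if (any(vals < 1L)) stop("all summary_config fields must be >= 1")
  structure(list(sj_deletion_cutoff = as.integer(sj_deletion_cutoff),
                 cj_deletion_cutoff = as.integer(cj_deletion_cutoff),
                 microhomology_min = as.integer(microhomology_min)),
            class = "summary_config")
}

pct1 <- function(num, den) ifelse(den > 0, round(100 * num / den, 1), NA_real_)

sj_count_row <- function(df, config) {
  imp <- df[!df$precise, , drop = FALSE]
  dl <- imp$del_left
  dr <- imp$del_right
  data.frame(
    n_total = nrow(df),
    n_precise = sum(df$precise),
    n_imprecise = nrow(imp),
    n_with_N = sum(nzchar(imp$n_insertion)),
    n_with_deletion = sum(dl > 0 | dr > 0),
    n_deleted_ends = sum(dl > 0) + sum(dr > 0),
    n_deleted_ends_gt_cutoff = sum(dl > config$sj_deletion_cutoff) +
      sum(dr > config$sj_deletion_cutoff),
    n_miscleavage = sum(imp$miscleavage),
    n_microhomology = sum(imp$microhomology_len >= config$microhomology_min),
    stringsAsFactors = FALSE)
}

sj_add_pcts <- function(s) {
  s$pct_imprecise <- pct1(s$n_imprecise, s$n_total)
  s$pct_n_of_imprecise <- pct1(s$n_with_N, s$n_imprecise)
  s$pct_n_of_total <- pct1(s$n_with_N, s$n_total)
  s$pct_deletion_of_imprecise <- pct1(s$n_with_deletion, s$n_imprecise)
  s$pct_deleted_ends_gt_cutoff <- pct1(s$n_deleted_ends_gt_cutoff,
                                       s$n_deleted_ends)
  s$pct_miscleavage_of_imprecise <- pct1(s$n_miscleavage, s$n_imprecise)
  s$pct_microhomology_of_imprecise <- pct1(s$n_microhomology, s$n_imprecise)
  s
}

#' Summarize signal-joint annotations per locus and genotype
#'
#' Produces one row per (locus, genotype) group plus one pooled row per
#' genotype (locus label `"pooled"`), with denominators as the reference
#' cohort prescribes: N addition, deletion, miscleavage and microhomology
#' frequencies are out of imprecise junctions; the over-cutoff deletion
#' fraction is out of deleted ENDS (two ends per junction); N prevalence is
#' additionally reported out of all junctions.  Pooled rows sum counts
#' across loci before computing percentages.  Percentages are rounded to
#' one decimal; empty denominators give `NA`.
#'
#' @param annotations Signal-joint annotation data frame (from
#'   [annotate_junctions()]); the signal insertion is read from the
#'   `n_insertion` column.
#' @param config A [summary_config()].
#' @return Data frame with columns `locus, genotype`, the count columns
#'   `n_total, n_precise, n_imprecise, n_with_N, n_with_deletion,
#'   n_deleted_ends, n_deleted_ends_gt_cutoff, n_miscleavage,
#'   n_microhomology` and the derived `pct_*` columns.
#' @export
summarize_signal_joints <- function(annotations, config = summary_config()) {
  if (any(annotations$joint_kind != "signal"))
    stop("summarize_signal_joints: annotations contain non-signal joints")
  if (!"genotype" %in% names(annotations))
    annotations$genotype <- NA_character_
  if (!nrow(annotations)) {
    skel <- cbind(data.frame(locus = character(0), genotype = character(0),
                             stringsAsFactors = FALSE),
                  sj_count_row(annotations, config)[0, , drop = FALSE])
    return(sj_add_pcts(skel))
  }
  key <- interaction(annotations$locus, annotations$genotype, drop = TRUE,
                     lex.order = TRUE)
  per <- do.call(rbind, lapply(split(annotations, key), function(grp) {
    cbind(data.frame(locus = grp$locus[1], genotype = grp$genotype[1],
                     stringsAsFactors = FALSE),
          sj_count_row(grp, config))
  }))
  count_cols <- setdiff(names(per), c("locus", "genotype"))
  pooled <- do.call(rbind, lapply(split(per, per$genotype), function(grp) {
    cbind(data.frame(locus = "pooled", genotype = grp$genotype[1],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(colSums(grp[count_cols]))))
  }))
  out <- sj_add_pcts(rbind(per, pooled))
  rownames(out) <- NULL
  out
}

#' Summarize coding-joint annotations per locus and genotype
#'
#' Per group and per region (V side = `del_left`, J side = `del_right`):
#' the fraction of junctions with any deletion (denominator: all events),
#' the mean deletion length among deleted events, and the fraction of
#' deleted events exceeding the cutoff (both out of deleted events only).
#' Fractions are in `[0, 1]`; means are `NA` when no event is deleted.
#'
#' @param annotations Coding-joint annotation data frame.
#' @param config A [summary_config()].
#' @return Data frame with columns `locus, genotype, n_total,
#'   v_frac_deleted, v_mean_deletion, v_frac_gt_cutoff, j_frac_deleted,
#'   j_mean_deletion, j_frac_gt_cutoff`.
#' @export
summarize_coding_joints <- function(annotations, config = summary_config()) {
  if (any(annotations$joint_kind != "coding"))
    stop("summarize_coding_joints: annotations contain non-coding joints")
  if (!"genotype" %in% names(annotations))
    annotations$genotype <- NA_character_
  side_stats <- function(del) {
    deleted <- del[del > 0]
    c(frac_deleted = if (length(del)) length(deleted) / length(del) else NA,
      mean_deletion = if (length(deleted)) mean(deleted) else NA_real_,
      frac_gt_cutoff = if (length(deleted))
        mean(deleted > config$cj_deletion_cutoff) else NA_real_)
  }
  key <- interaction(annotations$locus, annotations$genotype, drop = TRUE,
                     lex.order = TRUE)
  out <- do.call(rbind, lapply(split(annotations, key), function(grp) {
    v <- side_stats(grp$del_left)
    j <- side_stats(grp$del_right)
    data.frame(locus = grp$locus[1], genotype = grp$genotype[1],
               n_total = nrow(grp),
               v_frac_deleted = v[["frac_deleted"]],
               v_mean_deletion = v[["mean_deletion"]],
               v_frac_gt_cutoff = v[["frac_gt_cutoff"]],
               j_frac_deleted = j[["frac_deleted"]],
               j_mean_deletion = j[["mean_deletion"]],
               j_frac_gt_cutoff = j[["frac_gt_cutoff"]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Chi-squared test of independence
#'
#' Pearson chi-squared on an r x c contingency table, without continuity
#' correction (on 2x2 tables the statistic equals the closed form
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`).
#'
#' @param table Matrix (or object coercible to one) of nonnegative counts,
#'   at least 2x2, with no zero row or column margin.
#' @return List with `statistic`, `df`, `p_value` and the `expected` counts.
#' @export
chi_squared_independence <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("contingency table contains negative counts")
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingency table must be at least 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-squared test undefined: zero row or column margin")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected)
}

#' Two-tailed unpaired t-test
#'
#' Classic pooled-variance Student's t-test, two-sided; Welch's unequal
#' variance form is available behind `welch = TRUE`.  Two groups with zero
#' variance and equal means return `t = 0, p = 1`; zero variance with
#' unequal means is flagged as degenerate.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param welch Use the Welch approximation instead of pooled variance.
#' @return List with `t`, `df`, `p_value`.
#' @export
two_tailed_unpaired_t_test <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 observations")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (isTRUE(all.equal(mean(group_a), mean(group_b))))
      return(list(t = 0, df = length(group_a) + length(group_b) - 2,
                  p_value = 1))
    stop("degenerate input: zero variance in both groups with unequal means")
  }
  res <- stats::t.test(group_a, group_b, var.equal = !welch)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' Bundled TCRbeta signal-joint count table
#'
#' Per-locus signal-joint counts for wild-type mice and mice homozygous for
#' a C-terminal RAG2 frameshift truncation (genotype labels `"WT"` and
#' `"FS"`), at four TCRbeta/TCRdelta rearrangements, combined over two to
#' three animals per genotype.  Columns follow the conventions of
#' [summarize_signal_joints()]: N addition, deletion, miscleavage and
#' microhomology counts are out of imprecise junctions and
#' `n_deleted_ends_gt_cutoff` is out of deleted ends (cutoff 5 nt).  Where
#' the source tabulation omits the deleted-end count it is stored as the
#' minimum consistent value (one end per deleted junction).
#'
#' @return Data frame with columns `locus, genotype, n_total, n_imprecise,
#'   n_with_N, n_with_deletion, n_deleted_ends, n_deleted_ends_gt_cutoff,
#'   n_miscleavage, n_microhomology`.
#' @export
tcrb_sj_cohort <- function() {
  loci <- c("Vb14-Db1", "Vd5-Dd2", "Vb8.3-Db1.1", "Vb10-Db1.1")
  rbind(
    data.frame(locus = loci, genotype = "WT",
               n_total = c(79L, 28L, 27L, 25L),
               n_imprecise = c(11L, 9L, 8L, 6L),
               n_with_N = c(10L, 9L, 8L, 6L),
               n_with_deletion = c(0L, 3L, 3L, 0L),
               n_deleted_ends = c(0L, 3L, 3L, 0L),
               n_deleted_ends_gt_cutoff = c(0L, 0L, 0L, 0L),
               n_miscleavage = c(1L, 0L, 0L, 0L),
               n_microhomology = c(0L, 0L, 0L, 0L),
               stringsAsFactors = FALSE),
    data.frame(locus = loci, genotype = "FS",
               n_total = c(70L, 26L, 28L, 16L),
               n_imprecise = c(23L, 20L, 13L, 7L),
               n_with_N = c(16L, 14L, 13L, 6L),
               n_with_deletion = c(9L, 17L, 4L, 2L),
               n_deleted_ends = c(14L, 30L, 4L, 2L),
               n_deleted_ends_gt_cutoff = c(10L, 16L, 4L, 0L),
               n_miscleavage = c(3L, 4L, 5L, 2L),
               n_microhomology = c(2L, 2L, 0L, 1L),
               stringsAsFactors = FALSE))
}

#' Expand a signal-joint count table into per-junction annotation rows
#'
#' Reconstructs a minimal per-junction annotation data frame whose
#' [summarize_signal_joints()] counts reproduce the given count table
#' exactly; deleted junctions are assigned ends and lengths consistent with
#' the end counts (ends flagged over the cutoff get length `cutoff + 1`,
#' the rest length 1).  Useful for feeding published-style count summaries
#' through the summary and statistics machinery.
#'
#' @param counts Data frame as returned by [tcrb_sj_cohort()].
#' @param config A [summary_config()] supplying the deletion cutoff.
#' @return A signal-joint annotation data frame.
#' @export
sj_counts_to_annotations <- function(counts, config = summary_config()) {
  cutoff <- config$sj_deletion_cutoff
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    n <- r$n_total
    ni <- r$n_imprecise
    stopifnot(ni <= n, r$n_with_N <= ni, r$n_with_deletion <= ni,
              r$n_miscleavage <= r$n_with_N,
              r$n_with_N + r$n_microhomology <= ni)
    precise <- c(rep(FALSE, ni), rep(TRUE, n - ni))
    insertion <- rep("", n)
    if (r$n_with_N > 0) insertion[seq_len(r$n_with_N)] <- "A"
    miscleavage <- rep(FALSE, n)
    if (r$n_miscleavage > 0) miscleavage[seq_len(r$n_miscleavage)] <- TRUE
    mh <- rep(0L, n)
    if (r$n_microhomology > 0)
      mh[(ni - r$n_microhomology + 1L):ni] <- config$microhomology_min
    del_left <- del_right <- rep(0L, n)
    D <- r$n_with_deletion
    E <- r$n_deleted_ends
    G <- r$n_deleted_ends_gt_cutoff
    if (D > 0) {
      both <- E - D
      stopifnot(both >= 0, both <= D, G <= E)
      lens <- c(rep(cutoff + 1L, G), rep(1L, E - G))
      del_left[seq_len(D)] <- lens[seq_len(D)]
      if (both > 0)
        del_right[seq_len(both)] <- lens[(D + 1L):E]
    }
    data.frame(
      read_id = sprintf("%s_%s_%03d", r$genotype, r$locus, seq_len(n)),
      locus = r$locus, genotype = r$genotype, joint_kind = "signal",
      precise = precise, n_insertion = insertion,
      del_left = del_left, del_right = del_right,
      miscleavage = miscleavage, microhomology_len = mh,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
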