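# Thin file-to-file wrappers tying the modules into a pipeline.  These back
# the inst/cli/vdjoin.R command-line script; results go to files, messages to
# stderr, so outputs stay pipe-safe.

read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  for (col in c("p_left", "p_right", "n_insertion", "microhomology_seq",
                "miscleavage_seq"))
    if (col %in% names(df)) df[[col]][is.na(df[[col]])] <- ""
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotate a FASTA of junction reads against a locus reference file
#'
#' @param reads_fasta FASTA of junction sequences.
#' @param locus_file Locus reference TSV (see [load_locus_reference()]).
#' @param out_tsv Output annotation TSV path.
#' @param metadata_tsv Optional TSV with columns `read_id, locus` and
#'   optionally `genotype`, mapping reads to loci; without it all reads are
#'   assigned to the single locus in the reference file.
#' @param config An [annotation_config()].
#' @return The annotation data frame, invisibly.
#' @export
run_annotate <- function(reads_fasta, locus_file, out_tsv,
                         metadata_tsv = NULL,
                         config = annotation_config()) {
  loci <- load_locus_reference(locus_file)
  reads <- load_junction_reads(reads_fasta)
  if (!is.null(metadata_tsv)) {
    meta <- utils::read.delim(metadata_tsv, stringsAsFactors = FALSE)
    if (!all(c("read_id", "locus") %in% names(meta)))
      stop("metadata TSV needs read_id and locus columns")
    idx <- match(reads$read_id, meta$read_id)
    if (anyNA(idx))
      stop("metadata missing for read(s): ",
           paste(reads$read_id[is.na(idx)], collapse = ", "))
    reads$locus <- meta$locus[idx]
    if ("genotype" %in% names(meta)) reads$genotype <- meta$genotype[idx]
  } else {
    if (length(loci) != 1L)
      stop("multiple loci in reference but no metadata TSV mapping reads ",
           "to loci")
    reads$locus <- names(loci)
  }
  ann <- annotate_junctions(reads, loci, config)
  write_tsv(ann, out_tsv)
  invisible(ann)
}

#' Summarize an annotation TSV into cohort tables and statistics
#'
#' Writes `<out_prefix>_sj_summary.tsv` and/or `<out_prefix>_cj_summary.tsv`
#' according to the joint kinds present, plus `<out_prefix>_stats.tsv` with
#' a pooled imprecise/precise chi-squared comparison for every genotype
#' pair (signal joints, two or more genotypes).
#'
#' @param annotation_tsv Path to a TSV written by [run_annotate()].
#' @param out_prefix Output path prefix.
#' @param config A [summary_config()].
#' @return Invisibly, a list with `sj`, `cj` and `stats` data frames (those
#'   produced).
#' @export
run_summarize <- function(annotation_tsv, out_prefix,
                          config = summary_config()) {
  ann <- read_annotation_tsv(annotation_tsv)
  out <- list()
  if (any(ann$joint_kind == "signal")) {
    sj <- ann[ann$joint_kind == "signal", , drop = FALSE]
    out$sj <- summarize_signal_joints(sj, config)
    write_tsv(out$sj, paste0(out_prefix, "_sj_summary.tsv"))
    genotypes <- unique(sj$genotype)
    if (length(genotypes) >= 2L) {
      pooled <- out$sj[out$sj$locus == "pooled", ]
      combos <- utils::combn(genotypes, 2L, simplify = FALSE)
      stats_rows <- lapply(combos, function(gg) {
        a <- pooled[pooled$genotype == gg[1], ]
        b <- pooled[pooled$genotype == gg[2], ]
        tab <- rbind(c(a$n_imprecise, a$n_precise),
                     c(b$n_imprecise, b$n_precise))
        res <- chi_squared_independence(tab)
        data.frame(test = "chi_squared_independence",
                   comparison = paste(gg, collapse = "_vs_"),
                   quantity = "imprecise_vs_precise",
                   statistic = res$statistic, df = res$df,
                   p_value = res$p_value, stringsAsFactors = FALSE)
      })
      out$stats <- do.call(rbind, stats_rows)
      write_tsv(out$stats, paste0(out_prefix, "_stats.tsv"))
    } else {
      message("single genotype: no between-genotype statistics computed")
    }
  }
  if (any(ann$joint_kind == "coding")) {
    out$cj <- summarize_coding_joints(
      ann[ann$joint_kind == "coding", , drop = FALSE], config)
    write_tsv(out$cj, paste0(out_prefix, "_cj_summary.tsv"))
  }
  invisible(out)
}

#' Detect and score ADRs from an annotation TSV
#'
#' @param annotation_tsv Path to a TSV written by [run_annotate()].
#' @param out_tsv Output path for the scored ADR table.
#' @return The scored call data frame, invisibly.
#' @export
run_adr <- function(annotation_tsv, out_tsv) {
  ann <- read_annotation_tsv(annotation_tsv)
  calls <- adr_screen(ann)
  write_tsv(calls, out_tsv)
  invisible(calls)
}

#' Scan a FASTA for cryptic RSSs
#'
#' Writes a BED-like TSV of hits over every record.
#'
#' @param fasta Input FASTA.
#' @param out_bed Output BED-like TSV path.
#' @param config A [crss_config()].
#' @param consensus A [consensus_rss()].
#' @return The combined hit data frame, invisibly.
#' @export
run_crss_scan <- function(fasta, out_bed, config = crss_config(),
                          consensus = consensus_rss()) {
  seqs <- load_junction_reads(fasta)
  hits <- do.call(rbind, lapply(seq_len(nrow(seqs)), function(i)
    scan_sequence(seqs$sequence[i], consensus, config, seqs$read_id[i])))
  write_crss_bed(hits, out_bed)
  invisible(hits)
}

#' Simulate a demonstration cohort to disk
#'
#' @param out_dir Output directory (created if needed).
#' @param preset Preset name for [cohort_preset()].
#' @param n_junctions Junctions per locus and genotype.
#' @param seed Base seed.
#' @param loci Named list of loci; defaults to a bundled demonstration
#'   signal locus.
#' @return Invisibly, the [simulate_cohort()] result.
#' @export
run_simulate <- function(out_dir, preset = "table1_like", n_junctions = 150L,
                         seed = 1L, loci = NULL) {
  if (is.null(loci)) loci <- list(demo = demo_signal_locus())
  params <- cohort_preset(preset, n_junctions = n_junctions, seed = seed)
  simulate_cohort(loci, params, dir = out_dir)
}

#' Bundled demonstration loci
#'
#' Synthetic single-locus references (flanks are arbitrary fixed DNA, RSSs
#' are consensus) used by the simulator presets, examples and tests.
#'
#' @return A [locus_reference()].
#' @export
demo_signal_locus <- function() {
  locus_reference(
    "demoSJ",
    gene_segment_ref("demoV", "GATTACCAGTCAGGTCTGAC",
                     rss_spec("CACAGTG", "ACTGCTGCAGGA", "ACAAAAACC"),
                     side = "upstream"),
    gene_segment_ref("demoJ", "CCTGGTAACGATCAGTTCGA",
                     rss_spec("CACAGTG", "GGTTTTTGTACAGCCAGACAGTG", "ACAAAAACC"),
                     side = "downstream"),
    joint_kind = "signal")
}

#' @rdname demo_signal_locus
#' @export
demo_coding_locus <- function() {
  locus_reference(
    "demoCJ",
    gene_segment_ref("demoV", "GATTCGAGCAGTGGTACTTC",
                     rss_spec("CACAGTG", "GGTTTTTGTACAGCCAGACAGTG", "ACAAAAACC"),
                     side = "upstream", frame_anchor = 0L),
    gene_segment_ref("demoJ", "GGAACAGTCATTACCGGATC",
                     rss_spec("CACAGTG", "ACTGCTGCAGGA", "ACAAAAACC"),
                     side = "downstream", frame_anchor = 1L),
    joint_kind = "coding")
}
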