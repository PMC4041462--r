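#' Recombination signal sequence (RSS) specification
#'
#' An RSS consists of a conserved heptamer and nonamer separated by a spacer
#' of 12 or 23 nucleotides; the spacer length defines the site's class under
#' the 12/23 rule.
#'
#' @param heptamer 7-nt DNA string (heptamer reads away from the coding
#'   segment, starting at the cleavage site; canonically `CACAGTG`).
#' @param spacer 12- or 23-nt DNA string.
#' @param nonamer 9-nt DNA string.
#' @return An object of class `rss_spec` with fields `heptamer`, `spacer`,
#'   `nonamer` and `spacer_class` (12 or 23).
#' @examples
#' rss_spec("CACAGTG", strrep("A", 12), "ACAAAAACC")
#' @export
rss_spec <- function(heptamer, spacer, nonamer) {
  heptamer <- toupper(heptamer)
  spacer <- toupper(spacer)
  nonamer <- toupper(nonamer)
  if (nchar(heptamer) != 7L)
    stop("RSS heptamer must be 7 nt, got ", nchar(heptamer), " ('", heptamer, "')")
  if (nchar(nonamer) != 9L)
    stop("RSS nonamer must be 9 nt, got ", nchar(nonamer), " ('", nonamer, "')")
  if (!nchar(spacer) %in% c(12L, 23L))
    stop("RSS spacer must be 12 or 23 nt (12/23 rule), got ", nchar(spacer))
  for (s in c(heptamer, spacer, nonamer))
    if (!is_dna(s)) stop("non-DNA characters in RSS element '", s, "'")
  structure(
    list(heptamer = heptamer, spacer = spacer, nonamer = nonamer,
         spacer_class = nchar(spacer)),
    class = "rss_spec"
  )
}

#' Full RSS sequence
#'
#' Concatenates heptamer, spacer and nonamer (reading away from the coding
#' segment).
#'
#' @param rss An [rss_spec()] object.
#' @return A single DNA string of length 28 (12-RSS) or 39 (23-RSS).
#' @export
rss_seq <- function(rss) {
  stopifnot(inherits(rss, "rss_spec"))
  paste0(rss$heptamer, rss$spacer, rss$nonamer)
}

#' Consensus RSS used for cryptic-RSS match scoring
#'
#' The canonical mouse/human consensus heptamer and nonamer.  Spacer
#' positions carry no consensus and are never scored.
#'
#' @param heptamer,nonamer Override the canonical consensus strings.
#' @return An object of class `consensus_rss`.
#' @export
consensus_rss <- function(heptamer = "CACAGTG", nonamer = "ACAAAAACC") {
  heptamer <- toupper(heptamer)
  nonamer <- toupper(nonamer)
  stopifnot(nchar(heptamer) == 7L, nchar(nonamer) == 9L,
            is_dna(heptamer), is_dna(nonamer))
  structure(list(heptamer = heptamer, nonamer = nonamer),
            class = "consensus_rss")
}

#' Germline gene segment reference
#'
#' One side of a recombining locus: the coding flank adjacent to the RSS and
#' the RSS itself.  The coding flank is stored reading toward the RSS, i.e.
#' its RSS-proximal base is last.
#'
#' @param name Segment identifier (e.g. `"Vb14"`).
#' @param coding_flank DNA string of coding sequence abutting the RSS,
#'   RSS-proximal end last.  At least ~20 nt is recommended so that junction
#'   windows never exhaust the flank.
#' @param rss An [rss_spec()].
#' @param side `"upstream"` (left of the junction; deletions resect its 3'
#'   end) or `"downstream"` (right of the junction; deletions resect the end
#'   nearest the junction).
#' @param frame_anchor Optional integer 0-2: offset of the reading frame at
#'   the RSS-proximal coding boundary.  `NA` when unknown.
#' @return An object of class `gene_segment_ref`.
#' @export
gene_segment_ref <- function(name, coding_flank, rss,
                             side = c("upstream", "downstream"),
                             frame_anchor = NA_integer_) {
  side <- match.arg(side)
  coding_flank <- toupper(coding_flank)
  if (!nzchar(coding_flank))
    stop("segment '", name, "': coding_flank must be non-empty")
  if (!is_dna(coding_flank))
    stop("segment '", name, "': non-DNA characters in coding_flank")
  stopifnot(inherits(rss, "rss_spec"))
  if (!is.na(frame_anchor) && !frame_anchor %in% 0:2)
    stop("segment '", name, "': frame_anchor must be 0, 1, 2 or NA")
  structure(
    list(name = name, coding_flank = coding_flank, rss = rss, side = side,
         frame_anchor = as.integer(frame_anchor)),
    class = "gene_segment_ref"
  )
}

#' Locus reference: a recombining segment pair
#'
#' Pairs two gene segments into a coding- or signal-joint locus.  Signal
#' loci must obey the 12/23 rule (one 12-RSS and one 23-RSS).
#'
#' @param locus_name Locus identifier (e.g. `"Vb14-Jb1.1"`).
#' @param left_segment,right_segment [gene_segment_ref()] objects for the
#'   upstream and downstream side of the junction.
#' @param joint_kind `"coding"` or `"signal"`.
#' @return An object of class `locus_reference`.
#' @export
locus_reference <- function(locus_name, left_segment, right_segment,
                            joint_kind = c("coding", "signal")) {
  joint_kind <- match.arg(joint_kind)
  stopifnot(inherits(left_segment, "gene_segment_ref"),
            inherits(right_segment, "gene_segment_ref"))
  classes <- c(left_segment$rss$spacer_class, right_segment$rss$spacer_class)
  if (joint_kind == "signal") {
    if (classes[1] == classes[2])
      stop("locus '", locus_name, "': signal joint requires a 12/23 RSS ",
           "pair (12/23 rule), got ", classes[1], "/", classes[2])
    for (seg in list(left_segment, right_segment))
      if (substr(seg$rss$heptamer, 1, 3) != "CAC")
        warning("locus '", locus_name, "': heptamer of segment '", seg$name,
                "' does not begin with CAC; precise signal joints will not ",
                "regenerate an ApaL1 site")
  }
  structure(
    list(locus_name = locus_name, left_segment = left_segment,
         right_segment = right_segment, joint_kind = joint_kind),
    class = "locus_reference"
  )
}

# The two reference strings flanking the junction, 5'->3' in joint
# orientation.  For a coding joint these are the coding flanks; for a signal
# joint the left side is the reverse complement of the full upstream RSS
# (heptamer at the fusion) and the right side is the full downstream RSS.
joint_refs <- function(locus) {
  if (locus$joint_kind == "coding") {
    list(left = locus$left_segment$coding_flank,
         right = locus$right_segment$coding_flank)
  } else {
    list(left = revcomp(rss_seq(locus$left_segment$rss)),
         right = rss_seq(locus$right_segment$rss))
  }
}

LOCUS_FILE_COLS <- c("locus", "joint_kind", "segment_name", "side",
                     "coding_flank", "heptamer", "spacer", "nonamer")

#' Load locus references from a TSV file
#'
#' The reference file is a plain TSV with one row per gene segment and
#' columns `locus, joint_kind, segment_name, side, coding_flank, heptamer,
#' spacer, nonamer` plus an optional `frame_anchor`.  Each locus must supply
#' exactly one `upstream` and one `downstream` segment.
#'
#' @param path Path to the TSV file.
#' @return A named list of [locus_reference()] objects.
#' @export
load_locus_reference <- function(path) {
  if (!file.exists(path)) stop("locus reference file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(LOCUS_FILE_COLS, names(df))
  if (length(missing))
    stop("locus reference file missing column(s): ",
         paste(missing, collapse = ", "))
  if (!nrow(df)) {
    warning("locus reference file '", path, "' contains no records")
    return(list())
  }
  if (!"frame_anchor" %in% names(df)) df$frame_anchor <- NA
  loci <- lapply(split(df, df$locus), function(grp) {
    name <- grp$locus[1]
    if (nrow(grp) != 2L || !setequal(grp$side, c("upstream", "downstream")))
      stop("locus '", name, "': expected exactly one upstream and one ",
           "downstream segment record")
    if (length(unique(grp$joint_kind)) != 1L)
      stop("locus '", name, "': inconsistent joint_kind between segments")
    seg <- function(side) {
      r <- grp[grp$side == side, ]
      fa <- suppressWarnings(as.integer(r$frame_anchor))
      gene_segment_ref(r$segment_name, r$coding_flank,
                       rss_spec(r$heptamer, r$spacer, r$nonamer),
                       side = side, frame_anchor = fa)
    }
    locus_reference(name, seg("upstream"), seg("downstream"),
                    joint_kind = grp$joint_kind[1])
  })
  loci[unique(df$locus)]
}

#' Write locus references to a TSV file
#'
#' Inverse of [load_locus_reference()]; a written file loads back with
#' identical field values.
#'
#' @param loci A list of [locus_reference()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus_reference <- function(loci, path) {
  rows <- lapply(loci, function(lc) {
    do.call(rbind, lapply(list(lc$left_segment, lc$right_segment), function(seg) {
      data.frame(locus = lc$locus_name, joint_kind = lc$joint_kind,
                 segment_name = seg$name, side = seg$side,
                 coding_flank = seg$coding_flank,
                 heptamer = seg$rss$heptamer, spacer = seg$rss$spacer,
                 nonamer = seg$rss$nonamer,
                 frame_anchor = seg$frame_anchor,
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load junction reads from a FASTA file
#'
#' Each FASTA record becomes one junction read.  Sequences are uppercased;
#' lowercase input is accepted.  Records with non-DNA characters or
#' duplicated identifiers are rejected with the offending read id in the
#' message.
#'
#' @param path FASTA file of junction sequences.
#' @param locus A [locus_reference()] (or its name) to attach to every read.
#' @param metadata Named list of per-cohort labels, e.g.
#'   `list(genotype = "WT", cohort = "thymus1")`.
#' @return A data frame with columns `read_id`, `sequence`, `locus`,
#'   `genotype`, `cohort`.
#' @export
load_junction_reads <- function(path, locus = NULL,
                                metadata = list(genotype = NA, cohort = NA)) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  sequences <- toupper(as.character(seqs))
  if (anyDuplicated(ids))
    stop("duplicate read id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- !is_dna(sequences) | !nzchar(sequences)
  if (any(bad))
    stop("read(s) with non-DNA or empty sequence: ",
         paste(ids[bad], collapse = ", "))
  locus_name <- if (inherits(locus, "locus_reference")) locus$locus_name
                else if (is.null(locus)) NA_character_ else as.character(locus)
  data.frame(
    read_id = ids, sequence = unname(sequences), locus = locus_name,
    genotype = if (is.null(metadata$genotype)) NA_character_ else metadata$genotype,
    cohort = if (is.null(metadata$cohort)) NA_character_ else metadata$cohort,
    stringsAsFactors = FALSE
  )
}
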