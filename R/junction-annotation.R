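#' Annotation configuration
#'
#' Thresholds used when decomposing junction sequences.
#'
#' @param microhomology_min Minimum overlap (nt) reported as microhomology;
#'   shorter overlaps are folded into the left retained end.  Default 2, the
#'   conventional reporting cutoff for junctional microhomology.
#' @param miscleavage_min_match Minimum run of inserted bases matching the
#'   germline coding flank for a signal-joint miscleavage call.  Default 2.
#' @param max_p_length Maximum P-nucleotide length considered per end.
#'   Default 4.
#' @return An object of class `annotation_config`.
#' @export
annotation_config <- function(microhomology_min = 2L,
                              miscleavage_min_match = 2L,
                              max_p_length = 4L) {
  vals <- c(microhomology_min, miscleavage_min_match, max_p_length)
  if (any(vals < 1L)) stop("all annotation_config fields must be >= 1")
  structure(list(microhomology_min = as.integer(microhomology_min),
                 miscleavage_min_match = as.integer(miscleavage_min_match),
                 max_p_length = as.integer(max_p_length)),
            class = "annotation_config")
}

# Greedy maximal-match decomposition of a junction window against its two
# reference flanks.  Retained-left is the longest common prefix of the window
# and the left reference; retained-right is symmetric from the right.  When
# the two claims overlap, the overlap is reported as microhomology if it
# reaches `mh_min`, otherwise the ambiguous bases are assigned to the LEFT
# end (deterministic tie-break, matched by the brute-force oracle).
decompose_junction <- function(sequence, left_ref, right_ref, mh_min) {
  n <- nchar(sequence)
  a <- min(lcp_len(sequence, left_ref), nchar(left_ref))
  b <- min(lcs_len(sequence, right_ref), nchar(right_ref))
  mh <- 0L
  mh_seq <- ""
  if (a + b > n) {
    ov <- a + b - n
    if (ov >= mh_min) {
      mh <- ov
      mh_seq <- substr(sequence, a - ov + 1L, a)
    } else {
      b <- n - a
    }
  }
  middle <- if (mh > 0L) "" else substr(sequence, a + 1L, n - b)
  list(left_retained = a, right_retained = b,
       del_left = nchar(left_ref) - a, del_right = nchar(right_ref) - b,
       middle = middle, microhomology_len = mh, microhomology_seq = mh_seq)
}

# Longest j <= jmax such that the first j middle bases extend the left end as
# a reverse-complement palindrome of its terminal bases (P nucleotides).
p_extension_left <- function(middle, flank, jmax) {
  best <- 0L
  lim <- min(jmax, nchar(middle), nchar(flank))
  for (j in seq_len(lim)) {
    if (substr(middle, 1L, j) ==
        revcomp(substr(flank, nchar(flank) - j + 1L, nchar(flank))))
      best <- j
  }
  best
}

p_extension_right <- function(middle, flank, jmax) {
  best <- 0L
  nm <- nchar(middle)
  lim <- min(jmax, nm, nchar(flank))
  for (j in seq_len(lim)) {
    if (substr(middle, nm - j + 1L, nm) == revcomp(substr(flank, 1L, j)))
      best <- j
  }
  best
}

#' Annotate a coding joint
#'
#' Decomposes a coding-joint read into retained germline flank, per-end
#' deletions, P nucleotides, N nucleotides and microhomology, using greedy
#' maximal matching from both ends.  P nucleotides are assigned maximally
#' (before N classification) and only on ends with zero deletion, since
#' hairpin-derived palindromes require an unresected coding end.
#'
#' @param sequence Junction read spanning both coding flanks.
#' @param locus A [locus_reference()] with `joint_kind = "coding"`.
#' @param config An [annotation_config()].
#' @param read_id Optional identifier carried into the result.
#' @return An object of class `coding_joint_annotation`: a list with fields
#'   `read_id`, `sequence`, `left_retained`, `right_retained`, `del_left`,
#'   `del_right`, `p_left`, `p_right`, `n_insertion`, `microhomology_len`,
#'   `microhomology_seq`, `in_frame`.
#' @examples
#' locus <- locus_reference(
#'   "toy",
#'   gene_segment_ref("V", "TACTTC", rss_spec("CACAGTG", strrep("A", 23),
#'                    "ACAAAAACC"), "upstream"),
#'   gene_segment_ref("J", "GGAACA", rss_spec("CACAGTG", strrep("A", 12),
#'                    "ACAAAAACC"), "downstream"),
#'   joint_kind = "coding")
#' annotate_coding_joint("TACTTCGAGGAACA", locus)
#' @export
annotate_coding_joint <- function(sequence, locus,
                                  config = annotation_config(),
                                  read_id = NA_character_) {
  stopifnot(inherits(locus, "locus_reference"))
  if (locus$joint_kind != "coding")
    stop("locus '", locus$locus_name, "' is not a coding-joint locus")
  sequence <- toupper(sequence)
  refs <- joint_refs(locus)
  d <- decompose_junction(sequence, refs$left, refs$right,
                          config$microhomology_min)
  if (d$left_retained == 0L && d$right_retained == 0L)
    stop("read '", read_id, "': matches neither coding flank at >= 1 nt; ",
         "cannot annotate")
  middle <- d$middle
  p_left <- p_right <- ""
  if (d$microhomology_len == 0L && nzchar(middle)) {
    if (d$del_left == 0L) {
      j <- p_extension_left(middle, refs$left, config$max_p_length)
      if (j > 0L) {
        p_left <- substr(middle, 1L, j)
        middle <- substr(middle, j + 1L, nchar(middle))
      }
    }
    if (d$del_right == 0L && nzchar(middle)) {
      j <- p_extension_right(middle, refs$right, config$max_p_length)
      if (j > 0L) {
        p_right <- substr(middle, nchar(middle) - j + 1L, nchar(middle))
        middle <- substr(middle, 1L, nchar(middle) - j)
      }
    }
  }
  ann <- structure(
    list(read_id = read_id, sequence = sequence, joint_kind = "coding",
         left_retained = d$left_retained, right_retained = d$right_retained,
         del_left = d$del_left, del_right = d$del_right,
         p_left = p_left, p_right = p_right, n_insertion = middle,
         microhomology_len = d$microhomology_len,
         microhomology_seq = d$microhomology_seq,
         in_frame = "unknown"),
    class = "coding_joint_annotation"
  )
  ann$in_frame <- classify_in_frame(ann, locus)
  ann
}

#' Classify a coding joint as in or out of frame
#'
#' The joint preserves the reading frame iff its net length change relative
#' to the reference in-frame configuration (the blunt fusion of the two
#' untrimmed flanks) is a multiple of 3.  Requires frame anchors on both
#' segments; returns `"unknown"` when either is missing.
#'
#' @param annotation A `coding_joint_annotation`.
#' @param locus The [locus_reference()] used to produce it.
#' @return `"in"`, `"out"` or `"unknown"`.
#' @export
classify_in_frame <- function(annotation, locus) {
  if (is.na(locus$left_segment$frame_anchor) ||
      is.na(locus$right_segment$frame_anchor)) return("unknown")
  refs <- joint_refs(locus)
  obs <- annotation$left_retained + nchar(annotation$p_left) +
    nchar(annotation$n_insertion) + nchar(annotation$p_right) +
    annotation$right_retained - annotation$microhomology_len
  shift <- obs - (nchar(refs$left) + nchar(refs$right))
  if (shift %% 3L == 0L) "in" else "out"
}

APAL1_SITE <- "GTGCAC"

#' Annotate a signal joint
#'
#' Aligns the read against the two full RSS sequences fused heptamer to
#' heptamer (the upstream RSS reverse-complemented so its heptamer abuts the
#' fusion).  A joint is precise iff both heptamers are intact with no
#' inserted bases; precise joints regenerate the ApaL1 recognition site
#' `GTGCAC` straddling the fusion, which is checked in silico within +/-6 nt
#' of the inferred fusion point.  Inserted bases are screened for
#' miscleavage via [detect_miscleavage()].
#'
#' @param sequence Junction read spanning the heptamer-heptamer fusion.
#' @param locus A [locus_reference()] with `joint_kind = "signal"`.
#' @param config An [annotation_config()].
#' @param read_id Optional identifier.
#' @return An object of class `signal_joint_annotation`: a list with fields
#'   `read_id`, `sequence`, `precise`, `del_left_rss`, `del_right_rss`,
#'   `insertion`, `microhomology_len`, `microhomology_seq`, `miscleavage`,
#'   `miscleavage_seq`, `apal1_site_present`, `left_retained`,
#'   `right_retained`.
#' @export
annotate_signal_joint <- function(sequence, locus,
                                  config = annotation_config(),
                                  read_id = NA_character_) {
  stopifnot(inherits(locus, "locus_reference"))
  if (locus$joint_kind != "signal")
    stop("locus '", locus$locus_name, "' is not a signal-joint locus")
  sequence <- toupper(sequence)
  refs <- joint_refs(locus)
  d <- decompose_junction(sequence, refs$left, refs$right,
                          config$microhomology_min)
  if (d$left_retained == 0L && d$right_retained == 0L)
    stop("read '", read_id, "': no recognizable RSS context on either ",
         "side; cannot annotate")
  insertion <- d$middle
  precise <- d$del_left == 0L && d$del_right == 0L &&
    !nzchar(insertion) && d$microhomology_len == 0L
  fp <- d$left_retained + nchar(insertion) / 2  # fusion point (approx. mid-insertion)
  lo <- max(1L, as.integer(floor(fp)) - 5L)
  hi <- min(nchar(sequence), as.integer(ceiling(fp)) + 6L)
  apal1 <- (hi - lo + 1L) >= nchar(APAL1_SITE) &&
    grepl(APAL1_SITE, substr(sequence, lo, hi), fixed = TRUE)
  ann <- structure(
    list(read_id = read_id, sequence = sequence, joint_kind = "signal",
         precise = precise,
         del_left_rss = d$del_left, del_right_rss = d$del_right,
         insertion = insertion,
         microhomology_len = d$microhomology_len,
         microhomology_seq = d$microhomology_seq,
         miscleavage = FALSE, miscleavage_seq = "",
         apal1_site_present = apal1,
         left_retained = d$left_retained, right_retained = d$right_retained),
    class = "signal_joint_annotation"
  )
  detect_miscleavage(ann, locus, config)
}

#' Detect miscleavage at a signal joint
#'
#' Miscleavage is RAG cleavage displaced into the coding segment, carrying
#' coding-flank bases onto the signal end.  It is called when at least
#' `miscleavage_min_match` contiguous inserted bases adjacent to a signal end
#' match the germline coding bases abutting that RSS: on the left (inverted)
#' side of the joint these appear as the reverse complement of the flank's
#' RSS-proximal bases, on the right side in direct orientation.  An end with
#' RSS deletion cannot be flagged (a miscleaved end retains its full RSS).
#'
#' @param annotation A `signal_joint_annotation`.
#' @param locus The [locus_reference()] used to produce it.
#' @param config An [annotation_config()].
#' @return The annotation with `miscleavage` and `miscleavage_seq` updated.
#' @export
detect_miscleavage <- function(annotation, locus,
                               config = annotation_config()) {
  stopifnot(inherits(annotation, "signal_joint_annotation"))
  ins <- annotation$insertion
  m <- config$miscleavage_min_match
  annotation$miscleavage <- FALSE
  annotation$miscleavage_seq <- ""
  ni <- nchar(ins)
  if (ni < m) return(annotation)
  lf <- locus$left_segment$coding_flank
  rf <- locus$right_segment$coding_flank
  best_l <- best_r <- 0L
  if (annotation$del_left_rss == 0L) {
    lim <- min(ni, nchar(lf))
    for (j in seq_len(lim))
      if (j >= m &&
          substr(ins, 1L, j) ==
            revcomp(substr(lf, nchar(lf) - j + 1L, nchar(lf))))
        best_l <- j
  }
  if (annotation$del_right_rss == 0L) {
    lim <- min(ni, nchar(rf))
    for (j in seq_len(lim))
      if (j >= m &&
          substr(ins, ni - j + 1L, ni) ==
            substr(rf, nchar(rf) - j + 1L, nchar(rf)))
        best_r <- j
  }
  parts <- character(0)
  if (best_l >= m) parts <- c(parts, substr(ins, 1L, best_l))
  if (best_r >= m) parts <- c(parts, substr(ins, ni - best_r + 1L, ni))
  if (length(parts)) {
    annotation$miscleavage <- TRUE
    annotation$miscleavage_seq <- paste(parts, collapse = ",")
  }
  annotation
}

#' Reconstruct the junction window from an annotation
#'
#' Concatenates retained-left, P, N, P, retained-right with any
#' microhomology counted once.  For every valid annotation this reproduces
#' the observed read exactly (the reconstruction invariant).
#'
#' @param annotation A `coding_joint_annotation` or
#'   `signal_joint_annotation`.
#' @param locus The [locus_reference()] used to produce it.
#' @return The reconstructed DNA string.
#' @export
reconstruct_junction <- function(annotation, locus) {
  refs <- joint_refs(locus)
  a <- annotation$left_retained
  b <- annotation$right_retained
  left_part <- substr(refs$left, 1L, a)
  right_part <- substr(refs$right, nchar(refs$right) - b + 1L,
                       nchar(refs$right))
  mh <- annotation$microhomology_len
  if (mh > 0L)
    return(paste0(left_part, substr(right_part, mh + 1L, b)))
  middle <- if (inherits(annotation, "coding_joint_annotation"))
    paste0(annotation$p_left, annotation$n_insertion, annotation$p_right)
  else annotation$insertion
  paste0(left_part, middle, right_part)
}

#' Annotate a table of junction reads
#'
#' Routes each read to [annotate_coding_joint()] or
#' [annotate_signal_joint()] according to its locus' `joint_kind` and
#' returns one row per read.  Columns not applicable to a joint kind are
#' `NA`.
#'
#' @param reads Data frame with columns `read_id`, `sequence`, `locus`
#'   (locus name) and optionally `genotype`, `cohort` (as produced by
#'   [load_junction_reads()] or [simulate_cohort()]).
#' @param loci Named list of [locus_reference()] objects (names = locus
#'   names), or a single `locus_reference`.
#' @param config An [annotation_config()].
#' @return A data frame with columns `read_id, locus, genotype, joint_kind,
#'   sequence, left_retained, right_retained, del_left, del_right, p_left,
#'   p_right, n_insertion, microhomology_len, microhomology_seq,
#'   miscleavage, miscleavage_seq, precise, apal1_site_present, in_frame`.
#'   For signal joints the insertion is reported in `n_insertion` and
#'   deletions in `del_left`/`del_right` (counted into each RSS).
#' @export
annotate_junctions <- function(reads, loci, config = annotation_config()) {
  if (inherits(loci, "locus_reference"))
    loci <- setNames(list(loci), loci$locus_name)
  if (!"genotype" %in% names(reads)) reads$genotype <- NA_character_
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    locus <- loci[[r$locus]]
    if (is.null(locus))
      stop("read '", r$read_id, "': unknown locus '", r$locus, "'")
    if (locus$joint_kind == "coding") {
      a <- annotate_coding_joint(r$sequence, locus, config, r$read_id)
      data.frame(
        read_id = r$read_id, locus = r$locus, genotype = r$genotype,
        joint_kind = "coding", sequence = a$sequence,
        left_retained = a$left_retained, right_retained = a$right_retained,
        del_left = a$del_left, del_right = a$del_right,
        p_left = a$p_left, p_right = a$p_right, n_insertion = a$n_insertion,
        microhomology_len = a$microhomology_len,
        microhomology_seq = a$microhomology_seq,
        miscleavage = NA, miscleavage_seq = NA_character_,
        precise = NA, apal1_site_present = NA, in_frame = a$in_frame,
        stringsAsFactors = FALSE)
    } else {
      a <- annotate_signal_joint(r$sequence, locus, config, r$read_id)
      data.frame(
        read_id = r$read_id, locus = r$locus, genotype = r$genotype,
        joint_kind = "signal", sequence = a$sequence,
        left_retained = a$left_retained, right_retained = a$right_retained,
        del_left = a$del_left_rss, del_right = a$del_right_rss,
        p_left = NA_character_, p_right = NA_character_,
        n_insertion = a$insertion,
        microhomology_len = a$microhomology_len,
        microhomology_seq = a$microhomology_seq,
        miscleavage = a$miscleavage, miscleavage_seq = a$miscleavage_seq,
        precise = a$precise, apal1_site_present = a$apal1_site_present,
        in_frame = NA_character_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a junction annotation as an alignment-style text block
#'
#' Germline flanks on top, the annotated junction beneath: retained
#' germline in lowercase, N nucleotides in uppercase, P nucleotides
#' uppercase wrapped in asterisks, deletions as `(-n)` at the trimmed end
#' and microhomology underlined with `^`.
#'
#' @param annotation A coding or signal joint annotation object.
#' @param locus The [locus_reference()] used to produce it.
#' @return A character scalar (lines joined with `\n`).
#' @export
format_junction <- function(annotation, locus) {
  refs <- joint_refs(locus)
  a <- annotation$left_retained
  b <- annotation$right_retained
  germline <- paste0(refs$left, " / ", refs$right)
  dl <- if (inherits(annotation, "signal_joint_annotation"))
    annotation$del_left_rss else annotation$del_left
  dr <- if (inherits(annotation, "signal_joint_annotation"))
    annotation$del_right_rss else annotation$del_right
  left_part <- tolower(substr(refs$left, 1L, a))
  right_part <- tolower(substr(refs$right, nchar(refs$right) - b + 1L,
                               nchar(refs$right)))
  mid <- if (annotation$microhomology_len > 0L) {
    right_part <- substr(right_part, annotation$microhomology_len + 1L, b)
    paste0("[", tolower(annotation$microhomology_seq), "]")
  } else if (inherits(annotation, "coding_joint_annotation")) {
    paste0(if (nzchar(annotation$p_left)) paste0("*", annotation$p_left, "*"),
           annotation$n_insertion,
           if (nzchar(annotation$p_right)) paste0("*", annotation$p_right, "*"))
  } else annotation$insertion
  junction <- paste0(left_part, if (dl > 0L) sprintf("(-%d)", dl),
                     mid, if (dr > 0L) sprintf("(-%d)", dr), right_part)
  tags <- c(
    if (!is.null(annotation$in_frame) && annotation$in_frame != "unknown")
      if (annotation$in_frame == "in") "+" else "-",
    if (isTRUE(annotation$precise)) "precise",
    if (isTRUE(annotation$miscleavage)) "miscleavage")
  paste(c(paste0("germline: ", germline),
          paste0("junction: ", junction,
                 if (length(tags)) paste0("  [", paste(tags, collapse = " "), "]")),
          NULL), collapse = "\n")
}

#' @export
print.coding_joint_annotation <- function(x, ...) {
  cat("coding joint", if (!is.na(x$read_id)) paste0("'", x$read_id, "'"),
      sprintf("del_left=%d del_right=%d P='%s'/'%s' N='%s' MH=%d frame=%s\n",
              x$del_left, x$del_right, x$p_left, x$p_right, x$n_insertion,
              x$microhomology_len, x$in_frame))
  invisible(x)
}

#' @export
print.signal_joint_annotation <- function(x, ...) {
  cat("signal joint", if (!is.na(x$read_id)) paste0("'", x$read_id, "'"),
      sprintf("precise=%s del_left=%d del_right=%d ins='%s' miscleavage=%s apal1=%s\n",
              x$precise, x$del_left_rss, x$del_right_rss, x$insertion,
              x$miscleavage, x$apal1_site_present))
  invisible(x)
}
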