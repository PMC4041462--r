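#' Construct an ADR null model
#'
#' The chance-correction null for adjacent direct repeats: per-base
#' insertion probabilities for a locus together with the total number of
#' junctions sequenced at that locus.  Usually produced by
#' [estimate_adr_null()]; the constructor is exported so hypothetical nulls
#' can be scored directly.
#'
#' @param base_probs Named numeric vector over `A,C,G,T`, summing to 1.
#' @param n_junctions Total junctions for the locus (N), >= 1.
#' @param locus_name Optional label.
#' @return An object of class `adr_null_model`.
#' @export
adr_null_model <- function(base_probs, n_junctions, locus_name = NA_character_) {
  if (!setequal(names(base_probs), c("A", "C", "G", "T")))
    stop("base_probs must be named over A, C, G, T")
  base_probs <- base_probs[c("A", "C", "G", "T")]
  if (any(base_probs < 0) || abs(sum(base_probs) - 1) > 1e-9)
    stop("base_probs must be nonnegative and sum to 1")
  if (n_junctions < 1L) stop("n_junctions must be >= 1")
  structure(list(locus_name = locus_name, base_probs = base_probs,
                 n_junctions = as.integer(n_junctions)),
            class = "adr_null_model")
}

#' Estimate the ADR null model from annotated coding joints
#'
#' Pools the base frequencies of all N-classified inserted nucleotides at a
#' locus.  P-classified bases are excluded by construction (annotation
#' assigns P before N, so insertions explainable as P nucleotides never
#' enter the null).  `n_junctions` is the count of all junctions for the
#' locus, not only those with insertions.  When no usable inserted bases
#' exist the null falls back to uniform probabilities with a warning.
#'
#' @param annotations Annotation data frame (from [annotate_junctions()])
#'   restricted to coding joints, or any data frame with an `n_insertion`
#'   column.
#' @param locus_name Optional: restrict to rows with this `locus` and label
#'   the model.
#' @return An [adr_null_model()].
#' @export
estimate_adr_null <- function(annotations, locus_name = NULL) {
  if (!is.null(locus_name) && "locus" %in% names(annotations))
    annotations <- annotations[annotations$locus == locus_name, , drop = FALSE]
  if (!nrow(annotations)) stop("no junctions to estimate the null from")
  ins <- annotations$n_insertion
  ins <- ins[!is.na(ins)]
  bases <- strsplit(paste(ins, collapse = ""), "")[[1]]
  bases <- bases[bases %in% c("A", "C", "G", "T")]
  if (!length(bases)) {
    warning("no non-P inserted bases at locus '", locus_name,
            "'; falling back to a uniform base composition")
    probs <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  } else {
    tab <- table(factor(bases, levels = c("A", "C", "G", "T")))
    probs <- as.numeric(tab) / length(bases)
    names(probs) <- c("A", "C", "G", "T")
  }
  adr_null_model(probs, nrow(annotations),
                 if (is.null(locus_name)) NA_character_ else locus_name)
}

# inserted-sequence span (1-based, inclusive) of an annotation; width 0 if none
inserted_span <- function(annotation) {
  len <- if (inherits(annotation, "signal_joint_annotation"))
    nchar(annotation$insertion)
  else nchar(annotation$p_left) + nchar(annotation$n_insertion) +
    nchar(annotation$p_right)
  if (annotation$microhomology_len > 0L || len == 0L) return(c(0L, -1L))
  c(annotation$left_retained + 1L, annotation$left_retained + len)
}

#' Detect adjacent direct repeats in an annotated junction
#'
#' Scans the junction window for tandem pairs of identical k-mers
#' (k = 5, 4, 3; copies immediately adjacent, direct orientation) in which
#' exactly one copy lies wholly or partly in inserted (P/N) sequence while
#' the other copy is entirely germline-templated.  The maximal k is
#' reported per site: a candidate whose span is contained in an
#' already-reported longer repeat is suppressed.  K-mers containing `N` are
#' never candidates.
#'
#' @param annotation A coding or signal joint annotation object, or a row
#'   of the data frame from [annotate_junctions()].
#' @param k_range Repeat lengths considered, default `5:3`.
#' @return A data frame with zero or more rows and columns `read_id,
#'   repeat_seq, k, copy1_start, copy1_end, copy2_start, copy2_end,
#'   inserted_copy, borderline` (coordinates 1-based inclusive within the
#'   read; `borderline` flags inserted copies that also contain templated
#'   bases).
#' @export
detect_adrs <- function(annotation, k_range = 5:3) {
  if (is.data.frame(annotation)) annotation <- annotation_from_row(annotation)
  empty <- data.frame(read_id = character(0), repeat_seq = character(0),
                      k = integer(0), copy1_start = integer(0),
                      copy1_end = integer(0), copy2_start = integer(0),
                      copy2_end = integer(0), inserted_copy = integer(0),
                      borderline = logical(0), stringsAsFactors = FALSE)
  span <- inserted_span(annotation)
  if (span[2] < span[1]) return(empty)
  seq <- annotation$sequence
  n <- nchar(seq)
  out <- list()
  accepted <- matrix(integer(0), ncol = 2)
  overlaps <- function(s, e) s <= span[2] && e >= span[1]
  within <- function(s, e) s >= span[1] && e <= span[2]
  for (k in sort(k_range, decreasing = TRUE)) {
    if (2L * k > n) next
    for (i in seq_len(n - 2L * k + 1L)) {
      c1 <- substr(seq, i, i + k - 1L)
      if (c1 != substr(seq, i + k, i + 2L * k - 1L)) next
      if (grepl("N", c1, fixed = TRUE)) next
      s1 <- i; e1 <- i + k - 1L
      s2 <- i + k; e2 <- i + 2L * k - 1L
      if (nrow(accepted) &&
          any(s1 >= accepted[, 1] & e2 <= accepted[, 2])) next
      ov1 <- overlaps(s1, e1)
      ov2 <- overlaps(s2, e2)
      if (xor(ov1, ov2)) {
        ic <- if (ov1) 1L else 2L
        borderline <- if (ov1) !within(s1, e1) else !within(s2, e2)
        out[[length(out) + 1L]] <- data.frame(
          read_id = annotation$read_id, repeat_seq = c1, k = k,
          copy1_start = s1, copy1_end = e1, copy2_start = s2, copy2_end = e2,
          inserted_copy = ic, borderline = borderline,
          stringsAsFactors = FALSE)
        accepted <- rbind(accepted, c(s1, e2))
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# rebuild a minimal annotation object from one annotate_junctions() row
annotation_from_row <- function(row) {
  stopifnot(nrow(row) == 1L)
  if (row$joint_kind == "signal") {
    structure(list(read_id = row$read_id, sequence = row$sequence,
                   insertion = row$n_insertion,
                   microhomology_len = row$microhomology_len,
                   left_retained = row$left_retained,
                   right_retained = row$right_retained),
              class = "signal_joint_annotation")
  } else {
    structure(list(read_id = row$read_id, sequence = row$sequence,
                   p_left = row$p_left, p_right = row$p_right,
                   n_insertion = row$n_insertion,
                   microhomology_len = row$microhomology_len,
                   left_retained = row$left_retained,
                   right_retained = row$right_retained),
              class = "coding_joint_annotation")
  }
}

#' Score ADR calls against a null model
#'
#' The expected number of junctions carrying a given repeat by chance is the
#' product of the per-base insertion probabilities over the inserted copy,
#' multiplied by the total number of junctions at the locus
#' (e.g. `P(n) * P(n) * P(n) * N` for a 3-mer).  A call is significant when
#' this expected count is strictly below 0.5.  A base with probability zero
#' in the null gives expected count 0 (significant).
#'
#' @param calls Data frame from [detect_adrs()].
#' @param null An [adr_null_model()].
#' @return `calls` with `expected_count` and `significant` columns added.
#' @export
score_adrs <- function(calls, null) {
  stopifnot(inherits(null, "adr_null_model"))
  if (!nrow(calls)) {
    calls$expected_count <- numeric(0)
    calls$significant <- logical(0)
    return(calls)
  }
  calls$expected_count <- vapply(calls$repeat_seq, function(s) {
    p <- null$base_probs[strsplit(s, "")[[1]]]
    p[is.na(p)] <- 0
    prod(p) * null$n_junctions
  }, numeric(1), USE.NAMES = FALSE)
  calls$significant <- calls$expected_count < 0.5
  calls
}

#' Detect and score ADRs across an annotation table
#'
#' Runs [detect_adrs()] on every row, estimating one null model per locus
#' from the coding-joint insertions ([estimate_adr_null()]).  Signal-joint
#' ADRs (if any signal rows are present) are scored with their own locus
#' null and reported with `joint_kind = "signal"` so they can be tabulated
#' separately.
#'
#' @param annotations Data frame from [annotate_junctions()].
#' @param k_range Repeat lengths considered, default `5:3`.
#' @return Data frame of scored calls with `locus` and `joint_kind` columns.
#' @export
adr_screen <- function(annotations, k_range = 5:3) {
  pieces <- lapply(split(annotations,
                         annotations[c("locus", "joint_kind")], drop = TRUE),
                   function(grp) {
    null <- estimate_adr_null(grp, grp$locus[1])
    calls <- do.call(rbind, lapply(seq_len(nrow(grp)), function(i)
      detect_adrs(grp[i, ], k_range)))
    if (is.null(calls) || !nrow(calls)) return(NULL)
    calls <- score_adrs(calls, null)
    calls$locus <- grp$locus[1]
    calls$joint_kind <- grp$joint_kind[1]
    calls
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (!length(pieces)) {
    out <- detect_adrs(structure(
      list(read_id = NA_character_, sequence = "", p_left = "", p_right = "",
           n_insertion = "", microhomology_len = 0L, left_retained = 0L,
           right_retained = 0L), class = "coding_joint_annotation"))
    out$expected_count <- numeric(0)
    out$significant <- logical(0)
    out$locus <- character(0)
    out$joint_kind <- character(0)
    return(out)
  }
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res
}
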