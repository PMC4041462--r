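#' Cryptic-RSS scan configuration
#'
#' @param pair_threshold Minimum summed match score at which a 12/23 pair is
#'   called positive.  Default 19, the match count of the Notch1 cryptic
#'   RSSs that anchors the positivity cutoff.
#' @param spacer_tolerance Allowed deviation (nt) from the exact 12/23
#'   spacer lengths.  Default 0 (the match score has no spacer-length term).
#' @param report_floor Minimum site score for a hit to be reported by
#'   [scan_sequence()]; lower-scoring sites remain available to pairing
#'   functions that pass `report_floor = 0`.  Default 10.
#' @return An object of class `crss_config`.
#' @export
crss_config <- function(pair_threshold = 19L, spacer_tolerance = 0L,
                        report_floor = 10L) {
  if (pair_threshold < 0L || pair_threshold > 32L)
    stop("pair_threshold must be in [0, 32]")
  if (spacer_tolerance < 0L) stop("spacer_tolerance must be >= 0")
  structure(list(pair_threshold = as.integer(pair_threshold),
                 spacer_tolerance = as.integer(spacer_tolerance),
                 report_floor = as.integer(report_floor)),
            class = "crss_config")
}

empty_hits <- function() {
  data.frame(sequence_name = character(0), position = integer(0),
             strand = character(0), spacer_class = integer(0),
             spacer_len = integer(0), heptamer_matches = integer(0),
             nonamer_matches = integer(0), site_score = integer(0),
             site_start = integer(0), site_end = integer(0),
             stringsAsFactors = FALSE)
}

#' Score one candidate RSS window
#'
#' Positionwise identity count of the 7 heptamer and 9 nonamer positions
#' against the consensus; spacer positions are never scored and `N` never
#' matches.
#'
#' @param window DNA string of length `7 + spacer_class + 9`.
#' @param spacer_class 12 or 23.
#' @param consensus A [consensus_rss()].
#' @return A one-row hit data frame with columns `spacer_class,
#'   heptamer_matches, nonamer_matches, site_score` (position/strand `NA`:
#'   the window carries no coordinates).
#' @export
score_site <- function(window, spacer_class, consensus = consensus_rss()) {
  spacer_class <- as.integer(spacer_class)
  if (!spacer_class %in% c(12L, 23L)) stop("spacer_class must be 12 or 23")
  window <- toupper(window)
  wlen <- 7L + spacer_class + 9L
  if (nchar(window) != wlen)
    stop("window must be ", wlen, " nt for a ", spacer_class,
         "-RSS, got ", nchar(window))
  wi <- utf8ToInt(window)
  hm <- sum(wi[1:7] == utf8ToInt(consensus$heptamer))
  nm <- sum(wi[(7L + spacer_class + 1L):wlen] == utf8ToInt(consensus$nonamer))
  data.frame(sequence_name = NA_character_, position = NA_integer_,
             strand = NA_character_, spacer_class = spacer_class,
             spacer_len = spacer_class,
             heptamer_matches = as.integer(hm),
             nonamer_matches = as.integer(nm),
             site_score = as.integer(hm + nm),
             site_start = NA_integer_, site_end = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Scan a sequence for cryptic RSSs
#'
#' Applies [score_site()] at every position, on both strands, for both
#' spacer classes.  Hit coordinates: `position` is the 0-based start of the
#' heptamer in the input sequence's coordinates (for `-` strand hits the
#' heptamer reads on the reverse strand); `site_start`/`site_end` delimit
#' the whole site, 0-based half-open.
#'
#' @param sequence DNA string, length >= 28.
#' @param consensus A [consensus_rss()].
#' @param config A [crss_config()].
#' @param sequence_name Label carried into the output.
#' @param report_floor Minimum site score reported; defaults to
#'   `config$report_floor`.
#' @return A hit data frame (see [score_site()] for columns), ordered by
#'   `site_start`.
#' @export
scan_sequence <- function(sequence, consensus = consensus_rss(),
                          config = crss_config(), sequence_name = "seq",
                          report_floor = config$report_floor) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 28L)
    stop("sequence shorter than the minimal 12-RSS window (28 nt)")
  hi <- utf8ToInt(consensus$heptamer)
  ni <- utf8ToInt(consensus$nonamer)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else revcomp(sequence)
    si <- utf8ToInt(s)
    for (cls in c(12L, 23L)) {
      spacers <- unique(pmax(0L, cls + seq(-config$spacer_tolerance,
                                           config$spacer_tolerance)))
      for (sp in spacers) {
        wlen <- 16L + sp
        npos <- n - wlen + 1L
        if (npos < 1L) next
        idx <- seq_len(npos)
        hm <- integer(npos)
        for (j in 1:7) hm <- hm + (si[idx + j - 1L] == hi[j])
        nm <- integer(npos)
        off <- 7L + sp
        for (j in 1:9) nm <- nm + (si[idx + off + j - 1L] == ni[j])
        q0 <- idx - 1L
        pos0 <- if (strand == "+") q0 else n - q0 - 7L
        start0 <- if (strand == "+") q0 else n - q0 - wlen
        res[[length(res) + 1L]] <- data.frame(
          sequence_name = sequence_name, position = pos0, strand = strand,
          spacer_class = cls, spacer_len = sp,
          heptamer_matches = hm, nonamer_matches = nm,
          site_score = hm + nm, site_start = start0, site_end = start0 + wlen,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  out <- out[out$site_score >= report_floor, , drop = FALSE]
  out <- out[order(out$site_start, out$strand, out$spacer_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score a 12/23 cryptic-RSS pair
#'
#' Sums the two site scores; the pair is positive when the sum reaches the
#' pair threshold.  The two hits must have different spacer classes (12/23
#' rule).
#'
#' @param hit12,hit23 One-row hit data frames (from [score_site()] or
#'   [scan_sequence()]) with spacer classes 12 and 23.
#' @param config A [crss_config()].
#' @return An object of class `crss_pair`: list with `hit12`, `hit23`,
#'   `pair_score`, `positive`.
#' @export
score_pair <- function(hit12, hit23, config = crss_config()) {
  if (hit12$spacer_class == hit23$spacer_class)
    stop("12/23 rule violation: both sites have a ", hit12$spacer_class,
         "-nt spacer")
  if (hit12$spacer_class != 12L) { tmp <- hit12; hit12 <- hit23; hit23 <- tmp }
  ps <- hit12$site_score + hit23$site_score
  structure(list(hit12 = hit12, hit23 = hit23, pair_score = ps,
                 positive = ps >= config$pair_threshold),
            class = "crss_pair")
}

#' @export
print.crss_pair <- function(x, ...) {
  cat(sprintf("cRSS pair: 12-RSS score %d + 23-RSS score %d = %d (%s)\n",
              x$hit12$site_score, x$hit23$site_score, x$pair_score,
              if (x$positive) "positive" else "negative"))
  invisible(x)
}

# best hit in a context under the documented tie-break:
# highest score, then closest heptamer to the breakpoint, then + strand,
# then lowest coordinate
best_hit <- function(hits) {
  if (!nrow(hits)) return(NULL)
  ord <- order(-hits$site_score, hits$breakpoint_dist,
               hits$strand != "+", hits$position)
  hits[ord[1], , drop = FALSE]
}

#' Classify a breakpoint by its best cryptic-RSS pair
#'
#' Scans the sequence context on each side of a breakpoint for its best
#' cryptic RSS with the heptamer oriented toward the breakpoint (the
#' cleavage geometry): `-` strand sites in the left context, `+` strand
#' sites in the right context.  The best orientation-consistent 12/23 pair
#' is returned with its positivity flag; `NULL` when no such pair exists.
#'
#' @param left_context DNA immediately left of the breakpoint (breakpoint at
#'   its right edge), >= 28 nt.
#' @param right_context DNA immediately right of the breakpoint (breakpoint
#'   at its left edge), >= 28 nt.
#' @param consensus A [consensus_rss()].
#' @param config A [crss_config()].
#' @return A `crss_pair` (with per-side hits carrying `sequence_name`
#'   `"left"`/`"right"`), or `NULL`.
#' @export
classify_breakpoint_pair <- function(left_context, right_context,
                                     consensus = consensus_rss(),
                                     config = crss_config()) {
  nl <- nchar(left_context)
  hl <- scan_sequence(left_context, consensus, config, "left",
                      report_floor = 0L)
  hl <- hl[hl$strand == "-", , drop = FALSE]
  hl$breakpoint_dist <- nl - (hl$position + 7L)
  hr <- scan_sequence(right_context, consensus, config, "right",
                      report_floor = 0L)
  hr <- hr[hr$strand == "+", , drop = FALSE]
  hr$breakpoint_dist <- hr$position
  combos <- list(
    list(best_hit(hl[hl$spacer_class == 12L, , drop = FALSE]),
         best_hit(hr[hr$spacer_class == 23L, , drop = FALSE])),
    list(best_hit(hl[hl$spacer_class == 23L, , drop = FALSE]),
         best_hit(hr[hr$spacer_class == 12L, , drop = FALSE])))
  pairs <- Filter(Negate(is.null), lapply(combos, function(cb) {
    if (is.null(cb[[1]]) || is.null(cb[[2]])) return(NULL)
    score_pair(cb[[1]], cb[[2]], config)
  }))
  if (!length(pairs)) return(NULL)
  pairs[[which.max(vapply(pairs, `[[`, numeric(1), "pair_score"))]]
}

#' Write cRSS hits as a BED-like TSV
#'
#' Columns `sequence_name, start, end, name, score, strand` with 0-based
#' half-open coordinates over the full site span.
#'
#' @param hits Hit data frame from [scan_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crss_bed <- function(hits, path) {
  bed <- data.frame(
    sequence_name = hits$sequence_name, start = hits$site_start,
    end = hits$site_end,
    name = sprintf("cRSS%d_h%d_n%d", hits$spacer_class,
                   hits$heptamer_matches, hits$nonamer_matches),
    score = hits$site_score, strand = hits$strand, stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
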