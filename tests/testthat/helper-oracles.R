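# Independent brute-force oracles.  Each re-derives a result by exhaustive
# enumeration or naive rescanning, sharing no code with the implementation
# paths it checks.

# Exhaustive minimal-edit decomposition of a junction window.  Enumerates
# every (retained-left, retained-right) pair consistent with the flanks,
# scores it by deletions + insertions (overlapping claims are microhomology,
# not edits), takes the minimum, breaks ties by larger retained-left then
# larger retained-right, and finally applies the same sub-threshold
# microhomology fold (ambiguity to the left end) the annotation documents.
oracle_decompose <- function(sequence, left_ref, right_ref, mh_min) {
  n <- nchar(sequence)
  L <- nchar(left_ref)
  R <- nchar(right_ref)
  ok_a <- Filter(function(a) substr(sequence, 1, a) == substr(left_ref, 1, a),
                 0:min(n, L))
  ok_b <- Filter(function(b)
    substr(sequence, n - b + 1, n) == substr(right_ref, R - b + 1, R),
    0:min(n, R))
  best <- NULL
  for (a in ok_a) for (b in ok_b) {
    if (a + b <= n) {
      edits <- (L - a) + (R - b) + (n - a - b)
      mh <- 0L
    } else {
      mh <- a + b - n
      if (mh > min(a, b)) next
      edits <- (L - a) + (R - b)
    }
    cand <- list(a = a, b = b, edits = edits, mh = mh)
    if (is.null(best) || edits < best$edits ||
        (edits == best$edits && (a > best$a ||
                                 (a == best$a && b > best$b))))
      best <- cand
  }
  if (best$mh > 0 && best$mh < mh_min) {
    best$b <- n - best$a
    best$mh <- 0L
  }
  list(left_retained = best$a, right_retained = best$b,
       del_left = L - best$a, del_right = R - best$b,
       middle = if (best$mh > 0) "" else
         substr(sequence, best$a + 1, n - best$b),
       microhomology_len = best$mh)
}

# Longest reverse-complement palindromic extension by direct enumeration.
oracle_p_left <- function(middle, flank, jmax) {
  hits <- Filter(function(j) {
    probe <- paste(rev(strsplit(substr(middle, 1, j), "")[[1]]), collapse = "")
    probe == chartr("ACGT", "TGCA",
                    substr(flank, nchar(flank) - j + 1, nchar(flank)))
  }, seq_len(min(jmax, nchar(middle), nchar(flank))))
  if (length(hits)) max(unlist(hits)) else 0L
}

# Brute-force tandem-repeat scan with the inserted-copy rule; mirrors the
# documented maximal-k suppression with independent bookkeeping.
oracle_adrs <- function(sequence, ins_lo, ins_hi, k_range = 3:5) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  cand <- list()
  for (k in k_range) {
    if (2 * k > n) next
    for (i in seq_len(n - 2 * k + 1)) {
      c1 <- chars[i:(i + k - 1)]
      c2 <- chars[(i + k):(i + 2 * k - 1)]
      if (!all(c1 == c2) || any(c1 == "N")) next
      in1 <- length(intersect(i:(i + k - 1), seq2(ins_lo, ins_hi))) > 0
      in2 <- length(intersect((i + k):(i + 2 * k - 1),
                              seq2(ins_lo, ins_hi))) > 0
      if (sum(c(in1, in2)) != 1) next
      cand[[length(cand) + 1]] <- list(start = i, end = i + 2 * k - 1, k = k,
                                       seq = paste(c1, collapse = ""),
                                       inserted_copy = if (in1) 1L else 2L)
    }
  }
  if (!length(cand)) return(cand)
  # keep a candidate unless contained in a kept candidate of larger k
  ord <- order(-vapply(cand, `[[`, numeric(1), "k"),
               vapply(cand, `[[`, numeric(1), "start"))
  kept <- list()
  for (idx in ord) {
    c0 <- cand[[idx]]
    contained <- any(vapply(kept, function(d)
      d$k > c0$k && c0$start >= d$start && c0$end <= d$end, logical(1)))
    if (!contained) kept[[length(kept) + 1]] <- c0
  }
  kept[order(vapply(kept, `[[`, numeric(1), "start"))]
}

seq2 <- function(lo, hi) if (hi < lo) integer(0) else lo:hi

# Naive per-position cRSS rescanner using substring comparisons.
oracle_crss_scan <- function(sequence, consensus, floor = 0L) {
  out <- list()
  n <- nchar(sequence)
  rc <- function(s) paste(rev(strsplit(chartr("ACGTN", "TGCAN", s),
                                       "")[[1]]), collapse = "")
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else rc(sequence)
    for (cls in c(12L, 23L)) {
      wlen <- 16L + cls
      if (n < wlen) next
      for (q in 0:(n - wlen)) {
        win <- substr(s, q + 1, q + wlen)
        hm <- sum(strsplit(substr(win, 1, 7), "")[[1]] ==
                    strsplit(consensus$heptamer, "")[[1]])
        nm <- sum(strsplit(substr(win, 7 + cls + 1, wlen), "")[[1]] ==
                    strsplit(consensus$nonamer, "")[[1]])
        if (hm + nm < floor) next
        out[[length(out) + 1]] <- data.frame(
          position = if (strand == "+") q else n - q - 7L,
          strand = strand, spacer_class = cls,
          site_score = hm + nm, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$position, res$strand, res$spacer_class), , drop = FALSE]
}

# closed-form Pearson chi-squared for a 2x2 table
oracle_chisq_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# closed-form pooled-variance two-sample t statistic
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}
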