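# Junction windows are short (tens of nt), so plain character operations beat
# DNAString round-trips inside the annotation loops; Biostrings is used at the
# FASTA boundary instead.

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors.  `N` maps to
#' `N`; case is preserved.
#'
#' @param x Character vector of DNA strings (alphabet `A,C,G,T,N`).
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("CACAGTG", "acgtn"))
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nchar(s)) return("")
    intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", s))))
  }, character(1), USE.NAMES = FALSE)
}

is_dna <- function(x) grepl("^[ACGTN]*$", x)

# longest common prefix length of two strings
lcp_len <- function(a, b) {
  ai <- utf8ToInt(a)
  bi <- utf8ToInt(b)
  n <- min(length(ai), length(bi))
  if (n == 0L) return(0L)
  neq <- which(ai[seq_len(n)] != bi[seq_len(n)])
  if (length(neq)) neq[1L] - 1L else n
}

# longest common suffix length of two strings
lcs_len <- function(a, b) {
  ai <- rev(utf8ToInt(a))
  bi <- rev(utf8ToInt(b))
  n <- min(length(ai), length(bi))
  if (n == 0L) return(0L)
  neq <- which(ai[seq_len(n)] != bi[seq_len(n)])
  if (length(neq)) neq[1L] - 1L else n
}

# sample `n` bases from a named composition vector
sample_bases <- function(n, composition) {
  if (n <= 0L) return("")
  paste(sample(names(composition), n, replace = TRUE, prob = composition),
        collapse = "")
}

# 1 + geometric, mean `m` (m >= 1); capped at `cap`
rlen_geom1 <- function(n, m, cap = Inf) {
  m <- max(m, 1)
  pmin(1L + stats::rgeom(n, prob = 1 / m), cap)
}

# geometric on {0, 1, ...} with mean `m`
rlen_geom0 <- function(n, m) {
  if (m <= 0) return(rep(0L, n))
  stats::rgeom(n, prob = 1 / (1 + m))
}
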