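# Toy locus builders and random-sequence helpers shared across tests.

consensus_12 <- function() rss_spec("CACAGTG", strrep("A", 12), "ACAAAAACC")
consensus_23 <- function() rss_spec("CACAGTG", strrep("T", 23), "ACAAAAACC")

# coding locus from two literal flanks (upstream flank junction-proximal end
# last; downstream flank junction-proximal end first)
toy_coding_locus <- function(left_flank, right_flank, name = "toy",
                             frame_left = NA_integer_,
                             frame_right = NA_integer_) {
  locus_reference(
    name,
    gene_segment_ref("V", left_flank, consensus_23(), "upstream",
                     frame_anchor = frame_left),
    gene_segment_ref("J", right_flank, consensus_12(), "downstream",
                     frame_anchor = frame_right),
    joint_kind = "coding")
}

toy_signal_locus <- function(left_flank = "GATTACCAGTCAGGTCTGAC",
                             right_flank = "CCTGGTAACGATCAGTTCGA",
                             rss_left = consensus_12(),
                             rss_right = consensus_23(),
                             name = "toySJ") {
  locus_reference(
    name,
    gene_segment_ref("V", left_flank, rss_left, "upstream"),
    gene_segment_ref("J", right_flank, rss_right, "downstream"),
    joint_kind = "signal")
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# coding locus whose left flank uses only {A,C} and right flank only {G,T}:
# with N addition switched off, annotation boundaries are unambiguous
disjoint_alphabet_locus <- function(n = 20L) {
  toy_coding_locus(random_dna(n, c("A", "C")), random_dna(n, c("G", "T")),
                   name = "disjoint")
}

# insertion-only regime that can never be misread: flank junction-proximal
# ends use {C,T}, whose complements {G,A} are disjoint from the {C,T} N-base
# alphabet, so no N base can be reclassified as a P nucleotide (and with
# resection off the retained boundaries are exact)
pproof_insertion_locus <- function() {
  toy_coding_locus(paste0(random_dna(14), "CTCTCC"),
                   paste0("TTCCTC", random_dna(14)), name = "pproof")
}

pproof_n_composition <- c(A = 0, C = 0.5, G = 0, T = 0.5)
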