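# Independent brute-force oracle for the gap-budgeted aligner.
#
# An alignment with single-column indels is fully determined (up to the
# column order of adjacent gaps, which does not change the score) by the set
# of unpaired guide positions (RNA bulges) and unpaired target positions
# (DNA bulges); the remaining bases pair in order. Enumerating those sets
# enumerates every alignment within the gap budget.
brute_force_score <- function(guide, target, match = 1, mismatch = 0,
                              gap = -1.25, max_gaps = 3L) {
  g <- strsplit(guide, "")[[1]]
  t <- strsplit(target, "")[[1]]
  n <- length(g); m <- length(t)
  best <- -Inf
  for (g_rna in 0:max_gaps) {            # unpaired guide bases
    g_dna <- g_rna + (m - n)             # unpaired target bases
    if (g_dna < 0 || g_rna + g_dna > max_gaps) next
    if (n - g_rna < 0 || m - g_dna < 0) next
    gsets <- if (g_rna == 0) list(integer(0)) else
      asplit(utils::combn(n, g_rna), 2)
    tsets <- if (g_dna == 0) list(integer(0)) else
      asplit(utils::combn(m, g_dna), 2)
    for (gs in gsets) {
      gk <- if (length(gs)) g[-gs] else g
      for (ts in tsets) {
        tk <- if (length(ts)) t[-ts] else t
        sc <- sum(ifelse(gk == tk, match, mismatch)) +
          gap * (g_rna + g_dna)
        if (sc > best) best <- sc
      }
    }
  }
  best
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
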