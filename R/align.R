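# Bulge-aware pairwise alignment between an sgRNA spacer and a genomic site.
#
# The aligner is a Needleman-Wunsch variant with two CRISPR-specific
# components: (i) at most `max_gaps` single-column indels (bulges) over the
# whole alignment, and (ii) a protospacer-length search in which the site is
# extended or shortened by up to three nucleotides at its PAM-distal end and
# the best of the seven alignments (window lengths 17-23) is kept.

#' Align a guide against a fixed-length target window
#'
#' Global alignment under a hard gap budget: every gap is a single-column
#' indel consuming one unit of the budget (no affine extension). A gap in
#' the guide row is counted as a DNA bulge, a gap in the target row as an
#' RNA bulge. Ties resolve deterministically: fewer gaps, then fewer
#' mismatches, then gap columns placed closest to the PAM-proximal (3') end.
#'
#' @param guide a [guide_rna] or a 20-nt character sequence
#' @param target a 17-23 nt character sequence (PAM-proximal end last)
#' @param params an [alignment_params] object
#' @return an object of class `guide_target_alignment` with the aligned
#'   strings, score, match/mismatch/bulge decomposition, PAM-proximal
#'   mismatch positions (1..20 from the PAM) and mismatch base pairs
#' @examples
#' align_fixed("GAGTCCGAGCAGAAGAAGAA", "GAGTCCGAGCAGAAGAAGAA")
#' @export
align_fixed <- function(guide, target, params = alignment_params()) {
  g <- if (inherits(guide, "guide_rna")) guide$spacer else normalize_seq(guide)
  if (nchar(g) != 20L) stop("guide must be 20 nt", call. = FALSE)
  t <- normalize_seq(target)
  if (nchar(t) < 17L || nchar(t) > 23L) {
    stop("target must be 17-23 nt, got ", nchar(t), call. = FALSE)
  }
  if (abs(nchar(t) - 20L) > params$max_gaps) {
    stop("target length incompatible with gap budget", call. = FALSE)
  }
  raw <- dp_align_cpp(g, t, params$match, params$mismatch, params$gap,
                      params$max_gaps)
  new_alignment(raw, chosen_window = nchar(t), params = params)
}

new_alignment <- function(raw, chosen_window, params) {
  ag <- strsplit(raw$aligned_guide, "", fixed = TRUE)[[1]]
  at <- strsplit(raw$aligned_target, "", fixed = TRUE)[[1]]
  # PAM-proximal numbering: guide position = count of guide bases from the 3' end
  gpos <- rev(cumsum(rev(ag != "-")))
  is_mm <- ag != "-" & at != "-" & ag != at
  structure(list(
    aligned_guide = raw$aligned_guide,
    aligned_target = raw$aligned_target,
    score = raw$score,
    n_match = raw$n_match,
    n_mismatch = raw$n_mismatch,
    n_dna_bulge = raw$n_dna_bulge,
    n_rna_bulge = raw$n_rna_bulge,
    mismatch_positions = as.integer(gpos[is_mm]),
    mismatch_pairs = data.frame(
      guide = ag[is_mm],
      target_strand = complement_base(at[is_mm]),
      stringsAsFactors = FALSE),
    bulge_positions = as.integer(gpos[ag == "-" | at == "-"]),
    chosen_window = as.integer(chosen_window),
    params = params), class = "guide_target_alignment")
}

#' @export
print.guide_target_alignment <- function(x, ...) {
  cat("<guide_target_alignment> score", x$score,
      sprintf("(%dM %dX %d DNAb %d RNAb, window %d)\n", x$n_match,
              x$n_mismatch, x$n_dna_bulge, x$n_rna_bulge, x$chosen_window))
  cat(" guide : ", x$aligned_guide, "\n target: ", x$aligned_target, "\n")
  invisible(x)
}

#' Candidate protospacer windows of a target site
#'
#' Builds the PAM-proximal-anchored windows of lengths 17-23 from the site
#' sequence and its PAM-distal flank. Windows that cannot be built because
#' the flank is too short are dropped with a warning.
#'
#' @param site a [target_site], or a character sequence read as the extended
#'   PAM-distal context whose last base abuts the PAM
#' @param lengths window lengths to build
#' @return named character vector of windows (names = window length)
#' @export
target_windows <- function(site, lengths = 17:23) {
  ext <- if (inherits(site, "target_site")) {
    paste0(site$upstream_flank, site$site_seq)
  } else {
    normalize_seq(site, allow_n = TRUE)
  }
  L <- nchar(ext)
  ok <- lengths <= L
  if (!any(ok)) stop("no constructible window: context too short", call. = FALSE)
  if (!all(ok)) {
    warning("insufficient PAM-distal flank: windows truncated to lengths ",
            paste(lengths[ok], collapse = ","), call. = FALSE)
  }
  w <- vapply(lengths[ok], function(k) substr(ext, L - k + 1L, L), character(1))
  names(w) <- lengths[ok]
  w
}

#' Best-of-seven window alignment
#'
#' Runs [align_fixed] on each constructible window (lengths 17-23 anchored
#' at the PAM-proximal end) and returns the highest-scoring alignment with
#' its `chosen_window` recorded. Equal scores prefer the window closest to
#' 20 nt (then the shorter one), so a gapless 20-nt alignment is never
#' displaced by a tie.
#'
#' @inheritParams target_windows
#' @param guide a [guide_rna] or 20-nt sequence
#' @param params an [alignment_params]
#' @return a `guide_target_alignment`
#' @export
align_best_window <- function(guide, site, params = alignment_params()) {
  g <- if (inherits(guide, "guide_rna")) guide$spacer else normalize_seq(guide)
  w <- target_windows(site)
  w <- w[abs(as.integer(names(w)) - 20L) <= params$max_gaps]
  if (!length(w)) stop("no window compatible with the gap budget", call. = FALSE)
  scores <- dp_score_batch_cpp(rep(g, length(w)), unname(w), params$match,
                               params$mismatch, params$gap, params$max_gaps)
  lens <- as.integer(names(w))
  pref <- order(-scores, abs(lens - 20L), lens)
  best <- pref[1L]
  aln <- align_fixed(g, w[[best]], params)
  aln$chosen_window <- lens[best]
  aln
}

default_param_grid <- function() {
  expand.grid(mismatch = seq(0, -1.5, by = -0.25),
              gap = seq(-0.25, -3, by = -0.25))
}

#' Optimize alignment parameters against cleavage intensities
#'
#' Sweeps a (mismatch, gap) grid with the match reward fixed at 1; for each
#' grid point computes, per guide, the squared Pearson correlation between
#' best-window alignment scores and cleavage frequencies over non-exact-match
#' targets, averages the r-squared across guides, and returns the argmax.
#' Ties resolve toward the least-negative gap penalty, then the
#' least-negative mismatch penalty.
#'
#' @param records data frame with columns `guide_id`, `guide_seq`,
#'   `site_seq`, `up_flank`, and `freq` (cleavage frequency/intensity)
#' @param grid data frame of candidate `mismatch` and `gap` values
#' @param max_gaps gap budget applied at every grid point
#' @return the selected [alignment_params]; attribute `"r2"` carries the
#'   averaged r-squared achieved, `"surface"` the full grid with scores
#' @export
optimize_params <- function(records, grid = default_param_grid(),
                            max_gaps = 3L) {
  stopifnot(all(c("guide_id", "guide_seq", "site_seq", "freq") %in%
                  names(records)))
  up <- if ("up_flank" %in% names(records)) records$up_flank else ""
  ext <- paste0(ifelse(is.na(up), "", up), records$site_seq)
  # drop exact-match targets (their score is maximal by construction)
  L <- nchar(ext)
  win20 <- substr(ext, pmax(1L, L - 19L), L)
  keep <- win20 != records$guide_seq
  records <- records[keep, , drop = FALSE]
  ext <- ext[keep]
  if (!nrow(records)) stop("no non-exact-match targets", call. = FALSE)

  counts <- table(records$guide_id)
  bad <- names(counts)[counts < 2L]
  if (length(bad) == length(counts)) {
    stop("degenerate guide set: fewer than 2 non-exact-match targets for ",
         "every guide (e.g. ", bad[1L], ")", call. = FALSE)
  }
  use <- records$guide_id %in% names(counts)[counts >= 2L]
  records <- records[use, , drop = FALSE]
  ext <- ext[use]

  # windows for every record, grouped back to records inside the C++ sweep
  wlist <- lapply(ext, function(e) {
    lens <- 17:23
    lens <- lens[lens <= nchar(e) & abs(lens - 20L) <= max_gaps]
    vapply(lens, function(k) substr(e, nchar(e) - k + 1L, nchar(e)), character(1))
  })
  nw <- lengths(wlist)
  if (any(nw == 0L)) stop("record with no constructible window", call. = FALSE)
  gvec <- rep(records$guide_seq, nw)
  tvec <- unlist(wlist, use.names = FALSE)
  group <- rep(seq_len(nrow(records)) - 1L, nw)
  mism <- grid$mismatch
  gaps <- grid$gap
  mm_u <- sort(unique(mism), decreasing = TRUE)
  gp_u <- sort(unique(gaps), decreasing = TRUE)
  scores <- dp_score_grid_cpp(gvec, tvec, group, nrow(records), 1.0,
                              mm_u, gp_u, as.integer(max_gaps))

  guides <- split(seq_len(nrow(records)), records$guide_id)
  grid_full <- expand.grid(mismatch = mm_u, gap = gp_u)  # matches column order
  r2_bar <- vapply(seq_len(ncol(scores)), function(k) {
    r2 <- vapply(guides, function(idx) {
      s <- scores[idx, k]; f <- records$freq[idx]
      if (stats::sd(s) == 0 || stats::sd(f) == 0) return(NA_real_)
      stats::cor(s, f)^2
    }, numeric(1))
    mean(r2, na.rm = TRUE)
  }, numeric(1))
  if (all(is.nan(r2_bar) | is.na(r2_bar))) {
    const_guides <- names(guides)[vapply(guides, function(idx) {
      all(apply(scores[idx, , drop = FALSE], 2, stats::sd) == 0)
    }, logical(1))]
    stop("constant alignment scores for every grid point (guide ",
         paste(const_guides, collapse = ", "), ")", call. = FALSE)
  }
  best_val <- max(r2_bar, na.rm = TRUE)
  # tie-break: least-negative gap, then least-negative mismatch; grid rows
  # are already ordered gap desc within mismatch desc blocks
  ord <- order(-grid_full$gap, -grid_full$mismatch)
  cand <- ord[r2_bar[ord] >= best_val - 1e-12 & !is.na(r2_bar[ord])]
  pick <- cand[1L]
  out <- alignment_params(match = 1, mismatch = grid_full$mismatch[pick],
                          gap = grid_full$gap[pick], max_gaps = max_gaps)
  attr(out, "r2") <- r2_bar[pick]
  attr(out, "surface") <- cbind(grid_full, r2 = r2_bar)
  out
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    g <- as.character(genome)
  } else if (is.character(genome)) {
    g <- toupper(genome)
  } else {
    stop("genome must be a named character vector or DNAStringSet",
         call. = FALSE)
  }
  if (is.null(names(g)) || any(!nzchar(names(g)))) {
    stop("genome contigs must be named", call. = FALSE)
  }
  g
}

#' Batch alignment scores (low level)
#'
#' Optimal gap-budgeted alignment score for each guide/target pair, without
#' traceback. Unlike [align_fixed] no length constraints are imposed beyond
#' feasibility under the gap budget, which makes this the natural entry
#' point for property checks against enumeration oracles.
#'
#' @param guides,targets equal-length character vectors
#' @param params an [alignment_params]
#' @return numeric scores (NA where the length difference exceeds the
#'   budget)
#' @export
alignment_score_batch <- function(guides, targets,
                                  params = alignment_params()) {
  dp_score_batch_cpp(as.character(guides), as.character(targets),
                     params$match, params$mismatch, params$gap,
                     params$max_gaps)
}

#' Fetch a genomic interval
#'
#' Returns the sequence of `[start, end)` (0-based half-open, forward
#' strand), reverse-complemented when `strand` is `"-"`.
#'
#' @param genome named character vector or `DNAStringSet`
#' @param seq_id contig
#' @param start,end interval
#' @param strand "+" or "-"
#' @return character sequence
#' @export
genome_fetch <- function(genome, seq_id, start, end, strand = "+") {
  if (!seq_id %in% names(genome)) {
    stop("unknown contig: ", seq_id, call. = FALSE)
  }
  g <- genome[[seq_id]]
  if (start < 0L || end > nchar(g) || start > end) {
    stop("coordinates outside contig ", seq_id, call. = FALSE)
  }
  s <- substr(g, start + 1L, end)
  if (strand == "-") revcomp(s) else s
}

#' Build a target site from genome coordinates
#'
#' Extracts the protospacer, its PAM (3 nt immediately 3' of the protospacer
#' in the site's orientation) and up to `flank` nt of context on each side,
#' truncating at contig ends.
#'
#' @param genome named character vector (or `DNAStringSet`) of contigs
#' @param seq_id contig name
#' @param start,end protospacer coordinates, 0-based half-open, forward strand
#' @param strand "+" or "-"
#' @param flank flank length to attach (nt)
#' @return a [target_site]
#' @export
site_from_genome <- function(genome, seq_id, start, end, strand = "+",
                             flank = 100L) {
  genome <- as_genome(genome)
  if (!seq_id %in% names(genome)) {
    stop("unknown contig: ", seq_id, call. = FALSE)
  }
  clen <- nchar(genome[[seq_id]])
  if (start < 0L || end > clen) stop("coordinates outside contig", call. = FALSE)
  if (strand == "+") {
    pam <- genome_fetch(genome, seq_id, end, min(clen, end + 3L), "+")
    up <- genome_fetch(genome, seq_id, max(0L, start - flank), start, "+")
    dn <- genome_fetch(genome, seq_id, min(clen, end + 3L),
                       min(clen, end + 3L + flank), "+")
  } else {
    pam <- genome_fetch(genome, seq_id, max(0L, start - 3L), start, "-")
    up <- genome_fetch(genome, seq_id, end, min(clen, end + flank), "-")
    dn <- genome_fetch(genome, seq_id, max(0L, start - 3L - flank),
                       max(0L, start - 3L), "-")
  }
  if (nchar(pam) != 3L) stop("PAM truncated by contig end", call. = FALSE)
  target_site(seq_id, start, end, strand,
              genome_fetch(genome, seq_id, start, end, strand), pam,
              upstream_flank = up, downstream_flank = dn)
}

#' Relocate a non-canonical PAM to the nearest NGG or NAG
#'
#' Scans PAM shifts of 0, +1, -1, +2, -2 nt (downstream first at equal
#' distance, in the site's own orientation) for an NGG PAM; failing that,
#' the same order for an NAG PAM; failing that, the site is returned
#' unchanged. The protospacer window shifts consistently with the PAM.
#'
#' @param site a [target_site]
#' @param genome the genome the site's coordinates refer to
#' @param flank flank length on the rebuilt site
#' @return a [target_site]; attribute `"pam_shift"` records the shift applied
#' @export
relocate_pam <- function(site, genome, flank = 100L) {
  genome <- as_genome(genome)
  shifts <- c(0L, 1L, -1L, 2L, -2L)
  dir <- if (site$strand == "+") 1L else -1L
  pam_at <- function(k) {
    st <- site$start + k * dir; en <- site$end + k * dir
    clen <- nchar(genome[[site$seq_id]])
    if (st < 0L || en > clen) return(NA_character_)
    if (site$strand == "+") {
      if (en + 3L > clen) return(NA_character_)
      genome_fetch(genome, site$seq_id, en, en + 3L, "+")
    } else {
      if (st - 3L < 0L) return(NA_character_)
      genome_fetch(genome, site$seq_id, st - 3L, st, "-")
    }
  }
  pams <- vapply(shifts, pam_at, character(1))
  pick <- function(motif) {
    hit <- which(!is.na(pams) & substr(pams, 2L, 3L) == motif)
    if (length(hit)) shifts[hit[1L]] else NA_integer_
  }
  k <- pick("GG")
  if (is.na(k)) k <- pick("AG")
  if (is.na(k) || k == 0L) {
    out <- site
    attr(out, "pam_shift") <- 0L
    return(out)
  }
  out <- site_from_genome(genome, site$seq_id, site$start + k * dir,
                          site$end + k * dir, site$strand, flank = flank)
  attr(out, "pam_shift") <- k
  out
}

#' Realignment statistics for a record table
#'
#' Re-aligns every record with and without the gap budget and summarizes the
#' effect of allowing bulges: fraction and count of targets whose best
#' alignment contains a bulge, mean mismatch and matched-base counts, and
#' the per-guide averaged r-squared between alignment score and cleavage
#' frequency with gaps allowed versus disallowed.
#'
#' @param records record table with `guide_id`, `guide_seq`, `site_seq`,
#'   `up_flank`, `freq`
#' @param params [alignment_params] used for the gapped alignment
#' @return a list of summary statistics
#' @export
realignment_stats <- function(records, params = alignment_params()) {
  gapped <- lapply(seq_len(nrow(records)), function(i) {
    align_best_window(records$guide_seq[i],
                      paste0(records$up_flank[i], records$site_seq[i]), params)
  })
  gapless_params <- alignment_params(params$match, params$mismatch,
                                     gap = -4 * params$match * 20, max_gaps = 0L)
  gapless_score <- vapply(seq_len(nrow(records)), function(i) {
    ext <- paste0(records$up_flank[i], records$site_seq[i])
    w20 <- substr(ext, nchar(ext) - 19L, nchar(ext))
    align_fixed(records$guide_seq[i], w20, gapless_params)$score
  }, numeric(1))
  n_bulge <- vapply(gapped, function(a) a$n_dna_bulge + a$n_rna_bulge, numeric(1))
  score <- vapply(gapped, `[[`, numeric(1), "score")
  per_guide_r2 <- function(s) {
    sp <- split(seq_along(s), records$guide_id)
    r2 <- vapply(sp, function(idx) {
      if (length(idx) < 2L || stats::sd(s[idx]) == 0 ||
          stats::sd(records$freq[idx]) == 0) return(NA_real_)
      stats::cor(s[idx], records$freq[idx])^2
    }, numeric(1))
    mean(r2, na.rm = TRUE)
  }
  list(n_targets = nrow(records),
       n_with_bulges = sum(n_bulge > 0),
       frac_with_bulges = mean(n_bulge > 0),
       mean_bulges_when_present = if (any(n_bulge > 0))
         mean(n_bulge[n_bulge > 0]) else NA_real_,
       mean_mismatches = mean(vapply(gapped, `[[`, numeric(1), "n_mismatch")),
       mean_matches = mean(vapply(gapped, `[[`, numeric(1), "n_match")),
       r2_gapped = per_guide_r2(score),
       r2_gapless = per_guide_r2(gapless_score))
}
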