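# Training-set assembly: exhaustive mining of uncleaved candidate sites
# from a genome, study-level deduplication, and the class-balanced bootstrap
# rounds used for ensemble training.

find_pam_starts <- function(seq, motif2) {
  # 0-based PAM start positions s where bases 2-3 of the PAM match motif2
  hits <- gregexpr(paste0("(?=", motif2, ")"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 2L   # GG/AG sits at PAM offset 1; PAM start is 0-based
}

scan_strand <- function(contig_seq, pam_motifs) {
  motifs2 <- substr(pam_motifs, 2L, 3L)
  s <- sort(unique(unlist(lapply(motifs2, find_pam_starts, seq = contig_seq))))
  s[s >= 17L]   # need at least a 17-nt window upstream of the PAM
}

#' Mine uncleaved candidate sites for a guide from a genome
#'
#' Exhaustively scans both strands for NGG/NAG PAMs, aligns the guide to
#' the PAM-proximal-anchored windows upstream of each PAM with
#' [align_best_window] scoring, and retains sites whose best score strictly
#' exceeds `min_score` and that do not overlap any known cleaved interval
#' of the same guide.
#'
#' @param guide a [guide_rna] or 20-nt sequence
#' @param genome named character vector or `DNAStringSet`
#' @param params [alignment_params]
#' @param min_score retention threshold (strict inequality)
#' @param pam_motifs PAM motifs to scan (N is a wildcard first base)
#' @param exclude data frame of cleaved intervals for this guide (`chrom`,
#'   `start`, `end`, `strand`); overlapping candidates are dropped
#' @param flank flank length attached to returned sites
#' @return data frame of candidate sites with alignment `score`
#' @export
mine_negatives <- function(guide, genome, params = alignment_params(),
                           min_score = 14.75, pam_motifs = c("NGG", "NAG"),
                           exclude = NULL, flank = 100L) {
  g <- if (inherits(guide, "guide_rna")) guide$spacer else normalize_seq(guide)
  genome <- as_genome(genome)
  out <- list()
  for (contig in names(genome)) {
    seq_f <- genome[[contig]]
    Lc <- nchar(seq_f)
    for (strand in c("+", "-")) {
      s_seq <- if (strand == "+") seq_f else revcomp(seq_f)
      pam_starts <- scan_strand(s_seq, pam_motifs)
      if (!length(pam_starts)) next
      # extended PAM-distal context (up to 23 nt ending at the PAM)
      ext <- substring(s_seq, pmax(1L, pam_starts - 23L + 1L), pam_starts)
      wins <- lapply(ext, function(e) {
        lens <- 17:23
        lens <- lens[lens <= nchar(e) & abs(lens - 20L) <= params$max_gaps]
        vapply(lens, function(k)
          substr(e, nchar(e) - k + 1L, nchar(e)), character(1))
      })
      nw <- lengths(wins)
      keep <- nw > 0L
      pam_starts <- pam_starts[keep]; wins <- wins[keep]; nw <- nw[keep]
      if (!length(pam_starts)) next
      tvec <- unlist(wins, use.names = FALSE)
      group <- rep(seq_along(pam_starts) - 1L, nw)
      scores <- dp_score_grid_cpp(rep(g, length(tvec)), tvec, group,
                                  length(pam_starts), params$match,
                                  params$mismatch, params$gap,
                                  params$max_gaps)[, 1L]
      hit <- which(!is.na(scores) & scores > min_score)
      for (k in hit) {
        s0 <- pam_starts[k]          # 0-based PAM start on this strand's seq
        if (strand == "+") {
          st <- s0 - 20L; en <- s0
        } else {
          st <- Lc - s0; en <- Lc - s0 + 20L
        }
        if (st < 0L || en > Lc) next
        site <- site_from_genome(genome, contig, st, en, strand, flank = flank)
        out[[length(out) + 1L]] <- data.frame(
          chrom = contig, start = st, end = en, strand = strand,
          site_seq = site$site_seq, pam = site$pam,
          up_flank = site$upstream_flank, down_flank = site$downstream_flank,
          score = scores[k], stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), site_seq = character(0),
               pam = character(0), up_flank = character(0),
               down_flank = character(0), score = numeric(0),
               stringsAsFactors = FALSE)
  if (!is.null(exclude) && nrow(res)) {
    drop <- vapply(seq_len(nrow(res)), function(i) {
      any(exclude$chrom == res$chrom[i] & exclude$strand == res$strand[i] &
            exclude$start < res$end[i] & exclude$end > res$start[i])
    }, logical(1))
    res <- res[!drop, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Deduplicate guide collections across studies and drop excluded studies
#'
#' Guides profiled in several studies keep only the designated reference
#' study's collection (the most comprehensive platform); records from
#' excluded studies are removed entirely. If a duplicated guide is absent
#' from the reference study, the study with the most targets for that guide
#' is kept, with a warning.
#'
#' @param records record table with `study` and `guide_id`
#' @param reference_study study whose collections win for duplicated guides
#' @param exclude_studies studies removed outright
#' @return the filtered record table
#' @export
deduplicate <- function(records, reference_study = "Tsai",
                        exclude_studies = "Frock") {
  stopifnot(all(c("study", "guide_id") %in% names(records)))
  records <- records[!records$study %in% exclude_studies, , drop = FALSE]
  keep <- rep(TRUE, nrow(records))
  for (gid in unique(records$guide_id)) {
    sel <- records$guide_id == gid
    studies <- unique(records$study[sel])
    if (length(studies) <= 1L) next
    if (reference_study %in% studies) {
      chosen <- reference_study
    } else {
      counts <- table(records$study[sel])
      chosen <- names(counts)[which.max(counts)]
      warning("guide ", gid, " duplicated without reference study; keeping ",
              chosen, call. = FALSE)
    }
    keep[sel & records$study != chosen] <- FALSE
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

is_positive_record <- function(records) {
  if ("target_value" %in% names(records)) {
    records$target_value > 0
  } else if ("reads" %in% names(records)) {
    records$reads > 0
  } else {
    stop("records need a target_value or reads column", call. = FALSE)
  }
}

#' Draw one class-balanced bootstrap training round
#'
#' Per guide: the cleaved set is bootstrapped (with replacement) to twice
#' its original size, and an equal number of uncleaved records is sampled
#' uniformly without replacement, balancing the two classes while exposing
#' a wide repertoire of uncleaved sites across rounds.
#'
#' @param records record table (positives have `target_value > 0` or
#'   `reads > 0`)
#' @param seed integer seed for this round
#' @return the sampled record table; attribute `"round_seed"` records the
#'   seed
#' @export
sample_round <- function(records, seed) {
  pos <- is_positive_record(records)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  picked <- integer(0)
  for (gid in unique(records$guide_id)) {
    ip <- which(pos & records$guide_id == gid)
    ineg <- which(!pos & records$guide_id == gid)
    if (!length(ip)) next
    want <- 2L * length(ip)
    if (length(ineg) < want) {
      stop("guide ", gid, " has ", length(ineg),
           " uncleaved records; needs >= ", want, call. = FALSE)
    }
    picked <- c(picked, sample(ip, want, replace = TRUE),
                sample(ineg, want, replace = FALSE))
  }
  out <- records[picked, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "round_seed") <- as.integer(seed)
  attr(out, "indices") <- picked
  out
}

#' Seeds for the sampled training rounds
#'
#' @param master_seed integer master seed
#' @param rounds number of rounds
#' @return integer vector of per-round seeds (kept below 2^31)
#' @export
round_seeds <- function(master_seed, rounds = 100L) {
  (as.integer(master_seed) + 7919L * seq_len(rounds)) %% .Machine$integer.max
}
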