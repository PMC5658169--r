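# Readers/writers for the tabular record schema and FASTA genomes, plus the
# two sequence-level conveniences the command-line tool binds (scoring
# explicit guide/site pairs; ranking candidate sites within a sequence).

SCHEMA_VERSION <- "1.0"
SCHEMA_HEADER <- paste0("# offtargetr-records v", SCHEMA_VERSION)
REQUIRED_COLUMNS <- c("guide_id", "guide_seq", "chrom", "start", "end",
                      "strand", "site_seq")

#' Write a record table
#'
#' CSV with a schema-version header line; unknown columns pass through.
#'
#' @param records record table
#' @param path output path
#' @export
write_records <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(SCHEMA_HEADER, con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

detect_delim <- function(line) {
  if (lengths(regmatches(line, gregexpr("\t", line))) >
      lengths(regmatches(line, gregexpr(",", line)))) "\t" else ","
}

#' Read a record table
#'
#' Accepts comma- or tab-delimited text (auto-detected). Files written by
#' [write_records] carry a schema-version header; an unknown major version
#' is refused. Coordinates are normalized to 0-based half-open via the
#' explicit `coords` dialect flag (no guessing). Rows whose site sequence
#' is malformed (wrong length or alphabet) are quarantined with a warning
#' and returned in the `"quarantined"` attribute.
#'
#' @param path input path
#' @param coords `"bed0"` (0-based half-open) or `"1based"` (1-based
#'   inclusive; start is decremented)
#' @param genome optional genome for strand-aware sequence verification;
#'   mismatching rows are counted in a warning
#' @return record table (0-based half-open coordinates)
#' @export
read_records <- function(path, coords = c("bed0", "1based"), genome = NULL) {
  coords <- match.arg(coords)
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (startsWith(first, "# offtargetr-records")) {
    ver <- sub("^# offtargetr-records v", "", first)
    major <- strsplit(ver, ".", fixed = TRUE)[[1]][1]
    if (major != strsplit(SCHEMA_VERSION, ".", fixed = TRUE)[[1]][1]) {
      stop("unsupported records schema major version: ", ver, call. = FALSE)
    }
    skip <- 1L
    header_line <- readLines(path, n = 2L)[2L]
  } else {
    header_line <- first
  }
  sep <- detect_delim(header_line)
  rec <- utils::read.table(path, header = TRUE, sep = sep, skip = skip,
                           stringsAsFactors = FALSE, comment.char = "")
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(rec))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (coords == "1based") rec$start <- rec$start - 1L
  ok <- !is.na(rec$site_seq) & grepl("^[ACGTUacgtu]{17,23}$", rec$site_seq)
  quarantined <- rec[!ok, , drop = FALSE]
  if (nrow(quarantined)) {
    warning(nrow(quarantined), " malformed row(s) quarantined", call. = FALSE)
  }
  rec <- rec[ok, , drop = FALSE]
  rec$site_seq <- normalize_seq(rec$site_seq)
  rec$guide_seq <- normalize_seq(rec$guide_seq)
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    bad <- 0L
    for (i in seq_len(nrow(rec))) {
      got <- tryCatch(genome_fetch(genome, rec$chrom[i], rec$start[i],
                                   rec$end[i], rec$strand[i]),
                      error = function(e) NA_character_)
      if (is.na(got) || got != rec$site_seq[i]) bad <- bad + 1L
    }
    if (bad) warning(bad, " row(s) disagree with the genome sequence",
                     call. = FALSE)
  }
  rownames(rec) <- NULL
  attr(rec, "quarantined") <- quarantined
  rec
}

#' Read a genome FASTA
#'
#' @param path FASTA file
#' @return named character vector of contigs
#' @export
read_genome <- function(path) {
  as_genome(Biostrings::readDNAStringSet(path))
}

#' Write a genome FASTA
#'
#' @param genome named character vector
#' @param path output path
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(as_genome(genome))), path)
  invisible(path)
}

#' Score explicit guide/site pairs
#'
#' Aligns each pair with the best-window search; when a trained ensemble is
#' supplied the predicted cleavage propensity is added.
#'
#' @param pairs data frame with `guide_seq` and `site_seq` (plus optional
#'   `up_flank`, `down_flank`, `pam`)
#' @param params [alignment_params]
#' @param model optional `cleavage_ensemble`
#' @return `pairs` with alignment columns (and `score` when a model is
#'   given)
#' @export
score_pairs <- function(pairs, params = alignment_params(), model = NULL) {
  fm <- feature_matrix(pairs, params)
  out <- cbind(pairs,
               fm[, c("alignment_score", "chosen_window", "n_mismatch",
                      "n_dna_bulge", "n_rna_bulge")])
  if (!is.null(model)) out$score <- predict(model, fm)$score
  rownames(out) <- NULL
  out
}

#' Rank candidate target sites within a sequence
#'
#' Enumerates every NGG-followed window on both strands of the input
#' sequence, aligns the guide to each, and ranks candidates by predicted
#' propensity (when a model is given) or by alignment score.
#'
#' @param guide a [guide_rna] or 20-nt sequence
#' @param sequence the nucleotide sequence to scan
#' @param params [alignment_params]
#' @param model optional `cleavage_ensemble`
#' @param pam_motifs PAM motifs to accept
#' @return ranked data frame of candidates
#' @export
rank_within <- function(guide, sequence, params = alignment_params(),
                        model = NULL, pam_motifs = "NGG") {
  g <- if (inherits(guide, "guide_rna")) guide$spacer else normalize_seq(guide)
  sequence <- normalize_seq(sequence, allow_n = TRUE)
  cand <- mine_negatives(g, c(query = sequence), params, min_score = -Inf,
                         pam_motifs = pam_motifs, flank = 100L)
  if (!nrow(cand)) return(cand)
  if (!is.null(model)) {
    cand$guide_seq <- g
    fm <- feature_matrix(cand, params)
    cand$score_model <- predict(model, fm)$score
    cand <- cand[order(-cand$score_model), , drop = FALSE]
  } else {
    cand <- cand[order(-cand$score), , drop = FALSE]
  }
  rownames(cand) <- NULL
  cand
}
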