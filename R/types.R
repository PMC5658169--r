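#' @useDynLib offtargetr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Normalize a nucleotide sequence to the DNA alphabet
#'
#' Uppercases and maps U to T. Errors on any residual non-ACGT symbol unless
#' `allow_n = TRUE`, in which case N is tolerated (ambiguity handled
#' downstream by the consumer).
#'
#' @param x character vector of sequences
#' @param allow_n tolerate N symbols
#' @return normalized character vector
#' @keywords internal
normalize_seq <- function(x, allow_n = FALSE) {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop("non-ACGT symbol in sequence: ", substr(x[bad][1], 1, 40),
         call. = FALSE)
  }
  x
}

#' Construct a guide RNA
#'
#' A named 20-nt spacer, stored DNA-equivalent (U mapped to T), written
#' 5'->3' so the last base is PAM-proximal.
#'
#' @param id label for the guide
#' @param spacer 20-symbol sequence over ACGT/U
#' @return an object of class `guide_rna` with fields `id` and `spacer`
#' @examples
#' guide_rna("EMX1", "GAGTCCGAGCAGAAGAAGAA")
#' @export
guide_rna <- function(id, spacer) {
  spacer <- normalize_seq(spacer)
  if (nchar(spacer) != 20L) {
    stop("spacer must be exactly 20 nt, got ", nchar(spacer), call. = FALSE)
  }
  structure(list(id = as.character(id), spacer = spacer), class = "guide_rna")
}

#' @export
print.guide_rna <- function(x, ...) {
  cat("<guide_rna>", x$id, x$spacer, "\n")
  invisible(x)
}

#' Construct a genomic target site
#'
#' A stranded protospacer window with its PAM and flanking context.
#' Coordinates are 0-based half-open on the forward strand; minus-strand
#' sites store the reverse-complemented protospacer so `site_seq` always
#' reads 5'->3' with the PAM on its 3' side. `downstream_flank` is the
#' sequence immediately 3' of the PAM; `upstream_flank` immediately 5' of
#' the protospacer.
#'
#' @param seq_id contig/chromosome label
#' @param start,end integer protospacer coordinates (0-based half-open)
#' @param strand "+" or "-"
#' @param site_seq 17-23 nt protospacer sequence
#' @param pam 3-nt PAM
#' @param upstream_flank,downstream_flank flanking sequences (may be empty
#'   near contig ends; >= 100 nt each when available)
#' @return an object of class `target_site`
#' @export
target_site <- function(seq_id, start, end, strand, site_seq, pam,
                        upstream_flank = "", downstream_flank = "") {
  site_seq <- normalize_seq(site_seq)
  pam <- normalize_seq(pam, allow_n = TRUE)
  upstream_flank <- normalize_seq(upstream_flank, allow_n = TRUE)
  downstream_flank <- normalize_seq(downstream_flank, allow_n = TRUE)
  L <- nchar(site_seq)
  if (L < 17L || L > 23L) {
    stop("site_seq must be 17-23 nt, got ", L, call. = FALSE)
  }
  if (nchar(pam) != 3L) stop("pam must be exactly 3 nt", call. = FALSE)
  start <- as.integer(start); end <- as.integer(end)
  if (!is.na(start) && !is.na(end) && end - start != L) {
    stop("end - start (", end - start, ") must equal nchar(site_seq) (", L, ")",
         call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  structure(list(seq_id = as.character(seq_id), start = start, end = end,
                 strand = strand, site_seq = site_seq, pam = pam,
                 upstream_flank = upstream_flank,
                 downstream_flank = downstream_flank),
            class = "target_site")
}

#' @export
print.target_site <- function(x, ...) {
  cat(sprintf("<target_site> %s:%d-%d(%s) %s PAM=%s\n",
              x$seq_id, x$start, x$end, x$strand, x$site_seq, x$pam))
  invisible(x)
}

#' Alignment scoring parameters
#'
#' Match reward, mismatch and gap penalties, and the gap budget for the
#' bulge-aware alignment. The defaults are the values selected by grid
#' optimization against cleavage intensities: match 1, mismatch 0,
#' gap -1.25, and at most 3 single-column gaps.
#'
#' @param match match reward (> 0)
#' @param mismatch mismatch penalty (<= 0)
#' @param gap gap (bulge) penalty (< 0)
#' @param max_gaps maximum number of gap columns over the whole alignment
#' @return an object of class `alignment_params`
#' @export
alignment_params <- function(match = 1, mismatch = 0, gap = -1.25,
                             max_gaps = 3L) {
  if (!is.numeric(match) || match <= 0) stop("match must be > 0", call. = FALSE)
  if (!is.numeric(mismatch) || mismatch > 0) {
    stop("mismatch must be <= 0", call. = FALSE)
  }
  if (!is.numeric(gap) || gap >= 0) stop("gap must be < 0", call. = FALSE)
  max_gaps <- as.integer(max_gaps)
  if (max_gaps < 0L) stop("max_gaps must be >= 0", call. = FALSE)
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 max_gaps = max_gaps),
            class = "alignment_params")
}

#' @export
print.alignment_params <- function(x, ...) {
  cat(sprintf("<alignment_params> match=%g mismatch=%g gap=%g max_gaps=%d\n",
              x$match, x$mismatch, x$gap, x$max_gaps))
  invisible(x)
}

#' Reverse-complement a DNA string
#'
#' @param x character vector of ACGTN sequences
#' @return reverse complements
#' @export
revcomp <- function(x) {
  out <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

gc_fraction <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  ifelse(n > 0, gc / n, NA_real_)
}
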