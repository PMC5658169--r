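# Cross-study harmonization of cleavage read counts.
#
# Raw read counts from different detection platforms are not directly
# comparable. Counts are log-transformed (the transformed counts are
# approximately normal), each study is mapped onto the reference (GUIDE-seq)
# scale by ordinary least squares over the guide/site pairs it shares with
# the reference study, and the regression target is the harmonized value
# divided by the dataset maximum, so the label lives in [0, 1] with
# uncleaved sites at exactly 0.

#' Log-transform read counts
#'
#' `log(reads + pseudocount)` in the configured base.
#'
#' @param raw_reads non-negative counts
#' @param base logarithm base
#' @param pseudocount added before taking the log
#' @return transformed values
#' @export
log_transform <- function(raw_reads, base = 10, pseudocount = 1) {
  if (any(raw_reads < 0, na.rm = TRUE)) {
    stop("raw_reads must be non-negative", call. = FALSE)
  }
  log(raw_reads + pseudocount, base = base)
}

#' Invert [log_transform]
#' @param x transformed values
#' @inheritParams log_transform
#' @return raw counts
#' @export
unlog_transform <- function(x, base = 10, pseudocount = 1) {
  base^x - pseudocount
}

shared_key_match <- function(study_records, reference_records, slack = 2L) {
  # shared targets: identical guide, same contig and strand, protospacer
  # intervals overlapping within +/- slack nt (PAM relocation shifts
  # coordinates by up to 2)
  a <- study_records; b <- reference_records
  idx <- lapply(seq_len(nrow(a)), function(i) {
    j <- which(b$guide_id == a$guide_id[i] & b$chrom == a$chrom[i] &
                 b$strand == a$strand[i] &
                 b$start < a$end[i] + slack & b$end > a$start[i] - slack)
    if (length(j)) j[1L] else NA_integer_
  })
  cbind(i = seq_len(nrow(a)), j = unlist(idx))
}

#' Fit a per-study linear calibration onto the reference scale
#'
#' OLS of the reference log counts on the study log counts over the shared
#' (guide, site) pairs: `log_ref = slope * log_study + intercept`.
#'
#' @param study_records record table for one study (`guide_id`, `chrom`,
#'   `start`, `end`, `strand`, `reads`)
#' @param reference_records record table for the reference study
#' @param base,pseudocount passed to [log_transform]
#' @param slack interval slack (nt) when matching shared targets
#' @return an object of class `study_calibration`: slope, intercept,
#'   n_shared, fit_r2, and the fitted `lm`
#' @export
fit_calibration <- function(study_records, reference_records, base = 10,
                            pseudocount = 1, slack = 2L) {
  m <- shared_key_match(study_records, reference_records, slack)
  m <- m[!is.na(m[, "j"]), , drop = FALSE]
  if (nrow(m) < 2L) {
    stop("fewer than 2 shared targets between study and reference",
         call. = FALSE)
  }
  x <- log_transform(study_records$reads[m[, "i"]], base, pseudocount)
  y <- log_transform(reference_records$reads[m[, "j"]], base, pseudocount)
  if (stats::sd(x) == 0) {
    stop("zero variance in study log counts over shared targets",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  structure(list(
    study = if ("study" %in% names(study_records))
      study_records$study[1L] else NA_character_,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    n_shared = nrow(m),
    fit_r2 = stats::cor(x, y)^2,
    fit = fit), class = "study_calibration")
}

#' @export
print.study_calibration <- function(x, ...) {
  cat(sprintf("<study_calibration> %s: ref = %.4g * study + %.4g (n=%d, r2=%.3f)\n",
              x$study, x$slope, x$intercept, x$n_shared, x$fit_r2))
  invisible(x)
}

#' Harmonize all studies onto the reference scale
#'
#' Adds `log_reads` and `harmonized` columns. Records of the reference
#' study keep their log counts; every other study is mapped through its
#' fitted calibration. Uncleaved records (zero reads) get harmonized 0.
#'
#' @param records combined record table with a `study` column
#' @param reference_study the study defining the common scale
#' @inheritParams fit_calibration
#' @return records with `log_reads` and `harmonized` columns; attribute
#'   `"calibrations"` holds the fitted `study_calibration`s
#' @export
harmonize_studies <- function(records, reference_study = "Tsai", base = 10,
                              pseudocount = 1, slack = 2L) {
  stopifnot("study" %in% names(records), "reads" %in% names(records))
  records$log_reads <- log_transform(records$reads, base, pseudocount)
  records$harmonized <- records$log_reads
  ref <- records[records$study == reference_study & records$reads > 0, ,
                 drop = FALSE]
  if (!nrow(ref)) stop("reference study has no cleaved records", call. = FALSE)
  cals <- list()
  for (st in setdiff(unique(records$study), reference_study)) {
    sel <- records$study == st & records$reads > 0
    if (!any(sel)) next
    cal <- fit_calibration(records[sel, , drop = FALSE], ref, base,
                           pseudocount, slack)
    records$harmonized[sel] <- cal$slope * records$log_reads[sel] +
      cal$intercept
    cals[[st]] <- cal
  }
  records$harmonized[records$reads == 0] <- 0
  attr(records, "calibrations") <- cals
  records
}

#' Finalize regression targets
#'
#' Divides harmonized values by the dataset maximum over cleaved records;
#' negatives (possible after calibration of very low counts) are clamped to
#' 0 so the target lives in [0, 1] and uncleaved records sit at exactly 0.
#'
#' @param records harmonized record table
#' @return records with a `target_value` column
#' @export
finalize_targets <- function(records) {
  stopifnot("harmonized" %in% names(records))
  pos <- records$harmonized[records$reads > 0]
  if (!length(pos) || max(pos) <= 0) {
    stop("no cleaved records with positive harmonized value", call. = FALSE)
  }
  tv <- records$harmonized / max(pos)
  tv[tv < 0] <- 0
  tv[records$reads == 0] <- 0
  records$target_value <- tv
  records
}
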