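# Feature engineering for (guide, site, alignment) triples.
#
# The registry covers similarity features (alignment score, mismatch and
# bulge counts and positions, mismatch chemistry classes), PAM features,
# position-specific nucleotide identities, composition (GC), thermodynamics
# (nearest-neighbor duplex enthalpy over the 223-nt context), DNA-shape
# lookups (minor groove width around the PAM 6-mer, bending stiffness) and
# genomic annotations. Pluggable features without a provider are NA-flagged,
# never silently zero; the training stage imputes them with a companion
# missingness indicator.

# Unified nearest-neighbor stacking enthalpies, kcal/mol per dinucleotide
# step (10 unique values expanded to all 16 by reverse-complement symmetry).
# Version 1: SantaLucia unified consensus set; initiation terms excluded.
NN_DH_VERSION <- "unified-1998/v1"
NN_DH <- c(
  AA = -7.9, TT = -7.9,
  AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5,
  GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8,
  GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8,
  GG = -8.0, CC = -8.0)

#' Nearest-neighbor DNA duplex enthalpy
#'
#' Sums the embedded dinucleotide stacking enthalpy terms (kcal/mol) over
#' consecutive base pairs; duplex initiation terms are excluded. By
#' reverse-complement symmetry of the table, a sequence and its reverse
#' complement have equal enthalpy. Stacks containing an ambiguous base are
#' skipped with a warning.
#'
#' @param seq character vector of DNA sequences
#' @return numeric vector of enthalpies (kcal/mol); sequences shorter than
#'   2 nt contribute 0 with a warning
#' @examples
#' nn_enthalpy("ACGT")
#' @export
nn_enthalpy <- function(seq) {
  seq <- normalize_seq(seq, allow_n = TRUE)
  out <- vapply(seq, function(s) {
    n <- nchar(s)
    if (n < 2L) {
      warning("sequence shorter than 2 nt: enthalpy 0", call. = FALSE)
      return(0)
    }
    stacks <- substring(s, 1:(n - 1L), 2:n)
    vals <- NN_DH[stacks]
    if (anyNA(vals)) {
      warning(sum(is.na(vals)), " stack(s) with ambiguous base skipped",
              call. = FALSE)
    }
    sum(vals, na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
  out
}

#' Classify a mismatch in the RNA:DNA heteroduplex
#'
#' The pair is given as the sgRNA base (DNA-equivalent, U stored as T) and
#' the opposing target-strand base it faces in the heteroduplex. Wobble
#' pairs are rG.dT and rU.dG; otherwise the pair is a purine-purine
#' transition (RR), pyrimidine-pyrimidine transition (YY), or transversion.
#'
#' @param guide_base sgRNA base (A/C/G/T, U as T)
#' @param opposing_target_base the target-strand base facing it
#' @return one of `"wobble"`, `"transition_RR"`, `"transition_YY"`,
#'   `"transversion"` (vectorized)
#' @examples
#' classify_mismatch("G", "T")  # wobble
#' classify_mismatch("A", "G")  # purine-purine transition
#' @export
classify_mismatch <- function(guide_base, opposing_target_base) {
  g <- toupper(guide_base); d <- toupper(opposing_target_base)
  if (any(complement_base(d) == g)) {
    stop("called on a matched (complementary) pair", call. = FALSE)
  }
  pur <- c("A", "G")
  wob <- (g == "G" & d == "T") | (g == "T" & d == "G")
  rr <- g %in% pur & d %in% pur
  yy <- !(g %in% pur) & !(d %in% pur)
  ifelse(wob, "wobble",
         ifelse(rr, "transition_RR",
                ifelse(yy, "transition_YY", "transversion")))
}

MISMATCH_CLASSES <- c("wobble", "transition_RR", "transition_YY",
                      "transversion")

one_hot_base <- function(base, prefix) {
  v <- as.numeric(DNA_BASES == base)
  if (is.na(base) || !base %in% DNA_BASES) v <- rep(NA_real_, 4L)
  stats::setNames(v, paste0(prefix, "_", DNA_BASES))
}

#' Feature registry
#'
#' The ordered names of the canonical feature vector. `nullable` features
#' depend on optional providers (annotation tables, shape lookups, a folding
#' engine) and are NA when the provider is absent.
#'
#' @return character vector of feature names; attribute `"nullable"` lists
#'   the pluggable subset
#' @export
feature_registry <- function() {
  nm <- c("alignment_score", "chosen_window", "n_match", "n_mismatch",
          "n_bulge", "n_dna_bulge", "n_rna_bulge",
          paste0("mm_pos_", 1:20),
          paste0("n_", MISMATCH_CLASSES),
          "pam_NGG", "pam_NAG", "pam_other",
          paste0("pos2_", DNA_BASES), paste0("pos4_", DNA_BASES),
          paste0("pos5_", DNA_BASES), paste0("pos20_", DNA_BASES),
          paste0("pamdown", rep(1:5, each = 4), "_", DNA_BASES),
          "gc_site", "gc_flank_up", "gc_flank_down",
          "dna_enthalpy", "mgw_pam", "bend_stiffness",
          "dnase_hs", "exon_coding", "exon_opposite", "cpg_island",
          "expression", "sgrna_folding_energy")
  attr(nm, "nullable") <- c("mgw_pam", "bend_stiffness", "dnase_hs",
                            "exon_coding", "exon_opposite", "cpg_island",
                            "expression", "sgrna_folding_energy")
  nm
}

# mean pentamer lookup over the PAM-centered 6-mer region (NNGGNN when the
# PAM is canonical): site positions 2..1, PAM, first downstream base
mgw_around_pam <- function(site_seq, pam, down_flank, table5) {
  ctx <- paste0(substr(site_seq, nchar(site_seq) - 1L, nchar(site_seq)), pam,
                substr(down_flank, 1L, 1L))
  if (nchar(ctx) < 5L) return(NA_real_)
  pent <- substring(ctx, 1:(nchar(ctx) - 4L), 5:nchar(ctx))
  vals <- table5[pent]
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

stiffness_over <- function(seq, table2) {
  if (nchar(seq) < 2L) return(NA_real_)
  st <- substring(seq, 1:(nchar(seq) - 1L), 2:nchar(seq))
  vals <- table2[st]
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

lookup_annotation <- function(annotations, seq_id, start, end, col) {
  if (is.null(annotations)) return(NA_real_)
  hit <- annotations$seq_id == seq_id & annotations$start < end &
    annotations$end > start
  if (!any(hit)) return(0)
  v <- annotations[[col]][hit]
  if (is.null(v)) return(NA_real_)
  max(as.numeric(v), na.rm = TRUE)
}

#' Compute the feature vector for an aligned guide/site pair
#'
#' @param guide a [guide_rna] or 20-nt sequence
#' @param site a [target_site]
#' @param aln the [align_best_window] (or [align_fixed]) result for the pair
#' @param annotations optional annotation table: data frame with columns
#'   `seq_id`, `start`, `end` (0-based half-open) and any of `dnase_hs`,
#'   `exon_coding`, `exon_opposite`, `cpg_island`, `expression`
#' @param shape_mgw optional named numeric pentamer -> minor-groove-width
#'   lookup
#' @param shape_stiffness optional named numeric dinucleotide -> bending
#'   stiffness lookup
#' @param folding_energy optional numeric sgRNA folding energy (kcal/mol),
#'   e.g. from an external folding tool
#' @param flank_window flank length (nt) used for flank GC and the enthalpy
#'   context (the enthalpy window is site + PAM + `flank_window` each side)
#' @return named numeric vector following [feature_registry()]
#' @export
compute_features <- function(guide, site, aln, annotations = NULL,
                             shape_mgw = NULL, shape_stiffness = NULL,
                             folding_energy = NULL, flank_window = 100L) {
  g <- if (inherits(guide, "guide_rna")) guide$spacer else normalize_seq(guide)
  stopifnot(inherits(site, "target_site"),
            inherits(aln, "guide_target_alignment"))
  s <- site$site_seq
  L <- nchar(s)

  mm_pos <- stats::setNames(rep(0, 20L), paste0("mm_pos_", 1:20))
  mm_pos[aln$mismatch_positions[aln$mismatch_positions <= 20L]] <- 1

  cls <- if (nrow(aln$mismatch_pairs)) {
    classify_mismatch(aln$mismatch_pairs$guide,
                      aln$mismatch_pairs$target_strand)
  } else character(0)
  cls_n <- vapply(MISMATCH_CLASSES, function(k) sum(cls == k), numeric(1))
  names(cls_n) <- paste0("n_", MISMATCH_CLASSES)

  pam23 <- substr(site$pam, 2L, 3L)
  pam_oh <- c(pam_NGG = as.numeric(pam23 == "GG"),
              pam_NAG = as.numeric(pam23 == "AG"),
              pam_other = as.numeric(!pam23 %in% c("GG", "AG")))

  # PAM-proximal position k of the genomic site = site base L - k + 1
  site_base <- function(k) {
    if (k > L) NA_character_ else substr(s, L - k + 1L, L - k + 1L)
  }
  pos_oh <- c(one_hot_base(site_base(2L), "pos2"),
              one_hot_base(site_base(4L), "pos4"),
              one_hot_base(site_base(5L), "pos5"),
              one_hot_base(site_base(20L), "pos20"))
  down5 <- strsplit(substr(paste0(site$downstream_flank, "NNNNN"), 1L, 5L),
                    "")[[1]]
  down_oh <- unlist(lapply(1:5, function(i) {
    one_hot_base(down5[i], paste0("pamdown", i))
  }))

  up <- site$upstream_flank
  dn <- site$downstream_flank
  up_w <- substr(up, max(1L, nchar(up) - flank_window + 1L), nchar(up))
  dn_w <- substr(dn, 1L, flank_window)
  ctx <- paste0(up_w, s, site$pam, dn_w)

  out <- c(alignment_score = aln$score,
           chosen_window = as.numeric(aln$chosen_window),
           n_match = as.numeric(aln$n_match),
           n_mismatch = as.numeric(aln$n_mismatch),
           n_bulge = as.numeric(aln$n_dna_bulge + aln$n_rna_bulge),
           n_dna_bulge = as.numeric(aln$n_dna_bulge),
           n_rna_bulge = as.numeric(aln$n_rna_bulge),
           mm_pos, cls_n, pam_oh, pos_oh, down_oh,
           gc_site = gc_fraction(s),
           gc_flank_up = if (nzchar(up_w)) gc_fraction(up_w) else NA_real_,
           gc_flank_down = if (nzchar(dn_w)) gc_fraction(dn_w) else NA_real_,
           dna_enthalpy = nn_enthalpy(ctx),
           mgw_pam = if (is.null(shape_mgw)) NA_real_ else
             mgw_around_pam(s, site$pam, dn, shape_mgw),
           bend_stiffness = if (is.null(shape_stiffness)) NA_real_ else
             stiffness_over(paste0(s, site$pam), shape_stiffness),
           dnase_hs = if (is.null(annotations)) NA_real_ else
             lookup_annotation(annotations, site$seq_id, site$start, site$end,
                               "dnase_hs"),
           exon_coding = if (is.null(annotations)) NA_real_ else
             lookup_annotation(annotations, site$seq_id, site$start, site$end,
                               "exon_coding"),
           exon_opposite = if (is.null(annotations)) NA_real_ else
             lookup_annotation(annotations, site$seq_id, site$start, site$end,
                               "exon_opposite"),
           cpg_island = if (is.null(annotations)) NA_real_ else
             lookup_annotation(annotations, site$seq_id, site$start, site$end,
                               "cpg_island"),
           expression = if (is.null(annotations)) NA_real_ else
             lookup_annotation(annotations, site$seq_id, site$start, site$end,
                               "expression"),
           sgrna_folding_energy = if (is.null(folding_energy)) NA_real_ else
             as.numeric(folding_energy))
  reg <- feature_registry()
  missing_names <- setdiff(reg, names(out))
  if (length(missing_names)) {
    stop("feature registry mismatch; missing: ",
         paste(missing_names, collapse = ", "), call. = FALSE)
  }
  out[reg]
}

#' Feature matrix for a record table
#'
#' Aligns every record with [align_best_window] under `params` and computes
#' the full feature vector. Records must carry `guide_seq`, `site_seq` and
#' (optionally) `up_flank`/`down_flank` and `pam`; annotation columns
#' already present in the table (`dnase_hs`, `exon_coding`, `exon_opposite`,
#' `cpg_island`, `expression`, `sgrna_folding_energy`) override the
#' NA-flagged defaults, so simulated or externally supplied annotations pass
#' straight through.
#'
#' @param records record table (one row per guide/site pair)
#' @param params [alignment_params] used for the alignment features
#' @inheritParams compute_features
#' @return data frame: the feature columns of [feature_registry()], in order
#' @export
feature_matrix <- function(records, params = alignment_params(),
                           annotations = NULL, shape_mgw = NULL,
                           shape_stiffness = NULL, flank_window = 100L) {
  n <- nrow(records)
  up <- if ("up_flank" %in% names(records)) records$up_flank else rep("", n)
  dn <- if ("down_flank" %in% names(records)) records$down_flank else rep("", n)
  pam <- if ("pam" %in% names(records)) records$pam else rep("NNN", n)
  up[is.na(up)] <- ""; dn[is.na(dn)] <- ""
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    site <- target_site(
      seq_id = if ("chrom" %in% names(records)) records$chrom[i] else "?",
      start = if ("start" %in% names(records)) records$start[i] else NA,
      end = if ("end" %in% names(records)) records$end[i] else NA,
      strand = if ("strand" %in% names(records)) records$strand[i] else "+",
      site_seq = records$site_seq[i], pam = pam[i],
      upstream_flank = up[i], downstream_flank = dn[i])
    aln <- align_best_window(records$guide_seq[i], site, params)
    fe <- if ("sgrna_folding_energy" %in% names(records)) {
      records$sgrna_folding_energy[i]
    } else NULL
    rows[[i]] <- compute_features(records$guide_seq[i], site, aln,
                                  annotations = annotations,
                                  shape_mgw = shape_mgw,
                                  shape_stiffness = shape_stiffness,
                                  folding_energy = fe,
                                  flank_window = flank_window)
  }
  fm <- as.data.frame(do.call(rbind, rows))
  # per-record annotation columns in the table win over interval lookups
  for (col in c("dnase_hs", "exon_coding", "exon_opposite", "cpg_island",
                "expression")) {
    if (col %in% names(records) && is.null(annotations)) {
      fm[[col]] <- as.numeric(records[[col]])
    }
  }
  fm
}
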