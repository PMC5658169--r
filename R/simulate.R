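# Synthetic study generator: a random genome with planted on/off-target
# sites carrying controlled mismatch/bulge patterns, and multi-study read
# counts generated from a known latent effect model, so that every stage of
# the pipeline (alignment, harmonization, mining, training, CV, selection)
# can be validated against planted ground truth.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: five guides, one
#' hundred cleaved sites per guide whose mismatch load is skewed toward 2-4
#' mismatches with bulges in 18% of sites, a larger population of decoy
#' (uncleaved) sites of 3-5 mismatches, a human-like 41% GC genome, and a
#' latent cleavage intensity dominated by the alignment score with smaller
#' composition/thermodynamics effects plus log-scale noise.
#'
#' @param genome_length contig length (nt)
#' @param gc_fraction genome GC content
#' @param n_guides number of guides
#' @param n_positives cleaved sites planted per guide
#' @param n_decoys uncleaved decoy sites planted per guide
#' @param pos_mismatch_probs probabilities of 0..5 mismatches for cleaved
#'   sites
#' @param decoy_mismatch_probs probabilities of 0..5 mismatches for decoys
#' @param pos_bulge_prob,decoy_bulge_prob probability a planted site
#'   carries one bulge
#' @param pam_probs probabilities of NGG vs NAG PAM
#' @param b_aln,b_gc,b_enth latent effect-model coefficients (standardized
#'   alignment score, site GC, context enthalpy)
#' @param noise_sd log-scale noise sd of the latent intensity
#' @param read_mu,read_scale map latent to log10 reference reads
#' @param studies data frame `study`, `slope`, `intercept`, `noise_sd`
#'   (reference scale = slope * study scale + intercept)
#' @param master_seed seed for the whole simulation
#' @return list of class `sim_config`
#' @export
sim_config <- function(genome_length = 120000L, gc_fraction = 0.41,
                       n_guides = 5L, n_positives = 100L, n_decoys = 320L,
                       pos_mismatch_probs = c(0.06, 0.16, 0.26, 0.26, 0.18, 0.08),
                       decoy_mismatch_probs = c(0, 0, 0, 0.3, 0.4, 0.3),
                       pos_bulge_prob = 0.18, decoy_bulge_prob = 0.3,
                       pam_probs = c(NGG = 0.85, NAG = 0.15),
                       b_aln = 1.5, b_gc = 0.25, b_enth = 0.25,
                       noise_sd = 0.3, read_mu = 1.8, read_scale = 0.8,
                       studies = data.frame(study = "sim", slope = 1,
                                            intercept = 0, noise_sd = 0),
                       master_seed = 1L) {
  stopifnot(genome_length > 0, gc_fraction >= 0, gc_fraction <= 1,
            abs(sum(pos_mismatch_probs) - 1) < 1e-8,
            abs(sum(decoy_mismatch_probs) - 1) < 1e-8,
            pos_bulge_prob >= 0, pos_bulge_prob <= 1,
            all(c("study", "slope", "intercept") %in% names(studies)))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a random genome
#'
#' @param config a [sim_config]
#' @return named character vector with one contig (`simchr`)
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$master_seed)
  gc <- config$gc_fraction
  s <- paste(sample(c("A", "C", "G", "T"), config$genome_length,
                    replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
             collapse = "")
  c(simchr = s)
}

mutate_site <- function(spacer, n_mismatch, bulge, rng_env = NULL) {
  s <- strsplit(spacer, "")[[1]]
  if (n_mismatch > 0) {
    idx <- sample(length(s), n_mismatch)
    s[idx] <- vapply(s[idx], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  edits <- list(n_mismatch = n_mismatch, bulge = "none")
  if (bulge) {
    # interior placement: a bulge within ~4 nt of either end is cheaper to
    # explain as terminal mismatches than as an indel, i.e. unidentifiable
    k <- sample(5:16, 1)
    if (stats::runif(1) < 0.5) {
      s <- s[-k]                       # DNA lacks one base: RNA bulge
      edits$bulge <- "rna"
    } else {
      s <- append(s, sample(c("A", "C", "G", "T"), 1), after = k)
      edits$bulge <- "dna"             # DNA carries an extra base
    }
  }
  list(seq = paste(s, collapse = ""), edits = edits)
}

#' Plant on/off-target sites for a set of guides into a genome
#'
#' Sites (mutated protospacer + sampled PAM) overwrite non-overlapping
#' segments of the forward strand; placement collisions are re-drawn with
#' bounded retries. Each record stores the planted edit pattern.
#'
#' @param genome named character vector (one contig)
#' @param guides list of [guide_rna]
#' @param config a [sim_config]
#' @return list: `genome` (with sites written in) and `truth` (data frame
#'   of planted sites: coordinates, class, edits)
#' @export
plant_targets <- function(genome, guides, config = sim_config()) {
  contig <- names(genome)[1]
  seq <- genome[[contig]]
  Lc <- nchar(seq)
  n_sites <- length(guides) * (config$n_positives + config$n_decoys)
  slot_w <- 30L                          # site footprint incl. PAM, no overlap
  margin <- 110L                         # keep full flanks available
  n_slots <- (Lc - 2L * margin) %/% slot_w
  if (n_slots < n_sites) {
    stop("genome too short for ", n_sites, " planted sites", call. = FALSE)
  }
  slots <- margin + slot_w * (sample.int(n_slots, n_sites) - 1L)
  truth <- vector("list", n_sites)
  chars <- strsplit(seq, "")[[1]]
  i <- 0L
  for (g in guides) {
    classes <- c(rep(TRUE, config$n_positives), rep(FALSE, config$n_decoys))
    for (cl in classes) {
      i <- i + 1L
      probs <- if (cl) config$pos_mismatch_probs else config$decoy_mismatch_probs
      nm <- sample(0:5, 1, prob = probs)
      bp <- if (cl) config$pos_bulge_prob else config$decoy_bulge_prob
      m <- mutate_site(g$spacer, nm, stats::runif(1) < bp)
      pam <- paste0(sample(c("A", "C", "G", "T"), 1),
                    sample(c("GG", "AG"), 1, prob = config$pam_probs))
      planted <- paste0(m$seq, pam)
      p0 <- slots[i]                     # 0-based start of the planted block
      chars[(p0 + 1):(p0 + nchar(planted))] <- strsplit(planted, "")[[1]]
      pam_start <- p0 + nchar(m$seq)     # 0-based PAM start
      truth[[i]] <- data.frame(
        guide_id = g$id, guide_seq = g$spacer, chrom = contig,
        start = pam_start - 20L, end = pam_start, strand = "+",
        pam = pam, is_positive = cl, n_mismatch_planted = nm,
        bulge_planted = m$edits$bulge, stringsAsFactors = FALSE)
    }
  }
  genome[[contig]] <- paste(chars, collapse = "")
  list(genome = genome, truth = do.call(rbind, truth))
}

#' Simulate multi-study read counts from the latent effect model
#'
#' The latent log intensity of a cleaved site is a linear combination of
#' its standardized alignment score, site GC and context enthalpy plus
#' Gaussian noise; reference-scale log10 reads are an affine map of the
#' latent, and each study's counts are the inverse of its calibration
#' (reference = slope * study + intercept) with optional study noise.
#' Uncleaved sites emit zero reads.
#'
#' @param records cleaved-site record table with `site_seq`, `up_flank`,
#'   `down_flank`, `guide_seq`
#' @param config a [sim_config]
#' @param params [alignment_params] defining the generative alignment score
#' @return records replicated per study with `study` and `reads` columns;
#'   attribute `"latent"` stores the generative intensities
#' @export
simulate_reads <- function(records, config = sim_config(),
                           params = alignment_params()) {
  n <- nrow(records)
  score <- vapply(seq_len(n), function(i) {
    align_best_window(records$guide_seq[i],
                      paste0(records$up_flank[i], records$site_seq[i]),
                      params)$score
  }, numeric(1))
  gc <- gc_fraction(records$site_seq)
  enth <- nn_enthalpy(paste0(records$up_flank, records$site_seq,
                             records$pam, records$down_flank))
  z <- function(x) if (stats::sd(x) == 0) rep(0, length(x)) else
    (x - mean(x)) / stats::sd(x)
  latent <- config$b_aln * z(score) + config$b_gc * z(gc) +
    config$b_enth * z(enth) + stats::rnorm(n, 0, config$noise_sd)
  log_ref <- pmin(3.8, pmax(0.05, config$read_mu + config$read_scale * latent))
  out <- lapply(seq_len(nrow(config$studies)), function(si) {
    st <- config$studies[si, ]
    log_study <- (log_ref - st$intercept) / st$slope
    if (!is.null(st$noise_sd) && st$noise_sd > 0) {
      log_study <- log_study + stats::rnorm(n, 0, st$noise_sd)
    }
    r <- records
    r$study <- st$study
    r$reads <- pmax(1, round(10^pmax(0.02, log_study) - 1))
    r
  })
  out <- do.call(rbind, out)
  attr(out, "latent") <- latent
  attr(out, "generative_score") <- score
  out
}

#' Simulate a complete multi-study dataset
#'
#' Genome, guides, planted sites and read counts in one seeded call.
#'
#' @param config a [sim_config]
#' @return list of class `sim_dataset`: `genome`, `guides`, `records`
#'   (cleaved, one row per study per site), `decoy_truth` (planted
#'   uncleaved sites), `truth` (all planted sites)
#' @export
simulate_dataset <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  set.seed(config$master_seed + 1L)
  guides <- lapply(seq_len(config$n_guides), function(i) {
    guide_rna(paste0("guide", i),
              paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                    collapse = ""))
  })
  pl <- plant_targets(genome, guides, config)
  truth <- pl$truth
  sites <- lapply(seq_len(nrow(truth)), function(i) {
    site_from_genome(pl$genome, truth$chrom[i], truth$start[i], truth$end[i],
                     truth$strand[i], flank = 100L)
  })
  base <- data.frame(
    guide_id = truth$guide_id, guide_seq = truth$guide_seq,
    chrom = truth$chrom, start = truth$start, end = truth$end,
    strand = truth$strand,
    site_seq = vapply(sites, `[[`, character(1), "site_seq"),
    pam = vapply(sites, `[[`, character(1), "pam"),
    up_flank = vapply(sites, `[[`, character(1), "upstream_flank"),
    down_flank = vapply(sites, `[[`, character(1), "downstream_flank"),
    stringsAsFactors = FALSE)
  set.seed(config$master_seed + 2L)
  cleaved <- simulate_reads(base[truth$is_positive, , drop = FALSE], config)
  structure(list(genome = pl$genome, guides = guides, records = cleaved,
                 decoy_truth = cbind(base[!truth$is_positive, , drop = FALSE],
                                     truth[!truth$is_positive,
                                           c("n_mismatch_planted",
                                             "bulge_planted")]),
                 truth = truth, config = config), class = "sim_dataset")
}

#' Assemble a training table from a simulated dataset
#'
#' Mines uncleaved candidate sites from the simulated genome for each guide
#' (excluding its cleaved intervals), merges them with the cleaved records,
#' harmonizes studies and finalizes the [0, 1] regression target — the
#' same path a real multi-study compendium takes.
#'
#' @param sim a `sim_dataset`
#' @param params [alignment_params] used for mining
#' @param min_score mining retention threshold
#' @param reference_study study defining the harmonization scale
#' @return record table with `target_value`, ready for [loso_cv] /
#'   [train_ensemble]
#' @export
assemble_training <- function(sim, params = alignment_params(),
                              min_score = 14.75,
                              reference_study = sim$config$studies$study[1]) {
  cleaved <- sim$records
  negs <- lapply(sim$guides, function(g) {
    cl <- cleaved[cleaved$guide_id == g$id, , drop = FALSE]
    mined <- mine_negatives(g, sim$genome, params, min_score = min_score,
                            exclude = cl)
    if (!nrow(mined)) return(NULL)
    data.frame(guide_id = g$id, guide_seq = g$spacer,
               chrom = mined$chrom, start = mined$start, end = mined$end,
               strand = mined$strand, site_seq = mined$site_seq,
               pam = mined$pam, up_flank = mined$up_flank,
               down_flank = mined$down_flank,
               study = reference_study, reads = 0, stringsAsFactors = FALSE)
  })
  rec <- rbind(cleaved[, c("guide_id", "guide_seq", "chrom", "start", "end",
                           "strand", "site_seq", "pam", "up_flank",
                           "down_flank", "study", "reads")],
               do.call(rbind, negs))
  rec <- finalize_targets(harmonize_studies(rec, reference_study))
  rownames(rec) <- NULL
  rec
}
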