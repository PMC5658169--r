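# Cross-validation protocols and the metric suite.
#
# Leave-one-sgRNA-out: each fold holds out every record of one guide,
# re-optimizes the alignment parameters on the remaining guides, recomputes
# the alignment-derived features for training and test, trains the ensemble
# on balanced bootstrap rounds, and scores the held-out guide's cleaved
# sites against an equal-sized random draw of its uncleaved sites.
# Leave-study-out holds out whole studies instead (without per-fold
# parameter re-optimization) and reports unique-guide and common-guide
# metrics separately.

#' Ranking and regression metrics
#'
#' Pearson r-squared and Spearman rho between observed and predicted
#' values, RMSE, and (when binary labels are supplied) the areas under the
#' ROC curve (trapezoidal; equal to the normalized Mann-Whitney U
#' statistic) and the precision-recall curve (trapezoidal over distinct
#' score thresholds; precision = TP / (TP + FP), recall = TP / P).
#'
#' @param observed observed values
#' @param predicted predicted scores
#' @param labels optional logical/0-1 vector (TRUE/1 = cleaved)
#' @return named list: `pearson_r2`, `spearman_rho`, `rmse`, and `roc_auc`,
#'   `prc_auc` when labels are given; constant predictions yield NA
#'   correlations with a warning
#' @export
metric_suite <- function(observed, predicted, labels = NULL) {
  stopifnot(length(observed) == length(predicted))
  if (length(observed) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    warning("constant observed or predicted values: correlations undefined",
            call. = FALSE)
    r2 <- NA_real_; rho <- NA_real_
  } else {
    r2 <- stats::cor(observed, predicted)^2
    rho <- stats::cor(observed, predicted, method = "spearman")
  }
  out <- list(pearson_r2 = r2, spearman_rho = rho,
              rmse = sqrt(mean((observed - predicted)^2)))
  if (!is.null(labels)) {
    lab <- as.logical(labels)
    if (any(lab) && any(!lab)) {
      out$roc_auc <- roc_auc(predicted, lab)
      out$prc_auc <- prc_auc(predicted, lab)
    } else {
      out$roc_auc <- NA_real_
      out$prc_auc <- NA_real_
    }
  }
  out
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic (average ranks for
#' ties), identical to the trapezoidal area under the ROC curve swept over
#' the predicted scores as thresholds.
#'
#' @param score predicted scores
#' @param label logical labels (TRUE = positive)
#' @return AUC in [0, 1]
#' @export
roc_auc <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Trapezoidal area over the precision-recall points at every distinct
#' score threshold (descending), anchored at recall 0 with the precision of
#' the highest-scoring block. A perfect ranker attains 1 at any class
#' balance.
#'
#' @inheritParams roc_auc
#' @return PRC-AUC in [0, 1]
#' @export
prc_auc <- function(score, label) {
  label <- as.logical(label)
  if (!any(label) || all(label)) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  lab <- label[ord]; sc <- score[ord]
  tp <- cumsum(lab); fp <- cumsum(!lab)
  # evaluate at the last index of each tied-score block
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  prec <- (tp / (tp + fp))[keep]
  rec <- (tp / sum(lab))[keep]
  rec0 <- c(0, rec); prec0 <- c(prec[1], prec)
  sum(diff(rec0) * (prec0[-1] + prec0[-length(prec0)]) / 2)
}

#' Cross-validation configuration
#'
#' @param rounds sampled datasets per fold
#' @param num_trees trees per member forest
#' @param reoptimize re-optimize alignment parameters per fold (the
#'   leave-one-sgRNA-out default; leave-study-out uses fixed parameters)
#' @param grid parameter grid for [optimize_params]
#' @param params [alignment_params] used when not re-optimizing (and as the
#'   fallback when a fold's training guides cannot support optimization)
#' @param max_gaps gap budget
#' @param master_seed seed for sampling, forests and test-negative draws
#' @param mtry forest mtry (NULL = floor(p/3))
#' @return a list of class `cv_config`
#' @export
cv_config <- function(rounds = 100L, num_trees = 100L, reoptimize = TRUE,
                      grid = default_param_grid(),
                      params = alignment_params(), max_gaps = 3L,
                      master_seed = 1L, mtry = NULL) {
  structure(list(rounds = as.integer(rounds),
                 num_trees = as.integer(num_trees),
                 reoptimize = isTRUE(reoptimize), grid = grid, params = params,
                 max_gaps = as.integer(max_gaps),
                 master_seed = as.integer(master_seed), mtry = mtry),
            class = "cv_config")
}

record_ids <- function(records) {
  if ("record_id" %in% names(records)) return(records$record_id)
  paste(records$guide_id,
        if ("chrom" %in% names(records)) records$chrom else "?",
        if ("start" %in% names(records)) records$start else seq_len(nrow(records)),
        if ("strand" %in% names(records)) records$strand else "+",
        sep = ":")
}

fold_params <- function(train, config) {
  if (!config$reoptimize) return(config$params)
  cleaved <- train[train$target_value > 0, , drop = FALSE]
  cleaved$freq <- cleaved$target_value
  tryCatch(
    optimize_params(cleaved, grid = config$grid, max_gaps = config$max_gaps),
    error = function(e) {
      warning("parameter optimization failed (", conditionMessage(e),
              "); using configured params", call. = FALSE)
      config$params
    })
}

run_fold <- function(train, test, config, fold_seed) {
  params <- fold_params(train, config)
  ftrain <- feature_matrix(train, params)
  ftest <- feature_matrix(test, params)
  model <- train_ensemble(
    train, ftrain,
    ensemble_config(rounds = config$rounds, num_trees = config$num_trees,
                    mtry = config$mtry, master_seed = fold_seed))
  # test set: all positives + an equal-sized negative draw per guide
  pos <- test$target_value > 0
  set.seed(fold_seed)
  keep <- unlist(lapply(unique(test$guide_id), function(gid) {
    ip <- which(pos & test$guide_id == gid)
    ineg <- which(!pos & test$guide_id == gid)
    c(ip, if (length(ineg)) ineg[sample.int(length(ineg),
                                            min(length(ineg), length(ip)))])
  }))
  keep <- sort(keep)
  pred <- predict(model, ftest[keep, , drop = FALSE])
  data.frame(record_id = record_ids(test)[keep],
             guide_id = test$guide_id[keep],
             study = if ("study" %in% names(test)) test$study[keep] else NA,
             observed = test$target_value[keep],
             label = pos[keep],
             predicted = pred$score,
             fold_params_mismatch = params$mismatch,
             fold_params_gap = params$gap,
             stringsAsFactors = FALSE)
}

per_guide_metrics <- function(pred) {
  sp <- split(pred, pred$guide_id)
  rows <- lapply(sp, function(d) {
    if (nrow(d) < 2L) return(NULL)
    m <- suppressWarnings(metric_suite(d$observed, d$predicted, d$label))
    data.frame(guide_id = d$guide_id[1], n = nrow(d),
               pearson_r2 = m$pearson_r2, spearman_rho = m$spearman_rho,
               rmse = m$rmse, roc_auc = m$roc_auc, prc_auc = m$prc_auc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

build_report <- function(pred) {
  pooled <- suppressWarnings(
    metric_suite(pred$observed, pred$predicted, pred$label))
  pg <- per_guide_metrics(pred)
  structure(list(
    pooled = pooled,
    per_guide = pg,
    per_guide_mean = vapply(pg[, -(1:2)], mean, numeric(1), na.rm = TRUE),
    per_guide_sd = vapply(pg[, -(1:2)], stats::sd, numeric(1), na.rm = TRUE),
    predictions = pred), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>\n pooled: ")
  cat(sprintf("r2=%.3f rho=%.3f ROC-AUC=%.3f PRC-AUC=%.3f rmse=%.3f\n",
              x$pooled$pearson_r2, x$pooled$spearman_rho,
              x$pooled$roc_auc %||% NA, x$pooled$prc_auc %||% NA,
              x$pooled$rmse))
  cat(sprintf(" per-guide mean r2=%.3f (sd %.3f), n guides=%d\n",
              x$per_guide_mean["pearson_r2"], x$per_guide_sd["pearson_r2"],
              nrow(x$per_guide)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leave-one-sgRNA-out cross-validation
#'
#' @param records full record table (`guide_id`, `guide_seq`, `site_seq`,
#'   flanks, `target_value`, annotation columns)
#' @param config a [cv_config]
#' @return a `cv_report`: pooled metrics, per-guide metrics (mean and sd),
#'   and the per-record prediction table
#' @export
loso_cv <- function(records, config = cv_config()) {
  guides <- unique(records$guide_id)
  if (length(guides) < 2L) stop("need at least 2 guides", call. = FALSE)
  preds <- vector("list", length(guides))
  for (k in seq_along(guides)) {
    gid <- guides[k]
    train <- records[records$guide_id != gid, , drop = FALSE]
    test <- records[records$guide_id == gid, , drop = FALSE]
    fold_seed <- (config$master_seed + 104729L * k) %% .Machine$integer.max
    preds[[k]] <- run_fold(train, test, config, fold_seed)
    # protocol audit: a held-out record must never reach training
    stopifnot(!any(preds[[k]]$record_id %in% record_ids(train)))
  }
  build_report(do.call(rbind, preds))
}

#' Leave-study-out cross-validation
#'
#' Each fold holds out all records of one study. Metrics are reported
#' separately for guides profiled in a single study ("unique") and guides
#' profiled in several ("common"). Alignment parameters are not
#' re-optimized per fold.
#'
#' @inheritParams loso_cv
#' @return list of class `lso_report`: per-study `cv_report`s plus
#'   unique/common splits
#' @export
leave_study_out <- function(records, config = cv_config(reoptimize = FALSE)) {
  stopifnot("study" %in% names(records))
  studies <- unique(records$study)
  if (length(studies) < 2L) stop("need at least 2 studies", call. = FALSE)
  guide_studies <- tapply(records$study, records$guide_id,
                          function(s) length(unique(s)))
  common_guides <- names(guide_studies)[guide_studies > 1L]
  out <- list()
  for (k in seq_along(studies)) {
    st <- studies[k]
    train <- records[records$study != st, , drop = FALSE]
    test <- records[records$study == st, , drop = FALSE]
    if (!nrow(test) || !length(unique(train$guide_id))) {
      warning("study ", st, " skipped: empty fold", call. = FALSE)
      next
    }
    fold_seed <- (config$master_seed + 224737L * k) %% .Machine$integer.max
    pred <- run_fold(train, test, config, fold_seed)
    is_common <- pred$guide_id %in% common_guides
    out[[st]] <- list(
      all = build_report(pred),
      unique_guides = if (any(!is_common))
        build_report(pred[!is_common, , drop = FALSE]) else NULL,
      common_guides = if (any(is_common))
        build_report(pred[is_common, , drop = FALSE]) else NULL)
  }
  structure(out, class = "lso_report")
}

#' Sensitivity of per-guide r-squared to the uncleaved sample size
#'
#' Recomputes the per-guide averaged r-squared while shrinking each guide's
#' uncleaved test draw from 100% down to 0% of its cleaved-set size.
#'
#' @param predictions the `predictions` table of a `cv_report`
#' @param fractions negative set sizes relative to the cleaved set
#' @param seed seed for the subsampling
#' @return data frame of `fraction` and averaged `pearson_r2`
#' @export
negative_fraction_sweep <- function(predictions,
                                    fractions = seq(1, 0, by = -0.25),
                                    seed = 1L) {
  if (any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  rows <- lapply(fractions, function(f) {
    r2 <- vapply(split(predictions, predictions$guide_id), function(d) {
      ip <- which(d$label); ineg <- which(!d$label)
      nneg <- round(f * length(ip))
      keep <- c(ip, if (nneg > 0 && length(ineg))
        ineg[sample.int(length(ineg), min(nneg, length(ineg)))])
      if (length(keep) < 2L) return(NA_real_)
      o <- d$observed[keep]; p <- d$predicted[keep]
      if (stats::sd(o) == 0 || stats::sd(p) == 0) return(NA_real_)
      stats::cor(o, p)^2
    }, numeric(1))
    data.frame(fraction = f, pearson_r2 = mean(r2, na.rm = TRUE))
  })
  do.call(rbind, rows)
}
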