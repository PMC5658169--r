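# Greedy forward feature selection under leave-one-sgRNA-out r-squared,
# forest importance extraction, the feature correlation matrix behind the
# importance graph, and the two mechanism-probing statistical tests
# (wobble enrichment across mismatch loads; depressed cleavage at extreme
# duplex enthalpy).

cv_r2_features <- function(records, X, cols, config) {
  guides <- unique(records$guide_id)
  preds <- obs <- list()
  for (k in seq_along(guides)) {
    gid <- guides[k]
    tr <- records$guide_id != gid
    fold_seed <- (config$master_seed + 104729L * k) %% .Machine$integer.max
    model <- train_ensemble(
      records[tr, , drop = FALSE], X[tr, cols, drop = FALSE],
      ensemble_config(rounds = config$rounds, num_trees = config$num_trees,
                      mtry = config$mtry, master_seed = fold_seed))
    te <- which(!tr)
    pos <- records$target_value[te] > 0
    set.seed(fold_seed)
    ineg <- te[!pos]
    keep <- c(te[pos], if (length(ineg))
      ineg[sample.int(length(ineg), min(length(ineg), sum(pos)))])
    pr <- predict(model, X[keep, cols, drop = FALSE])$score
    preds[[k]] <- pr
    obs[[k]] <- records$target_value[keep]
  }
  o <- unlist(obs); p <- unlist(preds)
  if (stats::sd(p) == 0 || stats::sd(o) == 0) return(NA_real_)
  stats::cor(o, p)^2
}

#' Greedy forward feature selection under cross-validated r-squared
#'
#' Starts from the single feature with the highest leave-one-sgRNA-out
#' pooled r-squared and iteratively adjoins the feature that increases it
#' the most. Candidate evaluation runs a reduced-cost CV configuration
#' (few sampling rounds, fixed alignment parameters) since a full-budget
#' CV per candidate per step is quadratic; the returned trace can be
#' re-scored at full budget. After selection one forest is fitted on the
#' selected set to extract relative importances.
#'
#' @param records training record table (with `target_value`, `guide_id`)
#' @param features feature data frame aligned with `records`
#' @param candidates candidate feature names (default: all columns)
#' @param n_iters number of features to select
#' @param config reduced-cost [cv_config] for candidate scoring
#' @return list of class `selection_trace`: `selected`, per-step `r2`,
#'   `importances` (normalized to sum 1)
#' @export
forward_select <- function(records, features,
                           candidates = colnames(features), n_iters = 15L,
                           config = cv_config(rounds = 5L, num_trees = 60L,
                                              reoptimize = FALSE)) {
  if (length(candidates) < 2L && n_iters > 0L) {
    stop("need at least 2 candidate features", call. = FALSE)
  }
  if (n_iters > length(candidates)) {
    warning("n_iters truncated to the number of candidates", call. = FALSE)
    n_iters <- length(candidates)
  }
  # constant columns can never help and break nothing: rank them last
  selected <- character(0)
  r2_trace <- numeric(0)
  for (step in seq_len(n_iters)) {
    pool <- setdiff(candidates, selected)
    scores <- vapply(pool, function(f) {
      cv_r2_features(records, features, c(selected, f), config)
    }, numeric(1))
    if (all(is.na(scores))) break
    best <- pool[which.max(scores)]
    selected <- c(selected, best)
    r2_trace <- c(r2_trace, max(scores, na.rm = TRUE))
  }
  imp <- if (length(selected)) {
    s <- sample_round(records, seed = config$master_seed)
    idx <- attr(s, "indices")
    dat <- impute_features(features[idx, selected, drop = FALSE])
    dat <- dat[, intersect(names(dat), c(selected,
                                         paste0("miss_", selected))),
               drop = FALSE]
    dat$..y.. <- records$target_value[idx]
    fit <- ranger::ranger(dependent.variable.name = "..y..", data = dat,
                          num.trees = 500, importance = "impurity",
                          seed = config$master_seed, num.threads = 1L)
    v <- fit$variable.importance
    v <- v[!startsWith(names(v), "miss_")]
    v / sum(v)
  } else numeric(0)
  structure(list(selected = selected, r2 = r2_trace, importances = imp),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace>\n")
  for (i in seq_along(x$selected)) {
    cat(sprintf(" %2d. %-24s r2=%.3f\n", i, x$selected[i], x$r2[i]))
  }
  invisible(x)
}

#' Pairwise feature correlations and forest importances
#'
#' The data behind the feature-importance graph: signed Pearson
#' correlations for every feature pair (constant features are NA-flagged)
#' and impurity importances from a forest on a balanced round, normalized
#' to sum 1.
#'
#' @param records training record table
#' @param features feature data frame
#' @param num_trees trees for the importance forest
#' @param seed seed
#' @return list: `correlation` (matrix), `importance` (named, sums to 1)
#' @export
importance_correlation_matrix <- function(records, features,
                                          num_trees = 500L, seed = 1L) {
  X <- as.matrix(impute_features(features))
  const <- apply(X, 2L, stats::sd) == 0
  cm <- suppressWarnings(stats::cor(X))
  cm[const, ] <- NA_real_; cm[, const] <- NA_real_
  diag(cm) <- ifelse(const, NA_real_, 1)
  s <- sample_round(records, seed = seed)
  idx <- attr(s, "indices")
  dat <- as.data.frame(X[idx, , drop = FALSE])
  dat$..y.. <- records$target_value[idx]
  fit <- ranger::ranger(dependent.variable.name = "..y..", data = dat,
                        num.trees = num_trees, importance = "impurity",
                        seed = seed, num.threads = 1L)
  v <- fit$variable.importance
  list(correlation = cm, importance = v / sum(v))
}

#' Wobble enrichment across mismatch loads
#'
#' Tests whether the proportion of wobble mismatches depends on the total
#' number of mismatches in a target: a chi-square test of independence on
#' the (mismatch-count bin) x (wobble, non-wobble) contingency table built
#' from the cleaved alignments. Bins whose expected counts fall below
#' `min_expected` are merged upward with a warning.
#'
#' @param mismatch_table data frame with per-target `n_mismatch` and
#'   `n_wobble`
#' @param min_expected minimum expected cell count before merging
#' @return `htest`-like list: `statistic`, `p_value`, `table`
#' @export
wobble_enrichment_test <- function(mismatch_table, min_expected = 1) {
  d <- mismatch_table[mismatch_table$n_mismatch > 0, , drop = FALSE]
  if (!nrow(d)) stop("no mismatching targets", call. = FALSE)
  wob <- tapply(d$n_wobble, d$n_mismatch, sum)
  tot <- tapply(d$n_mismatch, d$n_mismatch, sum)
  tab <- cbind(wobble = wob, nonwobble = tot - wob)
  if (nrow(tab) < 2L) stop("need at least 2 mismatch-count bins", call. = FALSE)
  if (all(tab[, "wobble"] == 0) || all(tab[, "nonwobble"] == 0)) {
    stop("degenerate table: all mismatches in one class", call. = FALSE)
  }
  repeat {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(expected >= min_expected) || nrow(tab) <= 2L) break
    warning("merging sparse mismatch bins", call. = FALSE)
    k <- nrow(tab)
    tab <- rbind(tab[seq_len(k - 2L), , drop = FALSE],
                 tab[k - 1L, ] + tab[k, ])
  }
  ht <- suppressWarnings(stats::chisq.test(tab))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, table = tab,
       df = unname(ht$parameter))
}

#' Permutation test for depressed cleavage at extreme duplex enthalpy
#'
#' Fixes the per-site enthalpy values, shuffles the cleavage frequencies
#' across sites `n_perm` times, and each time records the mean frequency of
#' the sites in the union of the two enthalpy tails (below the lower and
#' above the upper quantile). The one-sided p-value is the proportion of
#' permutations with a tail mean at or below the observed one, with the
#' add-one correction (k + 1) / (n_perm + 1).
#'
#' @param enthalpy per-site enthalpy (kcal/mol)
#' @param frequency per-site cleavage frequency
#' @param n_perm number of permutations
#' @param tails lower/upper quantiles delimiting the extremes
#' @param seed seed
#' @return list: `p_value`, `observed_mean`, `n_tail`
#' @export
enthalpy_tail_permutation_test <- function(enthalpy, frequency,
                                           n_perm = 1000L,
                                           tails = c(0.05, 0.95), seed = 1L) {
  stopifnot(length(enthalpy) == length(frequency))
  n <- length(enthalpy)
  if (n < 20L) stop("need at least 20 records", call. = FALSE)
  if (stats::sd(frequency) == 0) {
    warning("all frequencies equal: p = 1 by convention", call. = FALSE)
    return(list(p_value = 1, observed_mean = mean(frequency), n_tail = NA))
  }
  q <- stats::quantile(enthalpy, tails, names = FALSE)
  tail_idx <- which(enthalpy <= q[1] | enthalpy >= q[2])
  m <- length(tail_idx)
  obs <- mean(frequency[tail_idx])
  set.seed(as.integer(seed))
  perm_means <- vapply(seq_len(n_perm), function(i) {
    mean(frequency[sample.int(n, m)])
  }, numeric(1))
  k <- sum(perm_means <= obs)
  list(p_value = (k + 1) / (n_perm + 1), observed_mean = obs, n_tail = m)
}
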