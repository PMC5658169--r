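# Ensemble of random-forest regressors over class-balanced bootstrap rounds.
#
# Each of the `rounds` sampled datasets trains one forest; the cleavage
# propensity of a site is the mean prediction across members, with the
# member spread reported alongside. A classification variant (binary
# cleaved/uncleaved label, member-probability averaging) is exposed through
# `mode = "classification"`.

#' Ensemble training configuration
#'
#' Forest hyperparameters are deliberately explicit: the number of trees
#' and `mtry` (default `floor(p/3)`, the classical regression-forest
#' choice) are recorded in the trained model's metadata so any run can be
#' replayed.
#'
#' @param rounds number of sampled datasets / ensemble members
#' @param num_trees trees per member forest
#' @param mtry candidate features per split; `NULL` for `floor(p/3)` (at
#'   least 1)
#' @param min_node_size minimal terminal node size
#' @param mode `"regression"` (propensity on the harmonized scale) or
#'   `"classification"` (cleaved-probability averaging)
#' @param master_seed seed from which per-round sampling and forest seeds
#'   are derived
#' @return a list of class `ensemble_config`
#' @export
ensemble_config <- function(rounds = 100L, num_trees = 100L, mtry = NULL,
                            min_node_size = 5L,
                            mode = c("regression", "classification"),
                            master_seed = 1L) {
  mode <- match.arg(mode)
  structure(list(rounds = as.integer(rounds), num_trees = as.integer(num_trees),
                 mtry = mtry, min_node_size = as.integer(min_node_size),
                 mode = mode, master_seed = as.integer(master_seed)),
            class = "ensemble_config")
}

#' Impute pluggable features, adding missingness indicators
#'
#' Columns containing NA are imputed with the training median and paired
#' with a `miss_<name>` indicator so the forests can exploit missingness
#' itself; columns that are entirely NA impute to 0 (the indicator carries
#' all the signal).
#'
#' @param x feature data frame
#' @param stats imputation statistics from a previous call (training set);
#'   `NULL` to compute them from `x`
#' @return imputed data frame; attribute `"impute_stats"` carries the
#'   medians and indicator set for reuse at prediction time
#' @export
impute_features <- function(x, stats = NULL) {
  if (is.null(stats)) {
    miss_cols <- names(x)[vapply(x, anyNA, logical(1))]
    med <- vapply(x[miss_cols], function(v) {
      m <- stats::median(v, na.rm = TRUE)
      if (is.na(m)) 0 else m
    }, numeric(1))
    stats <- list(miss_cols = miss_cols, medians = med)
  }
  for (cn in stats$miss_cols) {
    v <- x[[cn]]
    x[[paste0("miss_", cn)]] <- as.numeric(is.na(v))
    v[is.na(v)] <- stats$medians[[cn]]
    x[[cn]] <- v
  }
  # columns with NA unseen at training time: fail loudly rather than guess
  leftover <- names(x)[vapply(x, anyNA, logical(1))]
  if (length(leftover)) {
    stop("NA in features without imputation statistics: ",
         paste(leftover, collapse = ", "), call. = FALSE)
  }
  attr(x, "impute_stats") <- stats
  x
}

#' Train the ensemble over sampled balanced rounds
#'
#' @param records record table (one row per guide/site pair) with
#'   `guide_id` and `target_value`
#' @param features feature data frame aligned row-for-row with `records`
#'   (e.g. from [feature_matrix])
#' @param config an [ensemble_config]
#' @return an object of class `cleavage_ensemble`
#' @export
train_ensemble <- function(records, features, config = ensemble_config()) {
  stopifnot(nrow(records) == nrow(features))
  if (!"target_value" %in% names(records)) {
    stop("records need a target_value column", call. = FALSE)
  }
  X <- impute_features(features)
  stats <- attr(X, "impute_stats")
  registry <- names(X)
  p <- ncol(X)
  mtry <- if (is.null(config$mtry)) max(1L, floor(p / 3)) else
    as.integer(config$mtry)
  seeds <- round_seeds(config$master_seed, config$rounds)
  members <- vector("list", config$rounds)
  for (r in seq_len(config$rounds)) {
    s <- sample_round(records, seed = seeds[r])
    idx <- attr(s, "indices")
    y <- records$target_value[idx]
    if (config$mode == "classification") {
      y <- factor(y > 0, levels = c(FALSE, TRUE))
    } else if (stats::sd(y) == 0) {
      stop("constant labels in round ", r, call. = FALSE)
    }
    dat <- X[idx, , drop = FALSE]
    dat$..y.. <- y
    members[[r]] <- ranger::ranger(
      dependent.variable.name = "..y..", data = dat,
      num.trees = config$num_trees, mtry = min(mtry, p),
      min.node.size = config$min_node_size,
      probability = config$mode == "classification",
      seed = seeds[r], num.threads = 1L, verbose = FALSE)
  }
  structure(list(members = members, feature_registry = registry,
                 impute_stats = stats, config = config,
                 mode = config$mode), class = "cleavage_ensemble")
}

#' @export
print.cleavage_ensemble <- function(x, ...) {
  cat(sprintf("<cleavage_ensemble> %d members (%s), %d features, %d trees each\n",
              length(x$members), x$mode, length(x$feature_registry),
              x$config$num_trees))
  invisible(x)
}

member_predictions <- function(model, features) {
  X <- features
  for (cn in setdiff(model$feature_registry, names(X))) {
    if (startsWith(cn, "miss_")) next
    stop("feature missing from input: ", cn, call. = FALSE)
  }
  X <- impute_features(X[, setdiff(model$feature_registry,
                                   paste0("miss_", model$impute_stats$miss_cols)),
                         drop = FALSE],
                       stats = model$impute_stats)
  X <- X[, model$feature_registry, drop = FALSE]
  vapply(model$members, function(m) {
    pr <- stats::predict(m, data = X, num.threads = 1L)$predictions
    if (model$mode == "classification") pr[, "TRUE"] else pr
  }, numeric(nrow(X)))
}

#' Predict cleavage propensity
#'
#' The propensity is the arithmetic mean of the member forests'
#' predictions; the member spread (min, max, sd) quantifies ensemble
#' disagreement.
#'
#' @param object a trained `cleavage_ensemble`
#' @param features feature data frame (rows = sites to score)
#' @param ... unused
#' @return data frame with `score`, `score_min`, `score_max`, `score_sd`
#' @export
predict.cleavage_ensemble <- function(object, features, ...) {
  pr <- member_predictions(object, features)
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1L)
  data.frame(score = rowMeans(pr),
             score_min = apply(pr, 1L, min),
             score_max = apply(pr, 1L, max),
             score_sd = apply(pr, 1L, stats::sd))
}

#' Score thresholds from the cleaved-set score distribution
#'
#' For each requested coverage quantile `q`, the cutoff that `q` of the
#' cleaved sites' predicted scores exceed (e.g. `q = 0.95` gives a lenient
#' detection threshold, `q = 0.5` a strict one).
#'
#' @param scores predicted propensities of cleaved sites (or a
#'   `cleavage_ensemble` plus `features` of cleaved sites)
#' @param quantiles coverage levels
#' @param features cleaved-site features if `scores` is a model
#' @param min_n minimum cleaved-set size accepted
#' @return named numeric vector of thresholds
#' @export
score_thresholds <- function(scores, quantiles = c(0.95, 0.50),
                             features = NULL, min_n = 20L) {
  if (inherits(scores, "cleavage_ensemble")) {
    scores <- predict(scores, features)$score
  }
  if (!length(scores)) stop("empty cleaved set", call. = FALSE)
  if (length(scores) < min_n) {
    stop("cleaved set too small (", length(scores), " < ", min_n, ")",
         call. = FALSE)
  }
  out <- stats::quantile(scores, probs = 1 - quantiles, names = FALSE)
  names(out) <- paste0("q", quantiles)
  out
}
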