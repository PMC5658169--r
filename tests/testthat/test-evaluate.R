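test_that("metric suite on a perfect predictor", {
  obs <- c(runif(50), rep(0, 50))
  lab <- obs > 0
  m <- metric_suite(obs, obs, lab)
  expect_equal(m$pearson_r2, 1)
  expect_equal(m$spearman_rho, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$roc_auc, 1)
  expect_equal(m$prc_auc, 1)
})

test_that("random scores against balanced labels give AUC 0.5", {
  set.seed(401)
  n <- 10000
  score <- runif(n)
  lab <- rep(c(TRUE, FALSE), n / 2)
  expect_equal(roc_auc(score, lab), 0.5, tolerance = 0.02)
})

test_that("ROC-AUC equals the Mann-Whitney normalization and pROC", {
  set.seed(402)
  for (i in 1:10) {
    n <- 40
    score <- round(runif(n), 2)   # ties included
    lab <- runif(n) < 0.4
    if (!any(lab) || all(lab)) next
    u <- wilcox.test(score[lab], score[!lab], exact = FALSE)$statistic
    expect_equal(roc_auc(score, lab), unname(u) / (sum(lab) * sum(!lab)))
    proc <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(lab, score, quiet = TRUE, direction = "<"))))
    expect_equal(roc_auc(score, lab), proc, tolerance = 1e-10)
  }
})

test_that("PRC-AUC of a perfect ranker is 1 at any class balance", {
  for (npos in c(2, 10, 50)) {
    score <- c(runif(npos, 0.6, 1), runif(200, 0, 0.5))
    lab <- c(rep(TRUE, npos), rep(FALSE, 200))
    expect_equal(prc_auc(score, lab), 1)
  }
})

test_that("constant predictions yield NA correlations with a warning", {
  expect_warning(m <- metric_suite(runif(10), rep(0.3, 10)), "constant")
  expect_true(is.na(m$pearson_r2))
  expect_false(is.na(m$rmse))
})

# compact synthetic records usable by the CV protocols without a genome:
# target is monotone in the (noisy) similarity of site to guide
cv_toy_records <- function(guides = 3, n_pos = 12, n_neg = 30, seed = 1,
                           studies = "s1") {
  set.seed(seed)
  mut <- function(seq, k) {
    s <- strsplit(seq, "")[[1]]
    i <- sample(20, k)
    s[i] <- vapply(s[i], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                   character(1))
    paste(s, collapse = "")
  }
  do.call(rbind, lapply(seq_len(guides), function(gi) {
    g <- random_seq(20)
    do.call(rbind, lapply(studies, function(st) {
      k_pos <- sample(0:3, n_pos, replace = TRUE)
      k_neg <- sample(4:6, n_neg, replace = TRUE)
      data.frame(
        study = st, guide_id = paste0("g", gi), guide_seq = g,
        chrom = "c1",
        start = seq_len(n_pos + n_neg) * 200,
        end = seq_len(n_pos + n_neg) * 200 + 20,
        strand = "+",
        site_seq = vapply(c(k_pos, k_neg), mut, character(1), seq = g),
        pam = "TGG", up_flank = random_seq(40), down_flank = random_seq(40),
        reads = c(round(1000 * 2^-k_pos), rep(0, n_neg)),
        stringsAsFactors = FALSE)
    }))
  }))
}

test_that("leave-one-sgRNA-out never leaks held-out records and reports metrics", {
  rec <- finalize_targets(harmonize_studies(cv_toy_records(seed = 403),
                                            reference_study = "s1"))
  rep <- loso_cv(rec, cv_config(rounds = 4, num_trees = 40,
                                reoptimize = FALSE, master_seed = 11))
  expect_s3_class(rep, "cv_report")
  # every guide was predicted by a model that never saw it (protocol audit
  # is enforced in-loop; check the output covers all guides)
  expect_setequal(unique(rep$predictions$guide_id), unique(rec$guide_id))
  # per-guide negatives are equal-sized draws
  for (gid in unique(rep$predictions$guide_id)) {
    d <- rep$predictions[rep$predictions$guide_id == gid, ]
    expect_equal(sum(!d$label), sum(d$label))
  }
  expect_true(all(c("pearson_r2", "spearman_rho", "rmse", "roc_auc",
                    "prc_auc") %in% names(rep$per_guide)))
  # strong similarity signal: the toy construction should be learnable
  expect_gt(rep$pooled$roc_auc, 0.8)
  expect_error(loso_cv(rec[rec$guide_id == "g1", ]), "at least 2 guides")
})

test_that("per-guide averaged metrics equal the mean of per-guide metrics", {
  rec <- finalize_targets(harmonize_studies(cv_toy_records(seed = 404),
                                            reference_study = "s1"))
  rep <- loso_cv(rec, cv_config(rounds = 3, num_trees = 30,
                                reoptimize = FALSE, master_seed = 12))
  manual <- vapply(split(rep$predictions, rep$predictions$guide_id),
                   function(d) cor(d$observed, d$predicted)^2, numeric(1))
  expect_equal(unname(rep$per_guide_mean["pearson_r2"]),
               mean(manual, na.rm = TRUE), tolerance = 1e-10)
})

test_that("leave-study-out splits unique and common guides", {
  rec1 <- cv_toy_records(guides = 2, seed = 405, studies = "s1")
  # second study re-profiles guide g1 (common) plus its own new guide
  rec2 <- rec1[rec1$guide_id == "g1", ]
  rec2$study <- "s2"
  rec2$reads <- pmax(0, round(rec2$reads * 1.6))
  extra <- cv_toy_records(guides = 1, seed = 406, studies = "s2")
  extra$guide_id <- "g9"
  rec <- rbind(rec1, rec2, extra)
  rec <- finalize_targets(harmonize_studies(rec, reference_study = "s1"))
  out <- leave_study_out(rec, cv_config(rounds = 3, num_trees = 30,
                                        reoptimize = FALSE, master_seed = 13))
  expect_s3_class(out, "lso_report")
  s2 <- out[["s2"]]
  expect_false(is.null(s2$common_guides))
  expect_false(is.null(s2$unique_guides))
  expect_setequal(unique(s2$common_guides$predictions$guide_id), "g1")
  expect_setequal(unique(s2$unique_guides$predictions$guide_id), "g9")
  expect_error(leave_study_out(rec[rec$study == "s1", ]),
               "at least 2 studies")
})

test_that("negative-fraction sweep: identity at 100%, positives-only at 0%", {
  set.seed(407)
  pred <- do.call(rbind, lapply(c("g1", "g2"), function(gid) {
    obs <- c(runif(15, 0.2, 1), rep(0, 15))
    data.frame(guide_id = gid, observed = obs,
               predicted = obs + rnorm(30, 0, 0.1),
               label = obs > 0, stringsAsFactors = FALSE)
  }))
  sw <- negative_fraction_sweep(pred, fractions = c(1, 0.5, 0))
  full <- mean(vapply(split(pred, pred$guide_id), function(d)
    cor(d$observed, d$predicted)^2, numeric(1)))
  pos_only <- mean(vapply(split(pred[pred$label, ], pred$guide_id[pred$label]),
                          function(d) cor(d$observed, d$predicted)^2,
                          numeric(1)))
  expect_equal(sw$pearson_r2[sw$fraction == 1], full, tolerance = 1e-10)
  expect_equal(sw$pearson_r2[sw$fraction == 0], pos_only, tolerance = 1e-10)
  expect_error(negative_fraction_sweep(pred, fractions = c(-0.1)),
               "\\[0, 1\\]")
})
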