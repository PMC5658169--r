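# independent naive scorer for the mining oracle: every PAM on either
# strand, gapless 20-mer match count only (mining must find at least these,
# and agree exactly when gaps cannot raise a random site above threshold)
naive_scan <- function(guide, contig, min_matches) {
  g <- strsplit(guide, "")[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else revcomp(contig)
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    for (p0 in 20:(n - 3)) {            # 0-based PAM start
      pam <- chars[(p0 + 2):(p0 + 3)]   # PAM bases 2-3 (1-based p0+2, p0+3)
      if (!(all(pam == c("G", "G")) || all(pam == c("A", "G")))) next
      win <- chars[(p0 - 19):p0]
      m <- sum(win == g)
      if (m > min_matches) {
        st <- if (strand == "+") p0 - 20 else nchar(contig) - p0
        hits[[length(hits) + 1]] <- data.frame(strand = strand, start = st,
                                               matches = m)
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else NULL
}

test_that("a planted perfect protospacer with TGG PAM is mined at score 20", {
  set.seed(91)
  g <- random_seq(20)
  left <- random_seq(60); right <- random_seq(60)
  genome <- c(chr1 = paste0(left, g, "TGG", right))
  res <- mine_negatives(g, genome, min_score = 19.5, flank = 10)
  expect_gte(nrow(res), 1)
  planted <- res[res$start == 60 & res$strand == "+", ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$score, 20)
  expect_equal(planted$site_seq, g)
})

test_that("a contig without NGG/NAG on either strand yields nothing", {
  genome <- c(chr1 = strrep("AT", 200))   # no G at all, no C either
  res <- mine_negatives(random_seq(20), genome, min_score = 0)
  expect_equal(nrow(res), 0)
})

test_that("mining agrees with a brute-force naive re-scan on a random contig", {
  set.seed(92)
  g <- random_seq(20)
  contig <- random_seq(5000)
  # embed two decoys: 2 and 4 mismatches
  mut <- function(seq, k) {
    s <- strsplit(seq, "")[[1]]
    i <- sample(20, k)
    s[i] <- vapply(s[i], function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                   character(1))
    paste(s, collapse = "")
  }
  contig <- paste0(substr(contig, 1, 2000), mut(g, 2), "TGG",
                   substr(contig, 2024, 3500), mut(g, 4), "AAG",
                   substr(contig, 3524, 5000))
  genome <- c(chr1 = contig)
  # gapless params so the naive match-count scan is an exact oracle
  p <- alignment_params(match = 1, mismatch = 0, gap = -1.25, max_gaps = 0L)
  res <- mine_negatives(g, genome, params = p, min_score = 14.75, flank = 5)
  oracle <- naive_scan(g, contig, min_matches = 14.75)
  expect_equal(nrow(res), nrow(oracle))
  expect_setequal(paste(res$strand, res$start), paste(oracle$strand, oracle$start))
  expect_setequal(res$score, oracle$matches)
})

test_that("mining is invariant under reverse-complementing the contig", {
  set.seed(93)
  g <- random_seq(20)
  contig <- paste0(random_seq(400), g, "CGG", random_seq(400))
  res_f <- mine_negatives(g, c(c1 = contig), min_score = 14.75, flank = 5)
  res_r <- mine_negatives(g, c(c1 = revcomp(contig)), min_score = 14.75,
                          flank = 5)
  expect_equal(nrow(res_f), nrow(res_r))
  Lc <- nchar(contig)
  mirrored <- data.frame(strand = ifelse(res_f$strand == "+", "-", "+"),
                         start = Lc - res_f$end)
  expect_setequal(paste(res_r$strand, res_r$start),
                  paste(mirrored$strand, mirrored$start))
  expect_setequal(res_r$score, res_f$score)
})

test_that("mined negatives never overlap excluded cleaved intervals", {
  set.seed(94)
  g <- random_seq(20)
  contig <- paste0(random_seq(100), g, "TGG", random_seq(100))
  cleaved <- data.frame(chrom = "c1", start = 100, end = 120, strand = "+")
  res <- mine_negatives(g, c(c1 = contig), min_score = 14.75, flank = 5,
                        exclude = cleaved)
  expect_false(any(res$chrom == "c1" & res$strand == "+" &
                     res$start < 120 & res$end > 100))
})

test_that("deduplication keeps the reference collection and drops exclusions", {
  rec <- data.frame(
    study = c(rep("Tsai", 3), rep("Kleinstiver", 2), rep("Frock", 2),
              rep("Ran", 2)),
    guide_id = c("g1", "g1", "g1", "g1", "g1", "g2", "g2", "g3", "g3"),
    reads = 1:9, stringsAsFactors = FALSE)
  out <- deduplicate(rec)
  expect_false(any(out$study == "Frock"))
  expect_equal(sort(unique(out$study[out$guide_id == "g1"])), "Tsai")
  expect_equal(sum(out$guide_id == "g1"), 3)
  expect_equal(sum(out$guide_id == "g3"), 2)   # single-study guide unchanged
  # duplicated guide absent from reference: keep the larger collection, warn
  rec2 <- data.frame(study = c("A", "A", "B"), guide_id = "g9", reads = 1:3,
                     stringsAsFactors = FALSE)
  expect_warning(out2 <- deduplicate(rec2, reference_study = "Tsai"),
                 "keeping A")
  expect_equal(unique(out2$study), "A")
})

make_balanced_records <- function(npos = 10, nneg = 30, guides = c("g1", "g2")) {
  do.call(rbind, lapply(guides, function(gid) {
    data.frame(guide_id = gid,
               record_id = paste0(gid, "_", seq_len(npos + nneg)),
               target_value = c(runif(npos, 0.1, 1), rep(0, nneg)),
               stringsAsFactors = FALSE)
  }))
}

test_that("sampled rounds are exactly class-balanced at 2x bootstrap", {
  set.seed(95)
  rec <- make_balanced_records()
  s <- sample_round(rec, seed = 123)
  for (gid in c("g1", "g2")) {
    sub <- s[s$guide_id == gid, ]
    expect_equal(sum(sub$target_value > 0), 20)   # 2 x 10 positives
    expect_equal(sum(sub$target_value == 0), 20)  # equal negatives
    # negatives drawn without replacement
    expect_false(any(duplicated(sub$record_id[sub$target_value == 0])))
  }
  expect_identical(sample_round(rec, seed = 123), sample_round(rec, seed = 123))
  expect_error(sample_round(make_balanced_records(npos = 20, nneg = 10), 1),
               "needs >=")
})

test_that("bootstrap inclusion frequency matches the binomial expectation", {
  set.seed(96)
  n <- 12
  rec <- make_balanced_records(npos = n, nneg = 3 * n, guides = "g1")
  pos_ids <- rec$record_id[rec$target_value > 0]
  rounds <- 600
  seen <- matrix(FALSE, rounds, n, dimnames = list(NULL, pos_ids))
  for (r in seq_len(rounds)) {
    s <- sample_round(rec, seed = 1000 + r)
    seen[r, ] <- pos_ids %in% s$record_id[s$target_value > 0]
  }
  p_expect <- 1 - (1 - 1 / n)^(2 * n)
  p_hat <- colMeans(seen)
  se <- sqrt(p_expect * (1 - p_expect) / rounds)
  expect_true(all(abs(p_hat - p_expect) < 3.5 * se))
})
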