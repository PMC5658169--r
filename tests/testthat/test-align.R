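test_that("identity and single-deletion alignments score as expected", {
  p <- alignment_params()
  a <- align_fixed(strrep("G", 20), strrep("G", 20), p)
  expect_equal(a$score, 20)
  expect_equal(a$n_match, 20)
  expect_equal(a$n_mismatch, 0)
  expect_equal(a$n_dna_bulge + a$n_rna_bulge, 0)

  g <- "ACGTACGTACGTACGTACGT"
  t <- paste0(substr(g, 1, 9), substr(g, 11, 20))  # drop target base 10
  a <- align_fixed(g, t, p)
  expect_equal(a$score, 19 * 1 + 1 * (-1.25))
  expect_equal(a$n_match, 19)
  expect_equal(a$n_dna_bulge + a$n_rna_bulge, 1)
  expect_equal(a$n_rna_bulge, 1)  # gap in the target row: unpaired spacer base
})

test_that("gapless alignment wins when gaps cannot pay for themselves", {
  # equal-length pair where any gapped alignment needs >= 2 gaps costing 2.5
  # while recovering <= 2 matches: returned alignment must be gapless
  set.seed(7)
  p <- alignment_params()
  for (i in 1:20) {
    g <- random_seq(20)
    t <- random_seq(20)
    a <- align_fixed(g, t, p)
    bf0 <- brute_force_score(g, t, max_gaps = 0L)
    bf <- brute_force_score(g, t, max_gaps = 3L)
    expect_equal(a$score, bf)
    if (bf == bf0) {
      expect_equal(a$n_dna_bulge + a$n_rna_bulge, 0)
    }
  }
})

test_that("DP equals brute-force enumeration on random short pairs", {
  set.seed(42)
  for (i in 1:150) {
    n <- sample(6:12, 1)
    m <- n + sample(-2:2, 1)
    mg <- sample(0:2, 1)
    if (abs(m - n) > mg) next
    g <- random_seq(n)
    t <- random_seq(m)
    mm <- -sample(0:6, 1) / 4
    gp <- -sample(1:12, 1) / 4
    got <- alignment_score_batch(g, t, alignment_params(1, mm, gp, mg))
    expect_equal(got, brute_force_score(g, t, 1, mm, gp, mg),
                 info = sprintf("%s vs %s (mm=%g gap=%g mg=%d)", g, t, mm, gp, mg))
  }
})

test_that("gap budget, score decomposition and monotonicity invariants hold", {
  set.seed(11)
  p <- alignment_params(mismatch = -0.25)
  for (i in 1:40) {
    g <- random_seq(20)
    t <- random_seq(sample(17:23, 1))
    a <- align_fixed(g, t, p)
    expect_lte(a$n_dna_bulge + a$n_rna_bulge, p$max_gaps)
    expect_equal(a$score,
                 p$match * a$n_match + p$mismatch * a$n_mismatch +
                   p$gap * (a$n_dna_bulge + a$n_rna_bulge))
    expect_equal(nchar(a$aligned_guide), nchar(a$aligned_target))

    # corrupt a matched column of the optimal alignment: the score can only
    # move within [old - (match - mismatch), old + (match - mismatch)] (a
    # different alignment may pair the substituted base as a new match)
    ag <- strsplit(a$aligned_guide, "")[[1]]
    at <- strsplit(a$aligned_target, "")[[1]]
    mcols <- which(ag != "-" & at != "-" & ag == at)
    if (length(mcols)) {
      k <- mcols[1]
      tpos <- sum(at[seq_len(k)] != "-")
      tt <- strsplit(t, "")[[1]]
      tt[tpos] <- setdiff(c("A", "C", "G", "T"), tt[tpos])[1]
      a2 <- align_fixed(g, paste(tt, collapse = ""), p)
      expect_lte(abs(a2$score - a$score), p$match - p$mismatch + 1e-12)
    }
  }
})

test_that("corrupting a matched base never increases the gapless score", {
  set.seed(13)
  p <- alignment_params(mismatch = -0.25, max_gaps = 0L)
  for (i in 1:30) {
    g <- random_seq(20)
    t <- random_seq(20)
    a <- align_fixed(g, t, p)
    gg <- strsplit(g, "")[[1]]
    tt <- strsplit(t, "")[[1]]
    k <- which(gg == tt)
    if (!length(k)) next
    tt[k[1]] <- setdiff(c("A", "C", "G", "T"), tt[k[1]])[1]
    a2 <- align_fixed(g, paste(tt, collapse = ""), p)
    expect_lt(a2$score, a$score)
  }
})

test_that("a prohibitive gap penalty reduces to the gapless Hamming score", {
  set.seed(3)
  p <- alignment_params(gap = -(1 * 3 * 2 + 1), max_gaps = 3L)
  for (i in 1:25) {
    g <- random_seq(20)
    t <- random_seq(20)
    a <- align_fixed(g, t, p)
    hamming <- sum(strsplit(g, "")[[1]] == strsplit(t, "")[[1]])
    expect_equal(a$score, hamming * 1 + (20 - hamming) * 0)
    expect_equal(a$n_dna_bulge + a$n_rna_bulge, 0)
  }
})

test_that("alignment is deterministic and mismatch bookkeeping is PAM-proximal", {
  g <- strrep("A", 20)
  t <- paste0(strrep("A", 19), "G")  # mismatch at the PAM-proximal base
  a <- align_fixed(g, t)
  expect_equal(a$mismatch_positions, 1L)
  expect_equal(a$mismatch_pairs$guide, "A")
  expect_equal(a$mismatch_pairs$target_strand, "C")  # opposing strand base

  t2 <- paste0("G", strrep("A", 19))  # mismatch at the PAM-distal base
  expect_equal(align_fixed(g, t2)$mismatch_positions, 20L)

  a1 <- align_fixed("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACG")
  a2 <- align_fixed("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACG")
  expect_identical(a1$aligned_target, a2$aligned_target)
})

test_that("align_fixed validates its inputs", {
  expect_error(align_fixed("ACGT", "ACGT"), "20 nt")
  expect_error(align_fixed(strrep("A", 20), strrep("A", 16)), "17-23")
  expect_error(align_fixed(strrep("A", 20), strrep("A", 24)), "17-23")
  expect_error(align_fixed(strrep("A", 20), paste0(strrep("A", 19), "X")),
               "non-ACGT")
  expect_error(align_fixed(strrep("A", 20), strrep("A", 17),
                           alignment_params(max_gaps = 2L)), "gap budget")
})

test_that("best-of-seven window search picks the top-scoring window", {
  p <- alignment_params()
  g <- "ACGTACGTACGTACGTACGT"
  site <- target_site("chr1", 100, 120, "+", g, "TGG",
                      upstream_flank = "AAATTTCCC")
  a <- align_best_window(g, site, p)
  expect_equal(a$chosen_window, 20L)
  expect_equal(a$score, 20)

  # 20-nt window has 2 mismatches (score 18); deleting one target base would
  # give 19 matches + 1 gap = 17.75 in the 19-nt window: 20-nt wins
  t20 <- paste0("TT", substr(g, 3, 20))
  site2 <- target_site("chr1", 100, 120, "+", t20, "TGG",
                       upstream_flank = "GGGGGGGGG")
  a2 <- align_best_window(g, site2, p)
  expect_equal(a2$chosen_window, 20L)
  expect_equal(a2$score, 18)

  # superset property: best-of-7 >= the 20-nt window score
  set.seed(5)
  for (i in 1:25) {
    gg <- random_seq(20)
    ext <- random_seq(23)
    s20 <- align_fixed(gg, substr(ext, 4, 23), p)$score
    expect_gte(align_best_window(gg, ext, p)$score, s20)
  }
})

test_that("window construction truncates with a warning on short flanks", {
  g <- random_seq(20)
  site <- target_site("c", 0, 20, "+", g, "AGG", upstream_flank = "A")
  expect_warning(w <- target_windows(site), "truncated")
  expect_equal(sort(as.integer(names(w))), 17:21)
  expect_error(target_windows(substr(g, 1, 16)), "no constructible window")
})

test_that("a 1-bulge window can beat the mismatch-only 20-nt window", {
  # target built by deleting a guide base; the extra PAM-distal flank base
  # completes a 20-nt window with many mismatches, while the 19-nt window
  # aligns with one bulge and 19 matches
  g <- "ACGTACGTACGTACGTACGT"
  t19 <- paste0(substr(g, 1, 9), substr(g, 11, 20))
  site <- target_site("c", 50, 69, "+", t19, "CGG",
                      upstream_flank = strrep("T", 10))
  a <- align_best_window(g, site)
  expect_equal(a$chosen_window, 19L)
  expect_equal(a$score, 17.75)
  expect_equal(a$n_rna_bulge + a$n_dna_bulge, 1)
})
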