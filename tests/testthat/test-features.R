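test_that("mismatch chemistry classes follow wobble/heteroduplex rules", {
  expect_equal(classify_mismatch("G", "T"), "wobble")
  expect_equal(classify_mismatch("T", "G"), "wobble")
  expect_equal(classify_mismatch("A", "G"), "transition_RR")
  expect_equal(classify_mismatch("G", "A"), "transition_RR")
  expect_equal(classify_mismatch("C", "T"), "transition_YY")
  expect_equal(classify_mismatch("A", "C"), "transversion")
  expect_equal(classify_mismatch("C", "A"), "transversion")
  # matched pairs are complementary in the heteroduplex, not identical
  expect_error(classify_mismatch("A", "T"), "matched")
  expect_error(classify_mismatch("G", "C"), "matched")
})

test_that("every mismatching heteroduplex pair maps to exactly one class", {
  for (g in c("A", "C", "G", "T")) {
    for (d in c("A", "C", "G", "T")) {
      if (chartr("ACGT", "TGCA", d) == g) next
      cls <- classify_mismatch(g, d)
      expect_true(cls %in% c("wobble", "transition_RR", "transition_YY",
                             "transversion"))
    }
  }
})

test_that("nearest-neighbor enthalpy matches an independent hand summation", {
  # independent: sum the published stack values directly
  expect_equal(nn_enthalpy("ACGT"), (-8.4) + (-10.6) + (-8.4))
  expect_equal(nn_enthalpy("AA"), -7.9)
  expect_warning(e1 <- nn_enthalpy("A"), "shorter than 2")
  expect_equal(e1, 0)
  expect_warning(nn_enthalpy("ANA"), "ambiguous")
})

test_that("enthalpy is reverse-complement symmetric and junction-additive", {
  set.seed(9)
  for (i in 1:20) {
    s <- random_seq(sample(10:60, 1))
    expect_equal(nn_enthalpy(s), nn_enthalpy(revcomp(s)))
  }
  x <- random_seq(15); y <- random_seq(12)
  junction <- paste0(substr(x, 15, 15), substr(y, 1, 1))
  expect_equal(nn_enthalpy(paste0(x, y)),
               nn_enthalpy(x) + nn_enthalpy(y) + unname(nn_enthalpy(junction)))
})

perfect_site <- function(guide, pam = "TGG") {
  target_site("chr1", 200, 220, "+", guide, pam,
              upstream_flank = random_seq(100),
              downstream_flank = random_seq(100))
}

test_that("a perfect-match NGG site yields the expected canonical features", {
  set.seed(31)
  g <- random_seq(20)
  site <- perfect_site(g)
  aln <- align_best_window(g, site)
  fv <- compute_features(g, site, aln)
  expect_equal(unname(fv["alignment_score"]), 20)
  expect_equal(unname(fv["n_mismatch"]), 0)
  expect_equal(unname(fv[paste0("n_", c("wobble", "transition_RR",
                                        "transition_YY", "transversion"))]),
               rep(0, 4))
  expect_equal(unname(fv["pam_NGG"]), 1)
  expect_equal(unname(fv["pam_NAG"]), 0)
  expect_equal(sum(fv[paste0("mm_pos_", 1:20)]), 0)
  expect_true(all(fv["gc_site"] >= 0 & fv["gc_site"] <= 1))
})

test_that("GC content and one-hot blocks behave", {
  g <- "GGGGCCCCGGGGCCCCGGGG"
  site <- target_site("c", 0, 20, "+", g, "AGG",
                      upstream_flank = strrep("A", 30),
                      downstream_flank = strrep("G", 30))
  fv <- compute_features(g, site, align_best_window(g, site))
  expect_equal(unname(fv["gc_site"]), 1.0)
  expect_equal(unname(fv["gc_flank_up"]), 0)
  expect_equal(unname(fv["gc_flank_down"]), 1)
  for (p in c("pos2", "pos4", "pos5", "pos20", paste0("pamdown", 1:5))) {
    expect_equal(sum(fv[paste0(p, "_", c("A", "C", "G", "T"))]), 1,
                 info = p)
  }
  expect_equal(sum(fv[c("pam_NGG", "pam_NAG", "pam_other")]), 1)
  # PAM-proximal numbering: pos20 is the 5'-most base of the 20-nt site
  expect_equal(unname(fv["pos20_G"]), 1)
  expect_equal(unname(fv["pos2_G"]), 1)  # 2nd base upstream of the PAM
})

test_that("per-class mismatch counts sum to n_mismatch on random alignments", {
  set.seed(17)
  for (i in 1:25) {
    g <- random_seq(20)
    site <- perfect_site(random_seq(20))
    aln <- align_best_window(g, site)
    fv <- compute_features(g, site, aln)
    expect_equal(sum(fv[paste0("n_", c("wobble", "transition_RR",
                                       "transition_YY", "transversion"))]),
                 unname(fv["n_mismatch"]))
    expect_equal(unname(fv["n_bulge"]),
                 unname(fv["n_dna_bulge"] + fv["n_rna_bulge"]))
  }
})

test_that("pluggable features are NA-flagged without providers, filled with them", {
  set.seed(41)
  g <- random_seq(20)
  site <- perfect_site(g)
  aln <- align_best_window(g, site)
  fv <- compute_features(g, site, aln)
  expect_true(all(is.na(fv[c("mgw_pam", "bend_stiffness", "dnase_hs",
                             "expression", "sgrna_folding_energy")])))

  pent <- expand.grid(rep(list(c("A", "C", "G", "T")), 5))
  pent_names <- apply(pent, 1, paste, collapse = "")
  mgw <- stats::setNames(runif(length(pent_names), 4, 6), pent_names)
  di <- expand.grid(rep(list(c("A", "C", "G", "T")), 2))
  stiff <- stats::setNames(runif(16, 0, 1), apply(di, 1, paste, collapse = ""))
  ann <- data.frame(seq_id = "chr1", start = 150, end = 260,
                    dnase_hs = 1, exon_coding = 1, exon_opposite = 0,
                    cpg_island = 0, expression = 7.5)
  fv2 <- compute_features(g, site, aln, annotations = ann, shape_mgw = mgw,
                          shape_stiffness = stiff, folding_energy = -3.2)
  expect_false(anyNA(fv2))
  expect_equal(unname(fv2["dnase_hs"]), 1)
  expect_equal(unname(fv2["expression"]), 7.5)
  expect_equal(unname(fv2["sgrna_folding_energy"]), -3.2)
  # non-overlapping annotation interval -> 0, not NA
  ann2 <- data.frame(seq_id = "chr1", start = 0, end = 10, dnase_hs = 1,
                     exon_coding = 0, exon_opposite = 0, cpg_island = 0,
                     expression = 2)
  fv3 <- compute_features(g, site, aln, annotations = ann2)
  expect_equal(unname(fv3["dnase_hs"]), 0)
})

test_that("feature extraction is pure and registry-ordered", {
  set.seed(53)
  g <- random_seq(20)
  site <- perfect_site(random_seq(20))
  aln <- align_best_window(g, site)
  expect_identical(compute_features(g, site, aln),
                   compute_features(g, site, aln))
  expect_identical(names(compute_features(g, site, aln)),
                   as.character(feature_registry()))
})

test_that("feature_matrix aligns and featurizes a record table", {
  set.seed(61)
  g <- random_seq(20)
  rec <- data.frame(
    guide_id = "g1", guide_seq = g,
    site_seq = c(g, paste0("TT", substr(g, 3, 20))),
    pam = c("AGG", "TAG"),
    up_flank = random_seq(30), down_flank = random_seq(30),
    dnase_hs = c(1, 0), stringsAsFactors = FALSE)
  fm <- feature_matrix(rec)
  expect_equal(nrow(fm), 2)
  expect_equal(fm$alignment_score[1], 20)
  expect_equal(fm$pam_NAG, c(0, 1))
  expect_equal(fm$dnase_hs, c(1, 0))
})
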