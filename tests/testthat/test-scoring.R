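test_that("splice consensus agrees with enumeration of all vote patterns", {
  # oracle: enumerate all 2^3 significance patterns; significant deltas sit
  # well past each threshold, non-significant ones well inside
  sig_val <- c(mes = -20, nns = -20, ssf = -20)
  ns_val <- c(mes = -1, nns = -1, ssf = -1)
  for (mes_on in c(FALSE, TRUE)) for (nns_on in c(FALSE, TRUE))
    for (ssf_on in c(FALSE, TRUE)) {
      votes <- sum(mes_on, nns_on, ssf_on)
      got <- splice_consensus(if (mes_on) sig_val["mes"] else ns_val["mes"],
                              if (nns_on) sig_val["nns"] else ns_val["nns"],
                              if (ssf_on) sig_val["ssf"] else ns_val["ssf"])
      expect_identical(got, votes >= 2,
                       label = sprintf("pattern %d%d%d", mes_on, nns_on, ssf_on))
    }
})

test_that("thresholds are per program and inclusive at the boundary", {
  # exactly at threshold counts as significant (documented decision)
  expect_true(splice_consensus(-10, -5, 0))
  expect_false(splice_consensus(-9.99, -5, 0))
  expect_false(splice_consensus(-10, -4.99, 0))
  expect_true(splice_consensus(0, -5, -15))
  # thresholds differ per program: -10 is enough for MES but not for SSF
  expect_false(splice_consensus(0, -4, -14.9))
  # absent programs abstain; all absent is no consensus
  expect_false(splice_consensus(NA, NA, NA))
  expect_false(splice_consensus(-20, NA, NA))
  expect_true(splice_consensus(-20, -20, NA))
  # worked examples
  expect_true(splice_consensus(-12, -6, -3))
  expect_false(splice_consensus(-12, -2, -3))
  expect_false(splice_consensus(0, 0, 0))
})

test_that("deltas recompute from wt/var scores when both are present", {
  ann <- ann_fixture(var_location = "intron", dist_nearest_ss = 5,
                     nearest_ss = "donor",
                     mes_wt = 10, mes_var = 8.9,   # -11% recomputed
                     nns_wt = 10, nns_var = 9.4,   # -6%
                     ssf_delta = -1)
  got <- score_variants(ann)
  expect_equal(got$final_score, 70)  # close splice via 2 recomputed votes
  # supplied delta wins only when scores are absent
  ann2 <- ann_fixture(var_location = "intron", dist_nearest_ss = 5,
                      nearest_ss = "donor",
                      mes_wt = 10, mes_var = 9.5, mes_delta = -50, # -5%: no vote
                      nns_delta = -6, ssf_delta = -1)
  expect_equal(score_variants(ann2)$final_score, 0)
})

test_that("splice categories follow the positional windows", {
  cfg <- scoring_config()
  # essential: two first intronic bases, either site, consensus irrelevant
  expect_equal(splice_category(1, "donor", FALSE, cfg), "essential")
  expect_equal(splice_category(2, "acceptor", FALSE, cfg), "essential")
  # close: donor -3..+6 / acceptor -12 intronic..+2 exonic, consensus needed
  expect_equal(splice_category(5, "donor", TRUE, cfg), "close")
  expect_equal(splice_category(-3, "donor", TRUE, cfg), "close")
  expect_equal(splice_category(6, "donor", TRUE, cfg), "close")
  expect_equal(splice_category(-4, "donor", TRUE, cfg), "none")
  expect_equal(splice_category(7, "donor", TRUE, cfg), "deep")
  expect_equal(splice_category(12, "acceptor", TRUE, cfg), "close")
  expect_equal(splice_category(-2, "acceptor", TRUE, cfg), "close")
  expect_equal(splice_category(-3, "acceptor", TRUE, cfg), "none")
  expect_equal(splice_category(13, "acceptor", TRUE, cfg), "deep")
  # deep intronic needs consensus; exonic side never deep
  expect_equal(splice_category(87, "acceptor", TRUE, cfg), "deep")
  expect_equal(splice_category(87, "acceptor", FALSE, cfg), "none")
  expect_equal(splice_category(-30, "donor", TRUE, cfg), "none")
  # unknown site type: none, with a warning when it would otherwise score
  expect_warning(got <- splice_category(87, NA, TRUE, cfg), "unknown")
  expect_equal(got, "none")
})

test_that("adjustments follow the conservation and predictor rules", {
  # conservation-adjusted categories gain exactly one step
  for (cat in c("nonsense", "start loss", "stop loss", "synonymous",
                "essential", "close", "deep")) {
    expect_equal(score_adjustment(cat, phastcons = 0.99), 5L, label = cat)
    expect_equal(score_adjustment(cat, phastcons = 0.5), 0L, label = cat)
  }
  # cutoff is strict: 0.95 itself does not trigger
  expect_equal(score_adjustment("nonsense", phastcons = 0.95), 0L)
  # frameshift / in-frame / known never adjust
  for (cat in c("frameshift", "in-frame", "known mutation", "none")) {
    expect_equal(score_adjustment(cat, phastcons = 0.99), 0L, label = cat)
  }
  # missense stacks +5 per deleterious predictor on top of conservation
  expect_equal(score_adjustment("missense", 0.99, sift_pred = "Deleterious",
                                pph2_pred = "probably damaging"), 15L)
  expect_equal(score_adjustment("missense", 0.5, sift_pred = "Deleterious"), 5L)
  expect_equal(score_adjustment("missense", 0.5, sift_weight = 0.04), 5L)
  expect_equal(score_adjustment("missense", 0.5, sift_pred = "Tolerated",
                                pph2_pred = "neutral"), 0L)
  # missing predictors contribute nothing
  expect_equal(score_adjustment("missense", NA), 0L)
})

test_that("known-mutation evidence overrides any category, unadjusted", {
  ann <- ann_fixture(coding_effect = "synonymous",
                     rs_clinical_significance = "pathogenic",
                     phastcons = 0.99)
  got <- score_variants(ann)
  expect_equal(got$final_score, 110)
  expect_equal(got$category, "known mutation")
  expect_equal(got$adjustment, 0L)
  # token match: non-pathogenic is not pathogenic
  benign <- ann_fixture(coding_effect = "synonymous",
                        rs_clinical_significance = "non-pathogenic")
  expect_equal(score_variants(benign)$final_score, 10)
  probable <- ann_fixture(coding_effect = "synonymous",
                          rs_clinical_significance = "probable-pathogenic")
  expect_equal(score_variants(probable)$final_score, 110)
  # user-supplied known ids extend the evidence
  plain <- ann_fixture(coding_effect = "synonymous")
  expect_equal(score_variants(plain, known_ids = "1_100_A_T")$final_score, 110)
})

test_that("the most pathogenic effect across transcripts and pathways wins", {
  # transcript A intronic, transcript B nonsense: nonsense wins
  anns <- dplyr::bind_rows(
    ann_fixture(transcript_id = "A", transcript_length = 3000,
                coding_effect = NA, var_location = "intron"),
    ann_fixture(transcript_id = "B", transcript_length = 1000,
                coding_effect = "nonsense"))
  got <- score_variants(anns)
  expect_equal(got$final_score, 100)
  expect_equal(got$transcript_id, "B")
  # last exon base: missense vs essential splice -> splice pathway, 90
  boundary <- ann_fixture(coding_effect = "missense", dist_nearest_ss = 1,
                          nearest_ss = "donor")
  got <- score_variants(boundary)
  expect_equal(got$final_score, 90)
  expect_equal(got$pathway, "splice")
  expect_equal(got$category, "essential splice")
  # same transcript, coding wins when stronger
  boundary2 <- ann_fixture(coding_effect = "nonsense", dist_nearest_ss = 5,
                           nearest_ss = "donor", mes_delta = -20,
                           nns_delta = -20, ssf_delta = -20)
  got <- score_variants(boundary2)
  expect_equal(got$final_score, 100)
  expect_equal(got$pathway, "coding")
})

test_that("scorer agrees with a brute-force oracle on random annotation sets", {
  set.seed(77)
  effects <- c(NA, "nonsense", "frameshift", "start loss", "stop loss",
               "missense", "in-frame", "synonymous")
  for (rep in 1:60) {
    n_tx <- sample(1:4, 1)
    anns <- dplyr::bind_rows(lapply(seq_len(n_tx), function(i) {
      ann_fixture(
        transcript_id = sprintf("T%d", i),
        transcript_length = sample(500:3000, 1),
        coding_effect = sample(effects, 1),
        var_location = sample(c("exon", "intron"), 1),
        phastcons = sample(c(NA, 0.5, 0.96, 0.99), 1),
        sift_pred = sample(c(NA, "Tolerated", "Deleterious"), 1),
        pph2_pred = sample(c(NA, "neutral", "probably damaging"), 1),
        dist_nearest_ss = sample(c(NA, -5, -2, 1, 2, 4, 10, 87), 1),
        nearest_ss = sample(c(NA, "donor", "acceptor"), 1),
        mes_delta = sample(c(NA, 0, -10, -30), 1),
        nns_delta = sample(c(NA, 0, -5, -30), 1),
        ssf_delta = sample(c(NA, 0, -15, -30), 1),
        rs_clinical_significance = sample(c(NA, NA, NA, "pathogenic"), 1))
    }))
    expected <- brute_force_score(anns)
    got <- suppressWarnings(score_variants(anns))$final_score
    expect_equal(got, expected, label = sprintf("random set %d", rep))
  }
})

test_that("scores are monotone in conservation and predictor evidence", {
  for (eff in c("nonsense", "missense", "synonymous")) {
    lo <- score_variants(ann_fixture(coding_effect = eff, phastcons = 0.5))
    hi <- score_variants(ann_fixture(coding_effect = eff, phastcons = 0.99))
    expect_gte(hi$final_score, lo$final_score)
  }
  base <- score_variants(ann_fixture(coding_effect = "missense"))
  plus1 <- score_variants(ann_fixture(coding_effect = "missense",
                                      sift_pred = "Deleterious"))
  plus2 <- score_variants(ann_fixture(coding_effect = "missense",
                                      sift_pred = "Deleterious",
                                      pph2_pred = "deleterious"))
  expect_true(base$final_score < plus1$final_score)
  expect_true(plus1$final_score < plus2$final_score)
})

test_that("every reachable default-config score lies in the closed score set", {
  reachable <- c(0, 10, 15, 25, 30, 40, 50, 55, 60, 65, 70, 75, 80, 85, 90,
                 95, 100, 105, 110)
  grid <- expand.grid(
    effect = c(NA, "nonsense", "frameshift", "start loss", "stop loss",
               "missense", "in-frame", "synonymous"),
    phast = c(0.5, 0.99),
    sift = c(NA, "Deleterious"),
    pph2 = c(NA, "probably damaging"),
    dist = c(NA, 1, 4, 87),
    site = c(NA, "donor", "acceptor"),
    consensus = c(FALSE, TRUE),
    known = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ann <- ann_fixture(
      coding_effect = g$effect, phastcons = g$phast, sift_pred = g$sift,
      pph2_pred = g$pph2, dist_nearest_ss = g$dist, nearest_ss = g$site,
      mes_delta = if (g$consensus) -30 else NA_real_,
      nns_delta = if (g$consensus) -30 else NA_real_,
      ssf_delta = NA_real_,
      rs_clinical_significance = if (g$known) "pathogenic" else NA_character_)
    s <- suppressWarnings(score_variants(ann))$final_score
    expect_true(s %in% reachable, label = sprintf("combo %d gives %s", i, s))
  }
})

test_that("category ordering is preserved under order-preserving configs", {
  cfg <- scoring_config(S_Known = 1100, S_Nonsense = 1000, S_Fs = 1000,
                        S_EssentialSplice = 900, S_StartLoss = 800,
                        S_StopLoss = 800, S_CloseSplice = 700,
                        S_Missense = 500, S_Inframe = 400,
                        S_DeepSplice = 250, S_Synonymous = 100)
  lo <- score_variants(ann_fixture(coding_effect = "synonymous"), cfg)
  mid <- score_variants(ann_fixture(coding_effect = "missense"), cfg)
  hi <- score_variants(ann_fixture(coding_effect = "nonsense"), cfg)
  expect_true(lo$final_score < mid$final_score)
  expect_true(mid$final_score < hi$final_score)
  expect_equal(hi$final_score, 1000)
})

test_that("unannotated cohort variants score zero and are flagged", {
  f <- write_test_vcf(list(c("1", "100", "A", "T", "60", "0/1"),
                           c("2", "200", "C", "G", "60", "1/1")),
                      samples = "P1")
  co <- read_cohort(f, verbose = FALSE)
  ann <- ann_fixture(variant_id = "1_100_A_T", coding_effect = "missense")
  scored <- score_cohort(co, ann)
  expect_equal(nrow(scored), 2)
  missing_row <- scored[scored$variant_id == "2_200_C_G", ]
  expect_equal(missing_row$final_score, 0L)
  expect_equal(missing_row$annotation_analysis, "No")
  expect_equal(missing_row$category, "not annotated")
})
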