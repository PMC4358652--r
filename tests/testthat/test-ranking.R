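# A small fully-specified cohort for ranking tests: one sample carrying
# variants with controlled scores and frequencies.
ranking_fixture <- function() {
  f <- write_test_vcf(list(
    c("1", "100", "A", "T", "60", "0/1:50:25,25", "0/0:50:50,0"),
    c("1", "200", "C", "G", "60", "0/1:50:25,25", "0/1:50:25,25"),
    c("2", "300", "G", "A", "60", "1/1:8:0,8",    "0/0:50:50,0"),
    c("2", "400", "T", "C", "60", "0/1:50:25,25", "0/0:50:50,0"),
    c("3", "500", "A", "G", "60", "0/1:50:25,25", "1/1:50:0,50")
  ), samples = c("P1", "P2"), format = "GT:DP:AD",
  path = tempfile(fileext = ".vcf"))
  cohort <- read_cohort(f, verbose = FALSE)
  ann <- dplyr::bind_rows(
    ann_fixture("1_100_A_T", gene = "GA", coding_effect = "nonsense"),
    ann_fixture("1_200_C_G", gene = "GA", coding_effect = "missense",
                rs_maf = 0.0001),
    ann_fixture("2_300_G_A", gene = "GB", coding_effect = "nonsense"),
    ann_fixture("2_400_T_C", gene = "GB", coding_effect = "missense"),
    ann_fixture("3_500_A_G", gene = "GC", coding_effect = "synonymous"))
  list(cohort = cohort, scored = score_cohort(cohort, ann))
}

test_that("byVar ranking orders by score with the documented tie-breaks", {
  fx <- ranking_fixture()
  rk <- rank_by_variant(fx$cohort, fx$scored, "P1")
  # only carried variants appear
  expect_setequal(rk$variant_id,
                  c("1_100_A_T", "1_200_C_G", "2_300_G_A", "2_400_T_C",
                    "3_500_A_G"))
  # oracle: exhaustive evaluation of the documented sort key
  key <- rk[, c("variant_id", "final_score", "max_af", "chrom", "pos")]
  ord <- order(-key$final_score, dplyr::coalesce(key$max_af, 0),
               key$chrom, key$pos)
  expect_identical(ord, seq_len(nrow(key)))
  expect_identical(rk$rank, seq_len(nrow(rk)))
  # two nonsense (100): absent frequency sorts before rsMAF... both absent
  # here, so coordinates break the tie
  top2 <- rk$variant_id[1:2]
  expect_identical(top2, c("1_100_A_T", "2_300_G_A"))
  # equal scores, one with a known rare frequency: absent (treated 0) first
  mis <- rk[rk$final_score == 50, ]
  expect_identical(mis$variant_id, c("2_400_T_C", "1_200_C_G"))
})

test_that("filtered ranking is a subset of the unfiltered one, order-compatible", {
  fx <- ranking_fixture()
  all_rk <- rank_by_variant(fx$cohort, fx$scored, "P1")
  flt_rk <- rank_by_variant(fx$cohort, fx$scored, "P1", filtered = TRUE)
  expect_true(all(flt_rk$variant_id %in% all_rk$variant_id))
  expect_identical(flt_rk$variant_id,
                   all_rk$variant_id[all_rk$variant_id %in% flt_rk$variant_id])
  # the depth-failing top variant (2_300, DP 8) drops out of the filtered
  # view but keeps its position in AllVariants
  expect_true("2_300_G_A" %in% all_rk$variant_id)
  expect_false("2_300_G_A" %in% flt_rk$variant_id)
  expect_equal(all_rk$rank[all_rk$variant_id == "2_300_G_A"], 2L)
})

test_that("byGene ranking uses the recessive-model gene key", {
  # gene with one hom 100 vs gene with hets {100, 10}: hom gene first
  f <- write_test_vcf(list(
    c("1", "100", "A", "T", "60", "1/1:50:0,50"),
    c("2", "200", "C", "G", "60", "0/1:50:25,25"),
    c("2", "300", "G", "A", "60", "0/1:50:25,25")
  ), samples = "P1", format = "GT:DP:AD", path = tempfile(fileext = ".vcf"))
  co <- read_cohort(f, verbose = FALSE)
  ann <- dplyr::bind_rows(
    ann_fixture("1_100_A_T", gene = "HOM", coding_effect = "nonsense"),
    ann_fixture("2_200_C_G", gene = "HET", coding_effect = "nonsense"),
    ann_fixture("2_300_G_A", gene = "HET", coding_effect = "synonymous"))
  rk <- rank_by_gene(co, score_cohort(co, ann), "P1")
  # oracle: HOM key = 100 (hom best), HET key = 10 (second-best het)
  expect_equal(rk$gene[rk$gene_rank == 1][1], "HOM")
  expect_equal(unique(rk$gene_score[rk$gene == "HOM"]), 100)
  expect_equal(unique(rk$gene_score[rk$gene == "HET"]), 10)

  # compound-het gene {90, 80} outranks a single het 110
  f2 <- write_test_vcf(list(
    c("1", "100", "A", "T", "60", "0/1:50:25,25"),
    c("2", "200", "C", "G", "60", "0/1:50:25,25"),
    c("2", "300", "G", "A", "60", "0/1:50:25,25")
  ), samples = "P1", format = "GT:DP:AD", path = tempfile(fileext = ".vcf"))
  co2 <- read_cohort(f2, verbose = FALSE)
  ann2 <- dplyr::bind_rows(
    ann_fixture("1_100_A_T", gene = "SOLO", coding_effect = "synonymous",
                rs_clinical_significance = "pathogenic"),       # known, 110
    ann_fixture("2_200_C_G", gene = "PAIR", coding_effect = "nonsense",
                dist_nearest_ss = 1, nearest_ss = "donor"),     # 100
    ann_fixture("2_300_G_A", gene = "PAIR", coding_effect = "start loss"))
  scored2 <- score_cohort(co2, ann2)
  rk2 <- rank_by_gene(co2, scored2, "P1")
  expect_equal(rk2$gene[rk2$gene_rank == 1][1], "PAIR") # 80 > 0
  # every variant of a reported gene appears in its block
  expect_equal(sum(rk2$gene == "PAIR"), 2)
  expect_equal(sum(rk2$gene == "SOLO"), 1)
  # within a block, members are ordered by score
  pair_scores <- rk2$final_score[rk2$gene == "PAIR"]
  expect_identical(pair_scores, sort(pair_scores, decreasing = TRUE))
})

test_that("report writing emits four deterministic files per sample", {
  fx <- ranking_fixture()
  outdir <- withr::local_tempdir()
  paths <- write_reports(fx$cohort, fx$scored, outdir)
  expect_equal(nrow(paths), 8) # 2 samples x 4 files
  expect_setequal(basename(paths$file[paths$sample_id == "P1"]),
                  c("P1.AllVariants.rankingByVar.tsv",
                    "P1.filteredVariants.rankingByVar.tsv",
                    "P1.AllVariants.rankingByGene.tsv",
                    "P1.filteredVariants.rankingByGene.tsv"))
  f1 <- file.path(outdir, "P1.AllVariants.rankingByVar.tsv")
  lines <- readLines(f1)
  expect_equal(lines[1], "## Barcode: P1 P2")
  header <- strsplit(lines[2], "\t")[[1]]
  expect_equal(header[1], "VariantID")
  expect_equal(utils::tail(header, 5),
               c("Barcode", "Hom_Count", "Het_Count", "Allele_Count",
                 "Sample_Count"))
  expect_true(all(c("VarScore", "AnnotationAnalysis", "CodingEffect",
                    "rsMAF", "DistNearestSS") %in% header))
  # every data row has the full column count
  expect_true(all(lengths(strsplit(lines[-(1:2)], "\t", fixed = TRUE)) ==
                    length(header)) || length(lines) == 2)
  # determinism: byte-identical on re-run
  before <- lapply(paths$file, readLines)
  write_reports(fx$cohort, fx$scored, outdir)
  after <- lapply(paths$file, readLines)
  expect_identical(before, after)
})

test_that("an empty filtered set still yields a header-only file", {
  f <- write_test_vcf(list(c("1", "100", "A", "T", "60", "0/1:5:3,2")),
                      samples = "P1", format = "GT:DP:AD",
                      path = tempfile(fileext = ".vcf"))
  co <- read_cohort(f, verbose = FALSE)
  scored <- score_cohort(co, ann_fixture("1_100_A_T",
                                         coding_effect = "missense"))
  outdir <- withr::local_tempdir()
  write_reports(co, scored, outdir)
  lines <- readLines(file.path(outdir, "P1.filteredVariants.rankingByVar.tsv"))
  expect_equal(length(lines), 2) # barcode line + header only
})

test_that("external gene annotations land in the report columns", {
  fx <- ranking_fixture()
  extann <- tibble::tibble(Gene = "GA", Expression = "brain")
  outdir <- withr::local_tempdir()
  write_reports(fx$cohort, fx$scored, outdir, extann = extann)
  lines <- readLines(file.path(outdir, "P1.AllVariants.rankingByVar.tsv"))
  header <- strsplit(lines[2], "\t")[[1]]
  expect_equal(utils::tail(header, 1), "Expression")
  rows <- strsplit(lines[-(1:2)], "\t")
  gene_col <- which(header == "Gene")
  expr_col <- which(header == "Expression")
  for (r in rows) {
    r <- c(r, rep("", length(header) - length(r))) # trailing empties
    expect_equal(r[expr_col] != "", r[gene_col] == "GA")
  }
})

test_that("category counts are per sample with an additive dataset row", {
  fx <- ranking_fixture()
  rep <- category_report(fx$cohort, fx$scored)
  expect_setequal(unique(rep$sample_id), c("P1", "P2", "all"))
  p1_mis <- rep[rep$sample_id == "P1" & rep$category == "missense", ]
  expect_equal(c(p1_mis$hom, p1_mis$het, p1_mis$total), c(0L, 2L, 2L))
  per_sample <- rep[rep$sample_id != "all", ]
  all_row <- rep[rep$sample_id == "all", ]
  for (cat in unique(all_row$category)) {
    expect_equal(all_row$hom[all_row$category == cat],
                 sum(per_sample$hom[per_sample$category == cat]))
    expect_equal(all_row$het[all_row$category == cat],
                 sum(per_sample$het[per_sample$category == cat]))
  }
  expect_equal(rep$total, rep$hom + rep$het)
})

test_that("unannotated carried variants count under 'not annotated'", {
  f <- write_test_vcf(list(c("1", "100", "A", "T", "60", "0/1")),
                      samples = "P1", path = tempfile(fileext = ".vcf"))
  co <- read_cohort(f, verbose = FALSE)
  scored <- score_cohort(co, ann_fixture("9_9_G_C")[0, ])
  rep <- category_report(co, scored)
  na_row <- rep[rep$sample_id == "P1" & rep$category == "not annotated", ]
  expect_equal(na_row$total, 1L)
})
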