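# Tab-separated report files: per sample, byVar and byGene rankings, each
# in an AllVariants and a filteredVariants version, plus the per-category
# count summary.

report_header_cols <- c(
  "VariantID", "Gene", "omimId", "TranscriptID", "TranscriptLength",
  "Chr", "Start", "End", "Ref", "Mut", "Phred_QUAL", "HomHet",
  "TotalReadDepth", "VarReadDepth", "%Reads_variation",
  "CodingEffect", "VarLocation", "Exon", "Intron",
  "gNomen", "cNomen", "pNomen",
  "rsID", "rsValidation", "rsClinicalSignificance", "rsMAF",
  "espAllMAF", "espEAMAF", "espAAMAF",
  "1000g_AF", "1000g_AFR_AF", "1000g_SAS_AF", "1000g_EAS_AF", "1000g_EUR_AF",
  "deltaMESscore", "wtMEScore", "varMEScore",
  "deltaSSFscore", "wtSSFScore", "varSSFScore",
  "deltaNNSscore", "wtNNSScore", "varNNSScore",
  "DistNearestSS", "NearestSS", "localSpliceEffect",
  "SiftPred", "SiftWeight", "SiftMedian", "PPH2pred",
  "phyloP", "PhastCons", "GranthamDist",
  "VarScore", "AnnotationAnalysis",
  "familyBarcode", "Barcode", "Hom_Count", "Het_Count", "Allele_Count",
  "Sample_Count"
)

# Assemble the report cells (all character, "" for absent) for one ranked
# sample tibble already joined with barcode columns.
format_report_rows <- function(ranked) {
  trunc50 <- function(x) substr(x, 1L, 50L)
  tibble(
    VariantID = ranked$variant_id,
    Gene = cell(ranked$gene),
    omimId = cell(ranked$omim_id),
    TranscriptID = cell(ranked$transcript_id),
    TranscriptLength = cell(ranked$transcript_length),
    Chr = ranked$chrom,
    Start = as.character(ranked$pos),
    End = as.character(ranked$pos + nchar(ranked$ref) - 1L),
    Ref = trunc50(ranked$ref),
    Mut = trunc50(ranked$alt),
    Phred_QUAL = cell(ranked$phred_qual),
    HomHet = ifelse(ranked$zygosity == 2L, "hom", "het"),
    TotalReadDepth = cell(ranked$total_depth),
    VarReadDepth = cell(ranked$alt_depth),
    `%Reads_variation` = cell(round(ranked$percent_alt, 1)),
    CodingEffect = cell(ranked$coding_effect),
    VarLocation = cell(ranked$var_location),
    Exon = cell(ranked$exon),
    Intron = cell(ranked$intron),
    gNomen = cell(ranked$gnomen),
    cNomen = cell(ranked$cnomen),
    pNomen = cell(ranked$pnomen),
    rsID = cell(ranked$rs_id),
    rsValidation = cell(ranked$rs_validation),
    rsClinicalSignificance = cell(ranked$rs_clinical_significance),
    rsMAF = cell(ranked$rs_maf),
    espAllMAF = cell(ranked$esp_all_maf),
    espEAMAF = cell(ranked$esp_ea_maf),
    espAAMAF = cell(ranked$esp_aa_maf),
    `1000g_AF` = cell(ranked$g1000_af),
    `1000g_AFR_AF` = cell(ranked$g1000_afr_af),
    `1000g_SAS_AF` = cell(ranked$g1000_sas_af),
    `1000g_EAS_AF` = cell(ranked$g1000_eas_af),
    `1000g_EUR_AF` = cell(ranked$g1000_eur_af),
    deltaMESscore = cell(ranked$mes_delta),
    wtMEScore = cell(ranked$mes_wt),
    varMEScore = cell(ranked$mes_var),
    deltaSSFscore = cell(ranked$ssf_delta),
    wtSSFScore = cell(ranked$ssf_wt),
    varSSFScore = cell(ranked$ssf_var),
    deltaNNSscore = cell(ranked$nns_delta),
    wtNNSScore = cell(ranked$nns_wt),
    varNNSScore = cell(ranked$nns_var),
    DistNearestSS = cell(ranked$dist_nearest_ss),
    NearestSS = cell(ranked$nearest_ss),
    localSpliceEffect = cell(ranked$local_splice_effect),
    SiftPred = cell(ranked$sift_pred),
    SiftWeight = cell(ranked$sift_weight),
    SiftMedian = cell(ranked$sift_median),
    PPH2pred = cell(ranked$pph2_pred),
    phyloP = cell(ranked$phylop),
    PhastCons = cell(ranked$phastcons),
    GranthamDist = cell(ranked$grantham),
    VarScore = as.character(ranked$final_score),
    AnnotationAnalysis = cell(ranked$annotation_analysis),
    familyBarcode = cell(if ("family_barcode" %in% names(ranked)) {
      ranked$family_barcode
    } else rep(NA_character_, nrow(ranked))),
    Barcode = ranked$barcode,
    Hom_Count = as.character(ranked$hom_count),
    Het_Count = as.character(ranked$het_count),
    Allele_Count = as.character(ranked$allele_count),
    Sample_Count = as.character(ranked$sample_count)
  )
}

write_one_report <- function(rows_df, path, sample_order, extann_cols = NULL) {
  header_line <- paste0("## Barcode: ", paste(sample_order, collapse = " "))
  cols <- c(report_header_cols, extann_cols)
  missing <- setdiff(cols, names(rows_df))
  for (m in missing) rows_df[[m]] <- ""
  rows_df <- rows_df[, cols, drop = FALSE]
  body <- if (nrow(rows_df) > 0) {
    do.call(paste, c(lapply(rows_df, function(x) replace_na(as.character(x), "")),
                     sep = "\t"))
  } else character()
  writeLines(c(header_line, paste(cols, collapse = "\t"), body), path,
             useBytes = TRUE)
  invisible(path)
}

#' Write the per-sample ranked report files
#'
#' For every cohort sample, four UTF-8 tab-separated files are written to
#' `outdir`:
#' `<sample>.AllVariants.rankingByVar.tsv`,
#' `<sample>.filteredVariants.rankingByVar.tsv`,
#' `<sample>.AllVariants.rankingByGene.tsv` and
#' `<sample>.filteredVariants.rankingByGene.tsv`,
#' plus one `category_counts.tsv` summary for the whole run. Each ranking
#' file starts with a `## Barcode: <sample order>` line, followed by the
#' header row and one variant per line. Output is deterministic: re-running
#' on the same input yields byte-identical files.
#'
#' @param cohort A `variant_cohort`.
#' @param scored Per-variant scores from [score_cohort()].
#' @param outdir Output directory (created if needed).
#' @param family Optional character vector of sample ids (user order) for
#'   the `familyBarcode` column.
#' @param filters A [filter_config()] for the filteredVariants files.
#' @param extann Optional gene-level external annotation table or path
#'   (see [merge_external()]); its columns are appended to every row.
#' @param include_filtered Write the filteredVariants files (default TRUE;
#'   `FALSE` emits only the AllVariants pair per sample).
#' @return Invisibly, a tibble of the written paths.
#' @export
write_reports <- function(cohort, scored, outdir, family = NULL,
                          filters = filter_config(), extann = NULL,
                          include_filtered = TRUE) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory: %s", outdir))
  }
  samples <- cohort_samples(cohort)
  bc <- barcodes(cohort)
  fam_bc <- if (!is.null(family)) family_barcode(cohort, family) else NULL
  extann_tbl <- NULL
  if (!is.null(extann)) {
    if (is.character(extann) && length(extann) == 1L) {
      extann_tbl <- readr::read_tsv(extann,
                                    col_types = readr::cols(.default = "c"),
                                    progress = FALSE)
    } else extann_tbl <- as_tibble(extann)
  }
  extann_cols <- if (!is.null(extann_tbl)) names(extann_tbl)[-1] else NULL

  decorate <- function(ranked) {
    ranked <- left_join(ranked, bc, by = "variant_id")
    if (!is.null(fam_bc)) ranked <- left_join(ranked, fam_bc, by = "variant_id")
    rows <- format_report_rows(ranked)
    if (!is.null(extann_tbl)) {
      rows <- merge_external(bind_cols(rows,
                                       tibble(gene = dplyr::coalesce(ranked$gene, ""))),
                             extann_tbl)
      rows$gene <- NULL
      for (ec in extann_cols) rows[[ec]] <- replace_na(rows[[ec]], "")
    }
    rows
  }

  out <- list()
  for (s in samples) {
    combos <- list(
      list(suffix = "AllVariants.rankingByVar", filtered = FALSE, by = "var"),
      list(suffix = "filteredVariants.rankingByVar", filtered = TRUE, by = "var"),
      list(suffix = "AllVariants.rankingByGene", filtered = FALSE, by = "gene"),
      list(suffix = "filteredVariants.rankingByGene", filtered = TRUE, by = "gene")
    )
    if (!include_filtered) {
      combos <- Filter(function(cmb) !cmb$filtered, combos)
    }
    for (cmb in combos) {
      ranked <- if (cmb$by == "var") {
        rank_by_variant(cohort, scored, s, filtered = cmb$filtered,
                        filters = filters)
      } else {
        rank_by_gene(cohort, scored, s, filtered = cmb$filtered,
                     filters = filters)
      }
      path <- file.path(outdir, sprintf("%s.%s.tsv", s, cmb$suffix))
      write_one_report(decorate(ranked), path, samples, extann_cols)
      out[[length(out) + 1L]] <- tibble(sample_id = s, file = path,
                                        filtered = cmb$filtered, by = cmb$by)
    }
  }
  counts <- category_report(cohort, scored)
  readr::write_tsv(counts, file.path(outdir, "category_counts.tsv"),
                   progress = FALSE)
  invisible(bind_rows(out))
}

report_category_levels <- c(
  "5'UTR", "3'UTR", "upstream", "downstream", "frameshift", "in-frame",
  "nonsense", "splice site", "start loss", "stop loss", "missense",
  "synonymous", "intronic", "not annotated"
)

# Map a scored representative onto the fixed count-report category list.
# Known-mutation status does not define a count category: the underlying
# coding effect / location is used.
report_category <- function(scored) {
  coding_set <- c("frameshift", "in-frame", "nonsense", "start loss",
                  "stop loss", "missense", "synonymous")
  dplyr::case_when(
    scored$annotation_analysis == "No" ~ "not annotated",
    scored$pathway == "splice" ~ "splice site",
    scored$coding_effect %in% coding_set ~ scored$coding_effect,
    scored$var_location %in% c("5'UTR", "5UTR") ~ "5'UTR",
    scored$var_location %in% c("3'UTR", "3UTR") ~ "3'UTR",
    scored$var_location %in% "upstream" ~ "upstream",
    scored$var_location %in% "downstream" ~ "downstream",
    scored$var_location %in% c("intron", "intronic") ~ "intronic",
    TRUE ~ "not annotated"
  )
}

#' Per-category variant counts
#'
#' Homozygous, heterozygous and total carrier counts per variant category,
#' for each sample and for the whole dataset (`sample_id = "all"`, the
#' column-wise sum over samples). The fixed category list covers
#' 5'/3' UTR, upstream, downstream, the coding-effect classes, splice site,
#' intronic and not annotated.
#'
#' @param cohort A `variant_cohort`.
#' @param scored Per-variant scores from [score_cohort()].
#' @return A tibble `sample_id`, `category`, `hom`, `het`, `total`.
#' @export
category_report <- function(cohort, scored) {
  scored <- mutate(scored, category_report = report_category(scored))
  calls <- as_tibble(cohort) |>
    filter(!is.na(.data$zygosity), .data$zygosity > 0L) |>
    left_join(select(scored, "variant_id", "category_report"),
              by = "variant_id")
  per_sample <- calls |>
    mutate(category = factor(.data$category_report,
                             levels = report_category_levels)) |>
    group_by(.data$sample_id, .data$category, .drop = FALSE) |>
    summarise(hom = sum(.data$zygosity == 2L),
              het = sum(.data$zygosity == 1L), .groups = "drop")
  whole <- per_sample |>
    group_by(.data$category) |>
    summarise(hom = sum(.data$hom), het = sum(.data$het), .groups = "drop") |>
    mutate(sample_id = "all")
  bind_rows(per_sample, whole) |>
    mutate(total = .data$hom + .data$het,
           category = as.character(.data$category)) |>
    select("sample_id", "category", "hom", "het", "total")
}
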