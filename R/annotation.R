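# Per-transcript annotation layer. Two sources are supported: a generic
# tab-separated annotation table (the column vocabulary of commercial batch
# annotators) and SnpEff-style ANN strings embedded in the VCF INFO field.
# Both converge on one tidy tibble with snake_case names; the original
# spellings are restored when reports are written.

# Table-header -> internal column name map (order also fixes report order).
ann_column_map <- c(
  VariantID         = "variant_id",
  Gene              = "gene",
  omimId            = "omim_id",
  TranscriptID      = "transcript_id",
  TranscriptLength  = "transcript_length",
  CodingEffect      = "coding_effect",
  VarLocation       = "var_location",
  Exon              = "exon",
  Intron            = "intron",
  gNomen            = "gnomen",
  cNomen            = "cnomen",
  pNomen            = "pnomen",
  rsID              = "rs_id",
  rsValidation      = "rs_validation",
  rsClinicalSignificance = "rs_clinical_significance",
  rsMAF             = "rs_maf",
  espAllMAF         = "esp_all_maf",
  espEAMAF          = "esp_ea_maf",
  espAAMAF          = "esp_aa_maf",
  `1000g_AF`        = "g1000_af",
  `1000g_AFR_AF`    = "g1000_afr_af",
  `1000g_SAS_AF`    = "g1000_sas_af",
  `1000g_EAS_AF`    = "g1000_eas_af",
  `1000g_EUR_AF`    = "g1000_eur_af",
  deltaMESscore     = "mes_delta",
  wtMEScore         = "mes_wt",
  varMEScore        = "mes_var",
  deltaSSFscore     = "ssf_delta",
  wtSSFScore        = "ssf_wt",
  varSSFScore       = "ssf_var",
  deltaNNSscore     = "nns_delta",
  wtNNSScore        = "nns_wt",
  varNNSScore       = "nns_var",
  DistNearestSS     = "dist_nearest_ss",
  NearestSS         = "nearest_ss",
  localSpliceEffect = "local_splice_effect",
  SiftPred          = "sift_pred",
  SiftWeight        = "sift_weight",
  SiftMedian        = "sift_median",
  PPH2pred          = "pph2_pred",
  phyloP            = "phylop",
  PhastCons         = "phastcons",
  GranthamDist      = "grantham"
)

ann_numeric_cols <- c(
  "transcript_length", "rs_validation", "rs_maf", "esp_all_maf", "esp_ea_maf",
  "esp_aa_maf", "g1000_af", "g1000_afr_af", "g1000_sas_af", "g1000_eas_af",
  "g1000_eur_af", "mes_delta", "mes_wt", "mes_var", "ssf_delta", "ssf_wt",
  "ssf_var", "nns_delta", "nns_wt", "nns_var", "dist_nearest_ss",
  "sift_weight", "sift_median", "phylop", "phastcons", "grantham"
)

ann_frequency_cols <- c("rs_maf", "esp_all_maf", "esp_ea_maf", "esp_aa_maf",
                        "g1000_af", "g1000_afr_af", "g1000_sas_af",
                        "g1000_eas_af", "g1000_eur_af")

# Ensure every internal annotation column exists (filled with NA) and has a
# usable type, so downstream code never branches on column presence.
ensure_annotation_columns <- function(ann) {
  ann <- as_tibble(ann)
  for (col in unname(ann_column_map)) {
    if (!col %in% names(ann)) {
      ann[[col]] <- if (col %in% ann_numeric_cols) NA_real_ else NA_character_
    }
  }
  for (col in ann_numeric_cols) {
    if (!is.numeric(ann[[col]])) {
      ann[[col]] <- suppressWarnings(as.numeric(ann[[col]]))
    }
  }
  ann
}

#' Read a per-transcript variant annotation table
#'
#' Loads a UTF-8 tab-separated annotation table whose header uses the
#' standard batch-annotator column names (`VariantID`, `Gene`,
#' `TranscriptID`, `CodingEffect`, `VarLocation`, `rsMAF`, `wtMEScore`,
#' `DistNearestSS`, `PhastCons`, ...). Splice-delta columns are expected as
#' `deltaMESscore`, `deltaSSFscore`, `deltaNNSscore` (percent change, signed,
#' negative = weaker site in the variant sequence). Columns outside the
#' known vocabulary are preserved untouched and passed through to reports.
#'
#' @param path Path to the tab-separated file.
#' @return A tibble with one row per (variant, transcript), internal
#'   snake_case names, numeric columns parsed, and unknown columns appended.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation table not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  mandatory <- c("VariantID", "Gene")
  missing <- setdiff(mandatory, names(raw))
  if (!any(c("CodingEffect", "VarLocation") %in% names(raw))) {
    missing <- c(missing, "CodingEffect or VarLocation")
  }
  if (length(missing) > 0) {
    abort(sprintf("annotation table '%s' lacks mandatory column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  known <- intersect(names(raw), names(ann_column_map))
  names(raw)[match(known, names(raw))] <- ann_column_map[known]
  ann <- ensure_annotation_columns(raw)
  dup <- duplicated(ann[, c("variant_id", "transcript_id")]) &
    !is.na(ann$transcript_id)
  if (any(dup)) {
    warn(sprintf("%d duplicated (VariantID, TranscriptID) row(s) dropped",
                 sum(dup)))
    ann <- ann[!dup, , drop = FALSE]
  }
  ann
}

# ---- SnpEff ANN parsing -----------------------------------------------------

# Effect-term -> coding-effect category. Composite terms ("A&B") map to their
# most severe mappable component (severity = default category base score).
snpeff_effect_map <- c(
  stop_gained                      = "nonsense",
  frameshift_variant               = "frameshift",
  start_lost                       = "start loss",
  initiator_codon_variant          = "start loss",
  stop_lost                        = "stop loss",
  missense_variant                 = "missense",
  inframe_insertion                = "in-frame",
  inframe_deletion                 = "in-frame",
  conservative_inframe_insertion   = "in-frame",
  conservative_inframe_deletion    = "in-frame",
  disruptive_inframe_insertion     = "in-frame",
  disruptive_inframe_deletion      = "in-frame",
  synonymous_variant               = "synonymous",
  stop_retained_variant            = "synonymous",
  start_retained_variant           = "synonymous"
)

snpeff_location_map <- c(
  intron_variant            = "intron",
  splice_acceptor_variant   = "intron",
  splice_donor_variant      = "intron",
  `5_prime_UTR_variant`     = "5'UTR",
  `5_prime_UTR_premature_start_codon_gain_variant` = "5'UTR",
  `3_prime_UTR_variant`     = "3'UTR",
  upstream_gene_variant     = "upstream",
  downstream_gene_variant   = "downstream"
)

coding_effect_severity <- c(
  "nonsense" = 100, "frameshift" = 100, "start loss" = 80, "stop loss" = 80,
  "missense" = 50, "in-frame" = 40, "synonymous" = 10
)

#' Parse a SnpEff `ANN` INFO string into transcript annotations
#'
#' One annotation record per comma-separated entry, in input order (SnpEff
#' emits them most- to least-severe). Effect terms are mapped onto the
#' coding-effect vocabulary (`stop_gained` -> nonsense, ...); composite
#' terms such as `stop_gained&splice_region_variant` take their most severe
#' mappable component, with the full term list kept in `effect_terms`.
#' Entries with fewer than 10 pipe-delimited fields are skipped with a
#' warning.
#'
#' @param ann_field The raw `ANN` value (single string).
#' @param variant_id Canonical id of the variant the field belongs to.
#' @return A tibble of transcript annotations (possibly zero rows).
#' @export
parse_snpeff_ann <- function(ann_field, variant_id = NA_character_) {
  if (is.na(ann_field) || ann_field == "") return(ensure_annotation_columns(tibble())[0, ])
  entries <- strsplit(ann_field, ",", fixed = TRUE)[[1]]
  fields <- strsplit(entries, "|", fixed = TRUE)
  short <- lengths(fields) < 10
  if (any(short)) {
    warn(sprintf("skipped %d ANN entr(y/ies) with < 10 fields", sum(short)))
    fields <- fields[!short]
  }
  if (length(fields) == 0) return(ensure_annotation_columns(tibble())[0, ])
  rows <- map(fields, function(f) {
    f <- c(f, rep("", max(0, 16 - length(f))))
    terms <- strsplit(f[2], "&", fixed = TRUE)[[1]]
    eff <- snpeff_effect_map[terms]
    eff <- eff[!is.na(eff)]
    coding <- if (length(eff) > 0) {
      eff[which.max(coding_effect_severity[eff])]
    } else NA_character_
    loc <- snpeff_location_map[terms]
    loc <- loc[!is.na(loc)][1]
    if (!is.na(coding)) loc <- "exon"
    cdna_len <- suppressWarnings(
      as.numeric(strsplit(f[12], "/", fixed = TRUE)[[1]][2]))
    tibble(
      variant_id = variant_id,
      gene = dplyr::na_if(f[4], ""),
      transcript_id = dplyr::na_if(f[7], ""),
      transcript_length = cdna_len,
      coding_effect = unname(coding),
      var_location = unname(loc),
      cnomen = dplyr::na_if(f[10], ""),
      pnomen = dplyr::na_if(f[11], ""),
      effect_terms = f[2]
    )
  })
  ensure_annotation_columns(list_rbind(rows))
}

#' Extract SnpEff annotations for every variant of a VCF file
#'
#' Re-reads `path`, splits multi-allelic records the same way
#' [read_cohort()] does, and parses the `ANN` INFO field, attaching each
#' entry to the normalized key of the ALT allele it describes (matched on
#' the entry's allele field; single-ALT records accept all entries).
#'
#' @param path A VCF path.
#' @return A tibble of transcript annotations keyed by `variant_id`.
#' @export
annotations_from_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)
  if (nrow(vcf@fix) == 0) return(ensure_annotation_columns(tibble())[0, ])
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  ann_raw <- vcfR::extract.info(vcf, "ANN")
  out <- list()
  for (i in seq_len(nrow(fix))) {
    if (is.na(ann_raw[i])) next
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    alts <- alts[!grepl("[][<>*]", alts)]
    if (length(alts) == 0) next
    keys <- normalize_variant(rep(fix$CHROM[i], length(alts)),
                              rep(fix$POS[i], length(alts)),
                              rep(fix$REF[i], length(alts)), alts)
    parsed <- parse_snpeff_ann(ann_raw[i])
    if (nrow(parsed) == 0) next
    entry_allele <- vapply(strsplit(strsplit(ann_raw[i], ",", fixed = TRUE)[[1]],
                                    "|", fixed = TRUE),
                           function(f) f[1], character(1))
    entry_allele <- entry_allele[lengths(
      strsplit(strsplit(ann_raw[i], ",", fixed = TRUE)[[1]], "|", fixed = TRUE)) >= 10]
    idx <- if (length(alts) == 1L) rep(1L, nrow(parsed)) else match(entry_allele, alts)
    keep <- !is.na(idx)
    parsed <- parsed[keep, , drop = FALSE]
    parsed$variant_id <- keys$id[idx[keep]]
    out[[length(out) + 1L]] <- parsed
  }
  if (length(out) == 0) return(ensure_annotation_columns(tibble())[0, ])
  list_rbind(out)
}

#' Restrict annotations to a cohort's non-redundant variant set
#'
#' Cohorts share most of their variants, so annotation is resolved once per
#' distinct variant key and then joined per sample: joining the returned
#' table against any single sample's variants is identical to annotating
#' that sample alone.
#'
#' @param cohort A `variant_cohort`.
#' @param annotations A transcript-annotation tibble.
#' @return The annotation rows whose `variant_id` occurs in the cohort.
#' @export
annotate_cohort <- function(cohort, annotations) {
  keys <- cohort_variants(cohort)
  semi_join(ensure_annotation_columns(annotations),
            distinct(keys[, "variant_id"]), by = "variant_id")
}

#' Select the representative transcript annotation for one variant
#'
#' The longest transcript of the gene is reported unless the variant is
#' strictly more pathogenic (higher final score) on another transcript;
#' score ties go to the longer transcript, then to the lexicographically
#' smaller transcript id. The choice is a pure function of the
#' (annotation, score) pairs — input order never matters.
#'
#' @param annotations Transcript annotations for one variant.
#' @param scores Numeric vector of final scores, parallel to `annotations`.
#' @return The selected annotation row (one-row tibble).
#' @export
select_representative <- function(annotations, scores) {
  annotations <- as_tibble(annotations)
  if (nrow(annotations) == 0) {
    abort("cannot select a representative transcript: no annotations")
  }
  stopifnot(length(scores) == nrow(annotations))
  len <- annotations$transcript_length %||% rep(NA_real_, nrow(annotations))
  len[is.na(len)] <- -1
  txid <- annotations$transcript_id %||% rep("", nrow(annotations))
  txid[is.na(txid)] <- ""
  ord <- order(-scores, -len, txid)
  annotations[ord[1], , drop = FALSE]
}

#' Append user gene-level annotations
#'
#' Joins a user-supplied gene annotation table (first column = gene symbol,
#' remaining columns free-form) onto rows carrying a gene symbol; genes
#' absent from the table yield empty cells. Duplicate gene rows keep the
#' first occurrence with a warning.
#'
#' @param rows A tibble with a `gene` (or `Gene`) column.
#' @param extann A data frame whose first column holds gene symbols, or a
#'   path to a tab-separated file of that shape.
#' @return `rows` with the extra columns appended in file order.
#' @export
merge_external <- function(rows, extann) {
  if (is.character(extann) && length(extann) == 1L) {
    extann <- readr::read_tsv(extann, col_types = readr::cols(.default = "c"),
                              progress = FALSE)
  }
  extann <- as_tibble(extann)
  if (ncol(extann) < 2) return(as_tibble(rows))
  names(extann)[1] <- "gene"
  dup <- duplicated(extann$gene)
  if (any(dup)) {
    warn(sprintf("%d duplicate gene row(s) in external annotation; keeping first",
                 sum(dup)))
    extann <- extann[!dup, , drop = FALSE]
  }
  rows <- as_tibble(rows)
  gene_col <- if ("gene" %in% names(rows)) "gene" else if ("Gene" %in% names(rows)) "Gene"
  if (is.null(gene_col)) abort("rows have no gene column to join external annotations on")
  left_join(rows, extann, by = setNames("gene", gene_col))
}
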