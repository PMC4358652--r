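# Cohort-level analysis: zygosity barcodes, family barcodes, inheritance
# pattern matching, cohort-frequency counts and the default filter cascade.

#' Zygosity barcodes for all variants of a cohort
#'
#' One digit per sample (cohort order, which is lexicographic and printed in
#' the report header): `0` hom-ref, `1` het, `2` hom-alt. Missing genotypes
#' are rendered as `0` (the barcode alphabet is only `{0,1,2}`) but counted
#' separately in `missing_count`. Derived counts: `hom_count` = number of
#' 2s, `het_count` = number of 1s, `allele_count` = `2*hom + het`,
#' `sample_count` = samples analyzed.
#'
#' @param cohort A `variant_cohort`.
#' @return A tibble with one row per variant key: `variant_id`, `barcode`,
#'   `hom_count`, `het_count`, `allele_count`, `sample_count`,
#'   `missing_count`.
#' @export
barcodes <- function(cohort) {
  samples <- cohort_samples(cohort)
  keys <- cohort_variants(cohort)
  n_s <- length(samples)
  digit_mat <- matrix(0L, nrow = nrow(keys), ncol = n_s,
                      dimnames = list(keys$variant_id, samples))
  miss_mat <- matrix(FALSE, nrow = nrow(keys), ncol = n_s)
  calls <- as_tibble(cohort)
  calls <- calls[calls$sample_id %in% samples, , drop = FALSE]
  ri <- match(calls$variant_id, keys$variant_id)
  ci <- match(calls$sample_id, samples)
  ok <- !is.na(ri) & !is.na(ci)
  zyg <- calls$zygosity[ok]
  idx <- cbind(ri[ok], ci[ok])
  digit_mat[idx] <- ifelse(is.na(zyg), 0L, zyg)
  miss_mat[idx] <- is.na(zyg)
  tibble(
    variant_id = keys$variant_id,
    barcode = unname(apply(digit_mat, 1, paste, collapse = "")),
    hom_count = as.integer(rowSums(digit_mat == 2L)),
    het_count = as.integer(rowSums(digit_mat == 1L)),
    missing_count = as.integer(rowSums(miss_mat)),
    sample_count = n_s
  ) |>
    mutate(allele_count = 2L * .data$hom_count + .data$het_count) |>
    select("variant_id", "barcode", "hom_count", "het_count", "allele_count",
           "sample_count", "missing_count")
}

#' Barcode of a single variant
#'
#' @param cohort A `variant_cohort`.
#' @param variant_id A variant id present in the cohort.
#' @return A one-row tibble (see [barcodes()]).
#' @export
build_barcode <- function(cohort, variant_id) {
  bc <- barcodes(cohort)
  row <- bc[bc$variant_id == variant_id, , drop = FALSE]
  if (nrow(row) == 0) abort(sprintf("unknown variant id: %s", variant_id))
  row
}

#' Family barcode: restriction to a user-ordered sample subset
#'
#' @param cohort A `variant_cohort`.
#' @param family Character vector of sample ids, in the user's order (the
#'   digits follow this order, not the cohort order).
#' @param variant_id Optional single id; default all variants.
#' @return A tibble `variant_id`, `family_barcode`.
#' @export
family_barcode <- function(cohort, family, variant_id = NULL) {
  samples <- cohort_samples(cohort)
  unknown <- setdiff(family, samples)
  if (length(unknown) > 0) {
    abort(sprintf("family sample(s) not in cohort: %s",
                  paste(unknown, collapse = ", ")))
  }
  bc <- barcodes(cohort)
  pos <- match(family, samples)
  fam <- unname(vapply(strsplit(bc$barcode, "", fixed = TRUE),
                       function(d) paste(d[pos], collapse = ""), character(1)))
  out <- tibble(variant_id = bc$variant_id, family_barcode = fam)
  if (!is.null(variant_id)) {
    out <- out[out$variant_id %in% variant_id, , drop = FALSE]
    if (nrow(out) == 0) abort(sprintf("unknown variant id: %s", variant_id))
  }
  out
}

#' Match a barcode against a zygosity pattern
#'
#' Position-wise comparison of barcode digits against a pattern over
#' `{0,1,2,?}`; `?` matches any digit. Typical uses: `"121"` for a
#' homozygous variant inherited from two heterozygous parents, `"010"`
#' (order father, proband, mother) for a candidate de novo variant.
#'
#' @param digits Character vector of barcodes.
#' @param pattern A single pattern of the same length.
#' @return Logical vector.
#' @export
match_pattern <- function(digits, pattern) {
  if (any(nchar(digits) != nchar(pattern))) {
    abort("pattern length must equal barcode length")
  }
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  vapply(strsplit(digits, "", fixed = TRUE),
         function(d) all(pat == "?" | pat == d), logical(1))
}

#' Cohort-frequency filter on barcode counts
#'
#' Keeps a variant only when it is seen fewer than `max_het` times
#' heterozygous *and* fewer than `max_hom` times homozygous across the
#' cohort — the "internal frequency database" use of the barcode counts.
#'
#' @param barcode_counts A tibble with `het_count` and `hom_count`
#'   (e.g. from [barcodes()]), or a single row.
#' @param max_het,max_hom Strict upper bounds on the carrier counts.
#' @return Logical vector: `TRUE` = keep.
#' @export
cohort_frequency_filter <- function(barcode_counts, max_het, max_hom) {
  assert_df_has(barcode_counts, c("het_count", "hom_count"), "barcode_counts")
  barcode_counts$het_count < max_het & barcode_counts$hom_count < max_hom
}

#' Filter configuration
#'
#' Thresholds of the default filter cascade used for the
#' `filteredVariants` reports. All removals on call quality are inclusive
#' (`<=`); the frequency removal is strict (`>`).
#'
#' @param min_total_depth Remove calls with total read depth at or below
#'   this value (default 10).
#' @param min_alt_reads Remove calls with this many or fewer supporting
#'   reads (default 10).
#' @param min_percent_alt Remove calls whose percent of supporting reads is
#'   at or below this value (default 15).
#' @param max_af Remove variants whose highest available population allele
#'   frequency exceeds this fraction (default 0.01).
#' @param dbsnp_min_validation_evidence dbSNP validation evidences required
#'   for the validated-benign removal (default 2).
#' @return A named list of class `filter_config`.
#' @export
filter_config <- function(min_total_depth = 10L, min_alt_reads = 10L,
                          min_percent_alt = 15, max_af = 0.01,
                          dbsnp_min_validation_evidence = 2L) {
  stopifnot(min_total_depth >= 0, min_alt_reads >= 0, min_percent_alt >= 0,
            max_af >= 0, max_af <= 1)
  structure(list(min_total_depth = min_total_depth,
                 min_alt_reads = min_alt_reads,
                 min_percent_alt = min_percent_alt,
                 max_af = max_af,
                 dbsnp_min_validation_evidence = dbsnp_min_validation_evidence),
            class = "filter_config")
}

#' Apply the default filter cascade to calls
#'
#' Five removal rules, each identified in the `reasons` column:
#'
#' * `depth` — total read depth `<= min_total_depth`;
#' * `alt_reads` — supporting reads `<= min_alt_reads`;
#' * `alt_ratio` — percent supporting reads `<= min_percent_alt`;
#' * `dbsnp_validated_benign` — dbSNP-validated (at least
#'   `dbsnp_min_validation_evidence` evidences) and not flagged pathogenic;
#' * `frequency` — highest available population allele frequency
#'   `> max_af`.
#'
#' Rules whose inputs are missing do not fire (a call without depth
#' information is not removed by the depth rules). Variants with
#' known-mutation evidence (`known` column) are exempt from the
#' `dbsnp_validated_benign` and `frequency` rules. `keep` is `TRUE` exactly
#' when no rule fired.
#'
#' @param calls A tibble with (any of) `total_depth`, `alt_depth`,
#'   `percent_alt`, `rs_validation`, `rs_clinical_significance`, `max_af`,
#'   `known` — e.g. cohort calls joined with [score_cohort()] output.
#' @param config A [filter_config()].
#' @return `calls` with logical `keep` and character `reasons`
#'   (comma-separated rule ids, `""` when kept) appended.
#' @export
apply_filters <- function(calls, config = filter_config()) {
  calls <- as_tibble(calls)
  n <- nrow(calls)
  get_col <- function(nm, default = NA) {
    if (nm %in% names(calls)) calls[[nm]] else rep(default, n)
  }
  total_depth <- get_col("total_depth", NA_real_)
  alt_depth <- get_col("alt_depth", NA_real_)
  percent_alt <- get_col("percent_alt", NA_real_)
  rs_validation <- get_col("rs_validation", NA_real_)
  clinsig <- get_col("rs_clinical_significance", NA_character_)
  max_af <- get_col("max_af", NA_real_)
  known <- get_col("known", FALSE)
  known <- na_false(known) | clinsig_pathogenic(clinsig)

  fired <- cbind(
    depth = na_false(total_depth <= config$min_total_depth),
    alt_reads = na_false(alt_depth <= config$min_alt_reads),
    alt_ratio = na_false(percent_alt <= config$min_percent_alt),
    dbsnp_validated_benign = !known &
      na_false(rs_validation >= config$dbsnp_min_validation_evidence) &
      !clinsig_pathogenic(clinsig),
    frequency = !known & na_false(max_af > config$max_af)
  )
  reasons <- apply(fired, 1, function(f) paste(colnames(fired)[f], collapse = ","))
  if (n == 0) reasons <- character()
  calls$keep <- rowSums(fired) == 0
  calls$reasons <- reasons
  calls
}
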