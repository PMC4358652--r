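# One-call pipeline: cohort + annotations -> scored, barcoded, filterable
# prioritization result with broom-style accessors.

#' Prioritize the variants of a cohort
#'
#' Runs the full workflow: restricts the annotation source to the cohort's
#' non-redundant variant set, scores every variant ([score_cohort()]),
#' builds the cohort (and optional family) barcodes, and evaluates the
#' default filter cascade for every carrier call. The result object feeds
#' [tidy()], [glance()], [autoplot()], [rank_by_variant()] /
#' [rank_by_gene()] via [write_reports()], and [category_report()].
#'
#' @param cohort A `variant_cohort` from [read_cohort()].
#' @param annotations Transcript annotations ([read_annotation_table()],
#'   [annotations_from_vcf()] or a compatible tibble).
#' @param scoring A [scoring_config()].
#' @param filters A [filter_config()].
#' @param known_ids Optional character vector of variant ids with external
#'   known-mutation evidence.
#' @param family Optional character vector of sample ids (user order) for
#'   the family barcode.
#' @param extann Optional gene-level external annotation table or path.
#' @return An object of class `variant_prioritization`.
#' @examples
#' sim <- simulate_cohort(simulation_config(n_samples = 3,
#'                                          n_background_variants = 20,
#'                                          seed = 7),
#'                        dir = tempdir())
#' cohort <- read_cohort(sim$vcf_path, verbose = FALSE)
#' ann <- read_annotation_table(sim$annotation_path)
#' fit <- prioritize(cohort, ann)
#' tidy(fit)
#' glance(fit)
#' @export
prioritize <- function(cohort, annotations, scoring = scoring_config(),
                       filters = filter_config(), known_ids = character(),
                       family = NULL, extann = NULL) {
  stopifnot(inherits(cohort, "variant_cohort"))
  scored <- score_cohort(cohort, annotations, scoring, known_ids)
  bc <- barcodes(cohort)
  fam <- if (!is.null(family)) family_barcode(cohort, family) else NULL
  calls <- as_tibble(cohort) |>
    left_join(select(scored, "variant_id", "final_score", "category",
                     "max_af", "rs_validation", "rs_clinical_significance",
                     "known"),
              by = "variant_id") |>
    apply_filters(filters)
  structure(list(cohort = cohort, scored = scored, barcodes = bc,
                 family_barcodes = fam, calls = calls,
                 scoring = scoring, filters = filters,
                 known_ids = known_ids, family = family, extann = extann),
            class = "variant_prioritization")
}

#' @export
print.variant_prioritization <- function(x, ...) {
  n_var <- nrow(x$scored)
  n_samp <- length(cohort_samples(x$cohort))
  cat(sprintf("Variant prioritization: %d variant(s) x %d sample(s)\n",
              n_var, n_samp))
  top <- tidy(x) |> head(5)
  cat("Top variants:\n")
  print(select(top, "variant_id", "gene", "category", "final_score",
               "barcode"))
  invisible(x)
}

#' Tidy a prioritization result
#'
#' One row per non-redundant variant: representative annotation, category,
#' final score and barcode counts, ordered from most to least likely
#' pathogenic.
#'
#' @param x A `variant_prioritization`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.variant_prioritization <- function(x, ...) {
  keys <- cohort_variants(x$cohort)
  out <- x$scored |>
    left_join(keys, by = "variant_id") |>
    left_join(x$barcodes, by = "variant_id")
  if (!is.null(x$family_barcodes)) {
    out <- left_join(out, x$family_barcodes, by = "variant_id")
  }
  arrange_ranking(out) |>
    select("variant_id", "chrom", "pos", "ref", "alt", "gene",
           "transcript_id", "category", "pathway", "base_score",
           "adjustment", "final_score", "max_af", "annotation_analysis",
           "barcode", dplyr::any_of("family_barcode"), "hom_count",
           "het_count", "allele_count", "sample_count")
}

#' Summarize a prioritization result
#'
#' @param x A `variant_prioritization`.
#' @param ... Unused.
#' @return A one-row tibble: sample and variant counts, annotation
#'   coverage, carrier-call counts before/after filtering, and the top
#'   score.
#' @export
glance.variant_prioritization <- function(x, ...) {
  tibble(
    n_samples = length(cohort_samples(x$cohort)),
    n_variants = nrow(x$scored),
    n_annotated = sum(x$scored$annotation_analysis == "Yes"),
    n_calls = nrow(x$calls),
    n_calls_pass = sum(x$calls$keep, na.rm = TRUE),
    max_score = if (nrow(x$scored)) max(x$scored$final_score) else NA_integer_
  )
}

#' Plot the score distribution of a prioritization result
#'
#' Bar chart of variant counts by final score, filled by category — the
#' at-a-glance view of how the cohort's variants spread across the scoring
#' scheme.
#'
#' @param object A `variant_prioritization`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.variant_prioritization <- function(object, ...) {
  df <- object$scored
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$final_score),
                                   fill = .data$category)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "final score", y = "variants", fill = "category") +
    ggplot2::theme_minimal()
}

#' Plot per-category carrier counts
#'
#' Companion plot to [category_report()]: homozygous and heterozygous
#' carrier counts per variant category for each sample.
#'
#' @param cohort A `variant_cohort`.
#' @param scored Output of [score_cohort()].
#' @return A ggplot object.
#' @export
plot_category_counts <- function(cohort, scored) {
  df <- category_report(cohort, scored) |>
    filter(.data$sample_id != "all") |>
    pivot_longer(c("hom", "het"), names_to = "zygosity", values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n,
                                   fill = .data$zygosity)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "carrier calls") +
    ggplot2::theme_minimal()
}
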