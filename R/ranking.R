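# Per-sample rankings and the tab-separated report files.

# deterministic byVar sort key: score desc, then rarest (absent frequency
# counts as 0 = rarest), then genomic coordinates.
arrange_ranking <- function(df) {
  df |>
    mutate(.af = dplyr::coalesce(.data$max_af, 0)) |>
    arrange(dplyr::desc(.data$final_score), .data$.af,
            chrom_rank(.data$chrom), .data$pos, .data$ref, .data$alt) |>
    select(-".af")
}

# join one sample's carrier calls with the per-variant scores
sample_scored_calls <- function(cohort, scored, sample) {
  samples <- cohort_samples(cohort)
  if (!sample %in% samples) abort(sprintf("unknown sample id: %s", sample))
  calls <- as_tibble(cohort) |>
    filter(.data$sample_id == sample, !is.na(.data$zygosity),
           .data$zygosity > 0L)
  left_join(calls, select(scored, -dplyr::any_of(c("chrom", "pos", "ref", "alt"))),
            by = "variant_id")
}

#' Rank one sample's variants from most to least likely pathogenic
#'
#' Only variants the sample actually carries (zygosity 1 or 2) appear.
#' Rows are ordered by final score (descending); ties are broken by the
#' lowest available population allele frequency (absent frequency sorts
#' first, as rarest) and then by genomic coordinates, so output order is
#' fully deterministic. With `filtered = TRUE` the default filter cascade
#' is applied first and removed calls are dropped.
#'
#' @param cohort A `variant_cohort`.
#' @param scored Per-variant scores from [score_cohort()].
#' @param sample A sample id.
#' @param filtered Apply [apply_filters()] and keep passing calls only.
#' @param filters A [filter_config()].
#' @return The sample's scored calls, ordered, with a `rank` column.
#' @export
rank_by_variant <- function(cohort, scored, sample, filtered = FALSE,
                            filters = filter_config()) {
  df <- sample_scored_calls(cohort, scored, sample)
  if (filtered) {
    df <- apply_filters(df, filters)
    df <- filter(df, .data$keep)
  }
  df <- arrange_ranking(df)
  mutate(df, rank = dplyr::row_number())
}

#' Rank one sample's genes from most to least likely causative
#'
#' Each gene is scored along two criteria: its most pathogenic homozygous
#' variant, and its two most pathogenic heterozygous variants (the
#' compound-heterozygote pair under a recessive model). The gene rank key
#' is the larger of (best homozygous score) and (second-best heterozygous
#' score) — the limiting allele — with the best heterozygous score as tie
#' breaker, then the gene symbol. Within a gene block every variant of the
#' gene is reported, ordered by score, so nothing is silently dropped.
#'
#' @inheritParams rank_by_variant
#' @return Ordered tibble of the sample's scored calls with `gene_rank`,
#'   `gene_score` and per-variant `rank` within the block.
#' @export
rank_by_gene <- function(cohort, scored, sample, filtered = FALSE,
                         filters = filter_config()) {
  df <- sample_scored_calls(cohort, scored, sample)
  if (filtered) {
    df <- apply_filters(df, filters)
    df <- filter(df, .data$keep)
  }
  df <- mutate(df, gene = dplyr::coalesce(.data$gene, ""))
  gene_keys <- df |>
    group_by(.data$gene) |>
    summarise(
      hom_best = suppressWarnings(max(.data$final_score[.data$zygosity == 2L],
                                      na.rm = TRUE)),
      het_best = suppressWarnings(max(.data$final_score[.data$zygosity == 1L],
                                      na.rm = TRUE)),
      het_second = {
        h <- sort(.data$final_score[.data$zygosity == 1L], decreasing = TRUE)
        if (length(h) >= 2) h[2] else -Inf
      },
      .groups = "drop") |>
    mutate(hom_best = ifelse(is.finite(.data$hom_best), .data$hom_best, -Inf),
           het_best = ifelse(is.finite(.data$het_best), .data$het_best, -Inf),
           gene_score = pmax(.data$hom_best, .data$het_second, 0)) |>
    arrange(dplyr::desc(.data$gene_score),
            dplyr::desc(pmax(.data$het_best, 0)), .data$gene) |>
    mutate(gene_rank = dplyr::row_number())
  df |>
    left_join(select(gene_keys, "gene", "gene_score", "gene_rank"),
              by = "gene") |>
    mutate(.af = dplyr::coalesce(.data$max_af, 0)) |>
    arrange(.data$gene_rank, dplyr::desc(.data$final_score), .data$.af,
            chrom_rank(.data$chrom), .data$pos, .data$ref, .data$alt) |>
    select(-".af") |>
    group_by(.data$gene_rank) |>
    mutate(rank = dplyr::row_number()) |>
    ungroup()
}
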