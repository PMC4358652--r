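# Category-based pathogenicity scoring. Each transcript annotation is
# scored along two pathways — the coding effect and the splice effect — and
# the more pathogenic one wins; across transcripts the most pathogenic
# effect is retained. Known-mutation evidence overrides everything.

#' Scoring configuration
#'
#' Base scores per variant category, the conservation/prediction adjustment
#' step, the splice-program significance thresholds and the splice-site
#' windows. Defaults encode the standard scheme: known mutation 110,
#' nonsense 100, frameshift 100, essential splice 90, start/stop loss 80,
#' close (intron-exon boundary) splice 70, missense 50, in-frame 40, deep
#' splice 25, synonymous 10; +5 when phastCons exceeds 0.95 (and, for
#' missense, +5 per deleterious protein prediction); splice significance at
#' a score drop of at least 10% (MaxEntScan), 5% (NNSplice) and 15%
#' (SpliceSiteFinder), with two of the three programs required.
#'
#' @param S_Known,S_Nonsense,S_Fs,S_EssentialSplice,S_StartLoss,S_StopLoss,S_CloseSplice,S_Missense,S_Inframe,S_DeepSplice,S_Synonymous
#'   Integer base scores per category.
#' @param adjustment_step Increment added per adjustment trigger.
#' @param phastcons_cutoff Conservation above this value triggers the
#'   adjustment (strictly greater).
#' @param mes_threshold,nns_threshold,ssf_threshold Percent-change
#'   thresholds; a program votes "significant" when its delta is at or
#'   below the (negative) threshold.
#' @param splice_consensus_min Programs required to call a splice effect.
#' @param donor_window,acceptor_window Close-splice windows in the signed
#'   distance convention of [splice_category()] (positive = intronic side).
#' @return A named list of class `scoring_config`.
#' @export
scoring_config <- function(S_Known = 110L, S_Nonsense = 100L, S_Fs = 100L,
                           S_EssentialSplice = 90L, S_StartLoss = 80L,
                           S_StopLoss = 80L, S_CloseSplice = 70L,
                           S_Missense = 50L, S_Inframe = 40L,
                           S_DeepSplice = 25L, S_Synonymous = 10L,
                           adjustment_step = 5L, phastcons_cutoff = 0.95,
                           mes_threshold = -10, nns_threshold = -5,
                           ssf_threshold = -15, splice_consensus_min = 2L,
                           donor_window = c(-3L, 6L),
                           acceptor_window = c(-2L, 12L)) {
  cfg <- list(S_Known = S_Known, S_Nonsense = S_Nonsense, S_Fs = S_Fs,
              S_EssentialSplice = S_EssentialSplice,
              S_StartLoss = S_StartLoss, S_StopLoss = S_StopLoss,
              S_CloseSplice = S_CloseSplice, S_Missense = S_Missense,
              S_Inframe = S_Inframe, S_DeepSplice = S_DeepSplice,
              S_Synonymous = S_Synonymous,
              adjustment_step = adjustment_step,
              phastcons_cutoff = phastcons_cutoff,
              mes_threshold = mes_threshold, nns_threshold = nns_threshold,
              ssf_threshold = ssf_threshold,
              splice_consensus_min = splice_consensus_min,
              donor_window = donor_window, acceptor_window = acceptor_window)
  base <- unlist(cfg[1:11])
  if (any(base < 0)) abort("base scores must be non-negative")
  structure(cfg, class = "scoring_config")
}

coding_base_score <- function(coding_effect, config) {
  dplyr::case_match(coding_effect,
    "nonsense"   ~ config$S_Nonsense,
    "frameshift" ~ config$S_Fs,
    "start loss" ~ config$S_StartLoss,
    "stop loss"  ~ config$S_StopLoss,
    "missense"   ~ config$S_Missense,
    "in-frame"   ~ config$S_Inframe,
    "synonymous" ~ config$S_Synonymous,
    .default = 0L
  )
}

# effective splice deltas: recomputed from wt/var scores when both present
# (and wt > 0); otherwise the supplied delta column is used as-is.
effective_delta <- function(wt, var, delta) {
  recompute <- !is.na(wt) & !is.na(var) & wt > 0
  out <- delta
  out[recompute] <- 100 * (var[recompute] - wt[recompute]) / wt[recompute]
  out
}

#' Two-of-three splice-program consensus
#'
#' A variant is considered to affect splicing when at least
#' `splice_consensus_min` (default 2) of the three assessment programs
#' report a significant score drop between the wild-type and variant
#' sequences: MaxEntScan at or below −10%, NNSplice at or below −5%,
#' SpliceSiteFinder at or below −15% (a delta exactly at the threshold
#' counts as significant). Programs without a value abstain; all-absent
#' gives `FALSE`.
#'
#' @param mes_delta,nns_delta,ssf_delta Percent score changes (negative =
#'   weaker site in the variant sequence).
#' @param config A [scoring_config()].
#' @return Logical vector.
#' @examples
#' splice_consensus(-12, -6, -3)   # MES + NNS vote: TRUE
#' splice_consensus(-12, -2, -3)   # only MES: FALSE
#' @export
splice_consensus <- function(mes_delta, nns_delta, ssf_delta,
                             config = scoring_config()) {
  votes <- cbind(na_false(mes_delta <= config$mes_threshold),
                 na_false(nns_delta <= config$nns_threshold),
                 na_false(ssf_delta <= config$ssf_threshold))
  unname(rowSums(votes) >= config$splice_consensus_min)
}

#' Splice-site category of a variant position
#'
#' Distance convention: `dist_nearest_ss > 0` lies on the intronic side of
#' the nearest splice site, `<= 0` on the exonic side. Categories:
#'
#' * `essential` — the two first intronic bases (+1/+2) of either site;
#'   canonical-site disruption, assigned regardless of program consensus.
#' * `close` — within the donor window −3..+6 or the acceptor window
#'   (−12 intronic .. +2 exonic), outside the essential bases, when the
#'   program consensus holds.
#' * `deep` — intronic beyond the close window, when the consensus holds.
#' * `none` — otherwise; also when the nearest-site type is unknown for an
#'   intronic position (warned once per call).
#'
#' @param dist_nearest_ss Signed distance in bp to the nearest splice site.
#' @param nearest_ss `"donor"` or `"acceptor"` (recycled as needed).
#' @param consensus Logical, result of [splice_consensus()].
#' @param config A [scoring_config()].
#' @return Character vector over `c("essential", "close", "deep", "none")`.
#' @export
splice_category <- function(dist_nearest_ss, nearest_ss, consensus,
                            config = scoring_config()) {
  n <- max(length(dist_nearest_ss), length(nearest_ss), length(consensus))
  dist <- rep_len(dist_nearest_ss, n)
  site <- rep_len(tolower(as.character(nearest_ss)), n)
  consensus <- rep_len(consensus, n)
  known_site <- na_false(site %in% c("donor", "acceptor"))
  essential <- known_site & na_false(dist %in% c(1, 2))
  in_donor <- na_false(site == "donor") &
    na_false(dist >= config$donor_window[1]) &
    na_false(dist <= config$donor_window[2])
  in_acceptor <- na_false(site == "acceptor") &
    na_false(dist >= config$acceptor_window[1]) &
    na_false(dist <= config$acceptor_window[2])
  close <- !essential & na_false(consensus) & (in_donor | in_acceptor)
  deep <- known_site & !essential & !close & na_false(consensus) &
    na_false(dist > 0)
  out <- rep("none", n)
  out[deep] <- "deep"
  out[close] <- "close"
  out[essential] <- "essential"
  unknown_site <- !known_site & na_false(dist > 0) & na_false(consensus)
  if (any(unknown_site)) {
    warn(sprintf("%d intronic variant(s) with unknown nearest splice site type; splice category set to none",
                 sum(unknown_site)))
  }
  out
}

splice_base_score <- function(category, config) {
  dplyr::case_match(category,
    "essential" ~ config$S_EssentialSplice,
    "close"     ~ config$S_CloseSplice,
    "deep"      ~ config$S_DeepSplice,
    .default = 0L
  )
}

sift_deleterious <- function(sift_pred, sift_weight) {
  na_false(str_detect(tolower(sift_pred %||% NA_character_),
                      "deleterious|damaging")) |
    na_false(sift_weight <= 0.05)
}

pph2_deleterious <- function(pph2_pred) {
  na_false(str_detect(tolower(pph2_pred %||% NA_character_),
                      "damaging|deleterious"))
}

# Categories whose score takes the conservation adjustment (the scheme's
# footnote-a rows). Frameshift, in-frame and known mutation never adjust.
conservation_adjusted_coding <- c("nonsense", "start loss", "stop loss",
                                  "missense", "synonymous")

#' Score adjustment for one annotation and category
#'
#' +`adjustment_step` (default 5) when phastCons strictly exceeds the cutoff
#' (0.95) and the category is one of the conservation-adjusted rows
#' (nonsense, essential/close/deep splice, start/stop loss, missense,
#' synonymous). Missense additionally gains +5 for each deleterious protein
#' prediction (SIFT and/or PolyPhen-2). Frameshift, in-frame and known
#' mutation are never adjusted; missing predictors contribute 0.
#'
#' @param category Category label: a coding effect, `"essential"`,
#'   `"close"`, `"deep"`, `"known mutation"` or `"none"`.
#' @param phastcons phastCons conservation in `[0, 1]` (NA allowed).
#' @param sift_pred,sift_weight,pph2_pred Protein-prediction fields.
#' @param config A [scoring_config()].
#' @return Integer vector of adjustments.
#' @export
score_adjustment <- function(category, phastcons, sift_pred = NA,
                             sift_weight = NA, pph2_pred = NA,
                             config = scoring_config()) {
  n <- length(category)
  phastcons <- rep_len(phastcons, n)
  sift_pred <- rep_len(sift_pred, n)
  sift_weight <- rep_len(sift_weight, n)
  pph2_pred <- rep_len(pph2_pred, n)
  eligible <- category %in% c(conservation_adjusted_coding,
                              "essential", "close", "deep")
  adj <- ifelse(eligible & na_false(phastcons > config$phastcons_cutoff),
                config$adjustment_step, 0L)
  is_mis <- category %in% "missense"
  adj <- adj + ifelse(is_mis & sift_deleterious(sift_pred, sift_weight),
                      config$adjustment_step, 0L)
  adj <- adj + ifelse(is_mis & pph2_deleterious(pph2_pred),
                      config$adjustment_step, 0L)
  as.integer(adj)
}

# dbSNP clinical-significance token match: "pathogenic" or
# "probable-pathogenic" as whole tokens, so "non-pathogenic" never matches.
clinsig_pathogenic <- function(clinsig) {
  vapply(strsplit(tolower(ifelse(is.na(clinsig), "", clinsig)),
                  "[;,/| ]+"),
         function(tok) any(tok %in% c("pathogenic", "probable-pathogenic",
                                      "probable_pathogenic",
                                      "likely-pathogenic",
                                      "likely_pathogenic")),
         logical(1))
}

# Per-transcript scoring: adds pathway scores and the per-transcript final
# score to an annotation tibble. Internal workhorse behind score_variants().
score_transcripts <- function(ann, config = scoring_config(),
                              known_ids = character()) {
  ann <- ensure_annotation_columns(ann)
  mes <- effective_delta(ann$mes_wt, ann$mes_var, ann$mes_delta)
  nns <- effective_delta(ann$nns_wt, ann$nns_var, ann$nns_delta)
  ssf <- effective_delta(ann$ssf_wt, ann$ssf_var, ann$ssf_delta)
  consensus <- splice_consensus(mes, nns, ssf, config)
  spl_cat <- splice_category(ann$dist_nearest_ss, ann$nearest_ss, consensus,
                             config)
  coding_base <- coding_base_score(ann$coding_effect, config)
  coding_adj <- score_adjustment(ifelse(is.na(ann$coding_effect), "none",
                                        ann$coding_effect),
                                 ann$phastcons, ann$sift_pred,
                                 ann$sift_weight, ann$pph2_pred, config)
  coding_adj[coding_base == 0L] <- 0L
  splice_base <- splice_base_score(spl_cat, config)
  splice_adj <- score_adjustment(spl_cat, ann$phastcons, config = config)
  coding_score <- coding_base + coding_adj
  splice_score <- splice_base + splice_adj
  splice_wins <- splice_score > coding_score
  known <- clinsig_pathogenic(ann$rs_clinical_significance) |
    ann$variant_id %in% known_ids
  ann |>
    mutate(
      splice_cat = spl_cat,
      tx_category = dplyr::case_when(
        known ~ "known mutation",
        splice_wins & spl_cat == "essential" ~ "essential splice",
        splice_wins & spl_cat == "close" ~ "close splice",
        splice_wins & spl_cat == "deep" ~ "deep splice",
        !is.na(ann$coding_effect) & coding_base > 0 ~ ann$coding_effect,
        TRUE ~ "none"),
      pathway = dplyr::case_when(
        known ~ "known",
        splice_wins ~ "splice",
        coding_score > 0 ~ "coding",
        TRUE ~ "none"),
      base_score = as.integer(dplyr::case_when(
        known ~ config$S_Known,
        splice_wins ~ splice_base,
        TRUE ~ coding_base)),
      adjustment = as.integer(dplyr::case_when(
        known ~ 0L,
        splice_wins ~ splice_adj,
        TRUE ~ coding_adj)),
      tx_score = .data$base_score + .data$adjustment,
      known = known
    )
}

#' Score the annotated variants of a cohort
#'
#' Applies the full scoring scheme to a transcript-annotation tibble and
#' reduces it to one row per variant. Per transcript, the coding-effect
#' pathway and the splice pathway are scored separately and the more
#' pathogenic of the two is kept (an SNV at an exon boundary can be both a
#' missense and a splice-site change); across transcripts the most
#' pathogenic effect is retained, the representative transcript being the
#' gene's longest unless another transcript scores strictly higher
#' (see [select_representative()]). Variants with known-mutation evidence
#' (dbSNP clinical significance pathogenic/probable-pathogenic, or listed
#' in `known_ids`) receive the unadjusted known-mutation score.
#'
#' @param annotations Transcript annotations ([read_annotation_table()],
#'   [annotations_from_vcf()] or compatible tibble).
#' @param config A [scoring_config()].
#' @param known_ids Optional character vector of variant ids with external
#'   known-mutation evidence.
#' @return A tibble with one row per `variant_id`: the representative
#'   annotation columns plus `category`, `pathway`, `base_score`,
#'   `adjustment`, `final_score`, `max_af`, `known` and
#'   `annotation_analysis`.
#' @export
score_variants <- function(annotations, config = scoring_config(),
                           known_ids = character()) {
  scored_tx <- score_transcripts(annotations, config, known_ids)
  if (nrow(scored_tx) == 0) {
    return(mutate(scored_tx, category = character(), final_score = integer(),
                  max_af = double(), annotation_analysis = character()))
  }
  freq <- as.matrix(scored_tx[, ann_frequency_cols])
  scored_tx$max_af_tx <- suppressWarnings(
    apply(freq, 1, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)))
  len <- scored_tx$transcript_length
  len[is.na(len)] <- -1
  txid <- scored_tx$transcript_id
  txid[is.na(txid)] <- ""
  scored_tx |>
    mutate(.len = len, .txid = txid) |>
    group_by(.data$variant_id) |>
    mutate(max_af = if (all(is.na(.data$max_af_tx))) NA_real_
           else max(.data$max_af_tx, na.rm = TRUE)) |>
    arrange(dplyr::desc(.data$tx_score), dplyr::desc(.data$.len),
            .data$.txid, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    select(-"max_af_tx", -".len", -".txid") |>
    rename(category = "tx_category", final_score = "tx_score") |>
    mutate(annotation_analysis = "Yes") |>
    arrange(.data$variant_id)
}

#' Complete scores for a cohort, including unannotated variants
#'
#' Wraps [score_variants()] and appends a zero-score row (category
#' `"not annotated"`, `annotation_analysis = "No"`) for every cohort
#' variant key absent from the annotation source.
#'
#' @inheritParams score_variants
#' @param cohort A `variant_cohort`.
#' @return One row per cohort variant key.
#' @export
score_cohort <- function(cohort, annotations, config = scoring_config(),
                         known_ids = character()) {
  ann <- annotate_cohort(cohort, annotations)
  scored <- score_variants(ann, config, known_ids)
  keys <- cohort_variants(cohort)
  missing_keys <- keys[!keys$variant_id %in% scored$variant_id, , drop = FALSE]
  if (nrow(missing_keys) > 0) {
    blank <- ensure_annotation_columns(
      tibble(variant_id = missing_keys$variant_id))
    blank <- mutate(blank, splice_cat = "none", category = "not annotated",
                    pathway = "none", base_score = 0L, adjustment = 0L,
                    final_score = 0L, known = FALSE, max_af = NA_real_,
                    annotation_analysis = "No")
    scored <- bind_rows(scored, blank)
  }
  arrange(scored, .data$variant_id)
}
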