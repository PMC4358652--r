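# Shared fixtures: small in-code VCFs and annotation rows.

write_test_vcf <- function(records, samples = "P1",
                           path = withr::local_tempfile(fileext = ".vcf",
                                                        .local_envir = parent.frame()),
                           format = "GT") {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           paste(samples, collapse = "\t")),
    vapply(records, function(r) {
      stopifnot(length(r) == 5 + length(samples)) # chrom,pos,ref,alt,qual + cells
      paste(c(r[1], r[2], ".", r[3], r[4], r[5], "PASS", ".", format,
              r[-(1:5)]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  path
}

# One-row transcript annotation with sensible defaults; override any field.
ann_fixture <- function(variant_id = "1_100_A_T", gene = "G1",
                        transcript_id = "T1", transcript_length = 1000,
                        coding_effect = NA_character_,
                        var_location = "exon", ...) {
  base <- tibble::tibble(variant_id = variant_id, gene = gene,
                         transcript_id = transcript_id,
                         transcript_length = transcript_length,
                         coding_effect = coding_effect,
                         var_location = var_location)
  extra <- list(...)
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  base
}

# Independent brute-force scorer used as oracle against score_variants().
# Scalar if-chains throughout; shares no code with the implementation.
brute_force_score <- function(ann_rows, known_ids = character()) {
  ann_rows <- varprior:::ensure_annotation_columns(ann_rows)
  base_of <- c(nonsense = 100, frameshift = 100, "start loss" = 80,
               "stop loss" = 80, missense = 50, "in-frame" = 40,
               synonymous = 10)
  best <- 0
  for (i in seq_len(nrow(ann_rows))) {
    r <- as.list(ann_rows[i, ])
    conserved <- !is.na(r$phastcons) && r$phastcons > 0.95
    # known mutation overrides everything
    toks <- strsplit(tolower(ifelse(is.na(r$rs_clinical_significance), "",
                                    r$rs_clinical_significance)),
                     "[;,/| ]+")[[1]]
    if (any(toks %in% c("pathogenic", "probable-pathogenic")) ||
        r$variant_id %in% known_ids) {
      return(110)
    }
    # coding pathway
    coding <- 0
    if (!is.na(r$coding_effect) && r$coding_effect %in% names(base_of)) {
      coding <- base_of[[r$coding_effect]]
      if (conserved && r$coding_effect %in%
          c("nonsense", "start loss", "stop loss", "missense", "synonymous")) {
        coding <- coding + 5
      }
      if (r$coding_effect == "missense") {
        sift_del <- (!is.na(r$sift_pred) &&
                       grepl("deleterious|damaging", tolower(r$sift_pred))) ||
          (!is.na(r$sift_weight) && r$sift_weight <= 0.05)
        pph_del <- !is.na(r$pph2_pred) &&
          grepl("damaging|deleterious", tolower(r$pph2_pred))
        if (sift_del) coding <- coding + 5
        if (pph_del) coding <- coding + 5
      }
    }
    # splice pathway
    d <- function(wt, var, given) {
      if (!is.na(wt) && !is.na(var) && wt > 0) 100 * (var - wt) / wt else given
    }
    mes <- d(r$mes_wt, r$mes_var, r$mes_delta)
    nns <- d(r$nns_wt, r$nns_var, r$nns_delta)
    ssf <- d(r$ssf_wt, r$ssf_var, r$ssf_delta)
    votes <- sum(c(!is.na(mes) && mes <= -10,
                   !is.na(nns) && nns <= -5,
                   !is.na(ssf) && ssf <= -15))
    dist <- r$dist_nearest_ss
    site <- tolower(ifelse(is.na(r$nearest_ss), "", r$nearest_ss))
    splice <- 0
    if (!is.na(dist) && site %in% c("donor", "acceptor")) {
      if (dist %in% c(1, 2)) {
        splice <- 90
      } else if (votes >= 2) {
        if (site == "donor" && dist >= -3 && dist <= 6) splice <- 70
        else if (site == "acceptor" && dist >= -2 && dist <= 12) splice <- 70
        else if (dist > 0) splice <- 25
      }
      if (splice > 0 && conserved) splice <- splice + 5
    }
    best <- max(best, coding, splice)
  }
  best
}
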