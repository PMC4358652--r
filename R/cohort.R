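# Cohort ingestion: one multi-sample VCF and/or many single-sample VCFs are
# merged into a single long tibble of carrier calls (class "variant_cohort").
# Hom-ref calls are implicit: a (variant, sample) pair absent from the table
# means the sample is homozygous for the reference allele. Missing genotypes
# (./.) are stored with zygosity NA and rendered as "0" in barcodes.

#' Genotype string to zygosity code
#'
#' Converts VCF `GT` strings to the integer zygosity codes used throughout
#' the package and in the cohort barcode: `0` homozygous reference, `1`
#' heterozygous, `2` homozygous alternate, `NA` missing (`./.` or `.`).
#' Phasing separators (`|`) are treated like `/`. For multi-allelic records
#' the code is computed against one alternate allele at a time
#' (`alt_index`): a `1/2` genotype is heterozygous (code 1) for each of the
#' two alternates. Haploid calls (e.g. male X) are coded as homozygous:
#' `"1"` gives 2 and `"0"` gives 0.
#'
#' @param gt Character vector of GT strings.
#' @param alt_index Integer, which ALT allele (1-based) the code refers to.
#' @return Integer vector of codes in `c(0L, 1L, 2L, NA)`.
#' @examples
#' zygosity_code(c("0/1", "1|1", "./.", "1/2"))
#' @export
zygosity_code <- function(gt, alt_index = 1L) {
  gt <- as.character(gt)
  u <- unique(gt)
  code_one <- function(g) {
    if (is.na(g) || g == "" || g == ".") return(NA_integer_)
    alleles <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1]]
    if (all(alleles == ".")) return(NA_integer_)
    n_alt <- sum(alleles == as.character(alt_index))
    if (length(alleles) == 1L) {
      # haploid: carrying the allele counts as homozygous
      return(if (n_alt >= 1L) 2L else 0L)
    }
    as.integer(min(n_alt, 2L))
  }
  lookup <- vapply(u, code_one, integer(1))
  unname(lookup[match(gt, u)])
}

#' Percent of reads supporting the alternate allele
#'
#' `100 * alt_depth / total_depth`, `NA` when the total depth is zero or
#' missing. Alternate depths exceeding the total (occasionally emitted by
#' callers that count differently) are clamped to 100% with a warning.
#'
#' @param alt_depth,total_depth Integer vectors of read counts.
#' @return Numeric vector of percentages in `[0, 100]` (or `NA`).
#' @examples
#' support_ratio(c(5, 0, 7), c(50, 30, 0))
#' @export
support_ratio <- function(alt_depth, total_depth) {
  out <- rep(NA_real_, length(alt_depth))
  ok <- !is.na(alt_depth) & !is.na(total_depth) & total_depth > 0
  out[ok] <- 100 * alt_depth[ok] / total_depth[ok]
  clamped <- na_false(out > 100)
  if (any(clamped)) {
    warn(sprintf("%d call(s) had alt depth > total depth; ratio clamped to 100%%",
                 sum(clamped)))
    out[clamped] <- 100
  }
  out
}

#' Minimal anchored representation of a variant allele pair
#'
#' Trims the shared suffix then the shared prefix of `ref`/`alt` (always
#' keeping at least one base of each, the VCF anchored-indel convention) and
#' shifts `pos` past any trimmed prefix. SNVs are returned unchanged;
#' differently padded representations of the same indel converge to one key.
#'
#' @param chrom,pos,ref,alt Parallel vectors describing the raw alleles.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `id`.
#' @examples
#' normalize_variant("1", 100, "CTT", "CT")   # anchored deletion at 100
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  n <- length(ref)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # right-trim common suffix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # left-trim common prefix, keeping one anchor base
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  tibble(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
         id = variant_id_string(chrom, pos, ref, alt))
}

#' Split a raw VCF record into per-alternate variant calls
#'
#' Expands one (possibly multi-allelic) record into one normalized variant
#' key per ALT allele, with every sample's zygosity computed against that
#' allele alone. Symbolic alleles (`<DEL>`, `<NON_REF>`, breakends, `*`)
#' are dropped with a warning.
#'
#' @param chrom,pos,ref Record coordinates and reference allele.
#' @param alt Comma-separated ALT string.
#' @param gt Named character vector of per-sample GT strings (may be empty).
#' @return A tibble with one row per (ALT, sample) — or per ALT when no
#'   samples are given — holding the normalized key and `zygosity`.
#' @export
split_multiallelic <- function(chrom, pos, ref, alt, gt = character()) {
  alts <- strsplit(as.character(alt), ",", fixed = TRUE)[[1]]
  symbolic <- grepl("[][<>*]", alts)
  if (any(symbolic)) {
    warn(sprintf("skipping %d symbolic ALT allele(s) at %s:%s",
                 sum(symbolic), chrom, pos))
    alts <- alts[!symbolic]
  }
  if (length(alts) == 0) return(tibble())
  keys <- normalize_variant(rep(chrom, length(alts)), rep(pos, length(alts)),
                            rep(ref, length(alts)), alts)
  keys$alt_index <- seq_along(alts)
  if (length(gt) == 0) return(keys)
  tidyr::crossing(keys, sample_id = names(gt)) |>
    mutate(zygosity = zygosity_code(gt[.data$sample_id], .data$alt_index[1]),
           .by = "alt_index") |>
    arrange(.data$alt_index, .data$sample_id)
}

# ---- VCF file parsing (vcfR-backed) ----------------------------------------

# Parse one VCF into long call records. Returns list(calls, variants,
# samples, path). Only carrier (zygosity 1/2) and missing-genotype rows are
# materialized.
parse_vcf_file <- function(path, verbose = TRUE) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE),
    error = function(e) abort(sprintf("failed to parse VCF '%s': %s",
                                      path, conditionMessage(e)))
  )
  if (nrow(vcf@fix) == 0) {
    return(list(calls = tibble(), variants = tibble(),
                samples = character(), path = path))
  }
  if (ncol(vcf@gt) < 2) {
    abort(sprintf("VCF '%s' has no sample genotype columns", path))
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]

  gt_mat <- vcfR::extract.gt(vcf, "GT")
  if (is.null(gt_mat)) abort(sprintf("VCF '%s' has no GT FORMAT field", path))
  safe_gt <- function(el, as_num = FALSE) {
    tryCatch(vcfR::extract.gt(vcf, el, as.numeric = as_num),
             error = function(e) NULL, warning = function(w) NULL)
  }
  dp_mat <- safe_gt("DP", TRUE)
  ad_mat <- safe_gt("AD")
  ro_mat <- safe_gt("RO", TRUE)
  ao_mat <- safe_gt("AO")

  qual <- suppressWarnings(as.numeric(fix$QUAL))
  n_rec <- nrow(fix)
  alt_list <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)

  rec_idx <- rep.int(seq_len(n_rec), lengths(alt_list))
  alt_vec <- unlist(alt_list, use.names = FALSE)
  alt_pos <- sequence(lengths(alt_list)) # alt index within its record

  symbolic <- grepl("[][<>*]", alt_vec)
  bad_seq <- !symbolic & !grepl("^[ACGTNacgtn]+$", alt_vec)
  if (any(symbolic) && verbose) {
    inform(sprintf("%s: skipped %d symbolic ALT allele(s)", path, sum(symbolic)))
  }
  if (any(bad_seq)) {
    warn(sprintf("%s: skipped %d ALT allele(s) with non-ACGTN characters",
                 path, sum(bad_seq)))
  }
  keep <- !symbolic & !bad_seq
  rec_idx <- rec_idx[keep]; alt_vec <- alt_vec[keep]; alt_pos <- alt_pos[keep]

  keys <- normalize_variant(fix$CHROM[rec_idx], fix$POS[rec_idx],
                            fix$REF[rec_idx], alt_vec)
  changed <- keys$pos != as.integer(fix$POS[rec_idx]) |
    keys$ref != toupper(fix$REF[rec_idx])
  if (any(changed) && verbose) {
    inform(sprintf("%s: normalized %d indel representation(s)",
                   path, sum(changed)))
  }

  # zygosity per (expanded alt, sample), via lookup over unique GT strings
  max_alt <- if (length(alt_pos)) max(alt_pos) else 0L
  zyg_by_index <- lapply(seq_len(max_alt), function(j) {
    m <- matrix(zygosity_code(as.vector(gt_mat), j),
                nrow = nrow(gt_mat), dimnames = dimnames(gt_mat))
    m
  })

  ad_field <- function(cells, j) {
    # AD = "ref,alt1,alt2,..."; take field j+1
    vapply(strsplit(ifelse(is.na(cells), "", cells), ",", fixed = TRUE),
           function(x) {
             if (length(x) >= j + 1L) suppressWarnings(as.numeric(x[j + 1L]))
             else NA_real_
           }, numeric(1))
  }
  ao_field <- function(cells, j) {
    vapply(strsplit(ifelse(is.na(cells), "", cells), ",", fixed = TRUE),
           function(x) {
             if (length(x) >= j) suppressWarnings(as.numeric(x[j]))
             else NA_real_
           }, numeric(1))
  }

  call_blocks <- lapply(seq_along(rec_idx), function(k) {
    i <- rec_idx[k]; j <- alt_pos[k]
    zyg <- zyg_by_index[[j]][i, ]
    sel <- is.na(zyg) | zyg > 0L
    if (!any(sel)) return(NULL)
    sel_samples <- samples[sel]
    total <- if (!is.null(dp_mat)) as.numeric(dp_mat[i, sel]) else NA_real_
    altd <- if (!is.null(ad_mat)) ad_field(ad_mat[i, sel], j)
            else if (!is.null(ao_mat)) ao_field(ao_mat[i, sel], j)
            else NA_real_
    if (all(is.na(total)) && !is.null(ro_mat) && !is.null(ao_mat)) {
      ro <- as.numeric(ro_mat[i, sel])
      ao_all <- vapply(strsplit(ifelse(is.na(ao_mat[i, sel]), "", ao_mat[i, sel]),
                                ",", fixed = TRUE),
                       function(x) sum(suppressWarnings(as.numeric(x))),
                       numeric(1))
      total <- ro + ao_all
    }
    tibble(row = k, rec = i, sample_id = sel_samples,
           zygosity = unname(zyg[sel]),
           total_depth = as.integer(round(total)),
           alt_depth = as.integer(round(altd)))
  })
  calls <- bind_rows(call_blocks)
  if (nrow(calls) > 0) {
    calls <- bind_cols(keys[calls$row, c("id", "chrom", "pos", "ref", "alt")],
                       calls[, c("sample_id", "zygosity", "total_depth",
                                 "alt_depth")],
                       tibble(phred_qual = qual[calls$rec])) |>
      rename(variant_id = "id") |>
      mutate(percent_alt = support_ratio(.data$alt_depth, .data$total_depth)) |>
      select("variant_id", "chrom", "pos", "ref", "alt", "sample_id",
             "zygosity", "total_depth", "alt_depth", "percent_alt",
             "phred_qual")
  }
  gt_cells <- as.vector(vcf@gt[, -1, drop = FALSE])
  n_bad_gt <- sum(!is.na(gt_cells) &
                    !grepl("^(\\.|([0-9.]+([/|][0-9.]+)*))(:|$)", gt_cells))
  if (n_bad_gt > 0) warn(sprintf("%s: %d malformed genotype field(s)", path, n_bad_gt))

  variants <- distinct(keys[, c("id", "chrom", "pos", "ref", "alt")]) |>
    rename(variant_id = "id")
  list(calls = calls, variants = variants, samples = samples, path = path)
}

#' Read one or more VCF files into a variant cohort
#'
#' Accepts any mix of multi-sample and single-sample VCF files (plain or
#' gzip-compressed), splits multi-allelic records, normalizes indel
#' representations to their minimal anchored form, and merges everything
#' into one cohort. Sample identifiers duplicated across files are kept
#' from their first occurrence with a warning. Sample order in the cohort
#' (and hence in every barcode and report) is lexicographic.
#'
#' The returned object is a tibble of *carrier* calls — one row per
#' (variant, sample) with zygosity 1 (het), 2 (hom-alt) or `NA` (missing
#' genotype). Hom-ref pairs are implicit. The full variant-key set and the
#' ordered sample list travel as attributes (`variants`, `samples`,
#' `provenance`) and via [cohort_variants()] and [cohort_samples()].
#'
#' @param paths Character vector of VCF paths (`.vcf` or `.vcf.gz`).
#' @param samples Optional character vector restricting the cohort to these
#'   sample ids; unknown ids are an error.
#' @param verbose Emit per-file progress and statistics messages.
#' @return A `variant_cohort` tibble with columns `variant_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `sample_id`, `zygosity`, `total_depth`,
#'   `alt_depth`, `percent_alt`, `phred_qual`.
#' @export
read_cohort <- function(paths, samples = NULL, verbose = TRUE) {
  stopifnot(length(paths) >= 1)
  parsed <- map(paths, parse_vcf_file, verbose = verbose)

  seen <- character()
  for (p in parsed) {
    dup <- intersect(p$samples, seen)
    if (length(dup) > 0) {
      warn(sprintf("duplicate sample id(s) %s in '%s'; keeping first occurrence",
                   paste(dup, collapse = ", "), p$path))
      p_keep <- setdiff(p$samples, dup)
      p$calls <- filter(p$calls, .data$sample_id %in% p_keep)
      p$samples <- p_keep
    }
    seen <- c(seen, p$samples)
  }
  # recompute after de-duplication (loop above modified local copies only)
  seen <- character(); calls_list <- list(); prov <- list()
  for (p in parsed) {
    keep_samples <- setdiff(p$samples, seen)
    calls_list[[length(calls_list) + 1L]] <-
      filter(p$calls, .data$sample_id %in% keep_samples)
    prov[[length(prov) + 1L]] <- tibble(sample_id = keep_samples, path = p$path)
    seen <- c(seen, keep_samples)
  }
  all_samples <- sort(seen)
  calls <- bind_rows(calls_list)
  variants <- bind_rows(map(parsed, "variants")) |> distinct() |> arrange_variants()
  provenance <- bind_rows(prov)

  if (!is.null(samples)) {
    unknown <- setdiff(samples, all_samples)
    if (length(unknown) > 0) {
      abort(sprintf("unknown sample id(s) in selection: %s",
                    paste(unknown, collapse = ", ")))
    }
    all_samples <- sort(samples)
    calls <- filter(calls, .data$sample_id %in% all_samples)
    provenance <- filter(provenance, .data$sample_id %in% all_samples)
  }
  n_missing <- sum(is.na(calls$zygosity))
  if (verbose) {
    inform(sprintf(
      "cohort: %d variant(s), %d sample(s), %d carrier call(s)%s",
      nrow(variants), length(all_samples), sum(!is.na(calls$zygosity)),
      if (n_missing > 0) sprintf(", %d missing genotype(s)", n_missing) else ""))
  }
  new_variant_cohort(calls, variants, all_samples, provenance)
}

new_variant_cohort <- function(calls, variants, samples, provenance) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) {
    calls <- tibble(variant_id = character(), chrom = character(),
                    pos = integer(), ref = character(), alt = character(),
                    sample_id = character(), zygosity = integer(),
                    total_depth = integer(), alt_depth = integer(),
                    percent_alt = double(), phred_qual = double())
  }
  calls <- calls[order(chrom_rank(calls$chrom), calls$pos, calls$ref,
                       calls$alt, calls$sample_id), ]
  structure(calls,
            variants = as_tibble(variants),
            samples = samples,
            provenance = as_tibble(provenance),
            class = c("variant_cohort", class(tibble())))
}

#' Cohort accessors
#'
#' `cohort_samples()` returns the ordered sample ids; `cohort_variants()`
#' the tibble of distinct normalized variant keys (including keys no
#' selected sample carries).
#'
#' @param cohort A `variant_cohort` from [read_cohort()].
#' @return A character vector / tibble.
#' @export
cohort_samples <- function(cohort) attr(cohort, "samples")

#' @rdname cohort_samples
#' @export
cohort_variants <- function(cohort) attr(cohort, "variants")

#' @export
print.variant_cohort <- function(x, ...) {
  cat(sprintf("# A variant cohort: %d variants x %d samples (%d carrier calls)\n",
              nrow(cohort_variants(x)), length(cohort_samples(x)), nrow(x)))
  NextMethod()
}

#' Write a cohort back to a (single, multi-sample) VCF file
#'
#' One bi-allelic record per normalized variant key, FORMAT `GT:DP:AD`.
#' Useful for export and for round-trip checks.
#'
#' @param cohort A `variant_cohort`.
#' @param path Output path (`.vcf`, plain text).
#' @return Invisibly, `path`.
#' @export
write_cohort_vcf <- function(cohort, path) {
  samples <- cohort_samples(cohort)
  variants <- arrange_variants(cohort_variants(cohort))
  zyg_w <- as_tibble(cohort)[, c("variant_id", "sample_id", "zygosity")] |>
    mutate(gt = dplyr::case_when(
      is.na(.data$zygosity) ~ "./.",
      .data$zygosity == 1L ~ "0/1",
      .data$zygosity == 2L ~ "1/1",
      TRUE ~ "0/0")) |>
    select("variant_id", "sample_id", "gt") |>
    pivot_wider(names_from = "sample_id", values_from = "gt",
                values_fill = "0/0")
  for (s in setdiff(samples, names(zyg_w))) zyg_w[[s]] <- "0/0"
  zyg_w <- zyg_w[match(variants$variant_id, zyg_w$variant_id), , drop = FALSE]
  gt_cells <- as.matrix(zyg_w[, samples, drop = FALSE])
  gt_cells[is.na(gt_cells)] <- "0/0"
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                     paste(samples, collapse = "\t")))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", ".", ".", "GT",
                apply(gt_cells, 1, paste, collapse = "\t"),
                sep = "\t")
  # guard against zero-variant cohorts (apply() degenerates)
  if (nrow(variants) == 0) body <- character()
  writeLines(c(header, body), path)
  invisible(path)
}
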