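# Synthetic cohorts with known ground truth. The generator emulates the
# structure the prioritization pipeline is built for: a pool of common
# polymorphisms (population frequency above 1%) shared across samples, plus
# private rare spiked mutations of chosen category and zygosity whose
# expected final score is recorded in a truth table.

#' Simulation configuration
#'
#' @param n_samples Number of samples in the cohort.
#' @param n_background_variants Size of the shared polymorphism pool;
#'   each sample carries a frequency-dependent subset, so the non-redundant
#'   variant count saturates as samples accumulate.
#' @param background_af_range Population allele frequencies of background
#'   variants, drawn uniformly (default 1%–50%; all above the default
#'   frequency-removal threshold).
#' @param spikes A tibble with columns `sample`, `category` (one of
#'   `"known"`, `"nonsense"`, `"missense"`, `"frameshift"`, `"synonymous"`,
#'   `"essential_splice"`), `zygosity` (1 or 2) and optional `gene`,
#'   `conserved` (logical, phastCons above the cutoff). Each spike is a
#'   private variant of that sample.
#' @param depth_mean,depth_size Negative-binomial read-depth model
#'   (mean / dispersion `size`); defaults emulate ~50x targeted coverage.
#' @param seed Integer seed; the seed fully determines all outputs.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 30L, n_background_variants = 1000L,
                              background_af_range = c(0.01, 0.5),
                              spikes = NULL, depth_mean = 50, depth_size = 10,
                              seed = 1L) {
  stopifnot(n_samples >= 1, n_background_variants >= 0,
            length(background_af_range) == 2,
            background_af_range[1] >= 0, background_af_range[2] <= 1)
  spikes <- if (is.null(spikes)) {
    tibble(sample = character(), category = character(), zygosity = integer(),
           gene = character(), conserved = logical())
  } else as_tibble(spikes)
  structure(list(n_samples = as.integer(n_samples),
                 n_background_variants = as.integer(n_background_variants),
                 background_af_range = background_af_range,
                 spikes = spikes, depth_mean = depth_mean,
                 depth_size = depth_size, seed = as.integer(seed)),
            class = "simulation_config")
}

spike_category_fields <- function(category, conserved) {
  # annotation fields + expected default-config score per spike category
  switch(category,
    known = list(coding_effect = "missense", var_location = "exon",
                 rs_clinical_significance = "pathogenic",
                 expected = 110L),
    nonsense = list(coding_effect = "nonsense", var_location = "exon",
                    expected = if (conserved) 105L else 100L),
    frameshift = list(coding_effect = "frameshift", var_location = "exon",
                      expected = 100L),
    missense = list(coding_effect = "missense", var_location = "exon",
                    expected = if (conserved) 55L else 50L),
    synonymous = list(coding_effect = "synonymous", var_location = "exon",
                      expected = if (conserved) 15L else 10L),
    essential_splice = list(var_location = "intron", dist_nearest_ss = 1,
                            nearest_ss = "donor", mes_delta = -40,
                            nns_delta = -40, ssf_delta = -40,
                            expected = if (conserved) 95L else 90L),
    abort(sprintf("unsupported spike category: %s", category))
  )
}

sim_sample_ids <- function(n) {
  sprintf(paste0("S%0", max(2L, nchar(n)), "d"), seq_len(n))
}

# genotype matrix (variants x samples) under Hardy-Weinberg at frequency af
hwe_genotypes <- function(af, n_samples) {
  n_var <- length(af)
  a1 <- matrix(rbinom(n_var * n_samples, 1L, rep(af, n_samples)),
               nrow = n_var)
  a2 <- matrix(rbinom(n_var * n_samples, 1L, rep(af, n_samples)),
               nrow = n_var)
  a1 + a2
}

#' Generate a synthetic cohort with known ground truth
#'
#' Produces a VCF (text), a matching per-transcript annotation table
#' (text), and a truth table listing each spiked variant with its expected
#' final score under the default [scoring_config()]. Background variants
#' are common polymorphisms (dbSNP-validated, benign, with `rsMAF` equal to
#' their simulated population frequency) of synonymous / missense /
#' intronic type; spiked variants are private to their sample, carry no
#' population frequency, and are annotated so that the scorer assigns their
#' category. Two runs with the same configuration are byte-identical.
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory; when given, `cohort.vcf`,
#'   `annotations.tsv` and `truth.tsv` are written there.
#' @return A list with elements `vcf` (character lines), `annotation_table`
#'   (tibble, report-style column names), `truth` (tibble), `samples`, and
#'   — when `dir` is given — `vcf_path`, `annotation_path`, `truth_path`.
#' @export
simulate_cohort <- function(config = simulation_config(), dir = NULL) {
  withr::with_seed(config$seed, simulate_cohort_impl(config, dir))
}

simulate_cohort_impl <- function(config, dir) {
  n_s <- config$n_samples
  n_bg <- config$n_background_variants
  samples <- sim_sample_ids(n_s)
  spikes <- config$spikes
  if (nrow(spikes) > 0) {
    if (!all(c("sample", "category", "zygosity") %in% names(spikes))) {
      abort("spikes needs columns sample, category, zygosity")
    }
    if (!all(spikes$sample %in% samples)) {
      abort("spike sample(s) outside the simulated cohort")
    }
    if (!"gene" %in% names(spikes)) spikes$gene <- NA_character_
    if (!"conserved" %in% names(spikes)) spikes$conserved <- FALSE
    spikes$conserved <- replace_na(spikes$conserved, FALSE)
  }
  n_sp <- nrow(spikes)
  n_var <- n_bg + n_sp
  bases <- c("A", "C", "G", "T")

  chrom <- sort(sample(1:22, n_var, replace = TRUE))
  pos <- integer(n_var)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos[i] <- sort(sample.int(5e7, length(i)))
  }
  ref <- sample(bases, n_var, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  chrom <- as.character(chrom)
  ids <- variant_id_string(chrom, pos, ref, alt)
  spike_rows <- if (n_sp > 0) sample.int(n_var, n_sp) else integer()
  is_spike <- seq_len(n_var) %in% spike_rows

  af <- runif(n_var, config$background_af_range[1], config$background_af_range[2])
  geno <- hwe_genotypes(af, n_s)
  colnames(geno) <- samples
  # spikes are private: wipe the background genotypes on spike rows
  geno[spike_rows, ] <- 0L
  if (n_sp > 0) {
    geno[cbind(spike_rows, match(spikes$sample, samples))] <-
      as.integer(spikes$zygosity)
  }

  # depths: NB total depth, binomial alt depth by zygosity; a called
  # carrier always has at least one supporting read
  dp <- matrix(pmax(1L, rnbinom(n_var * n_s, mu = config$depth_mean,
                                size = config$depth_size)),
               nrow = n_var)
  p_alt <- matrix(c(0, 0.5, 1)[geno + 1L], nrow = n_var)
  ad <- matrix(rbinom(n_var * n_s, as.vector(dp), as.vector(p_alt)),
               nrow = n_var)
  ad[geno > 0L] <- pmax(1L, ad[geno > 0L])

  gt_str <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow = n_var)
  cells <- matrix(paste0(gt_str, ":", dp, ":", dp - ad, ",", ad),
                  nrow = n_var)
  qual <- round(runif(n_var, 50, 3000), 1)
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           paste(samples, collapse = "\t")),
    paste(chrom, pos, ".", ref, alt, qual, "PASS", ".", "GT:DP:AD",
          apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  )

  # ---- annotation table -----------------------------------------------------
  bg_type <- sample(c("synonymous", "missense", "intronic"), n_var,
                    replace = TRUE, prob = c(0.35, 0.25, 0.40))
  gene_pool <- sprintf("GENE%03d", sample.int(300, n_var, replace = TRUE))
  ann <- tibble(
    VariantID = ids,
    Gene = gene_pool,
    TranscriptID = sprintf("NM_%06d.1", seq_len(n_var)),
    TranscriptLength = sample(1000:6000, n_var, replace = TRUE),
    CodingEffect = dplyr::case_when(bg_type == "synonymous" ~ "synonymous",
                                    bg_type == "missense" ~ "missense",
                                    TRUE ~ NA_character_),
    VarLocation = ifelse(bg_type == "intronic", "intron", "exon"),
    rsID = sprintf("rs%07d", sample.int(9999999, n_var)),
    rsValidation = 2L,
    rsClinicalSignificance = NA_character_,
    rsMAF = round(af, 4),
    DistNearestSS = ifelse(bg_type == "intronic",
                           sample(30:5000, n_var, replace = TRUE), NA),
    NearestSS = ifelse(bg_type == "intronic",
                       sample(c("donor", "acceptor"), n_var, replace = TRUE),
                       NA),
    SiftPred = ifelse(bg_type == "missense", "Tolerated", NA),
    PPH2pred = ifelse(bg_type == "missense", "neutral", NA),
    PhastCons = round(runif(n_var, 0, 0.9), 3),
    deltaMESscore = NA_real_,
    deltaNNSscore = NA_real_,
    deltaSSFscore = NA_real_
  )
  truth <- NULL
  if (n_sp > 0) {
    for (k in seq_len(n_sp)) {
      i <- spike_rows[k]
      f <- spike_category_fields(spikes$category[k], spikes$conserved[k])
      ann$Gene[i] <- if (!is.na(spikes$gene[k])) spikes$gene[k]
                     else sprintf("SPIKE%02d", k)
      ann$CodingEffect[i] <- f$coding_effect %||% NA_character_
      ann$VarLocation[i] <- f$var_location
      ann$rsID[i] <- NA_character_
      ann$rsValidation[i] <- NA_integer_
      ann$rsClinicalSignificance[i] <- f$rs_clinical_significance %||% NA_character_
      ann$rsMAF[i] <- NA_real_
      ann$DistNearestSS[i] <- f$dist_nearest_ss %||% NA_real_
      ann$NearestSS[i] <- f$nearest_ss %||% NA_character_
      ann$SiftPred[i] <- NA_character_
      ann$PPH2pred[i] <- NA_character_
      ann$PhastCons[i] <- if (spikes$conserved[k]) 0.99 else 0.5
      if (!is.null(f$mes_delta)) {
        ann$deltaMESscore[i] <- f$mes_delta
        ann$deltaNNSscore[i] <- f$nns_delta
        ann$deltaSSFscore[i] <- f$ssf_delta
      }
    }
    truth <- tibble(variant_id = ids[spike_rows],
                    sample_id = spikes$sample,
                    category = spikes$category,
                    zygosity = as.integer(spikes$zygosity),
                    gene = ann$Gene[spike_rows],
                    expected_score = map_int(seq_len(n_sp), function(k) {
                      spike_category_fields(spikes$category[k],
                                            spikes$conserved[k])$expected
                    }))
  } else {
    truth <- tibble(variant_id = character(), sample_id = character(),
                    category = character(), zygosity = integer(),
                    gene = character(), expected_score = integer())
  }

  out <- list(vcf = vcf, annotation_table = ann, truth = truth,
              samples = samples)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$vcf_path <- file.path(dir, "cohort.vcf")
    out$annotation_path <- file.path(dir, "annotations.tsv")
    out$truth_path <- file.path(dir, "truth.tsv")
    writeLines(out$vcf, out$vcf_path)
    readr::write_tsv(ann, out$annotation_path, progress = FALSE)
    readr::write_tsv(truth, out$truth_path, progress = FALSE)
  }
  out
}

#' Trio fixture for inheritance-pattern analysis
#'
#' A three-sample cohort (father, proband, mother) with background
#' polymorphisms plus one planted variant whose family barcode — in the
#' order father, proband, mother — equals the requested pattern: `"121"`
#' (homozygous proband, heterozygous parents; the consanguineous recessive
#' case) or `"010"` (candidate de novo heterozygous variant in the
#' proband).
#'
#' @param pattern `"121"` or `"010"`.
#' @param seed Integer seed.
#' @param n_background_variants Background pool size.
#' @param dir Optional output directory (see [simulate_cohort()]).
#' @return As [simulate_cohort()], plus `family` (the ordered trio sample
#'   ids) and `planted_variant_id`.
#' @export
trio_fixture <- function(pattern = c("121", "010"), seed = 1L,
                         n_background_variants = 50L, dir = NULL) {
  pattern <- match.arg(pattern)
  zygs <- as.integer(strsplit(pattern, "")[[1]])
  trio <- sim_sample_ids(3L) # father, proband, mother (lexicographic)
  cfg <- simulation_config(
    n_samples = 3L, n_background_variants = n_background_variants,
    spikes = tibble(sample = trio[2], category = "nonsense",
                    zygosity = max(zygs), gene = "TRIOGENE"),
    seed = seed)
  out <- simulate_cohort(cfg, dir = NULL)
  # rewrite the planted variant's genotypes to the requested trio pattern
  planted <- out$truth$variant_id[1]
  family <- trio
  hdr_i <- grep("^#CHROM", out$vcf)
  body <- out$vcf[-seq_len(hdr_i)]
  key <- strsplit(planted, "_", fixed = TRUE)[[1]]
  rec_i <- which(startsWith(body, paste0(key[1], "\t", key[2], "\t")))[1]
  fields <- strsplit(body[rec_i], "\t", fixed = TRUE)[[1]]
  gt_of <- c("0/0", "0/1", "1/1")
  for (j in seq_along(family)) {
    cell_j <- strsplit(fields[9 + j], ":", fixed = TRUE)[[1]]
    dp <- as.integer(cell_j[2])
    adv <- c(0L, max(1L, as.integer(round(dp * 0.5))), dp)[zygs[j] + 1L]
    fields[9 + j] <- paste0(gt_of[zygs[j] + 1L], ":", dp, ":",
                            dp - adv, ",", adv)
  }
  body[rec_i] <- paste(fields, collapse = "\t")
  out$vcf <- c(out$vcf[seq_len(hdr_i)], body)
  out$family <- setNames(trio, c("father", "proband", "mother"))
  out$planted_variant_id <- planted
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$vcf_path <- file.path(dir, "trio.vcf")
    out$annotation_path <- file.path(dir, "annotations.tsv")
    out$truth_path <- file.path(dir, "truth.tsv")
    writeLines(out$vcf, out$vcf_path)
    readr::write_tsv(out$annotation_table, out$annotation_path, progress = FALSE)
    readr::write_tsv(out$truth, out$truth_path, progress = FALSE)
  }
  out
}
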