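# Internal helpers shared across modules.

# Natural (human) ordering for chromosome labels: 1..22 before X, Y, MT,
# "chr" prefixes untouched. Returns an integer rank usable in arrange().
chrom_rank <- function(chrom) {
  lev <- stringr::str_sort(unique(as.character(chrom)), numeric = TRUE)
  match(as.character(chrom), lev)
}

# Canonical variant identifier: <chrom>_<pos>_<ref>_<alt>.
variant_id_string <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = "_")
}

# Deterministic ordering of variant keys (chrom natural, then pos/ref/alt).
arrange_variants <- function(df) {
  dplyr::arrange(df, chrom_rank(.data$chrom), .data$pos, .data$ref, .data$alt)
}

# Treat NA as a fallback value in vectorized comparisons.
na_false <- function(x) !is.na(x) & x

# paste an NA-able numeric for report cells
cell <- function(x) {
  out <- as.character(x)
  out[is.na(x)] <- ""
  out
}

assert_df_has <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
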