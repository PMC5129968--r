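# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Canonical site key: one string per candidate variant.
site_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Natural-ish chromosome ordering: chr1..chr22, chrX, chrY, then others.
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(core))
  rank <- ifelse(!is.na(num), num,
                 ifelse(core == "X", 23L, ifelse(core == "Y", 24L, 25L)))
  rank
}

# Order a variant table by (chrom, pos, ref, alt).
order_sites <- function(df) {
  df[order(chrom_rank(df$chrom), df$chrom, df$pos, df$ref, df$alt), ,
     drop = FALSE]
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop_invalid("`%s` must lie in [0, 1]", name)
  }
  invisible(x)
}

check_count <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < as.integer(positive)) ||
      any(x != floor(x))) {
    stop_invalid("`%s` must be a %s integer", name,
                 if (positive) "positive" else "non-negative")
  }
  invisible(x)
}

# Interval overlap length for 0-based half-open intervals.
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}
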