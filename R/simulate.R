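# Synthetic multiregion tumor generator.
#
# Emulates what a mutation-calling pipeline sees for one case profiled with
# several regional biopsies plus a matched normal: per-region call sets,
# per-site read evidence, microsatellite repeat-length read histograms and
# binned read-depth tracks -- together with the ground truth that produced
# them, so every downstream stage can be tested for recovery.

#' Configuration for a simulated multiregion case
#'
#' Defaults emulate a three-biopsy exome design: three regions, tumor cell
#' purity 0.7, mean coverage 100x. Mutation architecture defaults to 500
#' trunk (public), 200 branch (shared) and 300 region-private mutations.
#' Unstable microsatellites default to clonal deletion slippage: at purity
#' 0.7 a clonally slipped locus shifts ~70% of tumor-sample reads, by -2
#' repeat units.
#'
#' @param n_regions number of regional biopsies (>= 1).
#' @param n_trunk,n_branch,n_private mutation counts per spatial category.
#' @param purity tumor cell fraction per region, recycled to `n_regions`.
#' @param mean_depth mean sequencing depth (Poisson mean) at mutation sites
#'   and microsatellite loci.
#' @param seq_error per-base sequencing error rate.
#' @param dropout per-region probability that a truly present mutation is
#'   missed by the caller (its read evidence remains); creates rescue cases.
#' @param n_microsat number of coding microsatellite loci.
#' @param n_msi_loci number of truly unstable loci (<= `n_microsat`).
#' @param slip_fraction fraction of tumor reads shifted at unstable loci.
#' @param slip_shift signed repeat-unit change of slipped reads.
#' @param n_bins number of read-depth bins.
#' @param segment_spec list of `list(start, end, log2)` giving true
#'   copy-number segments over bin indices (1-based, inclusive); uncovered
#'   bins are copy-neutral (log2 = 0). Ranges must be disjoint.
#' @param gc_bias_amp amplitude of the smooth multiplicative GC bias.
#' @param seed integer seed; the whole case is a deterministic function of
#'   the config including the seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_regions = 3L,
                       n_trunk = 500L, n_branch = 200L, n_private = 300L,
                       purity = 0.7,
                       mean_depth = 100,
                       seq_error = 0.001,
                       dropout = 0,
                       n_microsat = 1000L,
                       n_msi_loci = 20L,
                       slip_fraction = 0.7,
                       slip_shift = -2L,
                       n_bins = 300L,
                       segment_spec = list(list(start = 101L, end = 150L, log2 = 0.58),
                                           list(start = 201L, end = 260L, log2 = -1)),
                       gc_bias_amp = 0.3,
                       seed = 1L) {
  check_count(n_regions, "n_regions", positive = TRUE)
  check_count(n_trunk, "n_trunk"); check_count(n_branch, "n_branch")
  check_count(n_private, "n_private")
  purity <- rep_len(purity, n_regions)
  check_fraction(purity, "purity")
  if (!is.numeric(mean_depth) || mean_depth <= 0) {
    stop_invalid("`mean_depth` must be > 0")
  }
  check_fraction(seq_error, "seq_error")
  check_fraction(dropout, "dropout")
  check_count(n_microsat, "n_microsat"); check_count(n_msi_loci, "n_msi_loci")
  if (n_msi_loci > n_microsat) {
    stop_invalid("`n_msi_loci` (%d) must not exceed `n_microsat` (%d)",
                 n_msi_loci, n_microsat)
  }
  check_fraction(slip_fraction, "slip_fraction")
  if (slip_shift != floor(slip_shift)) stop_invalid("`slip_shift` must be an integer")
  check_count(n_bins, "n_bins", positive = TRUE)
  validate_segment_spec(segment_spec, n_bins)
  if (!is.numeric(gc_bias_amp) || gc_bias_amp < 0 || gc_bias_amp >= 1) {
    stop_invalid("`gc_bias_amp` must lie in [0, 1)")
  }
  check_count(seed, "seed")
  structure(list(
    n_regions = as.integer(n_regions),
    n_trunk = as.integer(n_trunk), n_branch = as.integer(n_branch),
    n_private = as.integer(n_private),
    purity = purity, mean_depth = mean_depth, seq_error = seq_error,
    dropout = dropout,
    n_microsat = as.integer(n_microsat), n_msi_loci = as.integer(n_msi_loci),
    slip_fraction = slip_fraction, slip_shift = as.integer(slip_shift),
    n_bins = as.integer(n_bins), segment_spec = segment_spec,
    gc_bias_amp = gc_bias_amp, seed = as.integer(seed)
  ), class = "sim_config")
}

validate_segment_spec <- function(segment_spec, n_bins) {
  if (length(segment_spec) == 0L) return(invisible(segment_spec))
  rng <- t(vapply(segment_spec, function(s) {
    s <- as.list(s)
    c(as.numeric(s$start %||% s[[1]]), as.numeric(s$end %||% s[[2]]))
  }, numeric(2)))
  if (any(rng[, 1] < 1) || any(rng[, 2] > n_bins) || any(rng[, 1] > rng[, 2])) {
    stop_invalid("segment_spec ranges must satisfy 1 <= start <= end <= n_bins")
  }
  o <- order(rng[, 1])
  rng <- rng[o, , drop = FALSE]
  if (nrow(rng) > 1 && any(rng[-1, 1] <= rng[-nrow(rng), 2])) {
    stop_invalid("segment_spec ranges overlap")
  }
  invisible(segment_spec)
}

#' Simulate alt/ref read counts at one site
#'
#' Reads supporting the variant are binomial with success probability
#' `vaf * (1 - seq_error) + (1 - vaf) * seq_error / 3`: a true mutant read is
#' miscalled away with probability `seq_error`, and a wild-type read is
#' miscalled to this specific alternate base with probability `seq_error / 3`.
#'
#' @param vaf variant allele fraction(s) in \[0, 1\].
#' @param depth total read depth(s) (>= 0); recycled against `vaf`.
#' @param seq_error per-base sequencing error rate.
#' @return a data.frame with columns `alt` and `ref`; `alt + ref == depth`.
#' @export
simulate_read_counts <- function(vaf, depth, seq_error = 0) {
  check_fraction(vaf, "vaf")
  check_count(depth, "depth")
  check_fraction(seq_error, "seq_error")
  n <- max(length(vaf), length(depth))
  vaf <- rep_len(vaf, n); depth <- rep_len(depth, n)
  p <- vaf * (1 - seq_error) + (1 - vaf) * seq_error / 3
  alt <- rbinom(n, size = depth, prob = p)
  data.frame(alt = alt, ref = depth - alt)
}

#' Symmetric triangular stutter profile around a reference repeat length
#'
#' The default null model for microsatellite repeat-length read
#' distributions: mass proportional to `half_width + 1 - |offset|` over
#' `ref_len +/- half_width`.
#'
#' @param ref_len reference repeat length (units).
#' @param half_width support half-width in repeat units.
#' @return named numeric probability vector over integer lengths.
#' @export
triangular_profile <- function(ref_len, half_width = 2L) {
  check_count(ref_len, "ref_len", positive = TRUE)
  check_count(half_width, "half_width")
  off <- seq.int(-half_width, half_width)
  w <- half_width + 1 - abs(off)
  p <- w / sum(w)
  names(p) <- ref_len + off
  p
}

#' Simulate tumor and normal repeat-length histograms for one microsatellite
#'
#' The normal histogram is a multinomial draw from `null_profile`. The tumor
#' histogram is drawn from the same law at a stable locus, and at an unstable
#' locus from the mixture `(1 - slip_fraction) * null + slip_fraction *
#' shift(null, slip_shift)`.
#'
#' @param null_profile named probability vector over integer repeat lengths
#'   (names are lengths); must sum to 1.
#' @param is_msi is the locus truly unstable?
#' @param slip_fraction fraction of tumor reads drawn from the shifted law.
#' @param slip_shift signed shift in repeat units applied to slipped reads.
#' @param n_reads reads to draw per sample (tumor and normal may differ;
#'   length-2 vector allowed as `c(tumor, normal)`).
#' @return list with named count vectors `tumor` and `normal`.
#' @export
simulate_microsat_locus <- function(null_profile, is_msi = FALSE,
                                    slip_fraction = 0.7, slip_shift = -2L,
                                    n_reads = 100L) {
  if (length(null_profile) == 0L || is.null(names(null_profile))) {
    stop_invalid("`null_profile` must be a non-empty named probability vector")
  }
  if (abs(sum(null_profile) - 1) > 1e-8) {
    stop_invalid("`null_profile` must sum to 1")
  }
  check_fraction(slip_fraction, "slip_fraction")
  n_reads <- rep_len(n_reads, 2L)
  check_count(n_reads, "n_reads", positive = TRUE)
  lens <- as.integer(names(null_profile))
  tumor_law <- null_profile
  tumor_lens <- lens
  if (isTRUE(is_msi) && slip_fraction > 0) {
    shifted_lens <- lens + as.integer(slip_shift)
    support <- sort(unique(c(lens, shifted_lens)))
    base <- shifted <- setNames(numeric(length(support)), support)
    base[as.character(lens)] <- null_profile
    shifted[as.character(shifted_lens)] <- null_profile
    tumor_law <- (1 - slip_fraction) * base + slip_fraction * shifted
    tumor_lens <- support
  }
  draw <- function(law, lens, n) {
    cnt <- as.vector(rmultinom(1, size = n, prob = law))
    setNames(cnt, lens)
  }
  list(tumor = draw(tumor_law, tumor_lens, n_reads[1]),
       normal = draw(null_profile, lens, n_reads[2]))
}

gc_bias_curve <- function(gc, amp) 1 + amp * sin(2 * pi * gc)

#' Simulate a binned tumor/normal read-depth track
#'
#' Per bin, depths are Poisson: the tumor mean is `mean_depth * 2^log2 *
#' (1 + gc_bias_amp * sin(2 pi gc))` with `log2` the true segment state;
#' the matched normal mean is `mean_depth * (1 + gc_bias_amp/2 *
#' sin(2 pi gc))`. GC bias is library-specific -- the two libraries get
#' different amplitudes -- so it does not cancel in the depth ratio, which
#' is what makes GC correction of the ratio necessary in the first place.
#'
#' @param config a [sim_config()]; uses `n_bins`, `mean_depth`,
#'   `segment_spec` and `gc_bias_amp`. Does not touch the RNG seed -- seed
#'   management belongs to the caller (see [simulate_case()]).
#' @param chrom chromosome label for the emitted bins.
#' @param bin_width bin width in bp (0-based half-open intervals).
#' @return data.frame with columns chrom, start, end, gc, tumor_depth,
#'   normal_depth, plus the hidden truth column `true_log2`.
#' @export
simulate_depth_profile <- function(config, chrom = "chr1", bin_width = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_bins
  true_log2 <- numeric(n)
  for (s in config$segment_spec) {
    s <- as.list(s)
    true_log2[seq.int(s$start %||% s[[1]], s$end %||% s[[2]])] <-
      as.numeric(s$log2 %||% s[[3]])
  }
  gc <- runif(n, 0.3, 0.7)
  normal <- rpois(n, config$mean_depth * gc_bias_curve(gc, config$gc_bias_amp / 2))
  tumor <- rpois(n, config$mean_depth * 2^true_log2 *
                   gc_bias_curve(gc, config$gc_bias_amp))
  data.frame(chrom = chrom,
             start = (seq_len(n) - 1L) * bin_width,
             end = seq_len(n) * bin_width,
             gc = gc, tumor_depth = tumor, normal_depth = normal,
             true_log2 = true_log2)
}

sim_bases <- c("A", "C", "G", "T")

# Consequence mix for simulated SNVs/indels; chosen so the NS/S SNV ratio is
# ~2.3, in the range seen for microsatellite-stable gastric tumors.
sim_consequence_probs <- c(missense = 0.52, synonymous = 0.25,
                           nonsense = 0.04, splicing = 0.02,
                           frameshift_indel = 0.10, inframe_indel = 0.04,
                           other = 0.03)

#' Simulate a complete multiregion tumor case
#'
#' Generates, under a single seeded RNG stream, the full set of tables a
#' call-level pipeline consumes: per-region mutation call sets, per-site
#' read evidence across all regions, microsatellite repeat-length histograms
#' for every tumor region and the matched normal, and per-region read-depth
#' tracks -- together with the ground truth (`$truth`).
#'
#' Trunk mutations are carried by every region, branch mutations by a proper
#' subset of >= 2 regions, private mutations by exactly one. Carried
#' mutations have VAF `purity / 2` (heterozygous, copy-neutral); a carried
#' mutation is emitted in a region's call set unless lost to caller
#' `dropout`, but its read evidence is always present.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_case`: list with elements `regions`,
#'   `calls`, `evidence`, `microsat`, `depth` (list of per-region bin
#'   tables), `truth` and `config`.
#' @export
simulate_case <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  R <- config$n_regions
  regions <- paste0("T", seq_len(R))
  n_mut <- config$n_trunk + config$n_branch + config$n_private
  category <- rep(c("public", "shared", "private"),
                  c(config$n_trunk, config$n_branch, config$n_private))
  if (R == 1L) category <- rep("public", n_mut)
  if (R == 2L && config$n_branch > 0) {
    stop_invalid("branch (shared) mutations need >= 3 regions")
  }

  # Unique sites.
  chrom <- paste0("chr", sample.int(22L, n_mut, replace = TRUE))
  pos <- sample.int(1e8L, n_mut)
  key <- paste(chrom, pos)
  while (anyDuplicated(key)) {
    dup <- duplicated(key)
    pos[dup] <- sample.int(1e8L, sum(dup))
    key <- paste(chrom, pos)
  }
  consequence <- sample(names(sim_consequence_probs), n_mut, replace = TRUE,
                        prob = sim_consequence_probs)
  is_indel <- consequence %in% c("frameshift_indel", "inframe_indel")
  ref <- character(n_mut); alt <- character(n_mut)
  snv_ref <- sample(sim_bases, n_mut, replace = TRUE)
  snv_alt <- vapply(snv_ref, function(b) sample(setdiff(sim_bases, b), 1L), "")
  ref[!is_indel] <- snv_ref[!is_indel]
  alt[!is_indel] <- snv_alt[!is_indel]
  if (any(is_indel)) {
    ins <- runif(sum(is_indel)) < 0.5
    tail1 <- sample(sim_bases, sum(is_indel), replace = TRUE)
    anchor <- snv_ref[is_indel]
    ref[is_indel] <- ifelse(ins, anchor, paste0(anchor, tail1))
    alt[is_indel] <- ifelse(ins, paste0(anchor, tail1), anchor)
  }
  gene <- sprintf("GENE%04d", sample.int(5000L, n_mut, replace = TRUE))
  protein_change <- ifelse(consequence %in% c("synonymous", "other", "splicing"),
                           "", sprintf("p.X%dY", sample.int(2000L, n_mut,
                                                            replace = TRUE)))

  # Region assignment.
  carried <- matrix(FALSE, n_mut, R, dimnames = list(NULL, regions))
  carried[category == "public", ] <- TRUE
  if (any(category == "shared")) {
    for (i in which(category == "shared")) {
      k <- if (R <= 3L) 2L else sample(2:(R - 1L), 1L)
      carried[i, sample.int(R, k)] <- TRUE
    }
  }
  if (any(category == "private")) {
    idx <- which(category == "private")
    carried[cbind(idx, sample.int(R, length(idx), replace = TRUE))] <- TRUE
  }

  # Read evidence: all sites x all regions.
  vaf <- sweep(carried * 1, 2, config$purity / 2, "*")
  depth <- matrix(rpois(n_mut * R, config$mean_depth), n_mut, R)
  rc <- simulate_read_counts(as.vector(vaf), as.vector(depth),
                             config$seq_error)
  alt_mat <- matrix(rc$alt, n_mut, R)
  evidence <- data.frame(
    chrom = rep(chrom, R), pos = rep(pos, R),
    ref = rep(ref, R), alt = rep(alt, R),
    region = rep(regions, each = n_mut),
    alt_count = as.vector(alt_mat),
    ref_count = as.vector(depth - alt_mat))

  # Per-region call sets: carried, supported by >= 1 read, not dropped out.
  dropped <- matrix(runif(n_mut * R) < config$dropout, n_mut, R)
  called <- carried & !dropped & alt_mat >= 1L
  calls <- do.call(rbind, lapply(seq_len(R), function(r) {
    i <- which(called[, r])
    data.frame(chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alt[i],
               gene = gene[i], protein_change = protein_change[i],
               consequence = consequence[i], region = regions[r])
  }))

  # Microsatellites.
  ms_id <- sprintf("MS%05d", seq_len(config$n_microsat))
  ref_len <- if (config$n_microsat) {
    sample(10:30, config$n_microsat, replace = TRUE)
  } else integer()
  msi_ids <- if (config$n_msi_loci) {
    sort(sample(ms_id, config$n_msi_loci))
  } else character()
  microsat <- NULL
  if (config$n_microsat > 0L) {
    rows <- vector("list", config$n_microsat)
    for (j in seq_len(config$n_microsat)) {
      prof <- triangular_profile(ref_len[j])
      is_msi <- ms_id[j] %in% msi_ids
      n_norm <- rpois(1L, config$mean_depth) + 1L
      normal <- simulate_microsat_locus(prof, FALSE,
                                        n_reads = c(1L, n_norm))$normal
      per_sample <- list(data.frame(locus_id = ms_id[j], sample = "normal",
                                    length = as.integer(names(normal)),
                                    read_count = as.vector(normal)))
      for (r in regions) {
        n_t <- rpois(1L, config$mean_depth) + 1L
        tum <- simulate_microsat_locus(prof, is_msi, config$slip_fraction,
                                       config$slip_shift,
                                       n_reads = c(n_t, 1L))$tumor
        per_sample[[length(per_sample) + 1L]] <-
          data.frame(locus_id = ms_id[j], sample = paste0("tumor:", r),
                     length = as.integer(names(tum)),
                     read_count = as.vector(tum))
      }
      rows[[j]] <- do.call(rbind, per_sample)
    }
    microsat <- do.call(rbind, rows)
    microsat <- microsat[microsat$read_count > 0L, , drop = FALSE]
    rownames(microsat) <- NULL
  }

  # Depth tracks: one per region (normal drawn once, shared).
  depth_tracks <- setNames(vector("list", R), regions)
  base <- simulate_depth_profile(config)
  for (r in regions) {
    trk <- base
    bias <- gc_bias_curve(trk$gc, config$gc_bias_amp)
    trk$tumor_depth <- rpois(nrow(trk),
                             config$mean_depth * 2^trk$true_log2 * bias)
    depth_tracks[[r]] <- trk
  }

  truth <- list(
    mutations = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                           gene = gene, consequence = consequence,
                           category = category,
                           regions = apply(carried, 1, function(z)
                             paste(regions[z], collapse = ","))),
    msi_loci = msi_ids,
    segments = config$segment_spec)

  structure(list(regions = regions, calls = calls, evidence = evidence,
                 microsat = microsat, depth = depth_tracks,
                 truth = truth, config = config),
            class = "sim_case")
}

#' @exportS3Method print sim_case
print.sim_case <- function(x, ...) {
  cat(sprintf("Simulated multiregion case: %d regions, %d mutations (%s)\n",
              length(x$regions), nrow(x$truth$mutations),
              paste(sprintf("%d %s", table(x$truth$mutations$category)[c("public", "shared", "private")],
                            c("public", "shared", "private")), collapse = ", ")))
  cat(sprintf("  microsatellites: %d (%d unstable); depth bins: %d/region\n",
              x$config$n_microsat, x$config$n_msi_loci, x$config$n_bins))
  invisible(x)
}

# ---- writers ---------------------------------------------------------------

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated case to a directory of plain-text tables
#'
#' Emits per-region minimal VCF 4.2 call sets, a MAF-like calls table, the
#' evidence, microsatellite-histogram and per-region depth-bin TSVs.
#'
#' @param case a `sim_case`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_case <- function(case, dir) {
  stopifnot(inherits(case, "sim_case"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in case$regions) {
    calls_r <- case$calls[case$calls$region == r, , drop = FALSE]
    ev_r <- case$evidence[case$evidence$region == r, , drop = FALSE]
    write_region_vcf(calls_r, file.path(dir, paste0("calls_", r, ".vcf")),
                     sample_id = r, evidence = ev_r)
    write_tsv(case$depth[[r]][, c("chrom", "start", "end", "gc",
                                  "tumor_depth", "normal_depth")],
              file.path(dir, paste0("depth_", r, ".tsv")))
  }
  write_maf(case$calls, file.path(dir, "calls.maf.tsv"))
  write_tsv(case$evidence, file.path(dir, "evidence.tsv"))
  if (!is.null(case$microsat)) {
    write_tsv(case$microsat, file.path(dir, "microsat.tsv"))
  }
  invisible(dir)
}
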