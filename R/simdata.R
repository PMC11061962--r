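#' Configure a synthetic two-group diploid dataset
#'
#' Defines a Balding-Nichols background model with optional planted sweeps.
#' Each group's per-site allele frequency is drawn around a shared ancestral
#' frequency `p` as `Beta(p(1-F)/F, (1-p)(1-F)/F)`, which has mean `p` and
#' variance `F p (1-p)`. Inside a sweep interval the target group's frequency
#' is redrawn with the (larger) sweep divergence `f_sweep` and then pushed
#' deterministically toward the nearer allele-frequency boundary, which
#' jointly elevates between-group differentiation and depresses within-group
#' diversity -- the two signals the genome scan keys on.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param snp_density expected polymorphic sites per bp (default `0.005`,
#'   i.e. ~50,000 sites on a 10 Mb chromosome).
#' @param n_groups number of population groups (>= 2).
#' @param n_per_group diploid individuals per group.
#' @param f_bg background (neutral) divergence `F`; `0` is allowed as the
#'   exact no-drift limit where every group frequency equals the ancestral
#'   frequency. Must satisfy `0 <= f_bg < 1`.
#' @param ancestral_range range of the Uniform ancestral-frequency draw.
#' @param sweeps `NULL` or a data.frame of [sweep_spec()] rows.
#' @param missing_rate per-genotype missingness probability.
#' @param info_fail_rate fraction of sites given exactly one filter-failing
#'   INFO metric (all other sites carry passing constants).
#' @param seed integer seed; fixes all generator output bit-identically.
#' @return a `sim_config` list.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 1e7),
                       snp_density = 0.005,
                       n_groups = 2L,
                       n_per_group = 25L,
                       f_bg = 0.05,
                       ancestral_range = c(0.05, 0.95),
                       sweeps = NULL,
                       missing_rate = 0,
                       info_fail_rate = 0,
                       seed = 1L) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stopf("chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0)) stopf("chromosome lengths must be positive")
  if (snp_density <= 0) stopf("snp_density must be > 0")
  if (n_groups < 2L) stopf("need at least two groups")
  if (n_per_group < 1L) stopf("need at least one individual per group")
  if (!is.finite(f_bg) || f_bg < 0 || f_bg >= 1)
    stopf("f_bg must lie in [0, 1); got %s", format(f_bg))
  if (length(ancestral_range) != 2L || ancestral_range[1] <= 0 ||
      ancestral_range[2] >= 1 || diff(ancestral_range) < 0)
    stopf("ancestral_range must be an increasing pair inside (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stopf("bad missing_rate")
  if (info_fail_rate < 0 || info_fail_rate > 1) stopf("bad info_fail_rate")
  if (!is.null(sweeps)) {
    sweeps <- data.table::as.data.table(sweeps)
    need <- c("chrom", "start", "end", "target_group", "f_sweep", "s")
    if (!all(need %in% names(sweeps))) stopf("sweeps lacks required columns")
    if (any(!sweeps$chrom %in% names(chrom_lengths)))
      stopf("sweep on unknown chromosome")
    if (any(sweeps$end <= sweeps$start)) stopf("sweep end must exceed start")
    if (any(sweeps$start < 0) ||
        any(sweeps$end > chrom_lengths[sweeps$chrom]))
      stopf("sweep interval outside its chromosome")
    if (any(sweeps$f_sweep <= 0 | sweeps$f_sweep >= 1))
      stopf("f_sweep must lie in (0, 1)")
    if (any(sweeps$s < 0 | sweeps$s > 1)) stopf("s must lie in [0, 1]")
    if (any(sweeps$target_group < 1L | sweeps$target_group > n_groups))
      stopf("sweep target_group out of range")
  }
  structure(list(
    chrom_lengths = chrom_lengths,
    snp_density = snp_density,
    n_groups = as.integer(n_groups),
    n_per_group = as.integer(n_per_group),
    group_names = paste0("pop", seq_len(n_groups)),
    f_bg = f_bg,
    ancestral_range = ancestral_range,
    sweeps = sweeps,
    missing_rate = missing_rate,
    info_fail_rate = info_fail_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Specify one planted sweep
#'
#' @param chrom chromosome name.
#' @param start,end sweep interval, 0-based half-open bp.
#' @param target_group 1-based index of the swept group.
#' @param f_sweep divergence used for the target group inside the sweep;
#'   should exceed the background `f_bg`.
#' @param s push strength in `[0, 1]`: a drawn frequency `p` becomes
#'   `p (1 - s)` when `p < 0.5` and `p + s (1 - p)` otherwise.
#' @return one-row data.table.
#' @export
sweep_spec <- function(chrom, start, end, target_group = 1L,
                       f_sweep = 0.6, s = 0.9) {
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(end),
                         target_group = as.integer(target_group),
                         f_sweep = f_sweep, s = s)
}

# Balding-Nichols draw; f = 0 collapses to the ancestral frequency.
rbeta_bn <- function(p, f) {
  if (f == 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

push_boundary <- function(p, s) ifelse(p < 0.5, p * (1 - s), p + s * (1 - p))

#' Simulate per-site allele frequencies
#'
#' Draws site positions uniformly (deduplicated, sorted) on each chromosome,
#' an ancestral frequency per site, and one Balding-Nichols frequency per
#' group. Sweep intervals override the target group's draw as described in
#' [sim_config()]. Also assigns random distinct REF/ALT bases per site.
#'
#' @param config a [sim_config()].
#' @return data.table with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `p_anc` and one frequency column `p_<group>` per group.
#' @export
simulate_site_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    tabs <- lapply(names(config$chrom_lengths), function(ch) {
      len <- config$chrom_lengths[[ch]]
      n_target <- stats::rpois(1L, config$snp_density * len)
      pos <- sort(unique(sample.int(len, min(n_target, len), replace = TRUE)))
      n <- length(pos)
      bases <- c("A", "C", "G", "T")
      ref <- sample(bases, n, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
      p_anc <- stats::runif(n, config$ancestral_range[1],
                            config$ancestral_range[2])
      dt <- data.table::data.table(chrom = ch, pos = pos, ref = ref,
                                   alt = alt, p_anc = p_anc)
      for (g in seq_len(config$n_groups))
        dt[[paste0("p_", config$group_names[g])]] <-
          rbeta_bn(p_anc, config$f_bg)
      if (!is.null(config$sweeps)) {
        sw <- config$sweeps[config$sweeps$chrom == ch, ]
        for (k in seq_len(nrow(sw))) {
          # site at POS occupies 0-based base POS-1
          idx <- which(dt$pos - 1L >= sw$start[k] & dt$pos - 1L < sw$end[k])
          if (!length(idx)) next
          gcol <- paste0("p_", config$group_names[sw$target_group[k]])
          drawn <- rbeta_bn(dt$p_anc[idx], sw$f_sweep[k])
          dt[[gcol]][idx] <- push_boundary(drawn, sw$s[k])
        }
      }
      dt
    })
    data.table::rbindlist(tabs)
  })
}

#' Sample diploid genotype dosages
#'
#' Each individual's dosage at a site is an independent `Binomial(2, p_g)`
#' draw from its group's frequency; optional missingness replaces dosages
#' with `NA` uniformly at random.
#'
#' @param freqs output of [simulate_site_frequencies()].
#' @param config the matching [sim_config()].
#' @return integer matrix (sites x samples) with dosages in `{0, 1, 2}` and
#'   sample names `<group>_<index>`.
#' @export
sample_genotypes <- function(freqs, config) {
  stopifnot(inherits(config, "sim_config"))
  n_sites <- nrow(freqs)
  samples <- unlist(lapply(config$group_names, function(g)
    sprintf("%s_%02d", g, seq_len(config$n_per_group))))
  withr::with_seed(config$seed + 1L, {
    cols <- lapply(config$group_names, function(g) {
      p <- freqs[[paste0("p_", g)]]
      matrix(stats::rbinom(n_sites * config$n_per_group, 2L, rep(p, config$n_per_group)),
             nrow = n_sites)
    })
    geno <- do.call(cbind, cols)
    colnames(geno) <- samples
    if (config$missing_rate > 0) {
      drop <- stats::runif(length(geno)) < config$missing_rate
      geno[drop] <- NA_integer_
    }
    geno
  })
}

# INFO metric constants. "pass" values sit comfortably inside the hard-filter
# acceptance region; each "fail" value violates exactly one SNP threshold.
.info_pass <- c(QD = 25, FS = 1, MQ = 60, SOR = 1,
                MQRankSum = 0, ReadPosRankSum = 0, InbreedingCoeff = 0.1)
.info_fail <- c(QD = 1, FS = 80, MQ = 30, SOR = 5,
                MQRankSum = -15, ReadPosRankSum = -10)

#' Write a simulated dataset to disk
#'
#' Emits a plain-text VCF v4.2 (GT genotypes, constant passing INFO metrics
#' except for a configured fraction of sites given one failing metric), a
#' two-column population map TSV, and the planted-sweep truth intervals as
#' BED (0-based half-open, with the target group name in column 4).
#'
#' @param freqs site table from [simulate_site_frequencies()].
#' @param genotypes dosage matrix from [sample_genotypes()].
#' @param config the matching [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return named list of file paths (`vcf`, `pop_map`, `truth`).
#' @export
emit_dataset <- function(freqs, genotypes, config, out_dir) {
  stopifnot(inherits(config, "sim_config"),
            nrow(freqs) == nrow(genotypes))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(freqs)

  info_vals <- matrix(rep(.info_pass, each = n), nrow = n,
                      dimnames = list(NULL, names(.info_pass)))
  withr::with_seed(config$seed + 2L, {
    fail_idx <- which(stats::runif(n) < config$info_fail_rate)
    if (length(fail_idx)) {
      which_metric <- sample(names(.info_fail), length(fail_idx),
                             replace = TRUE)
      for (i in seq_along(fail_idx))
        info_vals[fail_idx[i], which_metric[i]] <- .info_fail[[which_metric[i]]]
    }
  })
  info_str <- apply(info_vals, 1L, function(v)
    paste(sprintf("%s=%s", names(.info_pass), format(v, trim = TRUE)),
          collapse = ";"))

  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_codes[genotypes + 1L], nrow = n)
  gt[is.na(genotypes)] <- "./."

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=dsscan-simdata",
    sprintf("##contig=<ID=%s,length=%d>", names(config$chrom_lengths),
            as.integer(config$chrom_lengths)),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            names(.info_pass), names(.info_pass)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(genotypes)), collapse = "\t"))
  body <- paste(freqs$chrom, freqs$pos, ".", freqs$ref, freqs$alt, ".", ".",
                info_str, "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  vcf_path <- file.path(out_dir, "variants.vcf")
  writeLines(c(header, body), vcf_path)

  pm_path <- file.path(out_dir, "pop_map.tsv")
  grp <- sub("_[0-9]+$", "", colnames(genotypes))
  writeLines(c("sample_id\tgroup",
               paste(colnames(genotypes), grp, sep = "\t")), pm_path)

  truth_path <- file.path(out_dir, "truth.bed")
  if (is.null(config$sweeps)) {
    writeLines(character(0), truth_path)
  } else {
    writeLines(paste(config$sweeps$chrom, config$sweeps$start,
                     config$sweeps$end,
                     config$group_names[config$sweeps$target_group],
                     sep = "\t"), truth_path)
  }
  list(vcf = vcf_path, pop_map = pm_path, truth = truth_path)
}

#' Simulate and optionally write a full dataset
#'
#' Convenience wrapper running [simulate_site_frequencies()],
#' [sample_genotypes()] and, when `out_dir` is given, [emit_dataset()].
#'
#' @inheritParams emit_dataset
#' @param config a [sim_config()].
#' @return list with `freqs`, `genotypes`, `truth` (data.table of sweep
#'   intervals, possibly empty) and `files` (`NULL` unless written).
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  freqs <- simulate_site_frequencies(config)
  geno <- sample_genotypes(freqs, config)
  files <- if (!is.null(out_dir)) emit_dataset(freqs, geno, config, out_dir)
  truth <- if (is.null(config$sweeps))
    data.table::data.table(chrom = character(), start = integer(),
                           end = integer(), target_group = integer())
  else data.table::copy(config$sweeps)
  list(freqs = freqs, genotypes = geno, truth = truth, files = files)
}
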