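#' Scan parameters
#'
#' Bundles the tunables of a sweep scan. The Z|delta-pi| cutoff 3.09 is the
#' standard-normal upper quantile at one-sided tail probability 0.001
#' (`qnorm(0.999)` rounded to two decimals); the F_ST statistic is noisier
#' per window, so its cutoff is raised to 6. Both thresholds are strict:
#' a window exactly at the cutoff is not significant.
#'
#' @param window_size,step_size sliding-window geometry in bp.
#' @param k_permutations permutation replicates for the null (default 100).
#' @param zfst_cutoff,zdpi_cutoff significance cutoffs (strict `>`).
#' @param seed integer seed driving the permutation null.
#' @return a `scan_params` list.
#' @export
scan_params <- function(window_size = 40000L, step_size = 20000L,
                        k_permutations = 100L,
                        zfst_cutoff = 6, zdpi_cutoff = 3.09,
                        seed = 1L) {
  if (step_size > window_size) stopf("step_size exceeds window_size")
  if (!is.finite(zfst_cutoff) || !is.finite(zdpi_cutoff))
    stopf("cutoffs must be finite")
  structure(list(window_size = as.integer(window_size),
                 step_size = as.integer(step_size),
                 k_permutations = as.integer(k_permutations),
                 zfst_cutoff = zfst_cutoff, zdpi_cutoff = zdpi_cutoff,
                 seed = as.integer(seed)),
            class = "scan_params")
}

#' Call significant windows per statistic
#'
#' A window is a putative selective sweep for F_ST iff `z_fst > zfst_cutoff`
#' and for |delta-pi| iff `z_dpi > zdpi_cutoff` (strict inequalities; NA
#' never significant).
#'
#' @param scores a [compute_zscores()] table.
#' @param params a [scan_params()].
#' @return list of data.tables `fst` and `dpi` with the significant windows.
#' @export
call_windows <- function(scores, params = scan_params()) {
  list(fst = scores[!is.na(scores$z_fst) & scores$z_fst > params$zfst_cutoff],
       dpi = scores[!is.na(scores$z_dpi) & scores$z_dpi > params$zdpi_cutoff])
}

# Reduce a set of half-open intervals, merging only where they share >= 1 bp
# (abutting intervals with end == start stay separate); aggregates window
# counts and Z maxima through the revmap.
merge_intervals <- function(dt) {
  if (!nrow(dt)) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), n_windows = integer(),
                                  max_z_fst = numeric(), max_z_dpi = numeric()))
  }
  gr <- granges0(dt$chrom, dt$start, dt$end)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  zf <- if ("max_z_fst" %in% names(dt)) dt$max_z_fst
        else if ("z_fst" %in% names(dt)) dt$z_fst else rep(NA_real_, nrow(dt))
  zd <- if ("max_z_dpi" %in% names(dt)) dt$max_z_dpi
        else if ("z_dpi" %in% names(dt)) dt$z_dpi else rep(NA_real_, nrow(dt))
  nw <- if ("n_windows" %in% names(dt)) dt$n_windows else rep(1L, nrow(dt))
  max_or_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    n_windows = vapply(revmap, function(ix) sum(nw[ix]), 1L),
    max_z_fst = vapply(revmap, function(ix) max_or_na(zf[ix]), 1),
    max_z_dpi = vapply(revmap, function(ix) max_or_na(zd[ix]), 1))
}

#' Merge significant windows into discrete selective sweeps
#'
#' Within a chromosome, significant windows sharing at least one bp are
#' merged transitively into one DSS spanning the minimum start to the
#' maximum end. Abutting half-open intervals (`end == start`) are not
#' merged. The number of contributing windows and the per-statistic Z
#' maxima are aggregated.
#'
#' @param windows significant windows (one element of [call_windows()]).
#' @return data.table `chrom`, `start`, `end`, `n_windows`, `max_z_fst`,
#'   `max_z_dpi`, sorted and pairwise non-overlapping.
#' @export
merge_to_dss <- function(windows) {
  out <- merge_intervals(windows)
  data.table::setorder(out, chrom, start)
  out[]
}

#' Union of the per-statistic DSS calls
#'
#' The final prediction is the interval union of the F_ST-derived and
#' |delta-pi|-derived DSS lists, re-merged on >= 1 bp overlap. Each final
#' DSS carries a method flag (`"fst"`, `"dpi"` or `"both"`), and the
#' fraction of each input list overlapped by the other is reported (the two
#' statistics are largely complementary, so this is typically well below 1).
#'
#' @param dss_fst,dss_dpi per-statistic [merge_to_dss()] tables.
#' @return list with `dss` (final table, extra column `method`) and
#'   `overlap` (`fst_in_dpi`, `dpi_in_fst` fractions, NA when the
#'   corresponding input is empty).
#' @export
union_dss <- function(dss_fst, dss_dpi) {
  combined <- data.table::rbindlist(list(dss_fst, dss_dpi), fill = TRUE)
  final <- merge_intervals(combined)
  data.table::setorder(final, chrom, start)
  if (nrow(final)) {
    gr_final <- granges0(final$chrom, final$start, final$end)
    in_fst <- GenomicRanges::countOverlaps(
      gr_final, granges0(dss_fst$chrom, dss_fst$start, dss_fst$end)) > 0
    in_dpi <- GenomicRanges::countOverlaps(
      gr_final, granges0(dss_dpi$chrom, dss_dpi$start, dss_dpi$end)) > 0
    final[, method := data.table::fcase(in_fst & in_dpi, "both",
                                        in_fst, "fst",
                                        default = "dpi")]
  } else {
    final[, method := character(0)]
  }
  frac_overlapped <- function(x, y) {
    if (!nrow(x)) return(NA_real_)
    if (!nrow(y)) return(0)
    mean(GenomicRanges::countOverlaps(
      granges0(x$chrom, x$start, x$end),
      granges0(y$chrom, y$start, y$end)) > 0)
  }
  list(dss = final[],
       overlap = list(fst_in_dpi = frac_overlapped(dss_fst, dss_dpi),
                      dpi_in_fst = frac_overlapped(dss_dpi, dss_fst)))
}

#' Summarize a DSS set
#'
#' @param dss a final DSS table.
#' @param genome_size total genome size in bp (> 0).
#' @param short_threshold length (bp) below which a DSS counts as "short"
#'   (strict `<`; default 140 kb).
#' @return list: `n`, `min_length`, `median_length`, `max_length`,
#'   `frac_short`, `genome_fraction` (total DSS length / genome size).
#' @export
dss_summary <- function(dss, genome_size, short_threshold = 140000) {
  if (genome_size <= 0) stopf("genome_size must be positive")
  len <- as.numeric(dss$end - dss$start)
  list(n = nrow(dss),
       min_length = if (length(len)) min(len) else NA_real_,
       median_length = if (length(len)) stats::median(len) else NA_real_,
       max_length = if (length(len)) max(len) else NA_real_,
       frac_short = if (length(len)) mean(len < short_threshold) else NA_real_,
       genome_fraction = sum(len) / genome_size)
}

# Chromosome lengths from ##contig header lines; falls back to the largest
# observed position per chromosome.
contig_lengths <- function(meta, sites) {
  lines <- grep("^##contig=", meta, value = TRUE)
  ids <- sub('.*ID=([^,>]+).*', "\\1", lines)
  lens <- suppressWarnings(as.numeric(sub('.*length=([0-9]+).*', "\\1", lines)))
  ok <- !is.na(lens) & nzchar(ids)
  out <- stats::setNames(lens[ok], ids[ok])
  missing <- setdiff(unique(sites$chrom), names(out))
  if (length(missing)) {
    fallback <- vapply(missing, function(ch) max(sites$pos[sites$chrom == ch]),
                       1)
    warnf("no contig length in header for %s; using max position",
          paste(missing, collapse = ", "))
    out <- c(out, fallback)
  }
  out[intersect(names(out), unique(sites$chrom))]
}

#' Run one full two-group sweep comparison
#'
#' End-to-end scan: parse the VCF, apply hard filters, select bi-allelic
#' polymorphic SNPs, compute windowed F_ST / |delta-pi|, build the
#' permutation null, Z-score, threshold, merge per-statistic DSSs and union
#' them. Deterministic given `params$seed`.
#'
#' @param vcf_path multi-sample VCF.
#' @param pop_map population map (path, table or named vector); see
#'   [read_sites()].
#' @param group_a,group_b character vectors of population-map group labels;
#'   multiple labels are pooled into one side of the comparison. The two
#'   sides must be disjoint and nonempty.
#' @param params a [scan_params()].
#' @param policy a [filter_policy()].
#' @param chrom_lengths optional named vector; defaults to the VCF
#'   `##contig` header lengths.
#' @param chromosomes optional chromosome include-list for the scan.
#' @param out_dir optional directory: writes the window table, null summary,
#'   DSS BED + extended TSV, and a JSON run manifest.
#' @return list: `sites` (scan sites), `windows` (Z-scored), `null`,
#'   `significant` (per-statistic window sets), `dss_fst`, `dss_dpi`,
#'   `dss` (final, with method flags), `overlap`, `summary`, `n_windows_called`,
#'   `params`, `label`.
#' @export
run_comparison <- function(vcf_path, pop_map, group_a, group_b,
                           params = scan_params(),
                           policy = filter_policy(),
                           chrom_lengths = NULL,
                           chromosomes = NULL,
                           out_dir = NULL) {
  stopifnot(inherits(params, "scan_params"))
  if (length(intersect(group_a, group_b)))
    stopf("group_a and group_b must be disjoint")
  if (is.character(pop_map) && length(pop_map) == 1L && file.exists(pop_map))
    pop_map <- read_popmap(pop_map)
  pop_map <- data.table::as.data.table(pop_map)
  unknown <- setdiff(c(group_a, group_b), unique(pop_map$group))
  if (length(unknown))
    stopf("group label(s) not in population map: %s",
          paste(unknown, collapse = ", "))
  # pool breed-level labels into the two comparison sides
  side <- data.table::fcase(pop_map$group %in% group_a, "A",
                            pop_map$group %in% group_b, "B",
                            default = NA_character_)
  pm2 <- pop_map[!is.na(side)][, list(sample_id = sample_id)]
  pm2[, group := side[!is.na(side)]]

  sites <- read_sites(vcf_path, pm2)
  if (is.null(chrom_lengths)) {
    v_meta <- vcfR::read.vcfR(vcf_path, verbose = FALSE, nrows = 1)@meta
    chrom_lengths <- contig_lengths(v_meta, sites)
  }
  filtered <- apply_hard_filters(sites, policy)
  scan <- select_scan_sites(filtered$kept, chromosomes = chromosomes)
  windows <- make_windows(chrom_lengths[names(chrom_lengths) %in%
                                          unique(scan$chrom)],
                          params$window_size, params$step_size)
  obs <- window_stats(scan, windows, "A", "B")
  null <- build_null(scan, windows, "A", "B",
                     k = params$k_permutations, seed = params$seed)
  scored <- compute_zscores(obs, null)
  sig <- call_windows(scored, params)
  dss_fst <- merge_to_dss(sig$fst)
  dss_dpi <- merge_to_dss(sig$dpi)
  final <- union_dss(dss_fst, dss_dpi)
  summ <- dss_summary(final$dss, genome_size = sum(chrom_lengths))

  label <- sprintf("%s_vs_%s", paste(group_a, collapse = "+"),
                   paste(group_b, collapse = "+"))
  res <- list(sites = scan, windows = scored, null = null,
              significant = sig, dss_fst = dss_fst, dss_dpi = dss_dpi,
              dss = final$dss, overlap = final$overlap, summary = summ,
              n_windows_called = list(fst = nrow(sig$fst),
                                      dpi = nrow(sig$dpi)),
              params = params, label = label)
  if (!is.null(out_dir)) write_comparison(res, out_dir)
  res
}

write_comparison <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fw <- function(x, f) data.table::fwrite(x, file.path(out_dir, f), sep = "\t")
  fw(res$windows, "windows.tsv")
  fw(res$dss, "dss.tsv")
  data.table::fwrite(res$dss[, c("chrom", "start", "end")],
                     file.path(out_dir, "dss.bed"),
                     sep = "\t", col.names = FALSE)
  null_tab <- data.table::rbindlist(lapply(res$null, function(nm)
    data.table::data.table(statistic = nm$statistic, k = nm$k, seed = nm$seed,
                           mu = nm$mu, sigma = nm$sigma,
                           n_pooled = nm$n_pooled)))
  fw(null_tab, "null_summary.tsv")
  manifest <- list(label = res$label,
                   params = unclass(res$params),
                   n_scan_sites = nrow(res$sites),
                   n_windows = nrow(res$windows),
                   n_windows_called = res$n_windows_called,
                   n_dss = nrow(res$dss),
                   summary = res$summary,
                   package_version = as.character(utils::packageVersion("dsscan")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
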