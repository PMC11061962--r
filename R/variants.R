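#' Read a population map
#'
#' Two-column TSV mapping sample id to group label; a header line whose
#' first field is `sample_id` or `sample` is skipped.
#'
#' @param path TSV path.
#' @return data.table with columns `sample_id`, `group`.
#' @export
read_popmap <- function(path) {
  pm <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("sample_id", "group"),
                          colClasses = "character")
  if (nrow(pm) && pm$sample_id[1] %in% c("sample_id", "sample"))
    pm <- pm[-1L]
  if (!nrow(pm)) stopf("empty population map: %s", path)
  if (anyDuplicated(pm$sample_id)) stopf("duplicate sample ids in map")
  pm
}

# Diploid GT string -> alt-allele dosage. Phased separators are normalized;
# anything not composed of 0/1 alleles (missing, or extra ALT alleles at
# multi-allelic sites, which are excluded from the scan) becomes NA.
.gt_lookup <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)

gt_to_dosage <- function(gt) {
  gt <- chartr("|", "/", gt)
  gt <- sub(":.*$", "", gt)
  out <- .gt_lookup[gt]
  dim(out) <- dim(gt)
  dimnames(out) <- dimnames(gt)
  out
}

#' Parse a VCF into per-site, per-group summaries
#'
#' For every VCF row and every group in the population map computes the
#' number of individuals with a called genotype (`n_<g>`), the alt-allele
#' frequency among called alleles (`p_<g>`), the observed heterozygote
#' fraction (`h_<g>`), and the per-site nucleotide diversity
#' `pi = 2 c_ref c_alt / (n (n - 1))` over `n = 2 n_<g>` called alleles
#' (NA when fewer than two alleles are called). Missing genotypes are
#' excluded from all four quantities; no imputation is done.
#'
#' @param vcf_path VCF v4.x path (plain or bgzipped).
#' @param pop_map a [read_popmap()] table, a path to one, or a named
#'   character vector `sample -> group`.
#' @return data.table with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `class` (`"SNP"`/`"indel"`), `biallelic`, the seven INFO metrics
#'   (`qd`, `fs`, `mq`, `sor`, `mq_rank_sum`, `read_pos_rank_sum`,
#'   `inbreeding_coeff`; NA where absent) and the per-group summaries.
#'   The group names are attached as `attr(, "groups")`.
#' @export
read_sites <- function(vcf_path, pop_map) {
  if (is.character(pop_map) && length(pop_map) == 1L && file.exists(pop_map))
    pop_map <- read_popmap(pop_map)
  if (!is.null(names(pop_map)) && is.character(pop_map))
    pop_map <- data.table::data.table(sample_id = names(pop_map),
                                      group = unname(pop_map))
  pop_map <- data.table::as.data.table(pop_map)

  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  vcf_samples <- colnames(gt)

  unmapped <- setdiff(vcf_samples, pop_map$sample_id)
  if (length(unmapped))
    warnf("ignoring %d VCF sample(s) absent from the population map: %s",
          length(unmapped), paste(head(unmapped, 5L), collapse = ", "))
  absent <- setdiff(pop_map$sample_id, vcf_samples)
  if (length(absent))
    warnf("%d mapped sample(s) not present in the VCF", length(absent))
  pop_map <- pop_map[pop_map$sample_id %in% vcf_samples, ]
  if (!nrow(pop_map)) stopf("no VCF sample is covered by the population map")
  groups <- unique(pop_map$group)

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt_split <- strsplit(alt, ",", fixed = TRUE)
  is_snp <- nchar(ref) == 1L &
    vapply(alt_split, function(a) all(nchar(a) == 1L & a %in% c("A", "C", "G", "T")), TRUE)

  info_keys <- c(qd = "QD", fs = "FS", mq = "MQ", sor = "SOR",
                 mq_rank_sum = "MQRankSum",
                 read_pos_rank_sum = "ReadPosRankSum",
                 inbreeding_coeff = "InbreedingCoeff")
  dt <- data.table::data.table(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = ref, alt = alt,
    class = ifelse(is_snp, "SNP", "indel"),
    biallelic = lengths(alt_split) == 1L)
  for (nm in names(info_keys))
    dt[[nm]] <- suppressWarnings(
      vcfR::extract.info(v, element = info_keys[[nm]], as.numeric = TRUE))

  dos <- gt_to_dosage(gt)
  for (g in groups) {
    cols <- pop_map$sample_id[pop_map$group == g]
    d <- dos[, cols, drop = FALSE]
    if (is.null(dim(d))) d <- matrix(d, nrow = nrow(dt))
    n_called <- rowSums(!is.na(d))
    ac <- rowSums(d, na.rm = TRUE)
    nall <- 2 * n_called
    dt[[paste0("n_", g)]] <- n_called
    dt[[paste0("p_", g)]] <- ifelse(n_called > 0, ac / nall, NA_real_)
    dt[[paste0("h_", g)]] <- ifelse(n_called > 0,
                                    rowSums(d == 1L, na.rm = TRUE) / n_called,
                                    NA_real_)
    dt[[paste0("pi_", g)]] <- ifelse(nall >= 2,
                                     2 * ac * (nall - ac) / (nall * (nall - 1)),
                                     NA_real_)
  }
  data.table::setattr(dt, "groups", groups)
  dt
}

#' Hard-filter thresholds for SNPs and indels
#'
#' Defaults follow the standard GATK-style hard filters: a SNP is removed
#' when `QD < 2`, `FS > 60`, `MQ < 40`, `SOR > 3`, `MQRankSum < -12.5` or
#' `ReadPosRankSum < -8`; an indel when `QD < 2`, `FS > 200`, `SOR > 10`,
#' `InbreedingCoeff < -0.8` or `ReadPosRankSum < -20`. All inequalities are
#' strict, so a metric exactly at its threshold passes, and an absent metric
#' never triggers removal.
#'
#' @param snp,indel named numeric vectors overriding individual thresholds.
#' @return a `filter_policy` list.
#' @export
filter_policy <- function(snp = NULL, indel = NULL) {
  pol <- list(
    snp = c(qd_lt = 2, fs_gt = 60, mq_lt = 40, sor_gt = 3,
            mq_rank_sum_lt = -12.5, read_pos_rank_sum_lt = -8),
    indel = c(qd_lt = 2, fs_gt = 200, sor_gt = 10,
              inbreeding_coeff_lt = -0.8, read_pos_rank_sum_lt = -20))
  if (!is.null(snp)) pol$snp[names(snp)] <- snp
  if (!is.null(indel)) pol$indel[names(indel)] <- indel
  structure(pol, class = "filter_policy")
}

#' Apply hard filters to a site table
#'
#' Partitions the input into kept and removed sites. A site is removed iff
#' any threshold condition for its class (SNP or indel) holds; see
#' [filter_policy()].
#'
#' @param sites a [read_sites()] table.
#' @param policy a [filter_policy()].
#' @return list with data.tables `kept` and `removed` (an exhaustive,
#'   disjoint partition of the input, order preserved).
#' @export
apply_hard_filters <- function(sites, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  snp <- policy$snp
  indel <- policy$indel
  fail_snp <- lt_na_false(sites$qd, snp[["qd_lt"]]) |
    gt_na_false(sites$fs, snp[["fs_gt"]]) |
    lt_na_false(sites$mq, snp[["mq_lt"]]) |
    gt_na_false(sites$sor, snp[["sor_gt"]]) |
    lt_na_false(sites$mq_rank_sum, snp[["mq_rank_sum_lt"]]) |
    lt_na_false(sites$read_pos_rank_sum, snp[["read_pos_rank_sum_lt"]])
  fail_indel <- lt_na_false(sites$qd, indel[["qd_lt"]]) |
    gt_na_false(sites$fs, indel[["fs_gt"]]) |
    gt_na_false(sites$sor, indel[["sor_gt"]]) |
    lt_na_false(sites$inbreeding_coeff, indel[["inbreeding_coeff_lt"]]) |
    lt_na_false(sites$read_pos_rank_sum, indel[["read_pos_rank_sum_lt"]])
  removed <- ifelse(sites$class == "SNP", fail_snp, fail_indel)
  out <- list(kept = sites[!removed], removed = sites[removed])
  data.table::setattr(out$kept, "groups", attr(sites, "groups"))
  data.table::setattr(out$removed, "groups", attr(sites, "groups"))
  out
}

#' Select sites usable by the sweep scan
#'
#' Retains bi-allelic SNPs that are polymorphic across all groups combined
#' (pooled alt-allele count strictly between 0 and the pooled called allele
#' count), optionally restricted to an include-list of chromosomes.
#'
#' @param sites a (typically hard-filtered) [read_sites()] table.
#' @param chromosomes optional character vector of chromosomes to keep.
#' @return filtered data.table; warns (does not error) when empty.
#' @export
select_scan_sites <- function(sites, chromosomes = NULL) {
  groups <- attr(sites, "groups")
  if (is.null(groups)) stopf("site table lacks group attribute")
  keep <- sites$biallelic & sites$class == "SNP"
  if (!is.null(chromosomes)) keep <- keep & sites$chrom %in% chromosomes
  ac <- Reduce(`+`, lapply(groups, function(g)
    2 * sites[[paste0("n_", g)]] *
      data.table::fifelse(is.na(sites[[paste0("p_", g)]]), 0,
                          sites[[paste0("p_", g)]])))
  an <- Reduce(`+`, lapply(groups, function(g) 2 * sites[[paste0("n_", g)]]))
  keep <- keep & ac > 1e-9 & ac < an - 1e-9
  out <- sites[keep]
  if (!nrow(out)) warnf("no scan sites remain after selection")
  data.table::setattr(out, "groups", groups)
  out
}
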