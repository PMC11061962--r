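# Internal helpers shared across modules.

# All genomic intervals inside the package are 0-based half-open [start, end).
# VCF positions (1-based) are converted on read; BED files are already
# 0-based half-open. GRanges is 1-based closed, so [start, end) maps to
# IRanges(start + 1, end).
granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(as.character(chrom),
                         IRanges::IRanges(start = start + 1L, end = end))
}

# Point query for 1-based positions (a SNP at POS occupies base POS-1..POS
# in 0-based half-open terms).
granges_pos <- function(chrom, pos) {
  GenomicRanges::GRanges(as.character(chrom), IRanges::IRanges(pos, pos))
}

# NA-safe comparisons: an absent metric can never trigger a filter.
lt_na_false <- function(x, thr) !is.na(x) & x < thr
gt_na_false <- function(x, thr) !is.na(x) & x > thr

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Per-group summary column names for a site table.
group_cols <- function(groups) {
  as.vector(t(outer(c("n", "p", "h", "pi"), groups, paste, sep = "_")))
}
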