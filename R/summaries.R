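#' Mean windowed nucleotide diversity for a group
#'
#' Arithmetic mean of window pi over windows with at least one usable site
#' (the windowed tables produced by [window_stats()] already exclude
#' zero-site windows).
#'
#' @param window_pi numeric vector of window pi values.
#' @return scalar mean; NA (with a warning) when no windows are available.
#' @export
group_mean_pi <- function(window_pi) {
  v <- window_pi[is.finite(window_pi)]
  if (!length(v)) {
    warnf("no scored windows: mean pi undefined")
    return(NA_real_)
  }
  mean(v)
}

#' Folded minor-allele-frequency spectrum
#'
#' Folds alt-allele frequencies to MAF `= min(p, 1 - p)` and bins them into
#' the three-part partition of `[0, 0.5]`: rare `[0, rare_max)`, low
#' `[rare_max, low_max]` (closed on both sides) and common
#' `(low_max, 0.5]`. Densities are normalized within each SNP class.
#'
#' @param p alt-allele frequencies in `[0, 1]`.
#' @param class optional character vector of SNP classes (e.g.
#'   `"synonymous"`/`"nonsynonymous"`); all SNPs form one class when `NULL`.
#' @param rare_max,low_max bin thresholds (defaults 0.005 and 0.01).
#' @return data.table `class`, `bin`, `count`, `density`.
#' @export
maf_spectrum <- function(p, class = NULL, rare_max = 0.005, low_max = 0.01) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("frequencies outside [0, 1]")
  if (is.null(class)) class <- rep("all", length(p))
  maf <- pmin(p, 1 - p)
  labs <- c(sprintf("[0,%g)", rare_max),
            sprintf("[%g,%g]", rare_max, low_max),
            sprintf("(%g,0.5]", low_max))
  bin <- data.table::fcase(maf < rare_max, labs[1],
                           maf <= low_max, labs[2],
                           default = labs[3])
  dt <- data.table::data.table(class = class,
                               bin = factor(bin, levels = labs))
  out <- dt[!is.na(maf), .(count = .N), by = .(class, bin)]
  full <- data.table::CJ(class = unique(class), bin = factor(labs, levels = labs))
  out <- merge(full, out, by = c("class", "bin"), all.x = TRUE)
  out[is.na(out$count), "count"] <- 0L
  out[, density := count / sum(count), by = class]
  data.table::setorder(out, class, bin)
  out[]
}

#' Linkage-disequilibrium decay from genotype dosages
#'
#' Composite LD: for every pair of polymorphic sites within `max_dist` bp,
#' r^2 is the squared Pearson correlation of the unphased dosage vectors
#' over individuals called at both sites (phase-free surrogate for
#' haplotype r^2). Pairs involving a zero-variance site are excluded. Mean
#' r^2 is reported per distance bin, and the decay rate is the midpoint of
#' the first (smallest-distance) populated bin whose mean r^2 is <= 0.2
#' (`NA` when no bin reaches it within `max_dist`).
#'
#' @param dosages sites x individuals matrix of dosages in `{0, 1, 2}`
#'   (NA = missing).
#' @param positions bp positions of the sites (single chromosome).
#' @param max_dist maximum pair distance in bp (default 300 kb).
#' @param bin_width distance-bin width in bp (default 100).
#' @param r2_target decay threshold (default 0.2).
#' @return list: `bins` data.table (`midpoint_bp`, `mean_r2`, `n_pairs`)
#'   and `decay_rate` (bp or NA).
#' @export
ld_decay <- function(dosages, positions, max_dist = 300000L,
                     bin_width = 100L, r2_target = 0.2) {
  stopifnot(nrow(dosages) == length(positions))
  ord <- order(positions)
  dosages <- dosages[ord, , drop = FALSE]
  positions <- positions[ord]
  v <- apply(dosages, 1L, stats::var, na.rm = TRUE)
  poly <- !is.na(v) & v > 0
  dosages <- dosages[poly, , drop = FALSE]
  positions <- positions[poly]
  n <- nrow(dosages)
  if (n < 2L) {
    warnf("fewer than two polymorphic sites: LD undefined")
    return(list(bins = data.table::data.table(midpoint_bp = numeric(),
                                              mean_r2 = numeric(),
                                              n_pairs = integer()),
                decay_rate = NA_real_))
  }
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n - 1L)) {
    jmax <- i + findInterval(positions[i] + max_dist, positions[-seq_len(i)])
    if (jmax > i) {
      ii <- c(ii, rep.int(i, jmax - i))
      jj <- c(jj, seq.int(i + 1L, jmax))
    }
  }
  if (!length(ii)) {
    warnf("no site pairs within max_dist")
    return(list(bins = data.table::data.table(midpoint_bp = numeric(),
                                              mean_r2 = numeric(),
                                              n_pairs = integer()),
                decay_rate = NA_real_))
  }
  r2 <- vapply(seq_along(ii), function(k) {
    r <- suppressWarnings(stats::cor(dosages[ii[k], ], dosages[jj[k], ],
                                     use = "pairwise.complete.obs"))
    r * r
  }, 1)
  dist <- positions[jj] - positions[ii]
  keep <- !is.na(r2)
  bin_idx <- pmax(ceiling(dist[keep] / bin_width), 1L)
  bt <- data.table::data.table(bin = bin_idx, r2 = r2[keep])
  bins <- bt[, .(mean_r2 = mean(r2), n_pairs = .N), by = bin]
  data.table::setorder(bins, bin)
  bins[, midpoint_bp := (bin - 0.5) * bin_width]
  crossed <- bins$mean_r2 <= r2_target
  decay <- if (any(crossed)) bins$midpoint_bp[which(crossed)[1]] else NA_real_
  list(bins = bins[, c("midpoint_bp", "mean_r2", "n_pairs")],
       decay_rate = decay)
}
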