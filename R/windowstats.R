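#' Build a sliding-window grid
#'
#' Windows start at `0, step, 2 step, ...` while the start is inside the
#' chromosome; each window ends at `min(start + size, length)`, so the final
#' window(s) are truncated at the chromosome end. Defaults are the standard
#' 40 kb windows advanced in 20 kb steps.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param size window size in bp.
#' @param step step size in bp; must not exceed `size`.
#' @return data.table `chrom`, `start`, `end` (0-based half-open) with the
#'   grid parameters attached as attributes.
#' @export
make_windows <- function(chrom_lengths, size = 40000L, step = 20000L) {
  if (size <= 0 || step <= 0) stopf("size and step must be positive")
  if (step > size) stopf("step (%d) exceeds window size (%d)", step, size)
  out <- data.table::rbindlist(lapply(names(chrom_lengths), function(ch) {
    len <- as.integer(chrom_lengths[[ch]])
    starts <- seq.int(0L, len - 1L, by = as.integer(step))
    data.table::data.table(chrom = ch, start = starts,
                           end = pmin(starts + as.integer(size), len))
  }))
  data.table::setattr(out, "size", as.integer(size))
  data.table::setattr(out, "step", as.integer(step))
  out
}

#' Per-site Weir-Cockerham variance components (two groups)
#'
#' For each site with `n_i` called diploids, alt frequency `p_i` and observed
#' heterozygote fraction `h_i` in groups 1 and 2, computes the
#' Weir-Cockerham (1984) among-population (`a`), among-individual (`b`) and
#' within-individual (`c`) variance components for `r = 2` populations:
#' \deqn{\bar n = (n_1 + n_2)/2, \quad
#'       n_c = 2\bar n - (n_1^2 + n_2^2)/(2\bar n)}
#' \deqn{\bar p = (n_1 p_1 + n_2 p_2)/(2\bar n), \quad
#'       s^2 = (n_1 (p_1-\bar p)^2 + n_2 (p_2-\bar p)^2)/\bar n, \quad
#'       \bar h = (n_1 h_1 + n_2 h_2)/(2\bar n)}
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}
#'       \left(\bar p(1-\bar p) - \frac{s^2}{2} - \frac{\bar h}{4}\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) - \frac{s^2}{2}
#'       - \frac{2\bar n - 1}{4\bar n}\bar h\right], \qquad c = \bar h / 2}
#' Sites where either group has fewer than two called individuals are not
#' usable and get NA components. Sites monomorphic in both groups yield
#' `(0, 0, 0)`.
#'
#' @param n1,p1,h1,n2,p2,h2 numeric vectors of equal length.
#' @return data.table with columns `a`, `b`, `c`.
#' @export
fst_components <- function(n1, p1, h1, n2, p2, h2) {
  usable <- !is.na(n1) & !is.na(n2) & n1 >= 2 & n2 >= 2 &
    !is.na(p1) & !is.na(p2) & !is.na(h1) & !is.na(h2)
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  usable <- usable & nc > 0 & nbar > 1
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!usable] <- NA_real_
  b[!usable] <- NA_real_
  cc[!usable] <- NA_real_
  data.table::data.table(a = a, b = b, c = cc)
}

# Map scan sites onto (possibly overlapping) windows once; the mapping is a
# function of positions only, so it is reused unchanged across permutation
# replicates.
window_assignment <- function(sites, windows) {
  hits <- GenomicRanges::findOverlaps(granges_pos(sites$chrom, sites$pos),
                                      granges0(windows$chrom, windows$start,
                                               windows$end))
  data.table::data.table(site = S4Vectors::queryHits(hits),
                         window = S4Vectors::subjectHits(hits))
}

#' Window-level F_ST, nucleotide diversity and |delta-pi|
#'
#' Weighted window F_ST is the ratio of sums
#' `sum(a) / sum(a + b + c)` over usable sites in the window (NA when the
#' denominator is zero); negative values are retained. Window nucleotide
#' diversity for each group is the sum of per-site pi divided by the window
#' length in bp (truncated windows use their true length), with a group
#' contributing 0 where it has no usable sites; `abs_delta_pi` is the
#' absolute difference of the two group values. Windows containing no scan
#' sites at all are excluded from the result (and hence from scoring).
#'
#' @param sites scan-site table (see [select_scan_sites()]).
#' @param windows a [make_windows()] grid.
#' @param group_a,group_b group labels present in `sites`.
#' @param assignment optional precomputed site-to-window map (internal use
#'   by the permutation null).
#' @return data.table `chrom`, `start`, `end`, `n_sites`, `fst`, `pi_a`,
#'   `pi_b`, `abs_delta_pi`.
#' @export
window_stats <- function(sites, windows, group_a, group_b,
                         assignment = NULL) {
  for (g in c(group_a, group_b))
    if (!paste0("p_", g) %in% names(sites))
      stopf("group '%s' not present in site table", g)
  if (is.null(assignment)) assignment <- window_assignment(sites, windows)

  comp <- fst_components(sites[[paste0("n_", group_a)]],
                         sites[[paste0("p_", group_a)]],
                         sites[[paste0("h_", group_a)]],
                         sites[[paste0("n_", group_b)]],
                         sites[[paste0("p_", group_b)]],
                         sites[[paste0("h_", group_b)]])
  pa <- sites[[paste0("pi_", group_a)]]
  pb <- sites[[paste0("pi_", group_b)]]

  w <- data.table::data.table(
    window = assignment$window,
    a = comp$a[assignment$site],
    abc = comp$a[assignment$site] + comp$b[assignment$site] +
      comp$c[assignment$site],
    pi_a = pa[assignment$site],
    pi_b = pb[assignment$site])
  agg <- w[, .(n_sites = .N,
               sum_a = sum(a, na.rm = TRUE),
               sum_abc = sum(abc, na.rm = TRUE),
               any_fst = any(!is.na(abc)),
               sum_pi_a = sum(pi_a, na.rm = TRUE),
               sum_pi_b = sum(pi_b, na.rm = TRUE)),
           by = window]
  out <- windows[agg$window, c("chrom", "start", "end")]
  out[, n_sites := agg$n_sites]
  len <- as.numeric(out$end - out$start)
  out[, fst := data.table::fifelse(agg$any_fst & abs(agg$sum_abc) > 0,
                                   agg$sum_a / agg$sum_abc, NA_real_)]
  out[, pi_a := agg$sum_pi_a / len]
  out[, pi_b := agg$sum_pi_b / len]
  out[, abs_delta_pi := abs(pi_a - pi_b)]
  data.table::setorder(out, chrom, start)
  out[]
}
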