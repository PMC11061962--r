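#' Permute per-site records across fixed genomic positions
#'
#' Reassigns the complete per-site payload (both groups' `n`, `p`, `h` and
#' per-site pi, jointly as one tuple) to the fixed set of genomic positions
#' by a uniform random permutation over all sites genome-wide. Positions,
#' alleles and INFO metrics stay put; the multiset of payloads is preserved
#' exactly. This destroys the spatial clustering of differentiated or
#' low-diversity sites -- the only signal the windowed scan responds to --
#' while keeping each site's internal frequency/diversity consistency.
#'
#' @param sites scan-site table.
#' @param seed integer seed for the permutation.
#' @return a new site table with permuted payload columns.
#' @export
permute_sites <- function(sites, seed) {
  groups <- attr(sites, "groups")
  if (is.null(groups)) stopf("site table lacks group attribute")
  payload <- intersect(group_cols(groups), names(sites))
  perm <- withr::with_seed(as.integer(seed), sample.int(nrow(sites)))
  out <- data.table::copy(sites)
  for (cl in payload) data.table::set(out, j = cl, value = sites[[cl]][perm])
  data.table::setattr(out, "groups", groups)
  out
}

#' Build the permutation null for the window statistics
#'
#' Repeats `k` times: permute the per-site payloads ([permute_sites()]),
#' recompute every window statistic, and collect the values of all scored
#' windows. The null mean and SD for each statistic are computed from the
#' windows of all replicates pooled together (sample SD, N-1 denominator).
#'
#' @param sites scan-site table.
#' @param windows a [make_windows()] grid.
#' @param group_a,group_b group labels.
#' @param k number of permutation replicates (default 100).
#' @param seed integer seed; replicate `i` permutes with `seed + i`.
#' @param keep_values if `TRUE`, the pooled per-window null values are kept
#'   in the result for diagnostics.
#' @return list with elements `fst` and `dpi`, each a `null_model` list
#'   carrying `statistic`, `k`, `seed`, `mu`, `sigma`, `n_pooled` and
#'   optionally `values`.
#' @export
build_null <- function(sites, windows, group_a, group_b,
                       k = 100L, seed = 1L, keep_values = FALSE) {
  if (k < 2L) stopf("need at least two permutation replicates")
  assignment <- window_assignment(sites, windows)
  fst_vals <- vector("list", k)
  dpi_vals <- vector("list", k)
  for (i in seq_len(k)) {
    perm <- permute_sites(sites, seed = as.integer(seed) + i)
    ws <- window_stats(perm, windows, group_a, group_b,
                       assignment = assignment)
    fst_vals[[i]] <- ws$fst[!is.na(ws$fst)]
    dpi_vals[[i]] <- ws$abs_delta_pi[!is.na(ws$abs_delta_pi)]
  }
  mk <- function(stat, vals) {
    v <- unlist(vals)
    mu <- mean(v)
    sigma <- stats::sd(v)
    if (!is.finite(sigma) || sigma == 0)
      stopf(paste0("degenerate permutation null for %s (sigma = 0): all ",
                   "permuted windows are identical; the scan cannot proceed"),
            stat)
    out <- list(statistic = stat, k = as.integer(k),
                seed = as.integer(seed), mu = mu, sigma = sigma,
                n_pooled = length(v))
    if (keep_values) out$values <- v
    structure(out, class = "null_model")
  }
  list(fst = mk("fst", fst_vals), dpi = mk("dpi", dpi_vals))
}

#' Z-score observed windows against the permutation null
#'
#' Applies the affine transforms
#' `z_fst = (fst - mu_null) / sigma_null` and
#' `z_dpi = (|delta-pi| - mu_null) / sigma_null`, each with its own null
#' moments. Undefined window statistics propagate as NA.
#'
#' @param windows observed [window_stats()] table.
#' @param null result of [build_null()].
#' @return the window table with `z_fst` and `z_dpi` columns added.
#' @export
compute_zscores <- function(windows, null) {
  stopifnot(inherits(null$fst, "null_model"), inherits(null$dpi, "null_model"))
  out <- data.table::copy(windows)
  out[, z_fst := (fst - null$fst$mu) / null$fst$sigma]
  out[, z_dpi := (abs_delta_pi - null$dpi$mu) / null$dpi$sigma]
  out[]
}
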