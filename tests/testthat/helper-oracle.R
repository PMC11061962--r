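# Independent straight-line oracles, written directly from the
# Weir-Cockerham (1984) two-population component formulas. Scalar loops on
# purpose: these must stay structurally independent of the package's
# vectorized implementation.

oracle_wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c(a = a, b = b, c = hbar / 2)
}

# Brute-force windowed weighted F_ST: loop over windows, loop over sites,
# accumulate numerator and denominator with the scalar oracle.
oracle_window_fst <- function(sites, windows) {
  out <- rep(NA_real_, nrow(windows))
  for (w in seq_len(nrow(windows))) {
    num <- 0; den <- 0; seen <- FALSE
    for (i in seq_len(nrow(sites))) {
      if (sites$chrom[i] != windows$chrom[w]) next
      pos0 <- sites$pos[i] - 1
      if (pos0 < windows$start[w] || pos0 >= windows$end[w]) next
      if (sites$n_A[i] < 2 || sites$n_B[i] < 2) next
      comp <- oracle_wc_components(sites$n_A[i], sites$p_A[i], sites$h_A[i],
                                   sites$n_B[i], sites$p_B[i], sites$h_B[i])
      num <- num + comp[["a"]]
      den <- den + sum(comp)
      seen <- TRUE
    }
    if (seen && abs(den) > 0) out[w] <- num / den
  }
  out
}
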