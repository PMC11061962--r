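test_that("the sliding-window grid starts, steps and truncates correctly", {
  w <- make_windows(c(chr1 = 100000L))
  expect_identical(nrow(w), 5L)
  expect_identical(w$start, seq(0L, 80000L, by = 20000L))
  expect_identical(w$end[5], 100000L)
  expect_identical(w$end[1:3], c(40000L, 60000L, 80000L))

  w2 <- make_windows(c(chr1 = 40000L))
  expect_identical(w2$start, c(0L, 20000L))
  expect_identical(w2$end, c(40000L, 40000L))

  # size == step gives a non-overlapping tiling
  w3 <- make_windows(c(chr1 = 100000L), size = 25000L, step = 25000L)
  expect_identical(w3$start, w3$end - 25000L)
  expect_identical(w3$start[-1], w3$end[-nrow(w3)])

  expect_error(make_windows(c(chr1 = 1e5), size = 100, step = 200), "step")
})

test_that("Weir-Cockerham components reproduce hand-evaluated cases", {
  # fixed difference, no heterozygotes: theta = 1
  comp <- fst_components(10, 1, 0, 10, 0, 0)
  expect_equal(comp$a, 0.5, tolerance = 1e-12)
  expect_equal(comp$b, 0, tolerance = 1e-12)
  expect_equal(comp$c, 0, tolerance = 1e-12)

  # monomorphic in both groups
  comp0 <- fst_components(10, 0, 0, 10, 0, 0)
  expect_identical(unlist(comp0), c(a = 0, b = 0, c = 0))

  # intermediate case, frozen from the scalar oracle
  comp2 <- fst_components(10, 0.8, 0.32, 10, 0.2, 0.32)
  expect_equal(comp2$a, 0.171111111111, tolerance = 1e-9)
  expect_equal(comp2$b, 0.008888888889, tolerance = 1e-9)
  expect_equal(comp2$c, 0.16, tolerance = 1e-12)
  theta <- comp2$a / (comp2$a + comp2$b + comp2$c)
  expect_equal(theta, 0.503268, tolerance = 1e-6)

  # sites with n < 2 in either group are unusable
  expect_true(is.na(fst_components(1, 0.5, 1, 10, 0.2, 0.3)$a))
})

test_that("components and window ratios match the brute-force oracle", {
  withr::local_seed(42)
  n <- 1000L
  sites <- make_site_table(
    chrom = "chr1", pos = sort(sample.int(2e5, n)),
    n_A = sample(2:30, n, TRUE), p_A = runif(n), h_A = runif(n),
    pi_A = runif(n, 0, 0.5),
    n_B = sample(2:30, n, TRUE), p_B = runif(n), h_B = runif(n),
    pi_B = runif(n, 0, 0.5))
  comp <- fst_components(sites$n_A, sites$p_A, sites$h_A,
                         sites$n_B, sites$p_B, sites$h_B)
  oracle <- t(mapply(oracle_wc_components,
                     sites$n_A, sites$p_A, sites$h_A,
                     sites$n_B, sites$p_B, sites$h_B))
  expect_equal(comp$a, oracle[, "a"], tolerance = 1e-12)
  expect_equal(comp$b, oracle[, "b"], tolerance = 1e-12)
  expect_equal(comp$c, oracle[, "c"], tolerance = 1e-12)

  windows <- make_windows(c(chr1 = 2e5))
  ws <- window_stats(sites, windows, "A", "B")
  expected <- oracle_window_fst(sites, windows)
  expect_equal(ws$fst, expected[!is.na(expected)], tolerance = 1e-12)
})

test_that("window F_ST is the ratio of summed components", {
  # one fixed-difference site alone in its window
  s1 <- make_site_table("chr1", 100L, 10, 1, 0, 0.1, 10, 0, 0, 0.1)
  w <- make_windows(c(chr1 = 40000L), size = 40000L, step = 40000L)
  expect_equal(window_stats(s1, w, "A", "B")$fst, 1.0)

  # window of only monomorphic sites is excluded from scoring
  s2 <- make_site_table("chr1", c(100L, 200L), 10, 0, 0, 0,
                        10, 0, 0, 0)
  ws2 <- window_stats(s2, w, "A", "B")
  expect_true(is.na(ws2$fst))

  # ratio-of-sums for two sites: (0.5 + 0.171111)/(0.5 + 0.34)
  s3 <- make_site_table("chr1", c(100L, 200L),
                        n_A = 10, p_A = c(1, 0.8), h_A = c(0, 0.32), pi_A = 0,
                        n_B = 10, p_B = c(0, 0.2), h_B = c(0, 0.32), pi_B = 0)
  expect_equal(window_stats(s3, w, "A", "B")$fst, 0.671111111 / 0.84,
               tolerance = 1e-9)
})

test_that("window pi divides the per-site sum by the window length", {
  w <- make_windows(c(chr1 = 40000L), size = 40000L, step = 40000L)
  s <- make_site_table("chr1", c(100L, 200L), 10, c(0.5, 0.1), 0.5,
                       pi_A = c(0.5, 0.1),
                       n_B = 10, p_B = 0.5, h_B = 0.5, pi_B = c(0.5, 0.1))
  ws <- window_stats(s, w, "A", "B")
  expect_equal(ws$pi_a, 1.5e-5)
  # identical per-site pi in both groups gives |delta pi| = 0
  expect_equal(ws$abs_delta_pi, 0)

  # truncated windows use their true length
  wt <- make_windows(c(chr1 = 30000L), size = 40000L, step = 40000L)
  wst <- window_stats(s, wt, "A", "B")
  expect_equal(wst$pi_a, 0.6 / 30000)
})

test_that("per-site pi is invariant to swapping ref and alt labels", {
  g <- matrix(c(0L, 1L, 2L, 2L, 1L, 0L), nrow = 2, byrow = TRUE)
  a <- site_table_from_genotypes(g, rep("A", 3), "chr1", c(10L, 20L))
  b <- site_table_from_genotypes(2L - g, rep("A", 3), "chr1", c(10L, 20L))
  expect_equal(a$pi_A, b$pi_A)
  expect_equal(a$p_A, 1 - b$p_A)
})

test_that("mean window F_ST is near zero for undiverged groups", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e6), snp_density = 0.005,
                    n_per_group = 25L, f_bg = 0, seed = 31)
  sim <- simulate_dataset(cfg)
  sites <- site_table_from_genotypes(
    sim$genotypes, sub("_[0-9]+$", "", colnames(sim$genotypes)),
    sim$freqs$chrom, sim$freqs$pos)
  expect_gt(nrow(sites), 2000)
  w <- make_windows(c(chr1 = 1e6))
  ws <- window_stats(sites, w, "pop1", "pop2")
  expect_lt(abs(mean(ws$fst, na.rm = TRUE)), 0.02)
})

test_that("stronger sweep divergence does not lower sweep-window F_ST", {
  mean_sweep_fst <- function(f_sweep) {
    cfg <- sim_config(chrom_lengths = c(chr1 = 1e6), snp_density = 0.005,
                      f_bg = 0.05, seed = 17,
                      sweeps = sweep_spec("chr1", 4e5, 6e5,
                                          f_sweep = f_sweep, s = 0.5))
    sim <- simulate_dataset(cfg)
    sites <- site_table_from_genotypes(
      sim$genotypes, sub("_[0-9]+$", "", colnames(sim$genotypes)),
      sim$freqs$chrom, sim$freqs$pos)
    w <- make_windows(c(chr1 = 1e6))
    ws <- window_stats(sites, w, "pop1", "pop2")
    inside <- ws$start >= 4e5 & ws$end <= 6e5
    mean(ws$fst[inside], na.rm = TRUE)
  }
  vals <- vapply(c(0.1, 0.3, 0.6), mean_sweep_fst, 1)
  expect_true(all(diff(vals) >= 0))
})
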