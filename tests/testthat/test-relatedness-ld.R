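test_that("PI_HAT is exactly 1 for duplicated genotypes on fully called data", {
  set.seed(2)
  p <- runif(400, 0.1, 0.9)
  g <- rbinom(400, 2, p)
  gm <- gm_from_calls(cbind(g, g, rbinom(400, 2, p)),
                      pos = seq_len(400) * 50L,
                      samples = c("a", "b", "c"))
  est <- estimate_pi_hat(gm, c("a", "b"), allele_freqs = p)
  expect_equal(est$pi_hat, 1)
  expect_equal(est$N0 + est$N1, 0L)
  expect_false(est$low_confidence)

  self <- estimate_pi_hat(gm, c("a", "a"), allele_freqs = p)
  expect_equal(self$pi_hat, 1)
})

test_that("PI_HAT is symmetric in the pair and flags thin data", {
  set.seed(3)
  p <- runif(30, 0.2, 0.8)
  gm <- gm_from_calls(cbind(rbinom(30, 2, p), rbinom(30, 2, p)),
                      pos = seq_len(30) * 10L, samples = c("a", "b"))
  ab <- estimate_pi_hat(gm, c("a", "b"))
  ba <- estimate_pi_hat(gm, c("b", "a"))
  expect_equal(ab$pi_hat, ba$pi_hat)
  expect_true(ab$low_confidence)          # < 50 informative sites
})

test_that("pedigree simulations recover the expected PI_HAT per relationship", {
  means <- vapply(c(MZ = "MZ", PO = "PO", FS = "FS", UN = "UN"),
                  function(rel) {
    sim <- simulate_relatives(rel, n_sites = 5000, n_pairs = 10, seed = 71)
    mean(vapply(1:10, function(k)
      estimate_pi_hat(sim$matrix, paste0("pair", k, c("_a", "_b")),
                      allele_freqs = sim$freqs)$pi_hat, 0))
  }, 0)
  expect_equal(means[["MZ"]], 1)
  expect_lt(abs(means[["PO"]] - 0.5), 0.05)
  expect_lt(abs(means[["FS"]] - 0.5), 0.05)
  expect_lt(abs(means[["UN"]]), 0.05)
})

test_that("the all-pairs matrix is symmetric, zero-diagonal and permutation-stable", {
  set.seed(9)
  p <- runif(300, 0.1, 0.9)
  calls <- vapply(1:3, function(i) rbinom(300, 2, p), integer(300))
  gm <- gm_from_calls(calls, pos = seq_len(300) * 100L,
                      samples = c("a", "b", "c"))
  rel <- relatedness_matrix(gm)
  expect_equal(nrow(rel$pairs), 3L)
  expect_equal(rel$dissimilarity, t(rel$dissimilarity))
  expect_equal(unname(diag(rel$dissimilarity)), rep(0, 3))

  perm <- c(3L, 1L, 2L)
  gm_p <- genotype_matrix(gm$sites, gm$samples[perm], gm$calls[, perm])
  rel_p <- relatedness_matrix(gm_p)
  expect_equal(rel_p$dissimilarity[gm$samples, gm$samples],
               rel$dissimilarity)
})

test_that("strongly diverged populations show near-zero cross-population PI_HAT", {
  cfg <- sim_config(seed = 13, n_pop1 = 6, n_pop2 = 6,
                    chrom_lengths = c(chr1 = 2e6), variant_density = 1e-3,
                    invariant_density = 0, f_bg = 0.5, f_isl = 0.5,
                    islands = data.frame(chrom = "chr1", start = 0, end = 1),
                    missing_rate = 0)
  sim <- simulate_two_pop(cfg)
  rel <- relatedness_matrix(sim$matrix, sim$popmap)
  pop_of <- setNames(sim$popmap$population, sim$popmap$sample)
  cross <- rel$pairs[pop_of[rel$pairs$sample1] != pop_of[rel$pairs$sample2], ]
  expect_lt(mean(cross$pi_hat), 0.05)
})

test_that("r^2 handles identical, complementary and independent columns", {
  set.seed(12)
  x <- rbinom(50, 2, 0.5)
  calls <- cbind(x, x, 2L - x)
  gm <- gm_from_calls(t(matrix(calls, ncol = 3)), pos = c(100L, 200L, 300L))
  pr <- pairwise_r2(gm, min_maf = 0)
  expect_equal(pr$r2, rep(1, 3), tolerance = 1e-12)

  n_samp <- 50
  p <- runif(150, 0.2, 0.8)
  ind <- vapply(seq_len(n_samp), function(i) rbinom(150, 2, p),
                integer(150))
  gm2 <- gm_from_calls(ind, pos = seq_len(150) * 100L)
  pr2 <- pairwise_r2(gm2, min_maf = 0.1)
  se <- sd(pr2$r2) / sqrt(nrow(pr2))
  expect_lt(abs(mean(pr2$r2) - 1 / n_samp), 3 * se + 0.005)

  # allele-label flip at one site leaves r^2 unchanged
  flipped <- gm2$calls
  flipped[7L, ] <- 2L - flipped[7L, ]
  gm3 <- gm_from_calls(flipped, pos = gm2$sites$pos)
  pr3 <- pairwise_r2(gm3, min_maf = 0.1)
  expect_equal(pr3$r2, pr2$r2, tolerance = 1e-12)
})

test_that("r^2 against the explicit-formula oracle on incomplete data", {
  set.seed(31)
  calls <- matrix(sample(c(0:2, NA), 120, replace = TRUE,
                         prob = c(0.35, 0.3, 0.3, 0.05)), nrow = 4)
  gm <- gm_from_calls(calls, pos = c(100L, 300L, 600L, 900L))
  pr <- pairwise_r2(gm, min_maf = 0)
  for (row in seq_len(nrow(pr))) {
    i <- which(gm$sites$pos == pr$pos1[row])
    j <- which(gm$sites$pos == pr$pos2[row])
    expect_equal(pr$r2[row], r2_oracle(gm$calls[i, ], gm$calls[j, ]),
                 tolerance = 1e-12)
  }
})

test_that("distance bins are right-closed and report empty bins", {
  pr <- data.frame(chrom = "chr1", pos1 = 1L,
                   pos2 = c(2L, 10000L, 10001L),
                   dist = c(1L, 9999L, 10000L),
                   r2 = c(0.2, 0.4, 0.6))
  bins <- ld_decay_bins(pr, bin = 10000, max_dist = 30000)
  expect_equal(bins$n, c(3L, 0L, 0L))
  expect_equal(bins$mean_r2[1L], 0.4)
  expect_true(is.na(bins$mean_r2[2L]))

  one <- ld_decay_bins(data.frame(chrom = "chr1", pos1 = 1L, pos2 = 50001L,
                                  dist = 50000L, r2 = 0.33),
                       bin = 10000, max_dist = 50000)
  expect_equal(one$mean_r2[5L], 0.33)
})

test_that("recombining haplotypes yield distance-decaying r^2", {
  gm <- simulate_ld_haplotypes(n_samples = 60, n_sites = 150,
                               chrom_length = 5e5, n_founders = 6,
                               recomb_rate = 2e-5, mut_rate = 0.01,
                               seed = 19)
  bins <- ld_decay_bins(pairwise_r2(gm, max_dist = 5e5), bin = 10000,
                        max_dist = 5e5)
  ok <- which(bins$n > 0)
  sm <- stats::filter(bins$mean_r2[ok], rep(1 / 3, 3), sides = 2)
  sm <- sm[!is.na(sm)]
  # decay: smoothed curve drops from its head to its tail
  expect_lt(mean(tail(sm, 5)), mean(head(sm, 5)))
  expect_true(all(diff(sm) < 0.1))   # no large upward jumps after smoothing

  # zero-recombination limit with two founders: complete LD
  gm0 <- simulate_ld_haplotypes(n_samples = 30, n_sites = 40,
                                chrom_length = 1e5, n_founders = 2,
                                recomb_rate = 1e-12, mut_rate = 0,
                                seed = 23)
  pr0 <- pairwise_r2(gm0, min_maf = 0.01)
  expect_true(all(pr0$r2 > 0.99))
})

test_that("LD profiles are refused for tiny populations unless forced", {
  set.seed(44)
  calls <- matrix(sample(0:2, 60, replace = TRUE), ncol = 2)
  gm <- gm_from_calls(calls, pos = seq_len(30) * 1000L,
                      samples = c("a", "b"))
  expect_error(ld_decay(gm), "uninformative")
  expect_no_error(ld_decay(gm, force = TRUE, min_maf = 0))
})
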