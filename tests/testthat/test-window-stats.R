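test_that("window tiling follows the start < length rule with truncation", {
  w <- make_windows(c(chr1 = 100000))
  expect_equal(nrow(w), 10L)
  expect_equal(w$start, seq(0L, 90000L, by = 10000L))
  expect_equal(w$end[10L], 100000L)

  expect_equal(nrow(make_windows(c(chr1 = 50000))), 5L)

  tiny <- make_windows(c(chr1 = 10))
  expect_equal(nrow(tiny), 1L)
  expect_equal(c(tiny$start, tiny$end), c(0L, 10L))

  expect_error(make_windows(c(chr1 = 1e5), size = 1e4, step = 5e4), "gaps")
})

test_that("per-site pi and dxy match their combinatorial closed forms", {
  expect_equal(site_pi(2, 4), 2 / 3)
  expect_equal(site_pi(0, 8), 0)
  expect_equal(site_pi(1, 2), 1)
  expect_true(is.na(site_pi(0, 1)))

  expect_equal(site_dxy(1, 4, 3, 4), 0.625)
  expect_equal(site_dxy(0, 4, 0, 6), 0)
  expect_equal(site_dxy(0, 4, 4, 4), 1)
  expect_true(is.na(site_dxy(2, 4, 0, 0)))
})

test_that("Weir-Cockerham components match the ANOVA mean-squares oracle", {
  # fixed difference: ratio 1
  v <- wc_site_components(c(10, 0, 0), c(0, 0, 10))
  expect_equal(v[["a"]] / sum(v), 1)

  # identical genotype vectors: no between-population variance
  v2 <- wc_site_components(c(3, 4, 3), c(3, 4, 3))
  expect_lte(v2[["a"]], 0)

  v3 <- wc_site_components(c(1, 1, 0), c(0, 0, 2))
  expect_equal(unname(v3), unname(wc_anova_oracle(c(1, 1, 0), c(0, 0, 2))),
               tolerance = 1e-12)

  set.seed(99)
  for (i in 1:50) {
    c1 <- as.vector(rmultinom(1, sample(2:8, 1), runif(3)))
    c2 <- as.vector(rmultinom(1, sample(2:8, 1), runif(3)))
    expect_equal(unname(wc_site_components(c1, c2)),
                 unname(wc_anova_oracle(c1, c2)), tolerance = 1e-10)
  }
})

test_that("window summaries use missing-aware pair-count denominators", {
  # one variant site (c1=1,n1=4 ; c2=3,n2=4) + 15 fully called invariant sites
  calls <- rbind(c(0, 1, 1, 2),
                 matrix(0L, nrow = 15, ncol = 4))
  gm <- gm_from_calls(calls, pos = c(100L, seq(200L, 1600L, by = 100L)),
                      is_variant = c(TRUE, rep(FALSE, 15)))
  pm <- popmap_df(gm$samples, c("A", "A", "B", "B"))
  w <- windows_df("chr1", 0L, 50000L)
  ws <- summarize_windows(gm, pm, w)
  expect_equal(ws$dxy, 10 / (16 * 16), tolerance = 1e-12)
  expect_equal(ws$n_sites, 1L)
  expect_equal(ws$n_callable_pop1, 16L)
  # pop A: site pi = 1*3/C(4,2)=0.5 over 16 sites of C(4,2) pairs
  expect_equal(ws$pi_pop1, (1 * 3) / (6 * 16), tolerance = 1e-12)

  # no variant sites: pi = dxy = 0, fst undefined
  gm0 <- gm_from_calls(matrix(0L, nrow = 3, ncol = 4), is_variant = FALSE)
  ws0 <- summarize_windows(gm0, pm, w)
  expect_equal(ws0$pi_pop1, 0)
  expect_equal(ws0$dxy, 0)
  expect_true(is.na(ws0$fst))
})

test_that("window stats are invariant to sample order and population labels", {
  set.seed(5)
  calls <- matrix(sample(c(0:2, NA), 240, replace = TRUE,
                         prob = c(0.4, 0.3, 0.25, 0.05)), ncol = 8)
  gm <- gm_from_calls(calls, pos = seq_len(30) * 900L)
  pm <- popmap_df(gm$samples, rep(c("A", "B"), each = 4))
  w <- make_windows(c(chr1 = 27000), size = 10000, step = 5000)
  ws <- summarize_windows(gm, pm, w)

  perm <- sample(8)
  gm_p <- genotype_matrix(gm$sites, gm$samples[perm], gm$calls[, perm])
  expect_equal(summarize_windows(gm_p, pm, w), ws, ignore_attr = TRUE)

  # swapping population labels leaves dxy unchanged (symmetry)
  pm_swap <- popmap_df(gm$samples, rep(c("B", "A"), each = 4))
  ws_swap <- summarize_windows(gm, pm_swap, w)
  expect_equal(ws_swap$dxy, ws$dxy)
  expect_equal(ws_swap$fst, ws$fst)
})

test_that("a random split of one panmictic sample gives Fst near 0 and dxy near pi", {
  set.seed(21)
  n_site <- 2000; n_samp <- 20
  p <- runif(n_site, 0.1, 0.9)
  calls <- vapply(seq_len(n_samp), function(i) rbinom(n_site, 2, p),
                  integer(n_site))
  gm <- gm_from_calls(calls, pos = seq_len(n_site) * 10L)
  pm <- popmap_df(gm$samples, rep(c("A", "B"), each = 10))
  w <- windows_df("chr1", 0L, n_site * 10L + 1L)
  ws <- summarize_windows(gm, pm, w)
  expect_lt(abs(global_fst(gm, pm)), 0.01)
  expect_equal(ws$dxy, mean(c(ws$pi_pop1, ws$pi_pop2)), tolerance = 0.02)
})

test_that("MCAR masking shifts window pi and dxy by less than 3 SE", {
  set.seed(33)
  cfg <- sim_config(seed = 33, n_pop1 = 10, n_pop2 = 10,
                    chrom_lengths = c(chr1 = 2e6), variant_density = 1e-3,
                    invariant_density = 4e-3, f_bg = 0.1, f_isl = 0.1,
                    islands = data.frame(chrom = "chr1", start = 0, end = 1),
                    missing_rate = 0)
  sim <- simulate_two_pop(cfg)
  pm <- sim$popmap
  w <- make_windows(c(chr1 = 2e6))
  full <- summarize_windows(sim$matrix, pm, w)
  masked_calls <- sim$matrix$calls
  masked_calls[runif(length(masked_calls)) < 0.10] <- NA_integer_
  gm_m <- genotype_matrix(sim$matrix$sites, sim$matrix$samples, masked_calls)
  masked <- summarize_windows(gm_m, pm, w)
  # paired comparison across windows, 3 SE of the mean paired difference
  for (col in c("pi_pop1", "pi_pop2", "dxy")) {
    d <- masked[[col]] - full[[col]]
    se <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d)), max(3 * se, 1e-6))
  }
})

test_that("heterozygosity is counted per sample over called sites", {
  gm <- gm_from_calls(rbind(c(1, 0), c(1, 0), c(0, 2), c(2, NA)))
  het <- individual_heterozygosity(gm)
  expect_equal(het$het_rate[1L], 0.5)
  expect_equal(het$het_rate[2L], 0)
  expect_equal(het$n_called[2L], 3L)

  set.seed(8)
  calls <- matrix(rbinom(10000, 2, 0.5), ncol = 1)
  gm_hw <- gm_from_calls(calls, pos = seq_len(10000) * 10L,
                         samples = "s01")
  rate <- individual_heterozygosity(gm_hw)$het_rate
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(rate - 0.5), 3 * se)
})

test_that("genome-wide Fst recovers the Balding-Nichols divergence parameter", {
  est <- vapply(1:4, function(s) {
    cfg <- sim_config(seed = s, n_pop1 = 20, n_pop2 = 20,
                      chrom_lengths = c(chr1 = 5e6), variant_density = 1e-3,
                      invariant_density = 0, f_bg = 0.2, f_isl = 0.2,
                      islands = data.frame(chrom = "chr1", start = 0, end = 1),
                      missing_rate = 0)
    sim <- simulate_two_pop(cfg)
    global_fst(sim$matrix, sim$popmap)
  }, 0)
  expect_lt(abs(mean(est) - 0.2), 0.02)
})

test_that("dxy increases with split depth under post-split mutation accumulation", {
  dxy_at <- function(T_gen) {
    cfg <- sim_config(seed = 11, n_pop1 = 8, n_pop2 = 8,
                      chrom_lengths = c(chr1 = 2e6), variant_density = 5e-4,
                      invariant_density = 2e-3, f_bg = 0.1, f_isl = 0.1,
                      islands = data.frame(chrom = "chr1", start = 0, end = 1),
                      missing_rate = 0.02, split_time_gens = T_gen)
    sim <- simulate_two_pop(cfg)
    w <- make_windows(c(chr1 = 2e6), size = 2e6, step = 2e6)
    summarize_windows(sim$matrix, sim$popmap, w)$dxy
  }
  grid <- vapply(c(0, 1e5, 3e5, 6e5, 1e6), dxy_at, 0)
  expect_true(all(diff(grid) > 0))
})
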