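test_that("top-fraction flagging is rank-based with boundary ties included", {
  res <- empirical_top_fraction(1:100, 0.01)
  expect_equal(res$flagged, 100L)
  expect_equal(res$threshold, 100)

  v <- c(1:98, 99.5, 99.5)
  res2 <- empirical_top_fraction(v, 0.01)
  expect_equal(res2$flagged, c(99L, 100L))

  expect_warning(res3 <- empirical_top_fraction(rep(2, 50), 0.02), "all")
  expect_equal(res3$flagged, 1:50)

  expect_error(empirical_top_fraction(1:10, 0), "fraction")
  expect_error(empirical_top_fraction(1:10, 1.2), "fraction")
})

test_that("undefined windows are excluded before ranking", {
  v <- c(NA, 1:99, NA)
  res <- empirical_top_fraction(v, 0.01)
  expect_equal(res$n_defined, 99L)
  expect_equal(res$flagged, 100L)     # value 99 sits at index 100
})

test_that("outlier windows merge with an inclusive 10-kb gap rule", {
  w <- windows_df("chr1", c(0L, 10000L, 100000L),
                  c(50000L, 60000L, 150000L))
  m <- merge_outlier_windows(w, values = c(0.9, 0.8, 0.7))
  expect_equal(m$start, c(0L, 100000L))
  expect_equal(m$end, c(60000L, 150000L))
  expect_equal(m$max_value, c(0.9, 0.7))

  # gap of exactly 10 kb merges
  w2 <- windows_df("chr1", c(0L, 60000L), c(50000L, 110000L))
  m2 <- merge_outlier_windows(w2)
  expect_equal(nrow(m2), 1L)
  expect_equal(c(m2$start, m2$end), c(0L, 110000L))

  # gap of 10,001 bp does not
  w3 <- windows_df("chr1", c(0L, 60001L), c(50000L, 110000L))
  expect_equal(nrow(merge_outlier_windows(w3)), 2L)

  single <- merge_outlier_windows(windows_df("chr2", 30000L, 80000L))
  expect_equal(single$end - single$start, 50000L)
  expect_equal(nrow(merge_outlier_windows(windows_df(character(0),
                                                     integer(0),
                                                     integer(0)))), 0L)
})

test_that("merging agrees with a union-find closure oracle on random window sets", {
  set.seed(17)
  for (rep in 1:60) {
    n <- sample(1:25, 1)
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    start <- sample(0:40, n, replace = TRUE) * 10000L
    w <- windows_df(chrom, start, start + 50000L)
    gap <- sample(c(0L, 5000L, 10000L, 25000L), 1)
    got <- merge_outlier_windows(w, max_gap = gap)
    want <- merge_oracle(w, gap)
    expect_equal(got[, c("chrom", "start", "end")], want,
                 ignore_attr = TRUE)
    # disjointness and separation of the merged output
    if (nrow(got) > 1L) {
      same <- got$chrom[-nrow(got)] == got$chrom[-1L]
      gaps <- got$start[-1L] - got$end[-nrow(got)]
      expect_true(all(gaps[same] > gap))
    }
  }
})

test_that("region output is invariant to input window order", {
  set.seed(4)
  w <- windows_df("chr1", sample(0:30, 10) * 10000L, rep(0L, 10))
  w$end <- w$start + 50000L
  shuf <- w[sample(nrow(w)), ]
  expect_equal(merge_outlier_windows(w)[, 1:3],
               merge_outlier_windows(shuf)[, 1:3])
})

test_that("core islands are the merged intersection of both flag sets", {
  w <- make_windows(c(chr1 = 500000))       # 50 windows
  fst_flags <- c(1L, 2L, 7L, 40L)
  dxy_flags <- c(2L, 7L, 30L)
  core <- core_islands(fst_flags, dxy_flags, w)
  expect_equal(attr(core, "n_core_windows"), 2L)
  expect_equal(nrow(core), 1L)   # windows 2 [10k,60k) and 7 [60k,110k) chain
  expect_equal(c(core$start, core$end), c(10000L, 110000L))

  expect_equal(nrow(core_islands(c(1L, 2L), c(30L, 40L), w)), 0L)

  same <- core_islands(fst_flags, fst_flags, w)
  expect_equal(same[, c("chrom", "start", "end")],
               merge_outlier_windows(w[fst_flags, ])[, c("chrom", "start",
                                                         "end")])

  expect_error(core_islands(c(1L, 999L), dxy_flags, w), "outside")
})

test_that("gene-region overlap uses half-open semantics with deduplicated union", {
  genes <- data.frame(gene_id = c("gA", "gB", "gC"),
                      chrom = "chr1",
                      start = c(100L, 100L, 500L),
                      end = c(200L, 200L, 600L),
                      strand = "+")
  genes <- genes[-2L, ]                      # keep gA, gC
  regions <- data.frame(chrom = "chr1", start = c(150L, 200L, 0L),
                        end = c(300L, 300L, 120L))
  res <- genes_in_regions(regions, genes)
  expect_equal(res$per_region[[1L]], "gA")   # [150,300) overlaps [100,200)
  expect_equal(res$per_region[[2L]], character(0))  # [200,300) touches only
  expect_equal(res$per_region[[3L]], "gA")
  expect_equal(res$union, "gA")              # shared gene counted once
})

test_that("planted islands are recovered by the merged top-1% Fst regions", {
  cfg <- sim_config(seed = 101)
  sim <- simulate_two_pop(cfg)
  w <- make_windows(cfg$chrom_lengths)
  ws <- summarize_windows(sim$matrix, sim$popmap, w)
  top <- empirical_top_fraction(ws$fst, 0.01)
  reg <- merge_outlier_windows(ws[top$flagged, , drop = FALSE],
                               values = ws$fst[top$flagged])
  isl <- sim$truth$islands
  hit <- vapply(seq_len(nrow(isl)), function(i)
    any(reg$chrom == isl$chrom[i] & reg$start < isl$end[i] &
          reg$end > isl$start[i]), TRUE)
  inside <- 0
  for (i in seq_len(nrow(isl))) {
    sel <- reg$chrom == isl$chrom[i]
    ov <- pmin(reg$end, isl$end[i]) - pmax(reg$start, isl$start[i])
    inside <- inside + sum(pmax(ov, 0)[sel])
  }
  expect_gte(mean(hit), 0.9)
  expect_gte(inside / sum(reg$end - reg$start), 0.8)
})
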