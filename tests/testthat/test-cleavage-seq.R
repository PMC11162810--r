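test_that("profiles validate counts against coverage", {
  expect_error(cleavage_profile("t", c(5, 20), c(10, 10)), "exceed coverage")
  expect_error(cleavage_profile("t", c(-1, 2), 10), "nonnegative")
  p <- cleavage_profile("t", c(1, 2, 3), 10)
  expect_equal(p$coverage, c(10, 10, 10))
})

test_that("normcount self-normalises a flat profile to 1", {
  p <- cleavage_profile("t", rep(7, 20), 1000)
  for (i in c(2, 5, 10, 18)) expect_equal(normcount(p, i), 1.0)
})

test_that("normcount reproduces the hand-computed spike score", {
  # read starts: background 2 everywhere, 40 at position 7; under the
  # N+1 convention that 40 is attributed to residue 6
  counts <- rep(2, 15)
  counts[7] <- 40
  p <- cleavage_profile("t", counts, 1000)
  expect_equal(normcount(p, 6), 20.0)  # 40 / median(flanking 2s)
  # over an all-zero background the unit floor keeps the score finite
  z <- rep(0, 15)
  z[7] <- 7
  expect_equal(normcount(cleavage_profile("t", z, 1000), 6), 7.0)
})

test_that("normcount is invariant to rescaling all counts", {
  set.seed(31)
  counts <- rpois(30, 10)
  counts[12] <- 200
  for (c_mult in c(2, 5, 10)) {
    p1 <- cleavage_profile("t", counts, 10000)
    p2 <- cleavage_profile("t", counts * c_mult, 10000 * c_mult)
    expect_equal(normcount(p2, 11), normcount(p1, 11))
  }
})

test_that("stop_ratio is the attributed count over coverage", {
  counts <- c(0, 30, 0, 0)
  p <- cleavage_profile("t", counts, 100)
  expect_equal(stop_ratio(p, 1), 0.30)
  expect_equal(stop_ratio(p, 2), 0.0)
  full <- cleavage_profile("t", c(0, 100, 0), 100)
  expect_equal(stop_ratio(full, 1), 1.0)
  # zero coverage is undetected, not zero
  p0 <- cleavage_profile("t", c(0, 0, 0), c(10, 0, 10))
  expect_true(is.na(stop_ratio(p0, 1)))
})

test_that("call_sites finds the spiked site and channels non-U signal", {
  bases <- strsplit("AAAAUAAAAAGAAAAUAAAA", "")[[1]]
  counts <- rep(2, 20)
  counts[6] <- 40    # spike attributed to the U at residue 5
  counts[12] <- 40   # spike attributed to the G at residue 11 (m7G-like)
  p <- cleavage_profile("t", counts, 1000)
  calls <- call_sites(p, bases, score_threshold = 5)
  d_calls <- calls[calls$channel == "D", ]
  g_calls <- calls[calls$channel == "non_U", ]
  expect_equal(d_calls$position, 5L)
  expect_equal(g_calls$position, 11L)
  expect_true(all(d_calls$substoichiometric))
  # a flat profile yields nothing
  flat <- cleavage_profile("t", rep(3, 20), 1000)
  expect_equal(nrow(call_sites(flat, bases)), 0L)
})

test_that("heatmap_matrix averages replicates and keeps NA distinct from 0", {
  mk <- function(sr, sample, rep) {
    counts <- rep(0, 10)
    counts[5] <- round(sr * 100)
    cleavage_profile("t", counts, 100, sample = sample, replicate = rep)
  }
  profs <- list(mk(.30, "WT", 1), mk(.32, "WT", 2), mk(.28, "WT", 3),
                mk(0, "dB1dB2", 1), mk(0, "dB1dB2", 2))
  m <- heatmap_matrix(profs, sites = 4)
  expect_equal(m["4", "WT"], 0.30)
  expect_equal(m["4", "dB1dB2"], 0.0)
  reps <- attr(m, "replicates")
  # the double mutant has no third replicate: missing, not zero
  expect_true(is.na(reps["4", "dB1dB2", "3"]))
  expect_equal(unname(reps["4", "WT", ]), c(.30, .32, .28))
  bad <- c(profs, list(cleavage_profile("t", rep(0, 7), 100)))
  expect_error(heatmap_matrix(bad, 4), "inconsistent")
})

test_that("dose_response flags monotone, flat and shuffled series", {
  mk <- function(spike) {
    counts <- rep(2, 15)
    counts[8] <- spike
    cleavage_profile("t", counts, 1000)
  }
  rising <- list(mk(4), mk(10), mk(30), mk(80))
  dr <- dose_response(rising, 7, c(0.05, 0.5, 5, 25))
  expect_true(dr$monotone)
  expect_false(dr$flat)
  expect_equal(dr$score, sort(dr$score))
  flat <- dose_response(list(mk(10), mk(10), mk(10)), 7, c(1, 2, 3))
  expect_true(flat$monotone)
  expect_true(flat$flat)
  shuffled <- dose_response(list(mk(30), mk(4), mk(80)), 7, c(1, 2, 3))
  expect_false(shuffled$monotone)
})

test_that("sequencing panels reuse the attribution grid after WT scaling", {
  expect_equal(panel_attribution_from_seq(
    c(WT = .4, dB1 = 0, dB2 = .4, dB1dB2 = 0)), "B1_only")
  expect_equal(panel_attribution_from_seq(
    c(WT = .5, dB1 = .45, dB2 = .15, dB1dB2 = 0)), "redundant_B2_preferred")
  expect_equal(panel_attribution_from_seq(
    c(WT = 0, dB1 = 0, dB2 = 0, dB1dB2 = 0)), "none")
  expect_error(panel_attribution_from_seq(c(WT = .4, dB1 = 0)), "dB2")
})

test_that("cleavage tables round-trip through TSV", {
  p1 <- cleavage_profile("tA", c(1, 5, 2), 100, sample = "WT")
  p2 <- cleavage_profile("tB", c(0, 9, 1, 3), 200, sample = "WT")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cleavage_table(list(p1, p2), path)
  back <- read_cleavage_table(path, sample = "WT")
  expect_setequal(names(back), c("tA", "tB"))
  expect_equal(back$tA$counts, p1$counts)
  expect_equal(back$tB$coverage, p2$coverage)
})
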