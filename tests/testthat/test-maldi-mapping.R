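test_that("select_diagnostics picks the UDG fragment for an embedded D17", {
  # context as in tRNA-Phe: ...G | U D G | ... with A/G filler around
  t1 <- trna_from_display("phe", "AAGUDGAAA")
  d <- select_diagnostics(t1, "RNaseT1")
  expect_equal(nrow(d), 1L)
  expect_equal(d$fragment, "UDG")
  expect_equal(round(d$mz_modified), 978)
  expect_equal(round(d$mz_unmodified), 976)
  expect_equal(d$mz_modified - d$mz_unmodified, 2.016, tolerance = 1e-3)
  expect_length(attr(d, "unmonitorable"), 0L)
})

test_that("fragments with two candidate sites are ambiguous, not diagnostic", {
  t1 <- trna_from_display("amb", "AAGUDDGAA")
  d <- select_diagnostics(t1, "RNaseT1", candidate_sites = c("4", "5"))
  expect_equal(nrow(d), 0L)
  expect_setequal(attr(d, "unmonitorable"), c("4", "5"))
})

test_that("a mass collision with another digest fragment disqualifies a site", {
  # the unmodified pair member UUG appears verbatim elsewhere in the digest
  t1 <- trna_from_display("coll", "GUDGUUGA")
  d <- select_diagnostics(t1, "RNaseT1")
  expect_equal(nrow(d), 0L)
  expect_equal(attr(d, "unmonitorable"), "3")
  # removing the colliding copy restores monitorability
  t2 <- trna_from_display("ok", "GUDGAAGA")
  expect_equal(nrow(select_diagnostics(t2, "RNaseT1")), 1L)
})

test_that("match_peaks sums within tolerance and assigns by proximity", {
  t1 <- trna_from_display("phe", "AAGUDGAAA")
  d <- select_diagnostics(t1, "RNaseT1")
  one <- match_peaks(data.frame(mz = 978.1, intensity = 100), d, 0.5)
  expect_equal(c(one$I_mod, one$I_unmod), c(100, 0))
  two <- match_peaks(data.frame(mz = c(976.05, 978.1),
                                intensity = c(40, 60)), d, 0.5)
  expect_equal(c(two$I_mod, two$I_unmod), c(60, 40))
  # 977.0 sits between the pair, nearer than 1 Da to neither target
  none <- match_peaks(data.frame(mz = 977.0, intensity = 50), d, 0.5)
  expect_equal(c(none$I_mod, none$I_unmod), c(0, 0))
})

test_that("site_state applies the f thresholds and the detection floor", {
  expect_equal(site_state(100, 0), list(f = 1.0, call = "modified"))
  expect_equal(site_state(0, 100), list(f = 0.0, call = "unmodified"))
  expect_equal(site_state(30, 70), list(f = 0.3, call = "reduced"))
  expect_equal(site_state(85, 15)$call, "modified")
  expect_equal(site_state(10, 90)$call, "unmodified")
  low <- site_state(1, 1, floor = 5)
  expect_equal(low$call, "undetected")
  expect_true(is.na(low$f))
  expect_equal(detection_floor(data.frame(intensity = c(10, 100, 1000))), 5)
})

test_that("the knockout grid reproduces the four worked strain patterns", {
  # D17: present except where B1 is gone
  expect_equal(decide_attribution(panel_states(
    c("modified", "unmodified", "modified", "unmodified"))), "B1_only")
  # D20: both singles retain it, the B2 deletion much reduced
  expect_equal(decide_attribution(panel_states(
    c("modified", "modified", "reduced", "unmodified"),
    fs = c(1, 0.8, 0.3, 0))), "redundant_B2_preferred")
  # D20a in the initiator tRNA: neither single deletion dents it
  expect_equal(decide_attribution(panel_states(
    c("modified", "modified", "modified", "unmodified"),
    fs = c(1, 0.9, 0.85, 0))), "redundant")
  # D47: the B1 deletion abolishes it
  expect_equal(decide_attribution(panel_states(
    c("modified", "unmodified", "modified", "unmodified"))), "B1_only")
})

test_that("grid edge rules: no site, contamination, missing strain", {
  expect_equal(decide_attribution(panel_states(
    c("unmodified", "unmodified", "unmodified", "unmodified"))), "none")
  expect_equal(decide_attribution(panel_states(
    c("modified", "modified", "modified", "modified"))), "inconsistent")
  st <- panel_states(c("modified", "unmodified", "modified", "unmodified"))
  expect_error(decide_attribution(st[c("WT", "dB1", "dB2")]), "dB1dB2")
  # B2_only is the mirror image of B1_only
  expect_equal(decide_attribution(panel_states(
    c("modified", "modified", "unmodified", "unmodified"))), "B2_only")
})

test_that("attribution depends only on the states, not strain list order", {
  st <- panel_states(c("modified", "modified", "reduced", "unmodified"),
                     fs = c(1, 0.8, 0.3, 0))
  for (perm in list(c(4, 3, 2, 1), c(2, 4, 1, 3), c(3, 1, 4, 2))) {
    expect_equal(decide_attribution(st[perm]), "redundant_B2_preferred")
  }
})

test_that("peak lists round-trip through the TSV reader", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(mz = c(976.1, 978.1), intensity = c(40, 60)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  pk <- read_peak_list(path)
  expect_equal(pk$mz, c(976.1, 978.1))
  writeLines("a\tb\n1\t2", path)
  expect_error(read_peak_list(path), "mz, intensity")
})
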