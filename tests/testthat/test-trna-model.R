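test_that("position labels parse, format and order canonically", {
  p <- parse_position_label(c("17", "20a", "20b", "47"))
  expect_equal(p$number, c(17L, 20L, 20L, 47L))
  expect_equal(p$suffix, c("", "a", "b", ""))
  # round trip through the text form
  expect_equal(format_position_label(p$number, p$suffix),
               c("17", "20a", "20b", "47"))
  # total order: bare number < a < b, then the next number
  labs <- c("21", "20b", "17", "20", "20a")
  expect_equal(sort_position_labels(labs), c("17", "20", "20a", "20b", "21"))
  expect_error(parse_position_label("20ab"), "malformed")
  expect_error(parse_position_label("a20"), "malformed")
})

test_that("annotations apply by label and invalid ones are rejected", {
  mods <- data.frame(position_label = "3", modification_code = "D")
  t1 <- annotated_trna("t1", "GUUGA", modifications = mods)
  expect_equal(t1$residues$modification[3], "D")
  expect_equal(trna_display_string(t1), "GUDGA")

  # D requires a U residue
  expect_error(
    annotated_trna("t2", "GGGGA",
                   modifications = data.frame(position_label = "2",
                                              modification_code = "D")),
    "requires base U")
  # unknown code is named in the error
  expect_error(
    annotated_trna("t3", "GUUGA",
                   modifications = data.frame(position_label = "2",
                                              modification_code = "m9X")),
    "m9X")
  # duplicate annotation at one label
  expect_error(
    annotated_trna("t4", "GUUGA",
                   modifications = data.frame(position_label = c("2", "2"),
                                              modification_code = c("D", "D"))),
    "duplicate")
  # annotation at a label the sequence does not have
  expect_error(
    annotated_trna("t5", "GUUGA",
                   modifications = data.frame(position_label = "47",
                                              modification_code = "D")),
    "no residue labelled")
})

test_that("insertion labels map to the expected residue index", {
  labels <- c("18", "19", "20", "20a", "21")
  t1 <- annotated_trna("t1", "GUUUA", labels = labels)
  # counted by hand over (18, 19, 20, 20a, 21): "20a" is the 4th residue
  expect_equal(label_to_index(t1, "20a"), 4L)
  expect_equal(label_to_index(t1, "18"), 1L)
  expect_error(label_to_index(t1, "47"), "47")
  # labels must increase strictly in label order
  expect_error(annotated_trna("bad", "GUUUA",
                              labels = c("18", "20a", "20", "21", "22")),
               "strictly increasing")
})

test_that("label_to_index and index_to_label are inverse over all labels", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    t1 <- trna_from_display("p", random_residue_string(n))
    labs <- t1$residues$label
    idx <- vapply(labs, function(l) label_to_index(t1, l), integer(1))
    expect_equal(unname(idx), seq_len(n))
    expect_equal(unname(index_to_label(t1, idx)), unname(labs))
  }
})

test_that("FASTA + sidecar TSV round-trips through write and read", {
  labels <- c(as.character(15:20), "20a", as.character(21:24))
  t1 <- annotated_trna("trnaA", "GUUGACUAGCU", isoacceptor = "Phe-GAA",
                       labels = labels,
                       modifications = data.frame(
                         position_label = c("16", "20a"),
                         modification_code = c("D", "D")))
  t2 <- annotated_trna("trnaB", "GGUACCGAU")
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "set.fasta")
  mo <- file.path(dir, "mods.tsv")
  la <- file.path(dir, "labels.tsv")
  write_trna_set(list(trnaA = t1, trnaB = t2), fa, mo, la)
  back <- read_trna_set(fa, mo, la)
  expect_equal(names(back), c("trnaA", "trnaB"))
  expect_equal(back$trnaA$residues, t1$residues)
  expect_equal(back$trnaA$isoacceptor, "Phe-GAA")
  expect_equal(back$trnaB$residues, t2$residues)
  # a second write of the parsed set reproduces the files byte-for-byte
  fa2 <- file.path(dir, "set2.fasta")
  mo2 <- file.path(dir, "mods2.tsv")
  write_trna_set(back, fa2, mo2)
  expect_identical(readLines(fa2), readLines(fa))
  expect_identical(readLines(mo2), readLines(mo))
})

test_that("T is normalised to U and junk characters are rejected", {
  t1 <- annotated_trna("t1", "GTTGA")
  expect_equal(paste(t1$residues$base, collapse = ""), "GUUGA")
  expect_error(annotated_trna("t2", "GUXGA"), "non-RNA")
})

test_that("the modification table is user-extensible via TSV", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "mods.tsv")
  writeLines(c("code\tparent_base\tmono_delta\tavg_delta\tribose_methyl",
               "acp3U\tU\t101.04768\t101.104\tFALSE"), path)
  tab <- read_modification_table(path)
  expect_true("acp3U" %in% tab$code)
  expect_true("D" %in% tab$code)
  t1 <- annotated_trna("t1", "GUUGA",
                       modifications = data.frame(position_label = "2",
                                                  modification_code = "acp3U"),
                       mod_table = tab)
  expect_equal(t1$residues$modification[2], "acp3U")
})
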