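# Independent oracles and fixture builders used across the test files.

# Regex-based digestion oracle: splits a single-character residue string
# after every character in `cut_set` (e.g. "G" for RNase T1; "CUD" for
# RNase A acting on C, U and dihydrouridine).
oracle_digest_strings <- function(seq_string, cut_set) {
  pat <- sprintf("[^%s]*[%s]|[^%s]+$", cut_set, cut_set, cut_set)
  unlist(regmatches(seq_string, gregexpr(pat, seq_string)))
}

# Random plain-residue string (optionally containing D) for property tests
random_residue_string <- function(len, alphabet = c("A", "C", "G", "U", "D")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Build an annotated tRNA from a display string where "D" marks
# dihydrouridine
trna_from_display <- function(id, display, labels = NULL) {
  tokens <- strsplit(display, "")[[1]]
  bases <- ifelse(tokens == "D", "U", tokens)
  d_pos <- which(tokens == "D")
  if (is.null(labels)) labels <- as.character(seq_along(tokens))
  mods <- if (length(d_pos)) {
    data.frame(position_label = labels[d_pos], modification_code = "D")
  } else NULL
  annotated_trna(id, paste(bases, collapse = ""), labels = labels,
                 modifications = mods)
}

# site_state-like records from bare calls/fractions, for attribution tests
panel_states <- function(calls, fs = NULL) {
  strains <- c("WT", "dB1", "dB2", "dB1dB2")
  if (is.null(fs)) {
    fs <- vapply(calls, function(cl) switch(cl, modified = 1, unmodified = 0,
                                            reduced = 0.5, NA_real_),
                 numeric(1))
  }
  out <- lapply(seq_along(strains), function(i) list(f = fs[i], call = calls[i]))
  names(out) <- strains
  out
}
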