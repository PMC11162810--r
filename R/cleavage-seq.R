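#' Per-position cleavage profiles
#'
#' Aniline cleavage of base-labile residues (dihydrouridine, m7G, m3C,
#' ho5C) leaves a 5'-phosphate on the residue 3' of the lesion, so a
#' read starting at position `i + 1` reports cleavage at residue `i`
#' (the "N+1" convention). A profile records, for one tRNA in one
#' sample/replicate, the per-position 5'-P read-start counts and the
#' per-position traversing coverage.
#'
#' @param trna_id Reference tRNA identifier.
#' @param counts Integer vector of read-start counts.
#' @param coverage Integer vector (same length) of traversing reads;
#'   a scalar is recycled.
#' @param sample Sample name.
#' @param replicate Replicate number.
#' @return A `cleavage_profile` object.
#' @export
cleavage_profile <- function(trna_id, counts, coverage, sample = "sample",
                             replicate = 1L) {
  counts <- as.numeric(counts)
  if (length(coverage) == 1L) coverage <- rep(coverage, length(counts))
  coverage <- as.numeric(coverage)
  if (length(counts) != length(coverage)) {
    stop("counts and coverage must have equal length")
  }
  if (any(counts < 0) || any(coverage < 0)) {
    stop("counts and coverage must be nonnegative")
  }
  if (any(counts > coverage)) {
    stop("counts cannot exceed coverage")
  }
  structure(list(trna_id = trna_id, counts = counts, coverage = coverage,
                 sample = sample, replicate = as.integer(replicate)),
            class = "cleavage_profile")
}

#' Read cleavage count tables
#'
#' TSV with columns `trna_id`, `position_index`, `read_start_count`,
#' `coverage` (one file per sample/replicate); returns one profile per
#' tRNA.
#'
#' @param path Path to the TSV.
#' @param sample,replicate Metadata attached to each profile.
#' @return Named list of [cleavage_profile()]s.
#' @export
read_cleavage_table <- function(path, sample = "sample", replicate = 1L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("trna_id", "position_index", "read_start_count", "coverage")
  if (!all(need %in% names(tab))) {
    stop("cleavage table must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(tab, tab$trna_id), function(d) {
    d <- d[order(d$position_index), ]
    if (!identical(as.integer(d$position_index), seq_len(nrow(d)))) {
      stop("position_index must run 1..n for tRNA ", d$trna_id[1])
    }
    cleavage_profile(d$trna_id[1], d$read_start_count, d$coverage,
                     sample = sample, replicate = replicate)
  })
  out
}

#' Write a cleavage count table
#'
#' @param profiles List of [cleavage_profile()]s (one sample/replicate).
#' @param path Output TSV path.
#' @export
write_cleavage_table <- function(profiles, path) {
  tab <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(trna_id = p$trna_id,
               position_index = seq_along(p$counts),
               read_start_count = p$counts, coverage = p$coverage,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

# read-start counts attributed to residues (undoes the N+1 offset):
# residue i gets the read starts at i+1; the last residue has no
# downstream read start and is NA
attributed_counts <- function(profile) {
  n <- length(profile$counts)
  c(profile$counts[-1L], NA_real_)
}

#' Cleavage signal normalised to local background (NormCount)
#'
#' The signal attributed to residue `i` (read starts at `i + 1`) is
#' divided by the median attributed count over the `window` nearest
#' flanking residues — `window/2` on each side, excluding `i` itself,
#' truncated at the molecule ends — floored at 1 count to keep the score
#' finite over empty background. A flat profile scores 1 everywhere;
#' the score is scale-free above the floor.
#'
#' @param profile A [cleavage_profile()].
#' @param position 1-based residue index to score.
#' @param window Total number of flanking residues in the background
#'   (default 10: 5 per side).
#' @return Nonnegative score.
#' @examples
#' p <- cleavage_profile("t", c(rep(2, 5), 40, rep(2, 6)), 1000)
#' normcount(p, 5)  # spike attributed to residue 5: 40 / median(2) = 20
#' @export
normcount <- function(profile, position, window = 10L) {
  att <- attributed_counts(profile)
  n <- length(att)
  if (n < 3L) stop("profile too short to score (need >= 3 positions)")
  if (position < 1L || position > n || is.na(att[position])) {
    stop("position ", position, " has no attributed read-start")
  }
  half <- ceiling(window / 2)
  flanks <- setdiff(seq(max(1L, position - half),
                        min(n, position + half)), position)
  flanks <- flanks[!is.na(att[flanks])]
  if (!length(flanks)) stop("no flanking positions available")
  att[position] / max(stats::median(att[flanks]), 1)
}

#' Cleavage stop ratio (stoichiometry proxy)
#'
#' Attributed read-start counts divided by the traversing coverage at
#' that read start; lies in [0, 1] and estimates the modified fraction
#' at the residue.
#'
#' @inheritParams normcount
#' @return Ratio in [0, 1]; `NA` (undetected) when the coverage at the
#'   attributed read start is zero.
#' @export
stop_ratio <- function(profile, position) {
  n <- length(profile$counts)
  if (position < 1L || position >= n) {
    stop("position ", position, " has no attributed read-start")
  }
  cov <- profile$coverage[position + 1L]
  if (cov == 0) return(NA_real_)
  profile$counts[position + 1L] / cov
}

#' Call modified sites from a cleavage profile
#'
#' Scores every position with an attributed read start and flags those
#' with NormCount at or above `score_threshold`. Calls are restricted to
#' U/D-capable residues (channel `"D"`); high scores at non-U residues
#' (e.g. the strong m7G46 signal) are reported in a separate `"non_U"`
#' channel rather than suppressed. Called D sites with stop ratio below
#' 1 are flagged sub-stoichiometric.
#'
#' @param profile A [cleavage_profile()].
#' @param bases Character vector of residue bases (A/C/G/U) matching the
#'   profile length, or an [annotated_trna()].
#' @param candidates Optional indices to restrict the D-channel calls
#'   (default: all U residues).
#' @param score_threshold Minimum NormCount for a call (> 1).
#' @param window Background window for [normcount()].
#' @return data.frame with columns `position`, `base`, `normcount`,
#'   `stop_ratio`, `channel`, `substoichiometric`.
#' @export
call_sites <- function(profile, bases, candidates = NULL,
                       score_threshold = 5, window = 10L) {
  stopifnot(score_threshold > 1)
  if (inherits(bases, "annotated_trna")) bases <- bases$residues$base
  n <- length(profile$counts)
  if (length(bases) != n) {
    stop("bases length (", length(bases), ") != profile length (", n, ")")
  }
  scoreable <- seq_len(n - 1L)
  if (is.null(candidates)) candidates <- which(bases == "U")
  rows <- lapply(scoreable, function(i) {
    sc <- normcount(profile, i, window)
    if (sc < score_threshold) return(NULL)
    is_u <- bases[i] == "U" && i %in% candidates
    sr <- stop_ratio(profile, i)
    data.frame(position = i, base = bases[i], normcount = sc,
               stop_ratio = sr,
               channel = if (is_u) "D" else "non_U",
               substoichiometric = !is.na(sr) && sr < 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(position = integer(), base = character(),
                      normcount = numeric(), stop_ratio = numeric(),
                      channel = character(), substoichiometric = logical())
  }
  out
}

#' Site-by-sample stoichiometry matrix
#'
#' Builds the heatmap matrix of stop ratios: one row per called site,
#' one column per sample, averaging replicates; the per-replicate values
#' are retained in attribute `"replicates"` (site x sample x replicate
#' array). Missing replicates are `NA`, distinct from a measured zero.
#'
#' @param profiles List of [cleavage_profile()]s for one tRNA across
#'   samples and replicates.
#' @param sites Integer vector of residue positions.
#' @return Numeric matrix `length(sites)` x n_samples with dimnames.
#' @export
heatmap_matrix <- function(profiles, sites) {
  lens <- vapply(profiles, function(p) length(p$counts), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("profiles have inconsistent reference lengths")
  }
  samples <- unique(vapply(profiles, `[[`, character(1), "sample"))
  reps <- sort(unique(vapply(profiles, `[[`, integer(1), "replicate")))
  arr <- array(NA_real_,
               dim = c(length(sites), length(samples), length(reps)),
               dimnames = list(site = as.character(sites), sample = samples,
                               replicate = as.character(reps)))
  for (p in profiles) {
    j <- match(p$sample, samples)
    k <- match(p$replicate, reps)
    for (s in seq_along(sites)) {
      arr[s, j, k] <- stop_ratio(p, sites[s])
    }
  }
  mat <- apply(arr, c(1, 2), function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  dimnames(mat) <- dimnames(arr)[1:2]
  attr(mat, "replicates") <- arr
  mat
}

#' Dose-response of cleavage signal over an enzyme titration
#'
#' Orders the NormCount at one site by enzyme concentration and reports
#' whether the trend is monotone non-decreasing (rank concordance 1);
#' constant series are monotone but flagged flat.
#'
#' @param profiles List of [cleavage_profile()]s, one per concentration.
#' @param position Residue index scored.
#' @param concentrations Numeric vector of enzyme concentrations
#'   matching `profiles`.
#' @param window Background window for [normcount()].
#' @return List with `concentration`, `score` (both sorted by
#'   concentration), `monotone`, `flat`.
#' @export
dose_response <- function(profiles, position, concentrations, window = 10L) {
  if (length(profiles) < 3L) stop("need >= 3 concentrations")
  if (length(concentrations) != length(profiles)) {
    stop("one concentration per profile required")
  }
  o <- order(concentrations)
  scores <- vapply(profiles[o], normcount, numeric(1), position = position,
                   window = window)
  flat <- length(unique(scores)) == 1L
  monotone <- all(diff(scores) >= 0)
  list(concentration = concentrations[o], score = scores,
       monotone = monotone, flat = flat)
}

#' Knockout-panel attribution from sequencing stoichiometries
#'
#' Converts the four strain columns of a stop-ratio panel into site
#' states and reuses the MALDI attribution grid. Stop ratios are
#' sub-stoichiometric even at fully attributed sites, so each column is
#' first normalised to the wild-type value (capped at 1) before the
#' modified/reduced/unmodified thresholds apply; a wild-type ratio of
#' zero (or NA) means no modification to attribute.
#'
#' @param ratios Named numeric vector of stop ratios over `WT`, `dB1`,
#'   `dB2`, `dB1dB2`.
#' @param preference_margin See [decide_attribution()].
#' @return Attribution string as for [decide_attribution()].
#' @examples
#' panel_attribution_from_seq(c(WT = .4, dB1 = 0, dB2 = .4, dB1dB2 = 0))
#' @export
panel_attribution_from_seq <- function(ratios, preference_margin = 0.3) {
  need <- c("WT", "dB1", "dB2", "dB1dB2")
  if (!all(need %in% names(ratios))) {
    stop("ratios must be named over ", paste(need, collapse = ", "))
  }
  wt <- ratios[["WT"]]
  if (is.na(wt) || wt <= 0) return("none")
  states <- lapply(need, function(s) {
    r <- ratios[[s]]
    if (is.na(r)) return(list(f = NA_real_, call = "undetected"))
    f <- min(r / wt, 1)
    list(f = f, call = if (f >= 0.8) "modified"
                       else if (f <= 0.1) "unmodified" else "reduced")
  })
  names(states) <- need
  decide_attribution(states, preference_margin)
}
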