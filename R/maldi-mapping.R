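#' Read a MALDI peak list
#'
#' Two-column TSV (`mz`, `intensity`), one file per strain.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `mz` and `intensity`.
#' @export
read_peak_list <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(tab))) {
    stop("peak list ", path, " must have columns mz, intensity")
  }
  if (any(tab$mz <= 0) || any(tab$intensity < 0)) {
    stop("peak list ", path, ": mz must be positive, intensity nonnegative")
  }
  tab[c("mz", "intensity")]
}

#' Select diagnostic fragments for candidate D sites
#'
#' A candidate site is monitorable by MALDI when some digest fragment
#' contains it and no other candidate site, and when neither member of
#' its D/U mass pair collides (within `tolerance_da`) with any other
#' fragment of the same digest. For each site the smallest such fragment
#' is selected; sites with no passing fragment are reported as
#' unmonitorable.
#'
#' The D/U pair masses are computed with the site residue set to
#' dihydrouridine and to plain uridine respectively, other modifications
#' untouched, at the fragment's own termini (digestion products: 5'-OH,
#' 3'-phosphate).
#'
#' @param trna An [annotated_trna()].
#' @param enzyme `"RNaseT1"`, `"RNaseA"` or a [cleavage_rule()].
#' @param candidate_sites Character vector of position labels of U/D
#'   residues to monitor; defaults to all dihydrouridine-annotated
#'   residues.
#' @param tolerance_da Peak-matching tolerance in Da.
#' @param spec A [mass_spec()]; exact masses are used for collision
#'   checks regardless of its rounding.
#' @param mod_table Modification registry.
#' @return data.frame with one row per monitorable site: `trna_id`,
#'   `site`, `fragment`, `start_label`, `end_label`, `mz_modified`,
#'   `mz_unmodified`; unmonitorable site labels are attached as
#'   attribute `"unmonitorable"`.
#' @export
select_diagnostics <- function(trna, enzyme, candidate_sites = NULL,
                               tolerance_da = 0.5, spec = mass_spec(),
                               mod_table = default_modification_table()) {
  res <- trna$residues
  if (is.null(candidate_sites)) {
    candidate_sites <- res$label[!is.na(res$modification) &
                                   res$modification == "D"]
  }
  idx <- vapply(candidate_sites, function(l) label_to_index(trna, l),
                integer(1))
  if (any(res$base[idx] != "U")) {
    stop("candidate sites must be U/D residues")
  }
  exact <- mass_spec(spec$mode, spec$adduct, "exact")

  frags <- digest(trna, enzyme)
  spans <- lapply(frags, function(f) {
    c(position_label_key(f$start_label), position_label_key(f$end_label))
  })
  frag_mass <- vapply(frags, fragment_mass, numeric(1), spec = exact,
                      mod_table = mod_table)
  site_keys <- position_label_key(candidate_sites)

  variant_mass <- function(f, site_label, code) {
    i <- which(f$residues$label == site_label)
    f$residues$modification[i] <- code
    fragment_mass(f, exact, mod_table)
  }

  rows <- list()
  unmonitorable <- character()
  for (s in seq_along(candidate_sites)) {
    site <- candidate_sites[s]
    key <- site_keys[s]
    covering <- which(vapply(spans, function(sp) sp[1] <= key && key <= sp[2],
                             logical(1)))
    # smallest fragment first
    covering <- covering[order(vapply(covering, function(i) {
      nrow(frags[[i]]$residues)
    }, numeric(1)))]
    chosen <- NULL
    for (i in covering) {
      f <- frags[[i]]
      n_cand <- sum(site_keys >= position_label_key(f$start_label) &
                      site_keys <= position_label_key(f$end_label))
      if (n_cand != 1L) next
      mz_mod <- variant_mass(f, site, "D")
      mz_unmod <- variant_mass(f, site, NA_character_)
      others <- frag_mass[-i]
      if (any(abs(others - mz_mod) <= tolerance_da) ||
          any(abs(others - mz_unmod) <= tolerance_da)) next
      chosen <- data.frame(trna_id = trna$id, site = site,
                           fragment = fragment_string(f),
                           start_label = f$start_label,
                           end_label = f$end_label,
                           mz_modified = mz_mod, mz_unmodified = mz_unmod,
                           stringsAsFactors = FALSE)
      break
    }
    if (is.null(chosen)) unmonitorable <- c(unmonitorable, site)
    else rows[[length(rows) + 1L]] <- chosen
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trna_id = character(), site = character(),
               fragment = character(), start_label = character(),
               end_label = character(), mz_modified = numeric(),
               mz_unmodified = numeric(), stringsAsFactors = FALSE)
  attr(out, "unmonitorable") <- unmonitorable
  out
}

#' Match observed peaks to diagnostic mass pairs
#'
#' Each observed peak is assigned to the nearest theoretical mass
#' (across all diagnostics' modified and unmodified members) within
#' `tolerance_da`; intensities assigned to the same member are summed.
#' Peaks matching nothing are ignored.
#'
#' @param peaks data.frame with columns `mz`, `intensity`.
#' @param diagnostics Output of [select_diagnostics()].
#' @param tolerance_da Tolerance in Da (> 0).
#' @return `diagnostics` with added columns `I_mod`, `I_unmod`.
#' @export
match_peaks <- function(peaks, diagnostics, tolerance_da = 0.5) {
  stopifnot(tolerance_da > 0)
  nd <- nrow(diagnostics)
  targets <- c(diagnostics$mz_modified, diagnostics$mz_unmodified)
  acc <- numeric(length(targets))
  if (nrow(peaks) && length(targets)) {
    for (p in seq_len(nrow(peaks))) {
      d <- abs(targets - peaks$mz[p])
      b <- which.min(d)
      if (d[b] <= tolerance_da) acc[b] <- acc[b] + peaks$intensity[p]
    }
  }
  diagnostics$I_mod <- acc[seq_len(nd)]
  diagnostics$I_unmod <- acc[nd + seq_len(nd)]
  diagnostics
}

#' Call the modification state of one site in one strain
#'
#' The modified fraction is `f = I_mod / (I_mod + I_unmod)`. A site is
#' `undetected` when the summed pair intensity falls below `floor`
#' (conventionally 5% of the spectrum's median peak intensity);
#' otherwise it is called `modified` (f >= 0.8), `unmodified`
#' (f <= 0.1), or `reduced` in between. MALDI intensities are relative
#' within one spectrum, so only this ratio is interpreted.
#'
#' @param I_mod,I_unmod Summed intensities of the modified/unmodified
#'   pair members.
#' @param floor Detection floor on `I_mod + I_unmod`.
#' @param modified_min,unmodified_max Call thresholds on f.
#' @return List with `f` (NA when undetected) and `call`.
#' @examples
#' site_state(100, 0)$call   # "modified"
#' site_state(30, 70)$call   # "reduced"
#' @export
site_state <- function(I_mod, I_unmod, floor = 0,
                       modified_min = 0.8, unmodified_max = 0.1) {
  stopifnot(I_mod >= 0, I_unmod >= 0)
  total <- I_mod + I_unmod
  if (total <= floor || total == 0) {
    return(list(f = NA_real_, call = "undetected"))
  }
  f <- I_mod / total
  call <- if (f >= modified_min) "modified"
          else if (f <= unmodified_max) "unmodified"
          else "reduced"
  list(f = f, call = call)
}

#' Detection floor for a peak list
#'
#' 5% of the median peak intensity of the spectrum.
#'
#' @param peaks data.frame with column `intensity`.
#' @param fraction Fraction of the median used as floor.
#' @export
detection_floor <- function(peaks, fraction = 0.05) {
  if (!nrow(peaks)) return(0)
  fraction * stats::median(peaks$intensity)
}

#' Attribute a site to its synthase from a knockout-panel of states
#'
#' Given the per-strain states of one site across wild type, the two
#' single synthase knockouts and the double knockout, the grid decides
#' which enzyme(s) install the modification. Rules apply in order:
#' \enumerate{
#'   \item wild type unmodified (or undetected): no modification —
#'     `none`.
#'   \item double knockout still modified: `inconsistent` (flags
#'     contamination or mis-assignment).
#'   \item present in the B2 knockout but absent in the B1 knockout:
#'     `B1_only`.
#'   \item present in the B1 knockout but absent in the B2 knockout:
#'     `B2_only`.
#'   \item present (modified or reduced) in both single knockouts and
#'     absent in the double: `redundant`; when one single-knockout
#'     modified fraction is lower by more than `preference_margin`, the
#'     deleted enzyme of the lower strain contributed more —
#'     `redundant_B1_preferred` / `redundant_B2_preferred`.
#' }
#' Any other pattern is `inconsistent`.
#'
#' @param states Named list over `WT`, `dB1`, `dB2`, `dB1dB2`; each
#'   element a [site_state()] result (fields `f`, `call`).
#' @param preference_margin Minimum difference in single-knockout `f`
#'   for a preference call.
#' @return One of `"none"`, `"B1_only"`, `"B2_only"`, `"redundant"`,
#'   `"redundant_B1_preferred"`, `"redundant_B2_preferred"`,
#'   `"inconsistent"`.
#' @export
decide_attribution <- function(states, preference_margin = 0.3) {
  need <- c("WT", "dB1", "dB2", "dB1dB2")
  if (!all(need %in% names(states))) {
    stop("missing strain state(s): ",
         paste(setdiff(need, names(states)), collapse = ", "))
  }
  call_of <- function(s) states[[s]]$call
  f_of <- function(s) states[[s]]$f
  absent <- function(s) call_of(s) %in% c("unmodified", "undetected")
  present <- function(s) call_of(s) %in% c("modified", "reduced")

  if (absent("WT")) return("none")
  if (call_of("dB1dB2") == "modified") return("inconsistent")
  if (call_of("dB2") == "modified" && absent("dB1")) return("B1_only")
  if (call_of("dB1") == "modified" && absent("dB2")) return("B2_only")
  if (present("dB1") && present("dB2") && absent("dB1dB2")) {
    f1 <- f_of("dB1"); f2 <- f_of("dB2")
    if (is.finite(f1) && is.finite(f2)) {
      if (f2 <= f1 - preference_margin) return("redundant_B2_preferred")
      if (f1 <= f2 - preference_margin) return("redundant_B1_preferred")
    }
    return("redundant")
  }
  "inconsistent"
}

#' Per-site knockout-panel attribution from MALDI peak lists
#'
#' Runs the full analytical grid for one tRNA: select diagnostic
#' fragments, match each strain's peak list, call per-strain states and
#' attribute each site.
#'
#' @param trna An [annotated_trna()].
#' @param peak_lists Named list of peak data.frames over `WT`, `dB1`,
#'   `dB2`, `dB1dB2`.
#' @param enzyme Digestion enzyme.
#' @param tolerance_da Peak-matching tolerance in Da.
#' @param candidate_sites Optional site labels (default: D-annotated).
#' @param preference_margin See [decide_attribution()].
#' @param mod_table Modification registry.
#' @return data.frame with columns `trna_id`, `site`, `f_WT`, `f_dB1`,
#'   `f_dB2`, `f_dB1dB2`, and `attribution`.
#' @export
attribute_panel <- function(trna, peak_lists, enzyme = "RNaseT1",
                            tolerance_da = 0.5, candidate_sites = NULL,
                            preference_margin = 0.3,
                            mod_table = default_modification_table()) {
  strains <- c("WT", "dB1", "dB2", "dB1dB2")
  if (!all(strains %in% names(peak_lists))) {
    stop("peak_lists must be named over ", paste(strains, collapse = ", "))
  }
  diags <- select_diagnostics(trna, enzyme, candidate_sites,
                              tolerance_da = tolerance_da,
                              mod_table = mod_table)
  if (!nrow(diags)) {
    out <- data.frame(trna_id = character(), site = character(),
                      f_WT = numeric(), f_dB1 = numeric(), f_dB2 = numeric(),
                      f_dB1dB2 = numeric(), attribution = character())
    attr(out, "unmonitorable") <- attr(diags, "unmonitorable")
    return(out)
  }
  state_tab <- lapply(strains, function(s) {
    matched <- match_peaks(peak_lists[[s]], diags, tolerance_da)
    floor_s <- detection_floor(peak_lists[[s]])
    lapply(seq_len(nrow(matched)), function(r) {
      site_state(matched$I_mod[r], matched$I_unmod[r], floor = floor_s)
    })
  })
  names(state_tab) <- strains

  out <- data.frame(trna_id = diags$trna_id, site = diags$site,
                    f_WT = NA_real_, f_dB1 = NA_real_, f_dB2 = NA_real_,
                    f_dB1dB2 = NA_real_, attribution = NA_character_,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(diags))) {
    states <- lapply(state_tab, `[[`, r)
    out$f_WT[r] <- states$WT$f
    out$f_dB1[r] <- states$dB1$f
    out$f_dB2[r] <- states$dB2$f
    out$f_dB1dB2[r] <- states$dB1dB2$f
    out$attribution[r] <- decide_attribution(states, preference_margin)
  }
  attr(out, "unmonitorable") <- attr(diags, "unmonitorable")
  out
}

#' Write a panel attribution report
#'
#' TSV of the per-site table plus a JSON summary (attribution counts and
#' unmonitorable sites).
#'
#' @param panel Output of [attribute_panel()] (possibly row-bound over
#'   tRNAs).
#' @param tsv_path,json_path Output paths (either may be NULL).
#' @export
write_panel_report <- function(panel, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(panel, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    summary <- list(
      n_sites = nrow(panel),
      attribution_counts = as.list(table(panel$attribution)),
      unmonitorable = as.character(attr(panel, "unmonitorable")))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(panel)
}
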