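# Element masses: monoisotopic from IUPAC/CODATA, average from standard
# atomic weights. 5-decimal precision is ample for nominal-integer MALDI
# work on oligonucleotides.
.element_mono <- c(C = 12.00000, H = 1.00783, N = 14.00307, O = 15.99491,
                   P = 30.97376)
.element_avg <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.974)
.proton_mass <- 1.00728

# elemental composition of ribonucleoside-3'-monophosphates (free acid)
.nmp_formula <- list(
  A = c(C = 10, H = 14, N = 5, O = 7, P = 1),
  G = c(C = 10, H = 14, N = 5, O = 8, P = 1),
  C = c(C = 9,  H = 14, N = 3, O = 8, P = 1),
  U = c(C = 9,  H = 13, N = 2, O = 9, P = 1))

formula_mass <- function(formula, mode) {
  el <- if (mode == "monoisotopic") .element_mono else .element_avg
  sum(el[names(formula)] * formula)
}

nmp_mass <- function(base, mode) {
  vapply(base, function(b) formula_mass(.nmp_formula[[b]], mode), numeric(1))
}

water_mass <- function(mode) formula_mass(c(H = 2, O = 1), mode)
hpo3_mass <- function(mode) formula_mass(c(H = 1, P = 1, O = 3), mode)

#' Mass-spectrometry conventions
#'
#' Bundles the three choices that fix how a fragment mass is reported:
#' monoisotopic vs average masses, the adduct (positive-mode MALDI of
#' oligonucleotides observes the singly protonated `[M+H]+`; `[M-H]-`
#' and the neutral mass are also available), and rounding (`"exact"`, or
#' `"nominal"` integer m/z as printed on MALDI peak labels, rounding
#' half away from zero).
#'
#' @param mode `"monoisotopic"` or `"average"`.
#' @param adduct `"M+H"`, `"M-H"` or `"neutral"`.
#' @param rounding `"exact"` or `"nominal"`.
#' @return A `mass_spec` object.
#' @examples
#' fragment_mass(fragment_from_string("UDG"), mass_spec(rounding = "nominal"))
#' @export
mass_spec <- function(mode = c("monoisotopic", "average"),
                      adduct = c("M+H", "M-H", "neutral"),
                      rounding = c("exact", "nominal")) {
  structure(list(mode = match.arg(mode), adduct = match.arg(adduct),
                 rounding = match.arg(rounding)),
            class = "mass_spec")
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Mass of a modified oligonucleotide fragment
#'
#' The neutral mass is the sum of the residues'
#' nucleoside-3'-monophosphate masses (parent base plus modification
#' delta) minus one water per phosphodiester bond, adjusted for terminal
#' chemistry: the bare sum describes a 5'-OH/3'-phosphate fragment, so
#' 3'-OH subtracts HPO3, a 2',3'-cyclic phosphate subtracts water, and a
#' 5'-phosphate adds HPO3. The adduct then adds/removes a proton.
#'
#' @param fragment An `rna_fragment` (see [digest()],
#'   [fragment_from_string()]).
#' @param spec A [mass_spec()].
#' @param mod_table Modification registry supplying mass deltas.
#' @return Mass in Da (m/z for the charged adducts).
#' @examples
#' nominal <- mass_spec(rounding = "nominal")
#' fragment_mass(fragment_from_string("UDG"), nominal)  # 978
#' fragment_mass(fragment_from_string("UUG"), nominal)  # 976
#' @export
fragment_mass <- function(fragment, spec = mass_spec(),
                          mod_table = default_modification_table()) {
  res <- fragment$residues
  if (nrow(res) == 0L) stop("empty fragment")
  mode <- spec$mode
  delta_col <- if (mode == "monoisotopic") "mono_delta" else "avg_delta"
  m <- sum(nmp_mass(res$base, mode))
  has_mod <- !is.na(res$modification)
  if (any(has_mod)) {
    m <- m + sum(mod_lookup(res$modification[has_mod], mod_table, delta_col))
  }
  m <- m - (nrow(res) - 1L) * water_mass(mode)
  m <- m + switch(fragment$three_prime,
                  phosphate = 0,
                  OH = -hpo3_mass(mode),
                  cyclic_phosphate = -water_mass(mode),
                  stop("unknown 3' chemistry: ", fragment$three_prime))
  m <- m + switch(fragment$five_prime,
                  OH = 0,
                  P = hpo3_mass(mode),
                  stop("unknown 5' chemistry: ", fragment$five_prime))
  m <- m + switch(spec$adduct,
                  "M+H" = .proton_mass,
                  "M-H" = -.proton_mass,
                  neutral = 0)
  if (spec$rounding == "nominal") round_half_away(m) else m
}

#' Mass difference between two fragments of equal base composition
#'
#' For fragments identical except in their modification codes, the
#' difference is exactly the sum of modification-delta differences; one
#' dihydrouridine versus uridine gives +2.01565 Da monoisotopic — the
#' MALDI diagnostic -2 Da shift seen when a D site reverts to U in a
#' synthase knockout.
#'
#' @param frag_modified,frag_unmodified `rna_fragment`s of equal length,
#'   same bases and termini.
#' @inheritParams fragment_mass
#' @return Mass difference (modified minus unmodified) in Da.
#' @export
mass_delta <- function(frag_modified, frag_unmodified, spec = mass_spec(),
                       mod_table = default_modification_table()) {
  a <- frag_modified$residues
  b <- frag_unmodified$residues
  if (nrow(a) != nrow(b) || any(a$base != b$base)) {
    stop("fragments differ in base composition, not only in modifications")
  }
  if (frag_modified$five_prime != frag_unmodified$five_prime ||
      frag_modified$three_prime != frag_unmodified$three_prime) {
    stop("fragments differ in terminal chemistry")
  }
  exact <- mass_spec(spec$mode, "neutral", "exact")
  d <- fragment_mass(frag_modified, exact, mod_table) -
    fragment_mass(frag_unmodified, exact, mod_table)
  if (spec$rounding == "nominal") round_half_away(d) else d
}

#' Find fragment pairs with indistinguishable masses
#'
#' Guards diagnostic-fragment uniqueness: two digest products closer
#' than the instrument tolerance cannot be told apart on the spectrum.
#'
#' @param fragments List of `rna_fragment`s.
#' @param spec A [mass_spec()].
#' @param tolerance_da Mass tolerance in Da (> 0).
#' @inheritParams fragment_mass
#' @return data.frame with columns `i`, `j` (list indices), `mass_i`,
#'   `mass_j` for every unordered pair within tolerance.
#' @export
collision_check <- function(fragments, spec = mass_spec(), tolerance_da = 0.5,
                            mod_table = default_modification_table()) {
  stopifnot(tolerance_da > 0)
  n <- length(fragments)
  masses <- vapply(fragments, fragment_mass, numeric(1), spec = spec,
                   mod_table = mod_table)
  out <- data.frame(i = integer(), j = integer(),
                    mass_i = numeric(), mass_j = numeric())
  if (n < 2L) return(out)
  pairs <- utils::combn(n, 2L)
  hit <- abs(masses[pairs[1L, ]] - masses[pairs[2L, ]]) <= tolerance_da
  data.frame(i = pairs[1L, hit], j = pairs[2L, hit],
             mass_i = masses[pairs[1L, hit]], mass_j = masses[pairs[2L, hit]])
}

#' Write a theoretical-peak table
#'
#' TSV with columns fragment, composition, neutral_mass, mz_MplusH,
#' nominal_mz for a list of fragments.
#'
#' @param fragments List of `rna_fragment`s.
#' @param path Output TSV path.
#' @inheritParams fragment_mass
#' @export
write_peak_table <- function(fragments, path,
                             mod_table = default_modification_table()) {
  neutral <- mass_spec(adduct = "neutral")
  mh <- mass_spec(adduct = "M+H")
  nominal <- mass_spec(adduct = "M+H", rounding = "nominal")
  tab <- data.frame(
    fragment = vapply(fragments, fragment_string, character(1)),
    composition = vapply(fragments, function(f) {
      paste(sort(residue_display(f$residues)), collapse = "")
    }, character(1)),
    neutral_mass = vapply(fragments, fragment_mass, numeric(1), spec = neutral,
                          mod_table = mod_table),
    mz_MplusH = vapply(fragments, fragment_mass, numeric(1), spec = mh,
                       mod_table = mod_table),
    nominal_mz = vapply(fragments, fragment_mass, numeric(1), spec = nominal,
                        mod_table = mod_table),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
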