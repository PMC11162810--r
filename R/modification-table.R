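#' Modification table
#'
#' Registry of the RNA modifications the package understands, keyed by
#' MODOMICS-style short names. Each entry records the parent base, its
#' monoisotopic and average mass shifts relative to the unmodified
#' residue, and whether the ribose carries a 2'-O-methyl group (which
#' blocks the transesterification step of RNase T1 and RNase A cleavage).
#'
#' Dihydrouridine ("D") is uridine with a saturated C5=C6 bond: two extra
#' hydrogens, +2.01565 Da monoisotopic relative to U. That -2/+2 Da pair
#' is the diagnostic exploited by MALDI mapping of knockout panels.
#'
#' @return A data.frame with columns `code`, `parent_base`,
#'   `mono_delta`, `avg_delta`, `ribose_methyl`.
#' @examples
#' tab <- default_modification_table()
#' tab[tab$code == "D", ]
#' @export
default_modification_table <- function() {
  # deltas: CH2 = 14.01565 / 14.027 (methylations), 2H = 2.01565 / 2.016,
  # O = 15.99491 / 15.999 (hydroxylation); psi is mass-silent.
  tab <- rbind(
    data.frame(code = "D",    parent_base = "U", mono_delta = 2.01565,  avg_delta = 2.016,  ribose_methyl = FALSE),
    data.frame(code = "psi",  parent_base = "U", mono_delta = 0.0,      avg_delta = 0.0,    ribose_methyl = FALSE),
    data.frame(code = "m5U",  parent_base = "U", mono_delta = 14.01565, avg_delta = 14.027, ribose_methyl = FALSE),
    data.frame(code = "m7G",  parent_base = "G", mono_delta = 14.01565, avg_delta = 14.027, ribose_methyl = FALSE),
    data.frame(code = "m1A",  parent_base = "A", mono_delta = 14.01565, avg_delta = 14.027, ribose_methyl = FALSE),
    data.frame(code = "m6A",  parent_base = "A", mono_delta = 14.01565, avg_delta = 14.027, ribose_methyl = FALSE),
    data.frame(code = "m3C",  parent_base = "C", mono_delta = 14.01565, avg_delta = 14.027, ribose_methyl = FALSE),
    data.frame(code = "m5C",  parent_base = "C", mono_delta = 14.01565, avg_delta = 14.027, ribose_methyl = FALSE),
    data.frame(code = "ho5C", parent_base = "C", mono_delta = 15.99491, avg_delta = 15.999, ribose_methyl = FALSE),
    data.frame(code = "Um",   parent_base = "U", mono_delta = 14.01565, avg_delta = 14.027, ribose_methyl = TRUE),
    data.frame(code = "Cm",   parent_base = "C", mono_delta = 14.01565, avg_delta = 14.027, ribose_methyl = TRUE),
    data.frame(code = "Gm",   parent_base = "G", mono_delta = 14.01565, avg_delta = 14.027, ribose_methyl = TRUE),
    data.frame(code = "Am",   parent_base = "A", mono_delta = 14.01565, avg_delta = 14.027, ribose_methyl = TRUE)
  )
  tab
}

#' Read a user modification table
#'
#' Extends (or overrides) the built-in registry from a TSV with columns
#' `code`, `parent_base`, `mono_delta`, `avg_delta` and optional
#' `ribose_methyl` (TRUE/FALSE, default FALSE).
#'
#' @param path Path to the TSV.
#' @param base Table to extend; defaults to [default_modification_table()].
#' @return The merged modification table; user rows win on code clashes.
#' @export
read_modification_table <- function(path, base = default_modification_table()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("code", "parent_base", "mono_delta", "avg_delta")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("modification table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(tab$ribose_methyl)) tab$ribose_methyl <- FALSE
  tab$ribose_methyl <- as.logical(tab$ribose_methyl)
  if (!all(tab$parent_base %in% c("A", "C", "G", "U"))) {
    stop("parent_base must be one of A, C, G, U")
  }
  keep <- base[!base$code %in% tab$code, , drop = FALSE]
  rbind(keep, tab[names(base)])
}

mod_lookup <- function(code, table, column) {
  i <- match(code, table$code)
  if (anyNA(i)) {
    stop("unknown modification code(s): ",
         paste(unique(code[is.na(i)]), collapse = ", "))
  }
  table[[column]][i]
}
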