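#' Cleavage rules for in silico RNase digestion
#'
#' RNase T1 cleaves 3' of guanosine (including 7-methylguanosine, whose
#' Watson-Crick face is unchanged); RNase A cleaves 3' of pyrimidines —
#' C, U and dihydrouridine, whose saturated ring still presents the
#' 2'-OH/cyclising geometry the enzyme needs. Both enzymes proceed via
#' transesterification through the 2'-OH, so 2'-O-methylated residues
#' (codes flagged `ribose_methyl` in the modification table, e.g. Um,
#' Cm, Gm) are resistant by default. Both leave a linear 3'-phosphate on
#' the upstream product and a 5'-OH on the downstream one.
#'
#' @param enzyme `"RNaseT1"` or `"RNaseA"`.
#' @param resistant_codes Modification codes that block cleavage at their
#'   residue; defaults to the 2'-O-methyl codes of `mod_table`.
#' @param mod_table Modification registry.
#' @return A `cleavage_rule` object (enzyme name, target bases, resistant
#'   code set).
#' @export
cleavage_rule <- function(enzyme = c("RNaseT1", "RNaseA"),
                          resistant_codes = NULL,
                          mod_table = default_modification_table()) {
  enzyme <- match.arg(enzyme)
  if (is.null(resistant_codes)) {
    resistant_codes <- mod_table$code[mod_table$ribose_methyl]
  }
  structure(list(enzyme = enzyme,
                 target_bases = switch(enzyme,
                                       RNaseT1 = "G",
                                       RNaseA = c("C", "U")),
                 cleaves_after_D = (enzyme == "RNaseA"),
                 resistant_codes = resistant_codes),
            class = "cleavage_rule")
}

# TRUE where cleavage occurs 3' of each residue
rule_cuts_after <- function(rule, residues) {
  base_ok <- residues$base %in% rule$target_bases
  if (rule$cleaves_after_D) {
    base_ok <- base_ok | (!is.na(residues$modification) &
                            residues$modification == "D")
  }
  resistant <- !is.na(residues$modification) &
    residues$modification %in% rule$resistant_codes
  base_ok & !resistant
}

new_fragment <- function(residues, parent_id, five_prime, three_prime) {
  stopifnot(nrow(residues) > 0L)
  structure(list(residues = residues,
                 parent_id = parent_id,
                 start_label = residues$label[1L],
                 end_label = residues$label[nrow(residues)],
                 five_prime = five_prime,
                 three_prime = three_prime),
            class = "rna_fragment")
}

#' @export
print.rna_fragment <- function(x, ...) {
  cat("fragment ", fragment_string(x), " [", x$parent_id, " ",
      x$start_label, "-", x$end_label, ", 5'-", x$five_prime, ", 3'-",
      x$three_prime, "]\n", sep = "")
  invisible(x)
}

#' Fragment sequence string
#'
#' Residues print as their base letter, dihydrouridine as `D`, other
#' modifications as their bracketed code (`"[m7G]"`).
#'
#' @param fragment An `rna_fragment`.
#' @export
fragment_string <- function(fragment) {
  paste(residue_display(fragment$residues), collapse = "")
}

#' Build a fragment directly from a sequence string
#'
#' Accepts A/C/G/U letters, `D` for dihydrouridine, and bracketed
#' modification codes (`"U[m5U]G"` reads as U, m5U-modified U, G). Useful
#' for mass calculations on fragments quoted as strings.
#'
#' @param string Fragment sequence, e.g. `"UDG"`.
#' @param five_prime `"OH"` or `"P"`; digestion products carry 5'-OH.
#' @param three_prime `"phosphate"`, `"cyclic_phosphate"` or `"OH"`.
#' @param parent_id Provenance id recorded on the fragment.
#' @param mod_table Modification registry.
#' @return An `rna_fragment`.
#' @examples
#' frag <- fragment_from_string("UDG")
#' fragment_string(frag)
#' @export
fragment_from_string <- function(string, five_prime = "OH",
                                 three_prime = "phosphate",
                                 parent_id = "adhoc",
                                 mod_table = default_modification_table()) {
  stopifnot(is.character(string), length(string) == 1L, nzchar(string))
  tokens <- regmatches(string, gregexpr("\\[[^]]+\\]|.", string))[[1]]
  base <- character(length(tokens))
  modification <- rep(NA_character_, length(tokens))
  for (k in seq_along(tokens)) {
    tok <- tokens[k]
    if (startsWith(tok, "[")) {
      code <- substr(tok, 2L, nchar(tok) - 1L)
      base[k] <- mod_lookup(code, mod_table, "parent_base")
      modification[k] <- code
    } else if (tok == "D") {
      base[k] <- "U"
      modification[k] <- "D"
    } else if (tok %in% c("A", "C", "G", "U", "T")) {
      base[k] <- if (tok == "T") "U" else tok
    } else {
      stop("unrecognised residue token: ", tok)
    }
  }
  res <- data.frame(base = base, modification = modification,
                    label = as.character(seq_along(base)),
                    stringsAsFactors = FALSE)
  new_fragment(res, parent_id, five_prime, three_prime)
}

#' In silico RNase digestion of an annotated tRNA
#'
#' Cuts 3' of every residue satisfying the cleavage rule (and not
#' carrying a resistant modification). The complete-digest fragments
#' partition the sequence; with `missed_cleavages = k` every union of up
#' to `k + 1` adjacent complete fragments is additionally returned.
#' Internal fragments carry 5'-OH and a linear 3'-phosphate; the
#' parent's first fragment keeps the parent 5' chemistry (mature tRNA:
#' 5'-P) and the 3'-terminal fragment keeps the parent's 3'-OH (no
#' downstream phosphate acceptor exists at the molecule end).
#'
#' @param trna An [annotated_trna()].
#' @param enzyme `"RNaseT1"`, `"RNaseA"`, or a [cleavage_rule()].
#' @param missed_cleavages Nonnegative integer.
#' @param parent_five_prime 5' chemistry of the intact tRNA.
#' @return List of `rna_fragment` objects, complete-digest fragments
#'   first in sequence order, then unions by increasing span.
#' @examples
#' t1 <- annotated_trna("t1", "GUUGA",
#'   modifications = data.frame(position_label = "3", modification_code = "D"))
#' sapply(digest(t1, "RNaseT1"), fragment_string)
#' @export
digest <- function(trna, enzyme, missed_cleavages = 0L,
                   parent_five_prime = "P") {
  rule <- if (inherits(enzyme, "cleavage_rule")) enzyme else cleavage_rule(enzyme)
  stopifnot(missed_cleavages >= 0L)
  res <- trna$residues
  n <- nrow(res)
  cuts <- which(rule_cuts_after(rule, res))
  cuts <- cuts[cuts < n]                      # cutting after the 3' end is a no-op
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  nfrag <- length(starts)

  piece <- function(i, j) {
    first <- (i == 1L)
    last_res <- ends[j]
    new_fragment(res[starts[i]:last_res, , drop = FALSE], trna$id,
                 five_prime = if (first) parent_five_prime else "OH",
                 three_prime = if (last_res == n) "OH" else "phosphate")
  }

  out <- lapply(seq_len(nfrag), function(i) piece(i, i))
  if (missed_cleavages > 0L && nfrag > 1L) {
    for (k in seq_len(min(missed_cleavages, nfrag - 1L))) {
      for (i in seq_len(nfrag - k)) {
        out[[length(out) + 1L]] <- piece(i, i + k)
      }
    }
  }
  out
}

#' Digest fragments covering one position
#'
#' @inheritParams digest
#' @param label Position label of interest.
#' @return The fragments from [digest()] whose span includes `label`.
#' @export
fragments_covering <- function(trna, enzyme, label, missed_cleavages = 0L) {
  key <- position_label_key(label)
  # ensure the label exists
  label_to_index(trna, label)
  frags <- digest(trna, enzyme, missed_cleavages)
  Filter(function(f) {
    position_label_key(f$start_label) <= key &&
      key <= position_label_key(f$end_label)
  }, frags)
}

#' Write a fragment table
#'
#' TSV with columns parent_id, start_label, end_label,
#' sequence_with_mods, five_prime, three_prime.
#'
#' @param fragments List of `rna_fragment` objects.
#' @param path Output TSV path.
#' @export
write_fragment_table <- function(fragments, path) {
  tab <- data.frame(
    parent_id = vapply(fragments, `[[`, character(1), "parent_id"),
    start_label = vapply(fragments, `[[`, character(1), "start_label"),
    end_label = vapply(fragments, `[[`, character(1), "end_label"),
    sequence_with_mods = vapply(fragments, fragment_string, character(1)),
    five_prime = vapply(fragments, `[[`, character(1), "five_prime"),
    three_prime = vapply(fragments, `[[`, character(1), "three_prime"),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
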