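#' Modification-annotated tRNA sequences
#'
#' An `annotated_trna` holds one tRNA as an ordered table of residues,
#' each carrying its base (A/C/G/U), an optional modification code, and a
#' display position label. Labels default to `1..n` but may be supplied
#' explicitly to realise canonical tRNA numbering with insertion letters
#' (17, 20, 20a, 20b, 47); they must be unique and strictly increasing in
#' label order. Internally all algorithms use 1-based residue indices;
#' labels are an I/O and display concern only.
#'
#' @param id tRNA identifier.
#' @param sequence Character scalar over A/C/G/U (T accepted, normalised
#'   to U).
#' @param isoacceptor Optional isoacceptor name, e.g. `"Phe-GAA"`.
#' @param labels Optional character vector of per-residue position labels
#'   (same length as the sequence); defaults to `as.character(1:n)`.
#' @param modifications Optional data.frame with columns `position_label`
#'   and `modification_code`; each row installs one modification.
#' @param mod_table Modification registry, see
#'   [default_modification_table()].
#' @return An object of class `annotated_trna` with elements `id`,
#'   `isoacceptor` and `residues` (data.frame: `base`, `modification`,
#'   `label`).
#' @examples
#' t1 <- annotated_trna("t1", "GUUGA",
#'   modifications = data.frame(position_label = "3", modification_code = "D"))
#' trna_display_string(t1)
#' @export
annotated_trna <- function(id, sequence, isoacceptor = NA_character_,
                           labels = NULL, modifications = NULL,
                           mod_table = default_modification_table()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  bases <- normalize_rna_sequence(sequence)
  n <- length(bases)
  if (n == 0L) stop("tRNA ", id, ": empty sequence")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("tRNA ", id, ": ", length(labels), " labels for ", n, " residues")
  }
  key <- position_label_key(labels)
  if (anyDuplicated(labels) || any(diff(key) <= 0)) {
    stop("tRNA ", id, ": labels must be unique and strictly increasing")
  }
  residues <- data.frame(base = bases, modification = NA_character_,
                         label = labels, stringsAsFactors = FALSE)
  obj <- structure(list(id = id, isoacceptor = isoacceptor,
                        residues = residues),
                   class = "annotated_trna")
  if (!is.null(modifications) && nrow(modifications) > 0L) {
    for (r in seq_len(nrow(modifications))) {
      obj <- set_modification(obj, modifications$position_label[r],
                              modifications$modification_code[r],
                              mod_table = mod_table)
    }
  }
  obj
}

normalize_rna_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  bases <- strsplit(toupper(gsub("\\s", "", sequence)), "")[[1]]
  bases[bases == "T"] <- "U"
  bad <- setdiff(unique(bases), c("A", "C", "G", "U"))
  if (length(bad)) {
    stop("sequence contains non-RNA characters: ", paste(bad, collapse = ", "))
  }
  bases
}

set_modification <- function(trna, position_label, code,
                             mod_table = default_modification_table()) {
  i <- label_to_index(trna, position_label)
  if (!is.na(trna$residues$modification[i])) {
    stop("tRNA ", trna$id, ": duplicate annotation at label ", position_label)
  }
  parent <- mod_lookup(code, mod_table, "parent_base")
  if (trna$residues$base[i] != parent) {
    stop("tRNA ", trna$id, ": modification ", code, " requires base ",
         parent, " but label ", position_label, " is ",
         trna$residues$base[i])
  }
  trna$residues$modification[i] <- code
  trna
}

#' Map between position labels and residue indices
#'
#' `label_to_index()` returns the 1-based index of the residue carrying a
#' label; `index_to_label()` is its inverse. The two compose to the
#' identity over all labels of a tRNA.
#'
#' @param trna An [annotated_trna()].
#' @param label A position label string.
#' @param index A 1-based residue index.
#' @export
label_to_index <- function(trna, label) {
  i <- match(as.character(label), trna$residues$label)
  if (is.na(i)) {
    stop("tRNA ", trna$id, ": no residue labelled '", label, "'")
  }
  i
}

#' @rdname label_to_index
#' @export
index_to_label <- function(trna, index) {
  index <- as.integer(index)
  if (any(index < 1L | index > nrow(trna$residues))) {
    stop("tRNA ", trna$id, ": index out of range")
  }
  trna$residues$label[index]
}

#' @export
print.annotated_trna <- function(x, ...) {
  nmod <- sum(!is.na(x$residues$modification))
  cat("annotated_trna ", x$id,
      if (!is.na(x$isoacceptor)) paste0(" (", x$isoacceptor, ")"),
      ": ", nrow(x$residues), " nt, ", nmod, " modification(s)\n", sep = "")
  cat(" ", trna_display_string(x), "\n", sep = "")
  invisible(x)
}

#' @rdname annotated_trna
#' @param trna An `annotated_trna`.
#' @export
trna_display_string <- function(trna) {
  paste(residue_display(trna$residues), collapse = "")
}

# per-residue display: base letter, "D" for dihydrouridine, otherwise
# the code in brackets ("[m7G]")
residue_display <- function(residues) {
  ifelse(is.na(residues$modification), residues$base,
         ifelse(residues$modification == "D", "D",
                paste0("[", residues$modification, "]")))
}

#' Read a set of annotated tRNAs from FASTA plus sidecar TSVs
#'
#' The FASTA holds the primary sequences (U or T; T is normalised to U).
#' The modification sidecar TSV has columns `trna_id`, `position_label`,
#' `modification_code`, one row per installed modification. An optional
#' label TSV (`trna_id`, `label`, one row per residue in order) supplies
#' explicit canonical numbering; tRNAs without rows get labels `1..n`.
#'
#' FASTA headers may carry an isoacceptor after the id
#' (`>trna1 Phe-GAA`).
#'
#' @param fasta_path Path to the FASTA file.
#' @param modification_tsv Path to the modification sidecar TSV (or NULL).
#' @param label_tsv Optional path to the per-residue label TSV.
#' @param mod_table Modification registry.
#' @return Named list of [annotated_trna()] objects.
#' @export
read_trna_set <- function(fasta_path, modification_tsv = NULL,
                          label_tsv = NULL,
                          mod_table = default_modification_table()) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  isoacceptors <- ifelse(grepl("\\s", names(seqs)),
                         sub("^\\S+\\s+", "", names(seqs)), NA_character_)
  if (anyDuplicated(ids)) stop("duplicate FASTA ids in ", fasta_path)

  mods <- NULL
  if (!is.null(modification_tsv)) {
    mods <- utils::read.delim(modification_tsv, stringsAsFactors = FALSE,
                              colClasses = "character")
    need <- c("trna_id", "position_label", "modification_code")
    if (!all(need %in% names(mods))) {
      stop("modification TSV must have columns: ", paste(need, collapse = ", "))
    }
    orphan <- setdiff(unique(mods$trna_id), ids)
    if (length(orphan)) {
      stop("modification TSV refers to unknown tRNA id(s): ",
           paste(orphan, collapse = ", "))
    }
  }
  lab <- NULL
  if (!is.null(label_tsv)) {
    lab <- utils::read.delim(label_tsv, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (!all(c("trna_id", "label") %in% names(lab))) {
      stop("label TSV must have columns trna_id, label")
    }
  }

  out <- vector("list", length(ids))
  names(out) <- ids
  for (k in seq_along(ids)) {
    id <- ids[k]
    labels <- if (!is.null(lab) && id %in% lab$trna_id) {
      lab$label[lab$trna_id == id]
    } else NULL
    mk <- if (!is.null(mods)) {
      m <- mods[mods$trna_id == id, , drop = FALSE]
      if (nrow(m)) data.frame(position_label = m$position_label,
                              modification_code = m$modification_code,
                              stringsAsFactors = FALSE) else NULL
    } else NULL
    out[[k]] <- annotated_trna(id, as.character(seqs[[k]]),
                               isoacceptor = isoacceptors[k],
                               labels = labels, modifications = mk,
                               mod_table = mod_table)
  }
  out
}

#' Write a set of annotated tRNAs back to FASTA plus sidecar TSVs
#'
#' Inverse of [read_trna_set()]: reading the written files reproduces the
#' same set of tRNAs.
#'
#' @param trnas Named list of [annotated_trna()] objects.
#' @param fasta_path,modification_tsv,label_tsv Output paths; the label
#'   TSV is only written when `label_tsv` is non-NULL.
#' @export
write_trna_set <- function(trnas, fasta_path, modification_tsv,
                           label_tsv = NULL) {
  headers <- vapply(trnas, function(t) {
    if (!is.na(t$isoacceptor)) paste(t$id, t$isoacceptor) else t$id
  }, character(1))
  seqs <- vapply(trnas, function(t) paste(t$residues$base, collapse = ""),
                 character(1))
  writeLines(paste0(">", headers, "\n", seqs), fasta_path)

  rows <- do.call(rbind, lapply(trnas, function(t) {
    r <- t$residues
    m <- r[!is.na(r$modification), , drop = FALSE]
    if (!nrow(m)) return(NULL)
    data.frame(trna_id = t$id, position_label = m$label,
               modification_code = m$modification, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(trna_id = character(), position_label = character(),
                       modification_code = character())
  }
  utils::write.table(rows, modification_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(label_tsv)) {
    lrows <- do.call(rbind, lapply(trnas, function(t) {
      data.frame(trna_id = t$id, label = t$residues$label,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(lrows, label_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}
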