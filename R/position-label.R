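#' Position labels with insertion letters
#'
#' tRNA residues are conventionally numbered with a canonical scheme that
#' admits insertion letters in the D-loop and variable loop ("17", "20",
#' "20a", "20b", "47"). A label is a positive integer plus an optional
#' single lowercase suffix; labels order by number first, then suffix with
#' the bare number sorting before "a" before "b".
#'
#' Labels are plain character strings in all user-facing interfaces;
#' `parse_position_label()` and `format_position_label()` convert between
#' the string and its (number, suffix) parts, and `position_label_key()`
#' gives a numeric sort key realising the total order.
#'
#' @param label Character vector of labels such as `"20"` or `"20a"`.
#' @return `parse_position_label()`: a data.frame with columns `number`
#'   (integer) and `suffix` (character, `""` when absent).
#' @examples
#' parse_position_label(c("17", "20a"))
#' position_label_key("20") < position_label_key("20a")
#' @export
parse_position_label <- function(label) {
  label <- as.character(label)
  ok <- grepl("^[0-9]+[a-z]?$", label)
  if (any(!ok)) {
    stop("malformed position label(s): ",
         paste(unique(label[!ok]), collapse = ", "))
  }
  number <- as.integer(sub("[a-z]$", "", label))
  suffix <- sub("^[0-9]+", "", label)
  if (any(number < 1L)) stop("position label numbers must be positive")
  data.frame(number = number, suffix = suffix, stringsAsFactors = FALSE)
}

#' @rdname parse_position_label
#' @param number Integer vector of label numbers.
#' @param suffix Character vector of suffixes (`""` for none).
#' @export
format_position_label <- function(number, suffix = "") {
  paste0(as.integer(number), suffix)
}

#' @rdname parse_position_label
#' @export
position_label_key <- function(label) {
  p <- parse_position_label(label)
  # 27 slots per number: bare label, then a..z
  p$number * 27 + ifelse(p$suffix == "", 0L, match(p$suffix, letters))
}

#' @rdname parse_position_label
#' @export
sort_position_labels <- function(label) {
  label[order(position_label_key(label))]
}
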