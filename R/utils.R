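# Internal helpers shared across modules.

# Length of the human mitochondrial reference circle (rCRS).
MT_LENGTH <- 16569L

BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical variant identifier
#'
#' Variants are labelled `"<position><ref>><alt>"` (e.g. `"3107A>C"`),
#' 1-based on the 16,569 bp mitochondrial circle.
#'
#' @param position Integer vector of 1-based positions.
#' @param ref,alt Single-character reference/alternative bases.
#' @return Character vector of identifiers.
#' @export
variant_id <- function(position, ref, alt) {
  sprintf("%d%s>%s", as.integer(position), ref, alt)
}

# Coerce a reference to an upper-case character vector of single bases and
# check its length against the mitochondrial circle.
.reference_bases <- function(reference) {
  if (inherits(reference, "DNAString") || inherits(reference, "DNAStringSet")) {
    reference <- as.character(reference)[1L]
  }
  if (is.character(reference) && length(reference) == 1L && nchar(reference) > 1L) {
    reference <- strsplit(toupper(reference), "", fixed = TRUE)[[1L]]
  }
  if (length(reference) != MT_LENGTH) {
    stop("reference must have length ", MT_LENGTH, " (got ", length(reference), ")")
  }
  toupper(reference)
}

.assert_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("'", name, "' must be a single proportion in [0, 1]")
  }
  invisible(x)
}

# Row-wise max / which.max that tolerate NA columns (all-NA rows give NA).
.row_max_na <- function(m) {
  apply(m, 1L, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
}

.row_which_max_na <- function(m) {
  apply(m, 1L, function(r) if (all(is.na(r))) NA_integer_ else which.max(r))
}
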