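#' The eight-class secondary-structure alphabet
#'
#' Per-residue secondary structure is encoded with the standard DSSP
#' single-letter classes: `H` (alpha-helix), `G` (3_10-helix), `I`
#' (pi-helix), `E` (extended beta-strand), `B` (isolated beta-bridge),
#' `T` (hydrogen-bonded turn), `S` (bend), and `O` for the class DSSP
#' prints as a blank space ("loop/other"). `O` is the canonical internal
#' spelling of that blank class; readers additionally accept `" "`, `"-"`
#' and `"C"` as synonyms on input and normalize them to `O`.
#'
#' @return Character vector of the eight admissible symbols, in the order
#'   `H, G, I, E, B, T, S, O`.
#' @export
#' @examples
#' ss_alphabet()
ss_alphabet <- function() c("H", "G", "I", "E", "B", "T", "S", "O")

#' Reduced four-class alphabet used for transition tables
#'
#' Collapses the eight DSSP classes into `H`, `G`, `T` and `other`,
#' where `other` is exactly \{I, E, S, B, O\}. This is the classing used
#' for helix/turn transition kinetics, where `T` and `G` act as kinetic
#' intermediates between helix and coil.
#'
#' @return Character vector `c("H", "G", "T", "other")`.
#' @export
ss_reduced_alphabet <- function() c("H", "G", "T", "other")

# Synonyms accepted on input for the blank/other class.
.blank_synonyms <- c(" ", "-", "C", "O", "")

#' Normalize raw secondary-structure symbols
#'
#' Maps the DSSP blank class (and its common textual stand-ins `" "`,
#' `"-"`, `"C"`) to `O` and validates that every symbol belongs to the
#' eight-class alphabet.
#'
#' @param x Character vector of single-character symbols.
#' @param context Optional character scalar naming the source (file,
#'   line) used in error messages.
#' @return Character vector of the same length over [ss_alphabet()].
#' @export
normalize_ss_labels <- function(x, context = NULL) {
  x <- as.character(x)
  x[x %in% .blank_synonyms] <- "O"
  bad <- !(x %in% ss_alphabet())
  if (any(bad)) {
    where <- if (is.null(context)) "" else paste0(" in ", context)
    stop("unknown secondary-structure symbol(s) ",
         paste(sQuote(unique(x[bad])), collapse = ", "),
         where, "; admissible symbols are ",
         paste(ss_alphabet(), collapse = ""), call. = FALSE)
  }
  x
}

#' Collapse full-alphabet labels to the reduced classing
#'
#' @param x Character vector of symbols from [ss_alphabet()].
#' @return Character vector over [ss_reduced_alphabet()].
#' @export
reduce_ss_labels <- function(x) {
  out <- ifelse(x %in% c("H", "G", "T"), x, "other")
  out[is.na(x)] <- NA_character_
  out
}
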