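#' @keywords internal
"_PACKAGE"

#' The 20 canonical amino acids, alphabetical one-letter codes
#'
#' Internal ordering used for every 20-vector in the package (amino-acid
#' compositions, derived propensity scores, property indices).
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# residues AAindex files list on their two I-lines, in file order
AAINDEX_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# letters outside the canonical alphabet that still occur in real FASTA
AMBIGUOUS_RESIDUES <- c("B", "J", "O", "U", "X", "Z", "*", "-", ".")

#' All 400 ordered dipeptides
#'
#' @return Character vector of length 400: "AA", "AC", ..., "YY", first
#'   residue varying slowest, both in the order of [AA_ALPHABET].
#' @export
#' @examples
#' head(dipeptides())
dipeptides <- function() {
  paste0(rep(AA_ALPHABET, each = 20L), rep(AA_ALPHABET, times = 20L))
}

#' Validate protein sequences
#'
#' Uppercases sequences and checks them against the 20-letter alphabet.
#' A usable sequence must keep at least one dipeptide window (two adjacent
#' canonical residues) after ambiguity handling, so validated sequences are
#' always scorable.
#'
#' @param seqs Character vector of protein sequences, optionally named by
#'   record id.
#' @param ambiguous How to treat non-canonical letters (B, J, O, U, X, Z,
#'   gaps, stops): `"drop"` keeps the sequence and lets the composition
#'   stage exclude affected residues/windows; `"error"` rejects any
#'   sequence containing them.
#' @return The validated (uppercased) character vector, names preserved.
#' @export
#' @examples
#' validate_sequences(c(q1 = "apAP"))
validate_sequences <- function(seqs, ambiguous = c("drop", "error")) {
  ambiguous <- match.arg(ambiguous)
  if (!is.character(seqs) || length(seqs) == 0L)
    stop("'seqs' must be a non-empty character vector of sequences")
  seqs <- toupper(seqs)
  ids <- if (is.null(names(seqs))) paste0("seq", seq_along(seqs)) else names(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  for (i in seq_along(seqs)) {
    cc <- chars[[i]]
    bad <- setdiff(unique(cc), c(AA_ALPHABET, AMBIGUOUS_RESIDUES))
    if (length(bad) > 0L)
      stop(sprintf("sequence '%s' contains unrecognised characters: %s",
                   ids[i], paste(bad, collapse = ", ")))
    amb <- intersect(unique(cc), AMBIGUOUS_RESIDUES)
    if (length(amb) > 0L && ambiguous == "error")
      stop(sprintf("sequence '%s' contains ambiguous residues: %s",
                   ids[i], paste(amb, collapse = ", ")))
    ok <- cc %in% AA_ALPHABET
    if (sum(ok[-1] & ok[-length(ok)]) < 1L)
      stop(sprintf(
        "sequence '%s' has no valid dipeptide window (length >= 2 of canonical residues required)",
        ids[i]))
  }
  seqs
}
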