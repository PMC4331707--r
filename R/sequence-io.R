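#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that returns plain
#' uppercase character sequences named by the first whitespace-delimited
#' token of each header, the form every other function in the package
#' consumes.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return Named character vector, one element per record, order preserved.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a description", "APAP", ">b", "LQLQ"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path))
    stop(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L)
    stop(sprintf("no FASTA records found in %s", path))
  widths <- Biostrings::width(set)
  if (any(widths == 0L))
    stop(sprintf("empty sequence for FASTA record '%s' in %s",
                 names(set)[which(widths == 0L)[1L]], path))
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  ids <- if (is.null(names(seqs))) paste0("seq", seq_along(seqs)) else names(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# integer-encode one sequence against AA_ALPHABET; NA marks ambiguity
.encode <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1L]], AA_ALPHABET)
}

#' Amino-acid composition of a sequence
#'
#' Fraction of each of the 20 canonical residues. Ambiguous residues are
#' excluded from both numerator and denominator (policy "drop").
#'
#' @param seq A single protein sequence (character scalar).
#' @return Named numeric vector of 20 fractions summing to 1.
#' @export
#' @examples
#' amino_acid_composition("APAP")[c("A", "P")]
amino_acid_composition <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  idx <- .encode(toupper(seq))
  n <- sum(!is.na(idx))
  if (n == 0L)
    stop("sequence has no canonical residues; composition undefined")
  stats::setNames(tabulate(idx, nbins = 20L) / n, AA_ALPHABET)
}

#' Dipeptide composition of a sequence
#'
#' Fraction of each of the 400 ordered dipeptides among the overlapping
#' length-2 windows of the sequence; the denominator is the number of
#' windows made of two canonical residues (windows touching an ambiguous
#' residue are dropped together with their contribution to the count).
#'
#' @param seq A single protein sequence (character scalar), length >= 2.
#' @return Named numeric vector of 400 fractions summing to 1.
#' @export
#' @examples
#' dipeptide_composition("APAP")[c("AP", "PA")]
dipeptide_composition <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  idx <- .encode(toupper(seq))
  if (length(idx) < 2L)
    stop("sequence shorter than 2 residues has no dipeptide composition")
  a <- idx[-length(idx)]
  b <- idx[-1L]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok))
    stop("sequence has no valid dipeptide window")
  stats::setNames(tabulate((a[ok] - 1L) * 20L + b[ok], nbins = 400L) / sum(ok),
                  dipeptides())
}

# n x 400 dipeptide-composition matrix for a set of sequences (internal hot path)
.dpc_matrix <- function(seqs) {
  out <- matrix(0, nrow = length(seqs), ncol = 400L,
                dimnames = list(names(seqs), dipeptides()))
  for (i in seq_along(seqs)) out[i, ] <- dipeptide_composition(seqs[[i]])
  out
}

#' Pooled composition of a sequence collection
#'
#' Residue-pooled composition: counts are summed across all sequences and
#' divided by the total residue (or dipeptide-window) count, so long
#' sequences weigh proportionally more than short ones. This is the
#' dataset-level composition used to build the initial scoring card.
#'
#' @param seqs Character vector of sequences.
#' @param type `"aa"` for the 20-residue composition, `"dipeptide"` for the
#'   400-window composition.
#' @return Named numeric vector (20 or 400) summing to 1.
#' @export
#' @examples
#' pooled_composition(c("AA", "PP"), type = "aa")
pooled_composition <- function(seqs, type = c("dipeptide", "aa")) {
  type <- match.arg(type)
  if (length(seqs) == 0L)
    stop("cannot pool an empty sequence collection")
  if (type == "aa") {
    counts <- numeric(20L)
    for (s in seqs) {
      idx <- .encode(toupper(s))
      counts <- counts + tabulate(idx, nbins = 20L)
    }
    if (sum(counts) == 0) stop("no canonical residues in collection")
    return(stats::setNames(counts / sum(counts), AA_ALPHABET))
  }
  counts <- numeric(400L)
  for (s in seqs) {
    idx <- .encode(toupper(s))
    if (length(idx) < 2L)
      stop("sequence shorter than 2 residues has no dipeptide composition")
    a <- idx[-length(idx)]
    b <- idx[-1L]
    ok <- !is.na(a) & !is.na(b)
    counts <- counts + tabulate((a[ok] - 1L) * 20L + b[ok], nbins = 400L)
  }
  if (sum(counts) == 0) stop("no valid dipeptide windows in collection")
  stats::setNames(counts / sum(counts), dipeptides())
}
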