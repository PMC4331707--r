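#' Parse an AAindex1 flat file of amino-acid property indices
#'
#' Reads the AAindex1 dialect: records separated by `//`, an `H` line with
#' the accession, a `D` line with the description, and an `I` line followed
#' by two rows of ten numeric values in the A/R/N/D/C/Q/E/G/H/I then
#' L/K/M/F/P/S/T/W/Y/V order; `NA` marks a missing value. Values are
#' re-keyed to the package's alphabetical amino-acid order. Malformed
#' records are skipped with a warning.
#'
#' @param path Path to an AAindex1-format file, or a character vector of
#'   its lines.
#' @return List of property indices, each a list with elements
#'   `accession`, `description`, and `values` (named numeric vector of 20,
#'   possibly containing `NA`). The number of skipped records is attached
#'   as attribute `"n_skipped"`.
#' @export
parse_aaindex <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  recs <- split(lines, cumsum(c(TRUE, utils::head(trimws(lines), -1L) == "//")))
  out <- list()
  skipped <- 0L
  for (rec in recs) {
    rec <- rec[trimws(rec) != "//" & trimws(rec) != ""]
    if (length(rec) == 0L) next
    h <- grep("^H ", rec, value = TRUE)
    ii <- grep("^I ", rec)
    if (length(h) != 1L || length(ii) != 1L || ii + 2L > length(rec)) {
      skipped <- skipped + 1L
      warning("skipping malformed AAindex record",
              if (length(h) == 1L) paste0(" ", trimws(sub("^H ", "", h[1L]))))
      next
    }
    acc <- trimws(sub("^H ", "", h))
    d <- grep("^D ", rec, value = TRUE)
    desc <- if (length(d) > 0L) trimws(sub("^D ", "", d[1L])) else ""
    vals <- suppressWarnings(as.numeric(unlist(
      strsplit(trimws(rec[c(ii + 1L, ii + 2L)]), "\\s+"))))
    if (length(vals) != 20L) {
      skipped <- skipped + 1L
      warning(sprintf("skipping AAindex record %s: expected 20 values, got %d",
                      acc, length(vals)))
      next
    }
    v <- stats::setNames(vals, AAINDEX_ORDER)[AA_ALPHABET]
    out[[acc]] <- list(accession = acc, description = desc, values = v)
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Serialise property indices back to AAindex1 format
#'
#' Inverse of [parse_aaindex()]: writes H/D/I records with the two
#' ten-value rows in the canonical file order, `NA` for missing entries.
#' Values survive a parse/serialise round trip exactly.
#'
#' @param indices List of property indices as returned by [parse_aaindex()].
#' @param path Optional output path; if `NULL` the lines are returned.
#' @return Character vector of file lines (invisibly when `path` is given).
#' @export
format_aaindex <- function(indices, path = NULL) {
  lines <- unlist(lapply(indices, function(idx) {
    v <- idx$values[AAINDEX_ORDER]
    fmt <- function(x) paste(vapply(x, function(e)
      if (is.na(e)) "NA" else format(e, digits = 15), ""), collapse = "  ")
    c(paste("H", idx$accession),
      paste("D", idx$description),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste0("    ", fmt(v[1:10])),
      paste0("    ", fmt(v[11:20])),
      "//")
  }))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Correlate amino-acid propensity scores with one property index
#'
#' Pearson correlation over pairwise-complete values; a property is flagged
#' informative when `|r|` strictly exceeds the cutoff.
#'
#' @param aa_scores Named numeric vector of 20 amino-acid propensity scores
#'   (names in [AA_ALPHABET]).
#' @param index A property index as returned by [parse_aaindex()], or a
#'   named numeric vector of 20 values.
#' @param cutoff Informativeness cutoff on `|r|` (default 0.5).
#' @return List with `accession`, `r`, `n_used`, `informative`.
#' @export
correlate_index <- function(aa_scores, index, cutoff = 0.5) {
  if (is.numeric(index)) index <- list(accession = "", description = "",
                                       values = index)
  v <- index$values[AA_ALPHABET]
  s <- aa_scores[AA_ALPHABET]
  ok <- is.finite(v) & is.finite(s)
  if (sum(ok) < 3L)
    stop(sprintf("index %s: fewer than 3 complete pairs", index$accession))
  r <- pearson_r(s[ok], v[ok])
  list(accession = index$accession, r = r, n_used = sum(ok),
       informative = abs(r) > cutoff)
}

#' Scan property indices for informative physicochemical properties
#'
#' The SCM-PCP step: correlates the derived amino-acid propensity scores
#' with every supplied property index and ranks the results by `|r|`
#' (descending; ties broken by accession). Indices that cannot be
#' correlated (too many missing values, zero variance) are recorded with
#' `NA` rather than dropped silently.
#'
#' @param aa_scores Named numeric vector of 20 amino-acid propensity scores.
#' @param indices List of property indices from [parse_aaindex()].
#' @param cutoff Informativeness cutoff on `|r|` (default 0.5, strict).
#' @return Data frame with columns `accession`, `description`, `r`,
#'   `n_used`, `informative`, ranked by `|r|` descending.
#' @export
scan_indices <- function(aa_scores, indices, cutoff = 0.5) {
  if (length(indices) == 0L) stop("no property indices supplied")
  rows <- lapply(indices, function(idx) {
    res <- tryCatch(correlate_index(aa_scores, idx, cutoff),
                    error = function(e) {
                      warning(sprintf("index %s not correlated: %s",
                                      idx$accession, conditionMessage(e)))
                      list(accession = idx$accession, r = NA_real_,
                           n_used = NA_integer_, informative = NA)
                    })
    data.frame(accession = res$accession, description = idx$description,
               r = res$r, n_used = res$n_used, informative = res$informative)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(-abs(out$r), out$accession, na.last = TRUE), , drop = FALSE]
}

#' Correlate propensity scores with the class composition difference
#'
#' Pearson correlation between the 20 amino-acid propensity scores and the
#' per-residue amino-acid composition difference (positive class minus
#' negative class). A high value indicates the card's propensities track
#' simple compositional enrichment.
#'
#' @param aa_scores Named numeric vector of 20 amino-acid propensity scores.
#' @param pos_aac,neg_aac Amino-acid compositions (20 fractions or
#'   percentages) of the two classes, e.g. from [pooled_composition()].
#' @return Correlation coefficient.
#' @export
composition_difference_correlation <- function(aa_scores, pos_aac, neg_aac) {
  d <- pos_aac[AA_ALPHABET] - neg_aac[AA_ALPHABET]
  pearson_r(aa_scores[AA_ALPHABET], d)
}

#' Correlate propensity scores with an external 20-value scale
#'
#' Generic correlation against any user-supplied amino-acid scale (for
#' example experimentally measured side-chain reaction rate constants),
#' with an optional exclusion of named residues — useful when some side
#' chains are known not to carry the property being probed.
#'
#' @param aa_scores Named numeric vector of 20 amino-acid propensity scores.
#' @param values Named numeric vector of external values (names in
#'   one-letter codes).
#' @param exclude Character vector of one-letter codes to leave out.
#' @param log10_values If `TRUE`, correlate against `log10(values)` (for
#'   scales spanning orders of magnitude, e.g. rate constants).
#' @return List with `r` and `n_used`.
#' @export
correlate_external <- function(aa_scores, values, exclude = NULL,
                               log10_values = FALSE) {
  keep <- setdiff(intersect(AA_ALPHABET, names(values)), exclude)
  v <- values[keep]
  if (log10_values) v <- log10(v)
  ok <- is.finite(v) & is.finite(aa_scores[keep])
  if (sum(ok) < 3L) stop("fewer than 3 complete pairs after exclusion")
  list(r = pearson_r(aa_scores[keep][ok], v[ok]), n_used = sum(ok))
}

#' Packaged reference fixtures
#'
#' Small plain-text resources distributed with the package:
#' \describe{
#'   \item{`"reference_card"`}{The published photosynthetic-protein (PSP)
#'     reference values: 20 amino-acid propensity scores with the pooled
#'     amino-acid compositions (per cent) of the PSP and non-PSP training
#'     classes and their difference.}
#'   \item{`"aaindex"`}{Three AAindex property indices (BLAS910101 scaled
#'     side-chain hydrophobicity, PUNT030101 membrane propensity,
#'     WOLR810101 hydration potential) in AAindex1 flat-file format at
#'     full precision. The original WOLR810101 index has no proline value;
#'     the imputed value used in the published PSP analysis is included
#'     and noted in the file.}
#'   \item{`"rate_constants"`}{Hydroxyl-radical side-chain reaction rate
#'     constants (per molar per second) alongside the PSP propensity
#'     column as printed in the source analysis; that propensity column is
#'     internally inconsistent for five residues (T, S, N, H, C) and is
#'     kept verbatim for documentation, not for validation.}
#' }
#'
#' @param which One of `"reference_card"`, `"aaindex"`, `"rate_constants"`.
#' @return A data frame for the TSV fixtures, or a parsed index list (see
#'   [parse_aaindex()]) for `"aaindex"`.
#' @export
#' @examples
#' head(scm_fixture("reference_card"))
scm_fixture <- function(which = c("reference_card", "aaindex",
                                  "rate_constants")) {
  which <- match.arg(which)
  f <- switch(which,
              reference_card = "psp_reference_card.tsv",
              aaindex = "aaindex_subset.txt",
              rate_constants = "psp_rate_constants.tsv")
  path <- system.file("extdata", f, package = "scmcard", mustWork = TRUE)
  if (which == "aaindex") return(parse_aaindex(path))
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
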