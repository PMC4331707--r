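#' Min-max normalise raw scores to the [0, 1000] propensity scale
#'
#' Affine map `1000 * (x - min) / (max - min)`. A constant input vector is
#' mapped to the midpoint 500 so that downstream scoring stays defined.
#'
#' @param raw Numeric vector of finite values.
#' @return Numeric vector of the same length in [0, 1000], names preserved.
#' @export
#' @examples
#' normalize_scores(c(-1, 0, 1))
normalize_scores <- function(raw) {
  if (!is.numeric(raw) || any(!is.finite(raw)))
    stop("'raw' must be a numeric vector of finite values")
  rng <- range(raw)
  if (rng[1] == rng[2])
    return(stats::setNames(rep(500, length(raw)), names(raw)))
  1000 * (raw - rng[1]) / (rng[2] - rng[1])
}

#' Initial scoring card from dipeptide-composition differences
#'
#' The statistical seed of the scoring card method: for each of the 400
#' ordered dipeptides, subtract its composition in the negative class from
#' its composition in the positive class, then min-max normalise the 400
#' differences to [0, 1000]. Deterministic given the data.
#'
#' @param positives,negatives Character vectors of class / non-class
#'   training sequences.
#' @param pooled If `TRUE` (default) compositions are residue-pooled over
#'   each class (long sequences weigh more); if `FALSE` the unweighted mean
#'   of per-sequence compositions is used.
#' @return Named numeric vector of 400 dipeptide propensity scores in
#'   [0, 1000].
#' @export
#' @examples
#' card <- initial_card(c("AAAA", "AAAA"), c("PPPP", "PPPP"))
#' card[c("AA", "PP", "AC")]
initial_card <- function(positives, negatives, pooled = TRUE) {
  if (length(positives) == 0L || length(negatives) == 0L)
    stop("both positive and negative training sets must be non-empty")
  if (pooled) {
    raw <- pooled_composition(positives, "dipeptide") -
      pooled_composition(negatives, "dipeptide")
  } else {
    raw <- colMeans(.dpc_matrix(positives)) - colMeans(.dpc_matrix(negatives))
  }
  normalize_scores(raw)
}

#' Derive 20 amino-acid propensity scores from a dipeptide card
#'
#' The propensity of amino acid X is the mean of the 40 dipeptide scores
#' over the position slots XA..XY and AX..YX; the homodipeptide XX occupies
#' one slot in each set and therefore contributes twice, which is what
#' makes the count exactly 40.
#'
#' @param scores Named numeric vector of 400 dipeptide scores (names must
#'   cover [dipeptides()]).
#' @return Named numeric vector of 20 amino-acid scores.
#' @export
#' @examples
#' derive_aa_scores(setNames(rep(500, 400), dipeptides()))[1:3]
derive_aa_scores <- function(scores) {
  scores <- .check_card(scores)
  out <- vapply(AA_ALPHABET, function(x) {
    (sum(scores[paste0(x, AA_ALPHABET)]) + sum(scores[paste0(AA_ALPHABET, x)])) / 40
  }, numeric(1L))
  stats::setNames(out, AA_ALPHABET)
}

# validate and reorder a 400-score card
.check_card <- function(scores) {
  if (!is.numeric(scores) || is.null(names(scores)))
    stop("a scoring card is a named numeric vector of 400 dipeptide scores")
  dp <- dipeptides()
  if (!all(dp %in% names(scores)))
    stop(sprintf("scoring card is missing %d dipeptides (e.g. %s)",
                 sum(!dp %in% names(scores)),
                 paste(utils::head(setdiff(dp, names(scores)), 3), collapse = ", ")))
  scores <- scores[dp]
  if (any(!is.finite(scores)))
    stop("scoring card contains non-finite scores")
  scores
}

#' Score sequences with a scoring card
#'
#' The scoring function of the method: `S(P) = sum_i w_i * S_i`, where
#' `w_i` is the sequence's dipeptide-composition fraction and `S_i` the
#' card's propensity score for dipeptide i. Because the fractions sum to 1,
#' a card normalised to [0, 1000] yields scores in [0, 1000], comparable
#' across sequences of any length.
#'
#' @param scores Named numeric vector of 400 dipeptide scores.
#' @param seqs Character vector of sequences (each of length >= 2).
#' @return Named numeric vector of sequence scores.
#' @export
#' @examples
#' card <- setNames(rep(0, 400), dipeptides())
#' card[c("AP", "PA")] <- c(900, 100)
#' score_sequences(card, c(q = "APAP"))
score_sequences <- function(scores, seqs) {
  scores <- .check_card(scores)
  drop(.dpc_matrix(seqs) %*% scores)
}

#' Write a scoring card to a TSV file
#'
#' Two tab-separated columns (dipeptide, score) over 400 rows, preceded by
#' `#key: value` header lines carrying metadata (decision threshold, GA
#' weights, seed). Scores are written at full precision and the file
#' round-trips through [read_card()] exactly.
#'
#' @param scores Named numeric vector of 400 dipeptide scores.
#' @param path Output path.
#' @param meta Named list of scalar metadata written to the header.
#' @return `path`, invisibly.
#' @export
write_card <- function(scores, path, meta = list()) {
  scores <- .check_card(scores)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("#%s: %s", k, format(meta[[k]], digits = 17)), con)
  writeLines("dipeptide\tscore", con)
  writeLines(sprintf("%s\t%s", names(scores), format(scores, digits = 17)), con)
  invisible(path)
}

#' Read a scoring card written by [write_card()]
#'
#' @param path Path to a card TSV.
#' @return Named numeric vector of 400 scores; header metadata is attached
#'   as attribute `"meta"` (a named list, numeric where parseable).
#' @export
read_card <- function(path) {
  if (!file.exists(path)) stop(sprintf("card file not found: %s", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#([^:]+):\\s*(.*)$", h))[[1L]]
    if (length(kv) == 3L) {
      val <- suppressWarnings(as.numeric(kv[3L]))
      meta[[kv[2L]]] <- if (is.na(val)) kv[3L] else val
    }
  }
  # na.strings must stay empty: "NA" is the Asn-Ala dipeptide, not missing
  body <- utils::read.delim(text = lines[!grepl("^#", lines)],
                            stringsAsFactors = FALSE,
                            colClasses = c("character", "numeric"),
                            na.strings = character())
  if (!all(c("dipeptide", "score") %in% names(body)))
    stop("card file must have columns 'dipeptide' and 'score'")
  scores <- .check_card(stats::setNames(body$score, body$dipeptide))
  attr(scores, "meta") <- meta
  scores
}
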