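#' Train a scoring-card classifier
#'
#' The full scoring card method in one call: (1) validate the training
#' sequences; (2) build the initial card from the dipeptide-composition
#' difference between the classes, min-max normalised to [0, 1000];
#' (3) derive the 20 amino-acid propensity scores; (4) optionally refine
#' the card with an elitist genetic algorithm whose fitness is
#' `w1 * AUC + w2 * R` (cross-validated rank AUC plus the correlation to
#' the initial amino-acid scores); (5) select the decision threshold that
#' maximises training accuracy. The whole run is reproducible from `seed`.
#'
#' @param positives,negatives Character vectors of training sequences
#'   (e.g. from [read_fasta()]); ids must not overlap between the classes.
#' @param optimize If `TRUE` (default) run the genetic algorithm; if
#'   `FALSE` the composition-derived initial card is used as-is.
#' @param control GA and fitness settings from [scm_control()].
#' @param seed Integer seed governing fold assignment and GA randomness.
#' @param ambiguous Ambiguity policy passed to [validate_sequences()].
#' @return An object of class `"scm"`: a list with components
#'   `dipeptide_scores` (400, in [0, 1000]), `aa_scores` (20),
#'   `initial_scores`, `threshold`, `fitness`, `initial_fitness`, `trace`,
#'   `train` (training [evaluate_card()] metrics), `train_scores`
#'   (per-sequence training scores by class), `control`, `seed`, `call`.
#' @seealso [predict.scm()], [summary.scm()], [coef.scm()], [plot.scm()]
#' @export
#' @examples
#' d <- simulate_dataset(40, 40, c(40, 60), planted = c(AP = 8), seed = 7)
#' fit <- scm_train(d$positives, d$negatives, optimize = FALSE, seed = 7)
#' fit
scm_train <- function(positives, negatives, optimize = TRUE,
                      control = scm_control(), seed = 1L,
                      ambiguous = c("drop", "error")) {
  cl <- match.call()
  positives <- validate_sequences(positives, ambiguous)
  negatives <- validate_sequences(negatives, ambiguous)
  if (!is.null(names(positives)) && !is.null(names(negatives))) {
    dup <- intersect(names(positives), names(negatives))
    if (length(dup) > 0L)
      stop(sprintf("ids present in both classes: %s",
                   paste(utils::head(dup, 3), collapse = ", ")))
  }
  init <- initial_card(positives, negatives)
  if (optimize && control$generations > 0L) {
    opt <- scm_optimize(init, positives, negatives, control, seed = seed)
  } else {
    f0 <- scm_fitness(init, positives, negatives, control = control,
                      seed = seed)
    opt <- list(scores = init, fitness = f0, initial_fitness = f0,
                trace = data.frame(generation = integer(),
                                   best_fitness = numeric(),
                                   best_auc = numeric(), best_r = numeric()))
  }
  sp <- score_sequences(opt$scores, positives)
  sn <- score_sequences(opt$scores, negatives)
  threshold <- select_threshold(sp, sn)
  train <- evaluate_card(opt$scores, positives, negatives, threshold)
  structure(list(dipeptide_scores = opt$scores,
                 aa_scores = derive_aa_scores(opt$scores),
                 initial_scores = init,
                 threshold = threshold,
                 fitness = opt$fitness,
                 initial_fitness = opt$initial_fitness,
                 trace = opt$trace,
                 train = train,
                 train_scores = list(positives = sp, negatives = sn),
                 control = control, seed = seed, call = cl),
            class = "scm")
}

#' @export
print.scm <- function(x, ...) {
  cat("Scoring-card classifier (SCM)\n")
  cat("  call:", deparse(x$call), "\n")
  cat(sprintf("  training: %d positives, %d negatives\n",
              length(x$train_scores$positives), length(x$train_scores$negatives)))
  cat(sprintf("  fitness: %.4f (AUC %.4f, R %.4f)%s\n",
              x$fitness$fitness, x$fitness$auc, x$fitness$r,
              if (nrow(x$trace) > 0L)
                sprintf(" after %d generations", nrow(x$trace)) else
                  " (initial card, no optimisation)"))
  cat(sprintf("  threshold: %.4f; training accuracy %.2f%%\n",
              x$threshold, 100 * x$train$accuracy))
  invisible(x)
}

#' Extract scoring-card coefficients
#'
#' @param object An `"scm"` fit.
#' @param type `"dipeptide"` for the 400 dipeptide propensity scores,
#'   `"aa"` for the 20 derived amino-acid scores.
#' @param ... Ignored.
#' @return Named numeric vector.
#' @method coef scm
#' @export
coef.scm <- function(object, type = c("dipeptide", "aa"), ...) {
  switch(match.arg(type),
         dipeptide = object$dipeptide_scores,
         aa = object$aa_scores)
}

#' Predict class membership for new sequences
#'
#' Scores each query with the fitted card (`S(P) = sum w_i S_i`) and labels
#' it positive iff the score strictly exceeds the decision threshold.
#'
#' @param object An `"scm"` fit.
#' @param newdata Character vector of query sequences, or the path of a
#'   FASTA file.
#' @param type `"response"` for a data frame of id/score/label,
#'   `"score"` for the bare numeric scores.
#' @param threshold Decision threshold; defaults to the fitted one.
#' @param ... Ignored.
#' @return Data frame (see [classify_sequences()]) or numeric vector.
#' @export
predict.scm <- function(object, newdata, type = c("response", "score"),
                        threshold = object$threshold, ...) {
  type <- match.arg(type)
  if (length(newdata) == 1L && file.exists(newdata))
    newdata <- read_fasta(newdata)
  newdata <- validate_sequences(newdata)
  if (type == "score") return(score_sequences(object$dipeptide_scores, newdata))
  classify_sequences(object$dipeptide_scores, newdata, threshold)
}

#' Summarise a scoring-card fit
#'
#' @param object An `"scm"` fit.
#' @param n_top Number of top/bottom dipeptides to report.
#' @param ... Ignored.
#' @return An object of class `"summary.scm"`.
#' @method summary scm
#' @export
summary.scm <- function(object, n_top = 5L, ...) {
  s <- sort(object$dipeptide_scores, decreasing = TRUE)
  structure(list(fit = object,
                 top = utils::head(s, n_top),
                 bottom = utils::tail(s, n_top),
                 aa_ranked = sort(object$aa_scores, decreasing = TRUE)),
            class = "summary.scm")
}

#' @export
print.summary.scm <- function(x, ...) {
  print(x$fit)
  print(x$fit$train)
  cat("\nTop dipeptides:\n")
  print(round(x$top, 1))
  cat("Bottom dipeptides:\n")
  print(round(x$bottom, 1))
  cat("\nAmino-acid propensity scores (ranked):\n")
  print(round(x$aa_ranked, 1))
  invisible(x)
}

#' Plot a scoring-card fit
#'
#' Draws the training ROC curve and, when the card was optimised, the
#' per-generation best-fitness trace.
#'
#' @param x An `"scm"` fit.
#' @param which `"roc"`, `"trace"`, or `"both"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @method plot scm
#' @export
plot.scm <- function(x, which = c("both", "roc", "trace"), ...) {
  which <- match.arg(which)
  show_trace <- which %in% c("both", "trace") && nrow(x$trace) > 0L
  show_roc <- which %in% c("both", "roc")
  if (show_roc && show_trace) {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  if (show_roc) {
    roc <- roc_points(x$train_scores$positives, x$train_scores$negatives)
    graphics::plot(roc$fpr, roc$tpr, type = "l",
                   xlab = "False positive rate", ylab = "True positive rate",
                   main = sprintf("Training ROC (AUC = %.3f)", x$train$auc), ...)
    graphics::abline(0, 1, lty = 2, col = "grey")
  }
  if (show_trace) {
    graphics::plot(x$trace$generation, x$trace$best_fitness, type = "s",
                   xlab = "Generation", ylab = "Best fitness",
                   main = "GA fitness trace", ...)
  }
  invisible(x)
}
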