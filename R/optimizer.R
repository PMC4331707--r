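#' Pearson product-moment correlation
#'
#' [stats::cor()] with the validation the scoring-card workflow needs: at
#' least 3 paired values and nonzero variance on both sides, otherwise an
#' informative error rather than `NA`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient in [-1, 1].
#' @export
#' @examples
#' pearson_r(1:5, c(2, 4, 5, 4, 5))
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("need at least 3 complete pairs to compute a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in input")
  stats::cor(x, y)
}

#' Rank-based ROC AUC (Mann-Whitney estimator)
#'
#' Probability that a randomly drawn positive scores above a randomly
#' drawn negative, with ties credited 0.5. Exact; no curve interpolation.
#'
#' @param pos_scores,neg_scores Numeric score vectors for the two classes.
#' @return AUC in [0, 1].
#' @export
#' @examples
#' auc_rank(c(3, 4), c(1, 2))
auc_rank <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0L || nn == 0L)
    stop("AUC undefined: one class has no scores")
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# stratified fold assignment: list(pos = int vector, neg = int vector)
.make_folds <- function(n_pos, n_neg, k, seed = NULL) {
  if (k < 2L) stop("cv_folds must be >= 2")
  if (k > min(n_pos, n_neg))
    stop(sprintf("cv_folds = %d exceeds the smaller class size %d",
                 k, min(n_pos, n_neg)))
  if (!is.null(seed)) set.seed(seed)
  list(pos = sample(rep_len(seq_len(k), n_pos)),
       neg = sample(rep_len(seq_len(k), n_neg)))
}

#' Genetic-algorithm control parameters
#'
#' Collects the tunables of the elitist GA that refines a scoring card,
#' plus the fitness weights and cross-validation setting.
#'
#' @param pop_size Population size (>= 2).
#' @param generations Number of generations; 0 skips optimisation.
#' @param crossover_rate Probability a child is produced by uniform
#'   crossover of two parents (otherwise it is a mutated copy of one).
#' @param mutation_rate Per-gene probability of Gaussian perturbation.
#' @param mutation_scale Standard deviation of the perturbation on the
#'   0-1000 score scale; mutated genes are clipped back into [0, 1000].
#' @param w1,w2 Fitness weights on cross-validated AUC and on the Pearson
#'   correlation between initial and current amino-acid scores
#'   (`fitness = w1 * AUC + w2 * R`); defaults 0.9 and 0.1.
#' @param cv_folds Folds for the AUC cross-validation estimate (default 10).
#' @return A list of class `"scm_control"`.
#' @export
scm_control <- function(pop_size = 20L, generations = 50L,
                        crossover_rate = 0.7, mutation_rate = 0.05,
                        mutation_scale = 50, w1 = 0.9, w2 = 0.1,
                        cv_folds = 10L) {
  stopifnot(pop_size >= 2L, generations >= 0L,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            mutation_scale > 0, cv_folds >= 2L)
  if (w1 + w2 <= 0) stop("w1 + w2 must be positive")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_scale = mutation_scale,
                 w1 = w1, w2 = w2, cv_folds = as.integer(cv_folds)),
            class = "scm_control")
}

# fitness given precomputed dpc matrices and fixed folds (GA hot path)
.fitness_fast <- function(scores, initial_aa, x_pos, x_neg, folds, control) {
  sp <- drop(x_pos %*% scores)
  sn <- drop(x_neg %*% scores)
  k <- max(c(folds$pos, folds$neg))
  aucs <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    p <- sp[folds$pos == f]; n <- sn[folds$neg == f]
    if (length(p) > 0L && length(n) > 0L) aucs[f] <- auc_rank(p, n)
  }
  if (all(is.na(aucs)))
    stop("every cross-validation fold lacked one class; AUC undefined")
  if (anyNA(aucs))
    warning(sprintf("%d of %d folds had a single class and were excluded",
                    sum(is.na(aucs)), k))
  auc <- mean(aucs, na.rm = TRUE)
  r <- pearson_r(initial_aa,
                 derive_aa_scores(stats::setNames(scores, dipeptides())))
  list(fitness = control$w1 * auc + control$w2 * r, auc = auc, r = r)
}

#' Fitness of a scoring card
#'
#' `fitness = w1 * AUC + w2 * R`, where AUC is the mean rank-based ROC AUC
#' of the card's sequence scores over the held-out parts of a stratified
#' k-fold split (the card itself is held fixed; fold assignment is the only
#' randomness, drawn from `seed`), and R is the Pearson correlation between
#' `initial_aa` and the card's derived amino-acid scores. The AUC term
#' rewards discrimination, the R term anchors the optimised card to the
#' composition-derived one.
#'
#' @param scores Named numeric vector of 400 dipeptide scores.
#' @param positives,negatives Training sequences of the two classes.
#' @param initial_aa 20 amino-acid scores of the initial card; defaults to
#'   the card's own derived scores (making R = 1).
#' @param control An [scm_control()] object (uses `w1`, `w2`, `cv_folds`).
#' @param seed Integer seed for the fold assignment.
#' @return List with elements `fitness`, `auc`, `r`.
#' @export
scm_fitness <- function(scores, positives, negatives, initial_aa = NULL,
                        control = scm_control(), seed = 1L) {
  scores <- .check_card(scores)
  if (length(positives) == 0L || length(negatives) == 0L)
    stop("both classes must be non-empty")
  if (is.null(initial_aa)) initial_aa <- derive_aa_scores(scores)
  folds <- .make_folds(length(positives), length(negatives),
                       control$cv_folds, seed = seed)
  .fitness_fast(scores, initial_aa, .dpc_matrix(positives),
                .dpc_matrix(negatives), folds, control)
}

#' Optimise a scoring card with an elitist genetic algorithm
#'
#' Generational GA over the 400 scores: tournament selection, uniform
#' crossover, clipped Gaussian mutation, and strict elitism (the best-ever
#' card survives unchanged), so the returned fitness can never fall below
#' the initial card's. Fold assignment for the fitness AUC is drawn once
#' from `seed` and reused for every evaluation, making the whole run
#' reproducible from `seed` alone.
#'
#' @param initial Named numeric vector of 400 dipeptide scores in
#'   [0, 1000], typically from [initial_card()].
#' @param positives,negatives Training sequences.
#' @param control An [scm_control()] object.
#' @param seed Integer seed governing folds and all GA randomness.
#' @return List with elements `scores` (best card found), `fitness`
#'   (its fitness/auc/r), `initial_fitness`, and `trace` (data frame with
#'   one row per generation: `generation`, `best_fitness`, `best_auc`,
#'   `best_r`).
#' @export
scm_optimize <- function(initial, positives, negatives,
                         control = scm_control(), seed = 1L) {
  initial <- .check_card(initial)
  if (any(initial < 0 | initial > 1000))
    stop("initial card scores must lie in [0, 1000]")
  initial_aa <- derive_aa_scores(initial)
  x_pos <- .dpc_matrix(positives)
  x_neg <- .dpc_matrix(negatives)
  set.seed(seed)
  folds <- .make_folds(nrow(x_pos), nrow(x_neg), control$cv_folds)
  eval_fit <- function(s) .fitness_fast(s, initial_aa, x_pos, x_neg,
                                        folds, control)

  f0 <- eval_fit(initial)
  if (control$generations == 0L)
    return(list(scores = initial, fitness = f0, initial_fitness = f0,
                trace = data.frame(generation = integer(), best_fitness = numeric(),
                                   best_auc = numeric(), best_r = numeric())))

  mutate <- function(s) {
    hit <- stats::runif(400L) < control$mutation_rate
    if (any(hit))
      s[hit] <- pmin(1000, pmax(0, s[hit] +
                                  stats::rnorm(sum(hit), 0, control$mutation_scale)))
    s
  }
  pop <- c(list(initial),
           lapply(seq_len(control$pop_size - 1L), function(i) mutate(initial)))
  fits <- vapply(pop, function(s) eval_fit(s)$fitness, numeric(1L))

  best_i <- which.max(fits)
  best <- pop[[best_i]]
  best_fit <- eval_fit(best)
  trace <- data.frame(generation = seq_len(control$generations),
                      best_fitness = NA_real_, best_auc = NA_real_,
                      best_r = NA_real_)
  n <- control$pop_size
  for (g in seq_len(control$generations)) {
    children <- vector("list", n)
    children[[1L]] <- best          # elitism
    for (j in seq(2L, n)) {
      # binary tournament selection
      pick <- function() {
        ij <- sample.int(n, 2L)
        pop[[ij[if (fits[ij[1L]] >= fits[ij[2L]]) 1L else 2L]]]
      }
      child <- if (stats::runif(1L) < control$crossover_rate) {
        p1 <- pick(); p2 <- pick()
        mask <- stats::runif(400L) < 0.5
        p1[!mask] <- p2[!mask]
        p1
      } else pick()
      children[[j]] <- mutate(child)
    }
    pop <- children
    fits <- vapply(pop, function(s) eval_fit(s)$fitness, numeric(1L))
    gen_best <- which.max(fits)
    if (fits[gen_best] > best_fit$fitness) {
      best <- pop[[gen_best]]
      best_fit <- eval_fit(best)
    }
    trace$best_fitness[g] <- best_fit$fitness
    trace$best_auc[g] <- best_fit$auc
    trace$best_r[g] <- best_fit$r
  }
  names(best) <- dipeptides()
  list(scores = best, fitness = best_fit, initial_fitness = f0, trace = trace)
}
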