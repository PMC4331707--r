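# Independent brute-force oracles used across the suite. These deliberately
# take the slow, obvious route so they cannot share a bug with the
# implementation they check.

# random protein sequence over the canonical alphabet
rand_seq <- function(len, prob = NULL) {
  paste(sample(AA_ALPHABET, len, replace = TRUE, prob = prob), collapse = "")
}

# sliding-window dipeptide recount by string comparison
brute_dpc <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  wins <- paste0(chars[-length(chars)], chars[-1])
  wins <- wins[wins %in% dipeptides()]
  counts <- vapply(dipeptides(), function(d) sum(wins == d), numeric(1))
  counts / length(wins)
}

# amino-acid scores by looping over all 400 dipeptides, XX counted twice
brute_aa_scores <- function(scores) {
  out <- numeric(20)
  names(out) <- AA_ALPHABET
  for (d in dipeptides()) {
    a <- substr(d, 1, 1)
    b <- substr(d, 2, 2)
    out[a] <- out[a] + scores[d]
    out[b] <- out[b] + scores[d]
  }
  out / 40
}

# AUC by exhaustive pairwise comparison, ties worth one half
brute_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# best achievable training accuracy over every possible cutoff
brute_best_accuracy <- function(pos, neg) {
  cand <- c(-Inf, sort(unique(c(pos, neg))), Inf)
  best <- 0
  for (t in cand) {
    acc <- (sum(pos > t) + sum(neg <= t)) / (length(pos) + length(neg))
    best <- max(best, acc)
  }
  best
}

# Pearson correlation from the raw sum formula
brute_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# small planted dataset shared by several tests
make_planted <- function(n = 60, seed = 1, weight = 8, lens = c(40, 60)) {
  simulate_dataset(n, n, lens, planted = c(AP = weight), seed = seed)
}
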