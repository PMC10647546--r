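# Independent oracles, deliberately written against the definitions rather
# than through the package's code paths.

# Two-sided Fisher p by exhaustive enumeration of all 2x2 tables with the
# observed margins: sum the hypergeometric probabilities of every table no
# more probable than the observed one.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  x <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(x, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Weighted prediction quality score as straight arithmetic on the eight
# confusion counts (pos/neg x none/mild/moderate/severe).
oracle_penalty <- function(pos, neg, w, mode) {
  if (mode == "all_levels") {
    w$miss_mild * neg[["mild"]] + w$miss_moderate * neg[["moderate"]] +
      w$miss_severe * neg[["severe"]] + w$false_positive * pos[["none"]]
  } else {
    w$miss_moderate * neg[["moderate"]] + w$miss_severe * neg[["severe"]] +
      w$false_positive * (pos[["none"]] + pos[["mild"]])
  }
}

# Naive loop over every nonempty subset of elements: OR-rule prediction,
# direct counting, direct weighted sum. Returns a data frame keyed by the
# sorted comma-joined subset.
oracle_subset_scores <- function(cohort, elements, w, mode) {
  elements <- sort(elements)
  K <- length(elements)
  sev <- as.character(cohort$severity)
  out <- list()
  for (mask in 1:(2^K - 1)) {
    sub <- elements[bitwAnd(mask, 2^(seq_len(K) - 1)) > 0]
    pred <- rep(FALSE, nrow(cohort))
    for (el in sub) pred <- pred | cohort[[el]] == 1
    pos <- sapply(c("none", "mild", "moderate", "severe"),
                  function(s) sum(pred & sev == s))
    neg <- sapply(c("none", "mild", "moderate", "severe"),
                  function(s) sum(!pred & sev == s))
    out[[length(out) + 1L]] <- data.frame(
      elements = paste(sub, collapse = ","),
      size = length(sub),
      score = oracle_penalty(as.list(pos), as.list(neg), w, mode),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# A random severity-stratified confusion object plus its raw counts.
random_confusion <- function() {
  sev <- sample(severity_levels(), 60, replace = TRUE,
                prob = c(0.6, 0.15, 0.15, 0.1))
  pred <- runif(60) < 0.4
  list(cm = severity_confusion(sev, pred),
       pos = lapply(stats::setNames(nm = severity_levels()),
                    function(s) sum(pred & sev == s)),
       neg = lapply(stats::setNames(nm = severity_levels()),
                    function(s) sum(!pred & sev == s)))
}

# Small assessed-only synthetic cohort for selection tests.
small_cohort <- function(n = 250, seed = 20260919) {
  generate_cohort(cohort_config(n_assessed = n, n_unassessed = 0,
                                seed = seed))
}
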