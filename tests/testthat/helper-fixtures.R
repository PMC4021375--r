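# shared fixtures: tiny contexts, random datasets, independent oracles

toy_context <- function(sequence = "MKVANQWLLA", id = "P1", ...) {
  protein_context(id, sequence, ...)
}

# random labelled dataset over binary parameters (for property tests)
random_binary_dataset <- function(n_records, n_params, seed) {
  set.seed(seed)
  vals <- c("false", "true")
  features <- as.data.frame(
    matrix(sample(vals, n_records * n_params, replace = TRUE),
           nrow = n_records,
           dimnames = list(NULL, sprintf("p%02d", seq_len(n_params)))),
    stringsAsFactors = FALSE)
  labels <- sample(c("deleterious", "neutral"), n_records, replace = TRUE)
  # ensure both classes present
  labels[1] <- "deleterious"; labels[n_records] <- "neutral"
  indel_dataset(features, labels,
                schema = stats::setNames(rep(list(vals), n_params),
                                         names(features)))
}

# independent oracle: best score over ALL conjunctions of seed-true
# literals meeting the minpos/noise constraints, by exhaustive enumeration
oracle_best_score <- function(dataset, seed_idx, minpos, noise) {
  features <- dataset$features
  labels <- dataset$labels
  params <- names(features)
  seed_vals <- vapply(features, function(col) col[seed_idx], "")
  best <- NA_integer_
  for (k in seq_along(params)) {
    for (comb in utils::combn(length(params), k, simplify = FALSE)) {
      cov <- Reduce(`&`, lapply(comb, function(j) {
        features[[j]] == seed_vals[[j]]
      }))
      p <- sum(cov & labels == "deleterious")
      n <- sum(cov & labels == "neutral")
      if (p >= minpos && n <= noise) {
        score <- p - n
        if (is.na(best) || score > best) best <- score
      }
    }
  }
  best
}

# independent oracle: confusion-matrix statistics recomputed directly
# from raw (label, prediction) pairs
oracle_metrics <- function(labels, predictions) {
  tp <- sum(labels == "deleterious" & predictions == "deleterious")
  fp <- sum(labels == "neutral" & predictions == "deleterious")
  tn <- sum(labels == "neutral" & predictions == "neutral")
  fn <- sum(labels == "deleterious" & predictions == "neutral")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(
    accuracy = safe(tp + tn, tp + fp + tn + fn),
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    precision = safe(tp, tp + fp),
    npv = safe(tn, tn + fn),
    mcc = {
      den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
      if (den > 0) (tp * tn - fp * fn) / den else NA_real_
    })
}
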