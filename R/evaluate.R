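#' Predict deleterious/neutral status from a rule set
#'
#' A record is predicted deleterious iff at least one rule covers it; the
#' rules only characterise the deleterious class, so uncovered records
#' default to neutral.
#'
#' @param object a `rule_set`.
#' @param newdata a named character vector (one feature vector), a one-row
#'   data frame, a feature data frame, or an [indel_dataset()].
#' @param ... unused.
#' @return For a single vector: list with `label` and `firing_rules`
#'   (indices into `object$rules`). For tabular input: list with `labels`
#'   (character vector) and `firing` (list of index vectors per record).
#' @export
predict.rule_set <- function(object, newdata, ...) {
  if (inherits(newdata, "indel_dataset")) newdata <- newdata$features
  if (is.character(newdata) && !is.null(names(newdata))) {
    firing <- which(vapply(object$rules, covers, TRUE,
                           feature_vector = newdata))
    return(list(label = if (length(firing)) "deleterious" else "neutral",
                firing_rules = firing))
  }
  stopifnot(is.data.frame(newdata))
  if (!length(object$rules)) {
    return(list(labels = rep("neutral", nrow(newdata)),
                firing = rep(list(integer()), nrow(newdata))))
  }
  cov <- vapply(object$rules, covers_all, logical(nrow(newdata)),
                features = newdata)
  if (is.null(dim(cov))) cov <- matrix(cov, nrow = nrow(newdata))
  firing <- apply(cov, 1L, which, simplify = FALSE)
  list(labels = ifelse(rowSums(cov) > 0, "deleterious", "neutral"),
       firing = firing)
}

#' Confusion counts of a prediction
#'
#' @param labels true labels (`deleterious` = positive class).
#' @param predictions predicted labels.
#' @return Named integer vector `Tp`, `Fp`, `Tn`, `Fn`.
#' @export
confusion_counts <- function(labels, predictions) {
  stopifnot(length(labels) == length(predictions))
  c(Tp = sum(labels == "deleterious" & predictions == "deleterious"),
    Fp = sum(labels == "neutral" & predictions == "deleterious"),
    Tn = sum(labels == "neutral" & predictions == "neutral"),
    Fn = sum(labels == "deleterious" & predictions == "neutral"))
}

#' Prediction performance statistics
#'
#' Computes accuracy, sensitivity `Tp/(Tp+Fn)`, specificity `Tn/(Tn+Fp)`,
#' precision `Tp/(Tp+Fp)`, negative predictive value `Tn/(Tn+Fn)` and the
#' Matthews correlation coefficient
#' `(Tp*Tn - Fp*Fn) / sqrt((Tp+Fp)(Tp+Fn)(Tn+Fp)(Tn+Fn))` from a confusion
#' matrix. Any statistic with a zero denominator is reported as `NA`,
#' never silently 0.
#'
#' @param counts named vector or list with `Tp`, `Fp`, `Tn`, `Fn`.
#' @return List of class `metrics_report`.
#' @export
metrics <- function(counts) {
  counts <- as.list(counts)
  stopifnot(all(c("Tp", "Fp", "Tn", "Fn") %in% names(counts)))
  tp <- as.numeric(counts$Tp); fp <- as.numeric(counts$Fp)
  tn <- as.numeric(counts$Tn); fn <- as.numeric(counts$Fn)
  if (tp + fp + tn + fn < 1) stop("empty confusion matrix", call. = FALSE)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  structure(
    list(accuracy = div(tp + tn, tp + tn + fp + fn),
         sensitivity = div(tp, tp + fn),
         specificity = div(tn, tn + fp),
         precision = div(tp, tp + fp),
         npv = div(tn, tn + fn),
         mcc = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %s  sensitivity %s  specificity %s\nprecision %s  npv %s  mcc %s\n",
    render_percent(x$accuracy * 100), render_percent(x$sensitivity * 100),
    render_percent(x$specificity * 100), render_percent(x$precision * 100),
    render_percent(x$npv * 100),
    ifelse(is.na(x$mcc), "NA", sprintf("%.2f", x$mcc))))
  invisible(x)
}

#' Render a percentage to two decimals, half away from zero
#' @param x numeric percentage.
#' @return Character, e.g. `"84.38"`.
#' @export
render_percent <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.2f", round_half_away(x * 100) / 100))
}

#' Pooled precision of a set of firing rules
#'
#' The total precision of a prediction supported by several rules pools
#' their confusion counts on a reference dataset:
#' `100 * sum(Tp) / sum(Tp + Fp)` over the firing rules.
#'
#' @param firing_rules list of `indel_rule` objects (or a `rule_set`).
#' @param reference_dataset labelled [indel_dataset()] on which each
#'   rule's Tp/Fp are counted.
#' @return Percentage in \[0, 100\].
#' @export
total_precision <- function(firing_rules, reference_dataset) {
  if (inherits(firing_rules, "rule_set")) firing_rules <- firing_rules$rules
  if (!length(firing_rules)) {
    stop("total precision of an empty rule list is undefined", call. = FALSE)
  }
  pos <- reference_dataset$labels == "deleterious"
  tp <- fp <- 0
  for (r in firing_rules) {
    cov <- covers_all(r, reference_dataset$features)
    tp <- tp + sum(cov & pos)
    fp <- fp + sum(cov & !pos)
  }
  100 * tp / (tp + fp)
}

#' Per-rule coverage/precision assessment and multi-rule statistics
#'
#' Coverage of a rule is the percentage of all deleterious records of the
#' dataset it covers; precision the percentage of covered records that are
#' deleterious. Rules are ranked by decreasing precision, ties broken by
#' decreasing coverage. The multi-rule table reports, for each number of
#' firing rules k, how many deleterious and neutral records are covered by
#' exactly k rules and the pooled precision of those predictions.
#'
#' @param ruleset a `rule_set`.
#' @param dataset labelled [indel_dataset()].
#' @return List of class `rule_assessment`: `per_rule` (data frame with
#'   rule index, coverage_percent, precision_percent, in ranked order),
#'   `multi_rule` (data frame: n_rules, n_deleterious, n_neutral,
#'   average_precision) and `parameter_usage` (named integer vector).
#' @export
assess_rules <- function(ruleset, dataset) {
  pos <- dataset$labels == "deleterious"
  n_pos <- sum(pos)
  rules <- ruleset$rules
  if (!length(rules)) {
    return(structure(list(per_rule = data.frame(), multi_rule = data.frame(),
                          parameter_usage = integer()),
                     class = "rule_assessment"))
  }
  cov <- vapply(rules, covers_all, logical(nrow(dataset$features)),
                features = dataset$features)
  if (is.null(dim(cov))) cov <- matrix(cov, ncol = length(rules))
  per_rule <- data.frame(
    rule = seq_along(rules),
    coverage_percent = 100 * colSums(cov & pos) / n_pos,
    precision_percent = 100 * colSums(cov & pos) / colSums(cov)
  )
  ord <- order(-per_rule$precision_percent, -per_rule$coverage_percent,
               per_rule$rule)
  per_rule <- per_rule[ord, , drop = FALSE]
  rownames(per_rule) <- NULL

  k <- as.integer(rowSums(cov))
  ks <- sort(unique(k[k > 0L]))
  multi <- data.frame(
    n_rules = ks,
    n_deleterious = vapply(ks, function(kk) sum(k == kk & pos), 0L),
    n_neutral = vapply(ks, function(kk) sum(k == kk & !pos), 0L)
  )
  multi$average_precision <- 100 * multi$n_deleterious /
    (multi$n_deleterious + multi$n_neutral)

  usage <- table(unlist(lapply(rules, function(r) names(r$literals))))
  structure(
    list(per_rule = per_rule, multi_rule = multi,
         parameter_usage = stats::setNames(as.integer(usage), names(usage))),
    class = "rule_assessment"
  )
}

#' Parameter-usage histogram of a rule subset
#'
#' Counts how often each parameter appears as a literal across the given
#' rules (e.g. the rules firing for one prediction of interest).
#'
#' @param rules list of `indel_rule` objects (or a `rule_set`).
#' @return Named integer vector, decreasing.
#' @export
parameter_usage <- function(rules) {
  if (inherits(rules, "rule_set")) rules <- rules$rules
  usage <- table(unlist(lapply(rules, function(r) names(r$literals))))
  sort(stats::setNames(as.integer(usage), names(usage)), decreasing = TRUE)
}

# stratified fold assignment: per class, shuffled round-robin
stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  assignment <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

#' Stratified k-fold cross-validation of the rule learner
#'
#' Randomly partitions the dataset into `folds` parts, stratified by
#' class; each part serves once as the test set while a rule set is
#' learned on the remainder. Reports per-fold and average statistics, and
#' retains the rule set of the best-accuracy fold as the final model.
#'
#' @param dataset labelled [indel_dataset()].
#' @param config a [run_config()] with a seed; `folds`, `minpos`, `noise`
#'   are used.
#' @return List of class `cv_result`: `per_fold` (data frame of metrics),
#'   `average` (metrics list), `average_train_accuracy`, `final_ruleset`,
#'   `best_fold`, `fold_assignment`.
#' @export
cross_validate <- function(dataset, config = run_config(seed = 1L)) {
  seed <- require_seed(config)
  stopifnot(config$folds >= 2L)
  assignment <- stratified_folds(dataset$labels, config$folds, seed)
  fold_rows <- list()
  rulesets <- list()
  train_acc <- numeric(config$folds)
  for (f in seq_len(config$folds)) {
    test_idx <- which(assignment == f)
    train_idx <- which(assignment != f)
    train <- subset_dataset(dataset, train_idx)
    if (length(unique(train$labels)) < 2L) {
      stop("fold ", f, ": a class is absent from the training split",
           call. = FALSE)
    }
    fold_config <- config
    fold_config$seed <- seed + f
    rs <- learn(train, fold_config)
    rulesets[[f]] <- rs
    test <- subset_dataset(dataset, test_idx)
    m <- metrics(confusion_counts(test$labels,
                                  predict(rs, test$features)$labels))
    train_acc[f] <- metrics(confusion_counts(
      train$labels, predict(rs, train$features)$labels))$accuracy
    fold_rows[[f]] <- data.frame(fold = f, n_rules = length(rs$rules),
                                 as.data.frame(unclass(m)))
  }
  per_fold <- do.call(rbind, fold_rows)
  avg <- structure(as.list(colMeans(
    per_fold[, c("accuracy", "sensitivity", "specificity", "precision",
                 "npv", "mcc")], na.rm = TRUE)), class = "metrics_report")
  best <- which.max(per_fold$accuracy)
  structure(
    list(per_fold = per_fold, average = avg,
         average_train_accuracy = mean(train_acc),
         final_ruleset = rulesets[[best]], best_fold = best,
         fold_assignment = assignment),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds; average:\n", nrow(x$per_fold)))
  print(x$average)
  invisible(x)
}

#' Chi-square comparison of one parameter between classes
#'
#' Pearson chi-square test (no continuity correction by default) on the
#' value-by-class contingency table of a parameter; the null hypothesis is
#' that deleterious and neutral records share the same value distribution.
#' Constant parameters are skipped with a message.
#'
#' @param dataset labelled [indel_dataset()].
#' @param parameter parameter name; or omit to test every parameter (a
#'   data frame report is returned).
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @param alpha significance level (default 0.05, i.e. 95% confidence).
#' @return For one parameter: list with `chi2`, `dof`, `p_value`,
#'   `significant`, `table`; `NULL` (with a message) for a constant
#'   parameter. Without `parameter`: data frame over all parameters.
#' @export
chi_square_compare <- function(dataset, parameter = NULL, correct = FALSE,
                               alpha = 0.05) {
  if (is.null(parameter)) {
    rows <- lapply(names(dataset$schema), function(p) {
      r <- chi_square_compare(dataset, p, correct, alpha)
      if (is.null(r)) return(NULL)
      data.frame(parameter = p, chi2 = r$chi2, dof = r$dof,
                 p_value = r$p_value, significant = r$significant)
    })
    return(do.call(rbind, rows))
  }
  if (!parameter %in% names(dataset$schema)) {
    stop("unknown parameter '", parameter, "'", call. = FALSE)
  }
  if (length(unique(dataset$labels)) < 2L) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  col <- dataset$features[[parameter]]
  if (length(unique(col)) < 2L) {
    message("parameter '", parameter, "' is constant; chi-square skipped")
    return(NULL)
  }
  tab <- table(value = col, class = dataset$labels)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = as.numeric(ht$statistic), dof = as.numeric(ht$parameter),
       p_value = ht$p.value, significant = ht$p.value < alpha, table = tab)
}

#' Allele-frequency reliability analysis
#'
#' Groups variants into allele-frequency bins of width 0.1 and computes
#' the percentage predicted deleterious per bin, together with the Pearson
#' correlation between bin midpoint and that percentage. In population
#' data most common variants are expected neutral, so a reliable predictor
#' shows a negative correlation.
#'
#' @param predictions character vector of predicted labels.
#' @param allele_frequencies numeric vector in \[0, 1\], same length.
#' @return List with `bins` (data frame: midpoint, n, percent_deleterious;
#'   empty bins excluded) and `r` (Pearson correlation, `NA` with a
#'   message when undefined).
#' @export
af_reliability <- function(predictions, allele_frequencies) {
  stopifnot(length(predictions) == length(allele_frequencies))
  if (any(allele_frequencies < 0 | allele_frequencies > 1)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  edges <- seq(0, 1, by = 0.1)
  bin <- pmin(findInterval(allele_frequencies, edges,
                           rightmost.closed = TRUE), 10L)
  midpoints <- edges[-11] + 0.05
  rows <- lapply(1:10, function(b) {
    n <- sum(bin == b)
    if (n == 0L) return(NULL)
    data.frame(midpoint = midpoints[b], n = n,
               percent_deleterious =
                 100 * sum(predictions[bin == b] == "deleterious") / n)
  })
  empty <- sum(vapply(1:10, function(b) sum(bin == b) == 0L, TRUE))
  if (empty) {
    message(empty, " empty allele-frequency bin(s) excluded from the ",
            "correlation")
  }
  bins <- do.call(rbind, rows)
  r <- if (is.null(bins) || nrow(bins) < 2L ||
           stats::sd(bins$percent_deleterious) == 0) {
    message("correlation undefined (fewer than two bins or constant ",
            "percentages)")
    NA_real_
  } else {
    stats::cor(bins$midpoint, bins$percent_deleterious)
  }
  list(bins = bins, r = r)
}
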