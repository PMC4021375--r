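#' Discriminative power of a categorical parameter
#'
#' For each value i of the parameter, let fn_i and fp_i be the within-class
#' relative frequencies of the value among negative (neutral) and positive
#' (deleterious) examples. The discriminative power is
#' `x = sum_i |fn_i - fp_i|`, which ranges from 0 (identical class
#' distributions) to 2 (disjoint supports). Values absent from one class
#' contribute with the missing frequency taken as 0.
#'
#' @param dataset an [indel_dataset()] with both classes non-empty.
#' @param parameter parameter name.
#' @return List with `parameter` and `x`.
#' @export
discriminative_power <- function(dataset, parameter) {
  if (!parameter %in% names(dataset$schema)) {
    stop("unknown parameter '", parameter, "'", call. = FALSE)
  }
  pos <- dataset$labels == "deleterious"
  if (!any(pos) || all(pos)) {
    stop("both classes must be non-empty to compute discriminative power",
         call. = FALSE)
  }
  col <- dataset$features[[parameter]]
  values <- union(unique(col), dataset$schema[[parameter]])
  fp <- table(factor(col[pos], levels = values)) / sum(pos)
  fn <- table(factor(col[!pos], levels = values)) / sum(!pos)
  list(parameter = parameter, x = sum(abs(as.numeric(fn) - as.numeric(fp))))
}

# Cramer's V (bias-uncorrected) between two categorical vectors
cramers_v <- function(a, b) {
  ta <- table(a, b)
  if (nrow(ta) < 2L || ncol(ta) < 2L) {
    warning("constant parameter: association defined as 0", call. = FALSE)
    return(0)
  }
  chi2 <- suppressWarnings(
    stats::chisq.test(ta, correct = FALSE)$statistic)
  sqrt(as.numeric(chi2) / (sum(ta) * (min(dim(ta)) - 1L)))
}

#' Pairwise association between all parameters
#'
#' Cramér's V (bias-uncorrected) between every pair of categorical
#' parameters: a symmetric matrix with unit diagonal and entries in
#' \[0, 1\]. Constant parameters get association 0 with a warning.
#'
#' @param dataset an [indel_dataset()] with at least two parameters.
#' @return Numeric matrix with parameter names as dimnames.
#' @export
association_matrix <- function(dataset) {
  params <- names(dataset$schema)
  if (length(params) < 2L) {
    stop("at least two parameters are required", call. = FALSE)
  }
  m <- diag(1, length(params))
  dimnames(m) <- list(params, params)
  for (i in seq_along(params)[-length(params)]) {
    for (j in seq.int(i + 1L, length(params))) {
      v <- cramers_v(dataset$features[[params[i]]],
                     dataset$features[[params[j]]])
      m[i, j] <- m[j, i] <- v
    }
  }
  m
}

#' Filter parameters by discriminative power and mutual association
#'
#' Parameters are sorted by decreasing discriminative power x (ties broken
#' by schema order). A greedy pass keeps each parameter in turn and drops
#' every not-yet-processed parameter whose association with it reaches
#' `correlation_cutoff`; finally, kept parameters with `x < x_cutoff` are
#' dropped as non-discriminating. The result partitions the input into
#' `kept`, `dropped_correlated` and `dropped_low_x`.
#'
#' @param dataset an [indel_dataset()].
#' @param correlation_cutoff association threshold in \[0, 1\].
#' @param x_cutoff minimum discriminative power.
#' @return List of class `selection_result` with elements `kept` (ordered
#'   by decreasing x), `dropped_correlated` (data frame: dropped,
#'   kept_partner, association), `dropped_low_x`, `x` (named vector) and
#'   `correlation_matrix`.
#' @export
select_parameters <- function(dataset, correlation_cutoff = 0.7,
                              x_cutoff = 0.2) {
  stopifnot(correlation_cutoff >= 0, correlation_cutoff <= 1, x_cutoff >= 0)
  params <- names(dataset$schema)
  x <- vapply(params, function(p) discriminative_power(dataset, p)$x, 0)
  assoc <- association_matrix(dataset)
  ord <- params[order(-x, seq_along(params))]
  kept <- character()
  dropped <- data.frame(dropped = character(), kept_partner = character(),
                        association = numeric(), stringsAsFactors = FALSE)
  remaining <- ord
  while (length(remaining)) {
    p <- remaining[1]
    remaining <- remaining[-1]
    kept <- c(kept, p)
    if (length(remaining)) {
      hits <- remaining[assoc[p, remaining] >= correlation_cutoff]
      for (q in hits) {
        dropped <- rbind(dropped, data.frame(
          dropped = q, kept_partner = p, association = assoc[p, q],
          stringsAsFactors = FALSE))
      }
      remaining <- setdiff(remaining, hits)
    }
  }
  low <- kept[x[kept] < x_cutoff]
  kept <- kept[x[kept] >= x_cutoff]
  structure(
    list(kept = kept, dropped_correlated = dropped, dropped_low_x = low,
         x = x, correlation_matrix = assoc),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> kept %d, dropped %d correlated, %d low-x\n",
    length(x$kept), nrow(x$dropped_correlated), length(x$dropped_low_x)))
  invisible(x)
}

#' Wrapper grid over selection cutoffs
#'
#' For every combination of `correlation_cutoffs` and `x_cutoffs`, runs
#' [select_parameters()], restricts the dataset to the kept parameters and
#' measures cross-validated accuracy with [cross_validate()]. Also records
#' per-cell training and test accuracy against the number of kept
#' parameters, the standard over-fitting diagnostic.
#'
#' @param dataset an [indel_dataset()].
#' @param correlation_cutoffs,x_cutoffs numeric vectors of cutoffs.
#' @param config a [run_config()] with a seed.
#' @return Data frame with one row per grid cell: `correlation_cutoff`,
#'   `x_cutoff`, `n_parameters`, `cv_accuracy`, `train_accuracy`.
#' @export
wrapper_grid <- function(dataset, correlation_cutoffs = c(0.6, 0.7),
                         x_cutoffs = 0.2, config = run_config(seed = 1L)) {
  require_seed(config)
  grid <- expand.grid(correlation_cutoff = correlation_cutoffs,
                      x_cutoff = x_cutoffs, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cc <- grid$correlation_cutoff[i]
    xc <- grid$x_cutoff[i]
    sel <- select_parameters(dataset, cc, xc)
    if (!length(sel$kept)) {
      return(data.frame(correlation_cutoff = cc, x_cutoff = xc,
                        n_parameters = 0L, cv_accuracy = NA_real_,
                        train_accuracy = NA_real_))
    }
    sub <- subset_parameters(dataset, sel$kept)
    cv <- cross_validate(sub, config)
    data.frame(correlation_cutoff = cc, x_cutoff = xc,
               n_parameters = length(sel$kept),
               cv_accuracy = cv$average$accuracy,
               train_accuracy = cv$average_train_accuracy)
  })
  do.call(rbind, rows)
}
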