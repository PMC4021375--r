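new_rule <- function(literals, pos_covered = NA_integer_,
                     neg_covered = NA_integer_, seed_example = NA_character_) {
  stopifnot(length(literals) >= 1L, !is.null(names(literals)),
            !anyDuplicated(names(literals)))
  structure(
    list(literals = literals,
         pos_covered = as.integer(pos_covered),
         neg_covered = as.integer(neg_covered),
         seed_example = as.character(seed_example)),
    class = "indel_rule"
  )
}

new_rule_set <- function(rules, schema, config) {
  structure(list(rules = rules, schema = schema, config = config),
            class = "rule_set")
}

#' Render a rule in the human-readable style
#'
#' @param rule an `indel_rule`.
#' @return A string such as
#'   `"deleterious (A) if secondary_structure (A, strand), block (A, true)."`
#' @export
format_rule <- function(rule) {
  body <- paste(sprintf("%s (A, %s)", names(rule$literals), rule$literals),
                collapse = ", ")
  paste0("deleterious (A) if ", body, ".")
}

#' @export
print.indel_rule <- function(x, ...) {
  cat(format_rule(x), sprintf(" [pos %d, neg %d]\n",
                              x$pos_covered, x$neg_covered))
  invisible(x)
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set> %d rules (minpos %d, noise %d)\n",
              length(x$rules), x$config$minpos, x$config$noise))
  for (r in x$rules) cat("  ", format_rule(r), "\n", sep = "")
  invisible(x)
}

#' Does a rule cover a feature vector?
#'
#' A rule covers a record iff every literal `(parameter, value)` is
#' satisfied, i.e. the record assigns exactly that value to that parameter.
#'
#' @param rule an `indel_rule`.
#' @param feature_vector named character vector (or one-row data frame).
#' @return Logical scalar.
#' @export
covers <- function(rule, feature_vector) {
  if (is.data.frame(feature_vector)) {
    feature_vector <- unlist(feature_vector[1, , drop = TRUE])
  }
  p <- names(rule$literals)
  missing <- setdiff(p, names(feature_vector))
  if (length(missing)) {
    stop("feature vector lacks parameter '", missing[1],
         "' referenced by the rule", call. = FALSE)
  }
  all(feature_vector[p] == rule$literals)
}

# logical coverage of a rule over a whole feature data frame
covers_all <- function(rule, features) {
  cov <- rep(TRUE, nrow(features))
  for (p in names(rule$literals)) {
    if (is.null(features[[p]])) {
      stop("feature table lacks parameter '", p,
           "' referenced by the rule", call. = FALSE)
    }
    cov <- cov & (features[[p]] == rule$literals[[p]])
  }
  cov
}

# deterministic "is candidate a better rule than incumbent" ordering:
# higher score, then fewer literals, then lexicographically earlier
# parameter-index sequence (schema order)
better_state <- function(a, b) {
  if (is.null(b)) return(TRUE)
  if (a$score != b$score) return(a$score > b$score)
  if (length(a$idx) != length(b$idx)) return(length(a$idx) < length(b$idx))
  for (k in seq_along(a$idx)) {
    if (a$idx[k] != b$idx[k]) return(a$idx[k] < b$idx[k])
  }
  FALSE
}

#' Grow one rule from a positive seed example
#'
#' Beam search over conjunctions of attribute-value literals restricted to
#' the pairs true of the seed example (the propositional bottom clause).
#' Candidates are scored by `positives covered - negatives covered`; a
#' candidate is acceptable when it covers at least `minpos` positives and
#' at most `noise` negatives. Every candidate conjunction generated is
#' evaluated before beam truncation, and branches whose positive coverage
#' has already fallen below `minpos` are pruned (specialisation can only
#' shrink coverage). Ties are broken toward fewer literals, then schema
#' order.
#'
#' @param seed_example row index (or variant id) of a deleterious record.
#' @param dataset an [indel_dataset()].
#' @param config a [run_config()]; `minpos`, `noise`, `beam_width` and
#'   `max_literals` are used.
#' @return An `indel_rule`, or `NULL` when no acceptable rule exists.
#' @export
grow_rule <- function(seed_example, dataset, config = run_config()) {
  feats <- dataset$features
  params <- names(dataset$schema)
  if (is.character(seed_example)) {
    seed_example <- match(seed_example, dataset$variant_ids)
  }
  if (is.na(seed_example) || seed_example < 1L ||
      seed_example > nrow(feats)) {
    stop("seed example not found in the dataset", call. = FALSE)
  }
  if (dataset$labels[seed_example] != "deleterious") {
    stop("the seed example must be a positive (deleterious) record",
         call. = FALSE)
  }
  pos <- dataset$labels == "deleterious"
  seed_vals <- vapply(feats, function(col) col[seed_example], "")
  # M[i, j]: record i agrees with the seed on parameter j
  M <- vapply(seq_along(params),
              function(j) feats[[j]] == seed_vals[[j]],
              logical(nrow(feats)))
  if (is.null(dim(M))) M <- matrix(M, nrow = nrow(feats))

  best <- NULL
  beam <- list(list(idx = integer(), cov = rep(TRUE, nrow(feats))))
  for (depth in seq_len(config$max_literals)) {
    children <- list()
    seen <- character()
    for (st in beam) {
      for (j in setdiff(seq_along(params), st$idx)) {
        idx <- sort(c(st$idx, j))
        key <- paste(idx, collapse = ",")
        if (key %in% seen) next
        seen <- c(seen, key)
        cov <- st$cov & M[, j]
        p_cov <- sum(cov & pos)
        if (p_cov < config$minpos) next   # no descendant can recover
        n_cov <- sum(cov & !pos)
        cand <- list(idx = idx, cov = cov, pos = p_cov, neg = n_cov,
                     score = p_cov - n_cov)
        if (n_cov <= config$noise && better_state(cand, best)) best <- cand
        children[[length(children) + 1L]] <- cand
      }
    }
    if (!length(children)) break
    ord <- order(-vapply(children, `[[`, 0, "score"),
                 vapply(children, function(s) paste(
                   formatC(s$idx, width = 4, flag = "0"), collapse = ","),
                   ""))
    beam <- children[ord[seq_len(min(config$beam_width, length(children)))]]
  }
  if (is.null(best)) return(NULL)
  new_rule(stats::setNames(unname(seed_vals[best$idx]), params[best$idx]),
           best$pos, best$neg, dataset$variant_ids[seed_example])
}

#' Learn a rule set by sequential covering
#'
#' Iterates the positive (deleterious) examples in an order shuffled under
#' the run seed; each still-uncovered positive seeds one [grow_rule()]
#' search over the full training set. An accepted rule marks the positives
#' it covers; learning stops when every positive is covered or no
#' uncovered positive yields an acceptable rule. A rule whose covered
#' positives are a subset of an earlier rule's is discarded as redundant.
#' Every accepted rule covers at least `minpos` positives and at most
#' `noise` negatives on the full training set — with `noise = 0` the
#' training precision of every rule is therefore exactly 100%.
#'
#' @param dataset an [indel_dataset()] with both classes present.
#' @param config a [run_config()] with a seed.
#' @return A `rule_set`.
#' @export
learn <- function(dataset, config = run_config(seed = 1L)) {
  pos_idx <- which(dataset$labels == "deleterious")
  if (!length(pos_idx)) stop("no positive examples to learn from",
                             call. = FALSE)
  set.seed(require_seed(config))
  order_idx <- pos_idx[sample.int(length(pos_idx))]
  covered <- rep(FALSE, nrow(dataset$features))
  rules <- list()
  rule_pos_sets <- list()
  for (seed_i in order_idx) {
    if (covered[seed_i]) next
    rule <- grow_rule(seed_i, dataset, config)
    if (is.null(rule)) next
    cov <- covers_all(rule, dataset$features)
    pos_set <- which(cov & dataset$labels == "deleterious")
    redundant <- any(vapply(rule_pos_sets,
                            function(s) all(pos_set %in% s), TRUE))
    if (redundant) {
      covered[pos_set] <- TRUE
      next
    }
    stopifnot(length(pos_set) >= config$minpos,
              sum(cov & dataset$labels == "neutral") <= config$noise)
    rules[[length(rules) + 1L]] <- rule
    rule_pos_sets[[length(rule_pos_sets) + 1L]] <- pos_set
    covered[pos_set] <- TRUE
  }
  new_rule_set(rules, dataset$schema, config)
}
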