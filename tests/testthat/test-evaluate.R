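test_that("prediction defaults to neutral and reports every firing rule", {
  schema <- list(a = c("x", "y"), b = c("x", "y"))
  rules <- list(indelrules:::new_rule(c(a = "x")),
                indelrules:::new_rule(c(b = "x")),
                indelrules:::new_rule(c(a = "x", b = "x")))
  rs <- indelrules:::new_rule_set(rules, schema, run_config(seed = 1))
  p1 <- predict(rs, c(a = "x", b = "x"))
  expect_identical(p1$label, "deleterious")
  expect_identical(p1$firing_rules, c(1L, 2L, 3L))
  p2 <- predict(rs, c(a = "y", b = "y"))
  expect_identical(p2$label, "neutral")
  expect_length(p2$firing_rules, 0L)
  p3 <- predict(rs, c(a = "y", b = "x"))
  expect_identical(p3$label, "deleterious")
  expect_identical(p3$firing_rules, 2L)

  tab <- data.frame(a = c("x", "y"), b = c("y", "y"),
                    stringsAsFactors = FALSE)
  pt <- predict(rs, tab)
  expect_identical(pt$labels, c("deleterious", "neutral"))
})

test_that("metric formulas match their definitions, spot value included", {
  m <- metrics(c(Tp = 27, Fp = 5, Tn = 0, Fn = 0))
  expect_equal(m$precision, 27 / 32)
  expect_identical(render_percent(100 * m$precision), "84.38")

  perfect <- metrics(c(Tp = 10, Fp = 0, Tn = 10, Fn = 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)

  even <- metrics(c(Tp = 1, Fp = 1, Tn = 1, Fn = 1))
  expect_equal(even$accuracy, 0.5)
  expect_equal(even$mcc, 0)

  # undefined denominators surface as NA, never as 0
  no_pos_pred <- metrics(c(Tp = 0, Fp = 0, Tn = 5, Fn = 5))
  expect_true(is.na(no_pos_pred$precision))
  expect_true(is.na(no_pos_pred$mcc))
  expect_error(metrics(c(Tp = 0, Fp = 0, Tn = 0, Fn = 0)), "empty")
})

test_that("metrics agree with a brute-force recount on random predictions", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(20:60, 1)
    labels <- sample(c("deleterious", "neutral"), n, replace = TRUE)
    preds <- sample(c("deleterious", "neutral"), n, replace = TRUE)
    m <- metrics(confusion_counts(labels, preds))
    o <- oracle_metrics(labels, preds)
    for (stat in names(o)) {
      expect_equal(m[[stat]], o[[stat]], info = paste(seed, stat))
    }
  }
})

test_that("pooled precision sums confusion counts over the firing rules", {
  # rule r10: 10 positives, 0 negatives; rule r51: 5 positives, 1 negative
  features <- data.frame(
    g = c(rep("a", 10), rep("b", 5), "b", rep("c", 10)),
    stringsAsFactors = FALSE)
  labels <- c(rep("deleterious", 15), rep("neutral", 11))
  ds <- indel_dataset(features, labels)
  r10 <- indelrules:::new_rule(c(g = "a"))
  r51 <- indelrules:::new_rule(c(g = "b"))
  expect_equal(total_precision(list(r10, r51), ds), 100 * 15 / 16)
  expect_equal(total_precision(list(r10), ds), 100)
  # single rule: equals that rule's own precision
  expect_equal(total_precision(list(r51), ds), 100 * 5 / 6)
  expect_error(total_precision(list(), ds), "empty")
})

test_that("rule assessment ranks by precision then coverage and tabulates multiplicity", {
  features <- data.frame(
    g = c(rep("a", 55), rep("b", 20), rep("c", 475), rep("b", 5),
          rep("d", 95)),
    h = rep(c("u", "w"), 325),
    stringsAsFactors = FALSE)
  labels <- c(rep("deleterious", 550), rep("neutral", 100))
  ds <- indel_dataset(features, labels)
  rules <- list(indelrules:::new_rule(c(g = "a")),    # 55/550, 100%
                indelrules:::new_rule(c(g = "b")))    # 20 pos, 5 neg
  rs <- indelrules:::new_rule_set(rules, ds$schema, run_config(seed = 1))
  a <- assess_rules(rs, ds)
  expect_equal(a$per_rule$coverage_percent[a$per_rule$rule == 1], 10.0)
  expect_equal(a$per_rule$precision_percent[a$per_rule$rule == 1], 100)
  expect_identical(a$per_rule$rule, c(1L, 2L))  # higher precision first

  # equal precision: higher coverage ranks first
  rules2 <- list(indelrules:::new_rule(c(g = "b")),
                 indelrules:::new_rule(c(g = "a")))
  a2 <- assess_rules(indelrules:::new_rule_set(rules2, ds$schema,
                                               run_config(seed = 1)), ds)
  expect_identical(a2$per_rule$rule[1], 2L)

  # multiplicity table: records covered by exactly k rules
  multi <- a$multi_rule
  expect_identical(multi$n_rules, 1L)
  expect_identical(multi$n_deleterious, 75L)
  expect_identical(multi$n_neutral, 5L)
  expect_equal(multi$average_precision, 100 * 75 / 80)

  expect_identical(a$parameter_usage, c(g = 2L))
  expect_identical(parameter_usage(rs), c(g = 2L))
})

test_that("cross-validation partitions records and is seed-reproducible", {
  gd <- generate_dataset(planted_spec(n_pos = 50, n_neg = 50), seed = 31)
  cfg <- run_config(seed = 11, folds = 10, minpos = 4)
  cv1 <- cross_validate(gd$dataset, cfg)
  expect_identical(sort(unique(cv1$fold_assignment)), 1:10)
  expect_identical(as.integer(table(cv1$fold_assignment)), rep(10L, 10))
  # stratification: 5 of each class per fold
  per_class <- table(cv1$fold_assignment,
                     gd$dataset$labels)
  expect_true(all(per_class == 5L))
  cv2 <- cross_validate(gd$dataset, cfg)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_equal(cv1$per_fold, cv2$per_fold)
  expect_identical(cv1$best_fold,
                   which.max(cv1$per_fold$accuracy))

  tiny <- indel_dataset(data.frame(p = c("a", "b", "a")),
                        c("deleterious", "neutral", "deleterious"))
  expect_error(cross_validate(tiny, run_config(seed = 1, folds = 3)),
               "absent from the training split")
})

test_that("chi-square comparison uses the Pearson statistic on value-by-class tables", {
  # identical class distributions: chi2 = 0, p = 1
  ds0 <- indel_dataset(data.frame(p = rep(c("a", "b"), 20)),
                       rep(c("deleterious", "neutral"), each = 20))
  r0 <- chi_square_compare(ds0, "p")
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p_value, 1)
  expect_false(r0$significant)

  # contingency [[30,10],[10,30]], Yates off: expected cells all 20,
  # chi2 = 4 * (10^2 / 20) = 20, dof 1
  ds1 <- indel_dataset(
    data.frame(p = c(rep("a", 30), rep("b", 10),
                     rep("a", 10), rep("b", 30))),
    c(rep("deleterious", 40), rep("neutral", 40)))
  r1 <- chi_square_compare(ds1, "p")
  expect_equal(r1$chi2, 20)
  expect_identical(r1$dof, 1)
  expect_true(r1$significant)
  expect_true(r1$p_value < 0.05)

  const <- indel_dataset(data.frame(p = rep("a", 10), q = rep(c("a", "b"), 5)),
                         rep(c("deleterious", "neutral"), 5))
  expect_message(r2 <- chi_square_compare(const, "p"), "constant")
  expect_null(r2)
  report <- suppressMessages(chi_square_compare(const))
  expect_identical(report$parameter, "q")
})

test_that("allele-frequency bins and their correlation behave as specified", {
  # synthetic monotone-decreasing percentages give r = -1
  af <- rep(seq(0.05, 0.95, by = 0.1), each = 10)
  pct <- seq(90, 0, by = -10)
  preds <- unlist(lapply(seq_along(pct), function(i) {
    c(rep("deleterious", pct[i] / 10), rep("neutral", 10 - pct[i] / 10))
  }))
  res <- af_reliability(preds, af)
  expect_identical(nrow(res$bins), 10L)
  expect_equal(res$bins$midpoint, seq(0.05, 0.95, by = 0.1))
  expect_equal(res$bins$percent_deleterious, as.numeric(pct))
  expect_equal(res$r, -1)

  # all-neutral predictions: correlation undefined, with a notice
  expect_message(res2 <- af_reliability(rep("neutral", 100), af),
                 "undefined")
  expect_true(is.na(res2$r))
  expect_true(all(res2$bins$percent_deleterious == 0))

  # empty bins are excluded with a notice
  expect_message(
    res3 <- af_reliability(c("deleterious", "neutral"), c(0.05, 0.95)),
    "empty allele-frequency bin")
  expect_identical(nrow(res3$bins), 2L)
  expect_error(af_reliability("deleterious", 1.5), "\\[0, 1\\]")
})
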