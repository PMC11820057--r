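test_that("the wake-history rule relabels REM out of wake-rich contexts", {
  # 12 wake epochs, one NREM epoch, then REM: the REM run's history is
  # wake-rich, and the immediately preceding state is NREM
  h <- hypnogram(c(rep("W", 12), "NR", "R", "R"), 10)
  out <- rule_wake_history(h)
  expect_identical(out$labels, c(rep("W", 12), "NR", "NR", "NR"))

  # REM after 20 NREM epochs is untouched
  h2 <- hypnogram(c(rep("NR", 20), "R", "R"), 10)
  expect_identical(rule_wake_history(h2)$labels, h2$labels)

  # REM at the first epoch has no history and is left unchanged
  h3 <- hypnogram(c("R", "NR", "NR"), 10)
  expect_identical(rule_wake_history(h3)$labels, h3$labels)

  # short history counts only available epochs
  h4 <- hypnogram(c(rep("W", 5), "R"), 10)
  expect_identical(rule_wake_history(h4)$labels, h4$labels)
  h5 <- hypnogram(c(rep("W", 10), "R"), 10)
  expect_identical(rule_wake_history(h5)$labels, c(rep("W", 10), "W"))
})

test_that("the singleton-REM rule matches its worked example", {
  h <- hypnogram(c("NR", "NR", "R", "W"), 10)
  expect_identical(rule_drop_singleton_rem(h)$labels,
                   c("NR", "NR", "NR", "W"))
  h2 <- hypnogram(c("NR", "R", "R", "W"), 10)
  expect_identical(rule_drop_singleton_rem(h2)$labels, h2$labels)
  # leading singleton takes the following label
  h3 <- hypnogram(c("R", "W", "NR"), 10)
  expect_identical(rule_drop_singleton_rem(h3)$labels, c("W", "W", "NR"))
  expect_identical(rule_drop_singleton_rem(h, enabled = FALSE)$labels,
                   h$labels)
})

test_that("contextual rules are idempotent", {
  set.seed(71)
  for (i in 1:5) {
    lab <- sample(c("W", "NR", "R"), 200, replace = TRUE,
                  prob = c(0.4, 0.4, 0.2))
    h <- hypnogram(lab, 10)
    a1 <- rule_wake_history(h)
    expect_identical(rule_wake_history(a1)$labels, a1$labels)
    b1 <- rule_drop_singleton_rem(h)
    expect_identical(rule_drop_singleton_rem(b1)$labels, b1$labels)
  }
})

test_that("evaluation metrics have their closed-form extremes", {
  h <- hypnogram(rep(c("W", "NR", "R"), 20), 10)
  m <- evaluate_scoring(h, h)
  expect_equal(m$accuracy, 1)
  expect_equal(m$balanced_accuracy, 1)
  expect_equal(m$general_kappa, 1)
  expect_true(all(m$per_class[, c("recall", "f1", "kappa")] == 1))

  # cyclic shift on a balanced sequence: total disagreement
  shift <- c(W = "NR", NR = "R", R = "W")
  h2 <- hypnogram(unname(shift[h$labels]), 10)
  m2 <- evaluate_scoring(h2, h)
  expect_equal(m2$accuracy, 0)
  expect_equal(m2$balanced_accuracy, 0)

  expect_error(evaluate_scoring(h, hypnogram(h$labels[1:10], 10)),
               "length")
})

test_that("metrics agree with an independent textbook oracle", {
  set.seed(81)
  for (rep_i in 1:3) {
    a <- sample(c("W", "NR", "R"), 400, replace = TRUE)
    e <- ifelse(runif(400) < 0.7, a, sample(c("W", "NR", "R"), 400, TRUE))
    m <- evaluate_scoring(hypnogram(a, 10), hypnogram(e, 10))

    # plain-formula oracle, written independently of the implementation
    acc_o <- sum(a == e) / 400
    expect_equal(m$accuracy, acc_o, tolerance = 1e-12)
    recalls <- f1s <- kappas <- numeric(0)
    for (cl in c("W", "NR", "R")) {
      tp <- sum(a == cl & e == cl); fp <- sum(a == cl & e != cl)
      fn <- sum(a != cl & e == cl); tn <- 400 - tp - fp - fn
      recalls <- c(recalls, tp / (tp + fn))
      prec <- tp / (tp + fp)
      f1s <- c(f1s, 2 * prec * (tp / (tp + fn)) / (prec + tp / (tp + fn)))
      po <- (tp + tn) / 400
      pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / 400^2
      kappas <- c(kappas, (po - pe) / (1 - pe))
    }
    expect_equal(m$balanced_accuracy, mean(recalls), tolerance = 1e-12)
    expect_equal(unname(m$per_class[, "f1"]), f1s, tolerance = 1e-12)
    expect_equal(unname(m$per_class[, "kappa"]), kappas, tolerance = 1e-12)
    pe_g <- sum(table(e) * table(a)[names(table(e))]) / 400^2
    expect_equal(m$general_kappa, (acc_o - pe_g) / (1 - pe_g),
                 tolerance = 1e-12)
    # confusion matrix bookkeeping
    expect_equal(sum(m$confusion), 400)
    expect_equal(unname(rowSums(m$confusion)),
                 unname(as.numeric(table(factor(e, c("W", "NR", "R"))))))
  }
})

test_that("multiclass kappa cross-checks against caret", {
  set.seed(91)
  a <- sample(c("W", "NR", "R"), 300, replace = TRUE)
  e <- ifelse(runif(300) < 0.6, a, sample(c("W", "NR", "R"), 300, TRUE))
  m <- evaluate_scoring(hypnogram(a, 10), hypnogram(e, 10))
  cm <- caret::confusionMatrix(factor(a, c("W", "NR", "R")),
                               factor(e, c("W", "NR", "R")))
  expect_equal(m$accuracy, unname(cm$overall["Accuracy"]), tolerance = 1e-12)
  expect_equal(m$general_kappa, unname(cm$overall["Kappa"]), tolerance = 1e-12)
})
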