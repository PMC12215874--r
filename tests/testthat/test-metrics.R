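test_that("confusion tallies follow one-vs-rest accounting", {
  t1 <- confusion_tally(c("+", "+", "-"), c("+", "-", "-"))
  pos <- t1[t1$class == "+", ]
  expect_equal(pos$tp, 1)
  expect_equal(pos$fn, 1)
  expect_equal(pos$tn, 1)
  expect_equal(pos$fp, 0)
  expect_equal(sum(t1$support), 3)
  # conservation: TP+FP+FN+TN = n for every class
  expect_true(all(t1$tp + t1$fp + t1$fn + t1$tn == 3))

  perfect <- confusion_tally(c("a", "b", "c"), c("a", "b", "c"))
  expect_true(all(perfect$fp == 0 & perfect$fn == 0))

  expect_error(confusion_tally(c("a", "b"), c("a", "z"), classes = c("a", "b")),
               "label mismatch")
})

test_that("metric formulas reproduce hand-computed fixture values", {
  tally <- structure(data.frame(class = c("pos", "neg"),
                                tp = c(50, 35), fp = c(10, 5),
                                fn = c(5, 10), tn = c(35, 50),
                                support = c(55, 45)),
                     class = c("confusion_tally", "data.frame"))
  rep <- metrics_from_tally(tally, "per_class")
  pos <- rep$per_class[rep$per_class$class == "pos", ]
  expect_equal(pos$precision, 0.83333, tolerance = 1e-5)
  expect_equal(pos$recall, 0.90909, tolerance = 1e-5)
  expect_equal(pos$accuracy, 0.85, tolerance = 1e-12)
  expect_equal(pos$f1, 0.86957, tolerance = 1e-5)
  expect_equal(pos$specificity, 0.77778, tolerance = 1e-5)
  expect_equal(pos$error_rate, 1 - pos$accuracy, tolerance = 1e-12)
})

test_that("degenerate tallies yield flagged zeros, not NaN", {
  tally <- confusion_tally(c("a", "a", "b"), c("b", "b", "b"))
  rep <- metrics_from_tally(tally, "weighted")
  a <- rep$per_class[rep$per_class$class == "a", ]
  expect_equal(a$precision, 0)  # no predictions of class a
  expect_true(any(grepl("precision:a", rep$degenerate)))
  expect_false(anyNA(unlist(rep$per_class[, -1])))
})

test_that("weighted accuracy equals plain agreement and error its complement", {
  set.seed(21)
  for (rep_i in 1:5) {
    classes <- letters[1:4]
    y <- sample(classes, 40, replace = TRUE)
    p <- sample(classes, 40, replace = TRUE)
    m <- metrics_from_tally(confusion_tally(y, p, classes), "weighted")
    expect_equal(m$accuracy, mean(y == p), tolerance = 1e-12)
    expect_equal(m$error_rate, 1 - mean(y == p), tolerance = 1e-12)
  }
})

test_that("binary weighted metrics agree with direct two-class formulas", {
  set.seed(8)
  y <- sample(c("pos", "neg"), 60, replace = TRUE)
  p <- ifelse(stats::runif(60) < 0.75, y, sample(c("pos", "neg"), 60, replace = TRUE))
  tally <- confusion_tally(y, p, c("neg", "pos"))
  m <- metrics_from_tally(tally, "per_class")
  pos <- m$per_class[m$per_class$class == "pos", ]
  tp <- sum(y == "pos" & p == "pos"); fp <- sum(y == "neg" & p == "pos")
  fn <- sum(y == "pos" & p == "neg"); tn <- sum(y == "neg" & p == "neg")
  expect_equal(pos$precision, tp / (tp + fp))
  expect_equal(pos$recall, tp / (tp + fn))
  expect_equal(pos$specificity, tn / (tn + fp))
})

test_that("one-vs-rest AUC matches trivial orderings and the tie convention", {
  y <- c("a", "a", "b", "b")
  perfect <- matrix(c(0.9, 0.8, 0.1, 0.2, 0.1, 0.2, 0.9, 0.8), ncol = 2,
                    dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(roc_auc_ovr(y, perfect)$auc), c(1, 1))

  flat <- matrix(0.5, 4, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(roc_auc_ovr(y, flat)$auc), c(0.5, 0.5))

  # 4 samples: positives scored 0.9, 0.4; negatives 0.8, 0.1 -> 3/4 pairs won
  s <- matrix(c(0.9, 0.4, 0.8, 0.1), ncol = 1, dimnames = list(NULL, "p"))
  expect_equal(unname(roc_auc_ovr(c("p", "p", "n", "n"), s)$auc), 0.75)
})

test_that("rank AUC equals the exhaustive pair-counting oracle", {
  pair_auc <- function(y, s, cl) {
    pos <- s[y == cl]; neg <- s[y != cl]
    total <- 0
    for (a in pos) for (b in neg) total <- total + (a > b) + 0.5 * (a == b)
    total / (length(pos) * length(neg))
  }
  set.seed(17)
  for (rep_i in 1:25) {
    n <- sample(6:50, 1)
    classes <- letters[1:sample(2:4, 1)]
    y <- c(classes, sample(classes, n - length(classes), replace = TRUE))
    s <- matrix(round(stats::runif(length(y) * length(classes)), 2),
                ncol = length(classes), dimnames = list(NULL, classes))
    got <- roc_auc_ovr(y, s)$auc
    for (cl in classes) {
      expect_equal(unname(got[cl]), pair_auc(y, s[, cl], cl), tolerance = 1e-12)
    }
  }
})

test_that("AUC for a class absent from the truth is flagged undefined", {
  s <- matrix(0.5, 3, 2, dimnames = list(NULL, c("a", "b")))
  r <- roc_auc_ovr(c("a", "a", "a"), s)
  expect_true(is.na(r$auc["b"]))
  expect_true("b" %in% r$undefined)  # "a" is also degenerate: no negatives
})

test_that("two-group ANOVA reproduces the hand-computed fixture", {
  res <- compare_with_anova(c(1, 2), c(3, 4))
  expect_equal(res$f, 8, tolerance = 1e-12)
  expect_equal(res$p, 0.1056, tolerance = 1e-3)
  expect_equal(unname(res$means), c(1.5, 3.5))

  same <- compare_with_anova(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$f, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  # shift invariance
  shifted <- compare_with_anova(c(1, 2) + 10, c(3, 4) + 10)
  expect_equal(shifted$f, res$f, tolerance = 1e-10)

  degen <- compare_with_anova(c(1, 1), c(2, 2))
  expect_equal(degen$p, 0)
  expect_true(degen$degenerate)
})
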