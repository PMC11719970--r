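test_that("confusion counts enumerate correctly", {
  expect_identical(confusion(c(1, 1, 0, 0), c(1, 1, 0, 0)),
                   list(tp = 2L, fp = 0L, fn = 0L, tn = 2L))
  expect_identical(confusion(c(1, 1, 0, 0), c(1, 0, 1, 0)),
                   list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  expect_identical(confusion(0L, 1L), list(tp = 0L, fp = 1L, fn = 0L, tn = 0L))
  expect_error(confusion(c(1, 0), 1), "length")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("binary metrics match hand-derived values and flag degeneracy", {
  m <- binary_metrics(list(tp = 2, fp = 1, fn = 1, tn = 2))
  # (tp*tn - fp*fn)/sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)) = 3/sqrt(81)
  expect_equal(unname(m[c("accuracy", "precision", "recall", "mcc")]),
               c(4 / 6, 2 / 3, 2 / 3, 3 / 9))
  perfect <- binary_metrics(confusion(c(1, 0, 1), c(1, 0, 1)))
  expect_equal(as.numeric(perfect), rep(1, 5))
  # all-negative predictions with positives present: tp = fp = 0
  deg <- binary_metrics(list(tp = 0, fp = 0, fn = 2, tn = 2))
  expect_identical(unname(deg[["precision"]]), 0)
  expect_identical(unname(deg[["mcc"]]), 0)
  expect_setequal(attr(deg, "degenerate"), c("precision", "f1", "mcc"))
})

test_that("MCC properties: range, perfection, sign flip under inversion", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(4:40, 1)
    y <- c(0L, 1L, sample(0:1, n - 2, TRUE))   # both classes present
    p <- sample(0:1, n, TRUE)
    m <- binary_metrics(confusion(y, p))
    expect_gte(m[["mcc"]], -1); expect_lte(m[["mcc"]], 1)
    m_inv <- binary_metrics(confusion(y, 1L - p))
    if (length(attr(m, "degenerate")) == 0 &&
        length(attr(m_inv, "degenerate")) == 0) {
      expect_equal(m_inv[["mcc"]], -m[["mcc"]])
    }
  }
  expect_equal(binary_metrics(confusion(c(1, 1, 0), c(1, 1, 0)))[["mcc"]], 1)
})

test_that("multiclass metrics macro-average one-vs-rest", {
  perfect <- multiclass_metrics(degenerative_classes(),
                                degenerative_classes())
  expect_equal(as.numeric(perfect), rep(1, 4))
  m <- multiclass_metrics(c("A", "A", "B", "B"), c("A", "B", "A", "B"),
                          classes = c("A", "B"))
  # hand enumeration: each class has tp=1, fp=1, fn=1 -> precision 0.5
  expect_equal(unname(m[["accuracy"]]), 0.5)
  expect_equal(unname(m[["precision"]]), 0.5)
  single <- multiclass_metrics(c("A", "A"), c("A", "A"), classes = c("A", "B"))
  expect_equal(unname(single[["accuracy"]]), 1)
  expect_true(length(attr(single, "degenerate")) > 0)
  expect_error(multiclass_metrics("A", "C", classes = c("A", "B")), "unknown")
  # accuracy equals the confusion-matrix trace over n
  set.seed(8)
  y <- sample(degenerative_classes(), 60, TRUE)
  p <- sample(degenerative_classes(), 60, TRUE)
  tab <- table(factor(y, degenerative_classes()),
               factor(p, degenerative_classes()))
  expect_equal(multiclass_metrics(y, p, degenerative_classes())[["accuracy"]],
               sum(diag(tab)) / 60)
})

test_that("roc_and_threshold maximises TPR - FPR with the stated tie-break", {
  r <- roc_and_threshold(c(0.2, 0.3, 0.7, 0.8), c(0, 0, 1, 1))
  expect_equal(r$threshold, 0.5)
  expect_equal(r$j, 1)
  # uninformative equal scores: J = 0 at the above-max sentinel
  r2 <- roc_and_threshold(rep(0.4, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(r2$j, 0)
  expect_gt(r2$threshold, 0.4)
  # anti-correlated scores: J never negative (above-max sentinel wins)
  r3 <- roc_and_threshold(c(0.9, 0.8, 0.1, 0.2), c(0, 0, 1, 1))
  expect_equal(r3$j, 0)
  expect_gt(r3$threshold, 0.9)
  expect_error(roc_and_threshold(c(0.1, 0.9), c(1, 1)), "both classes")
})
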