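hazard_preds <- function(hazard, da = "ITS", blocked = FALSE) {
  data.frame(da = da, hazard = hazard,
             potency = ifelse(hazard == "SENSITIZER", "GHS_1B",
                       ifelse(hazard == "NON_SENSITIZER", "NC",
                              "INCONCLUSIVE")),
             blocked = blocked, stringsAsFactors = FALSE)
}

test_that("contingency tables tally and exclude correctly", {
  p <- hazard_preds(c("SENSITIZER", "SENSITIZER",
                      "NON_SENSITIZER", "NON_SENSITIZER"))
  ct <- build_contingency(p, c("POSITIVE", "POSITIVE", "NEGATIVE",
                               "NEGATIVE"), "HAZARD")
  expect_equal(unname(diag(ct$counts)), c(2, 2))
  expect_equal(sum(ct$counts), 4)
  expect_equal(sum(ct$excluded), 0)

  mixed <- build_contingency(p, c("POSITIVE", "NEGATIVE", "POSITIVE",
                                  "NEGATIVE"), "HAZARD")
  expect_equal(as.vector(mixed$counts), c(1, 1, 1, 1))

  p5 <- hazard_preds(c("SENSITIZER", "INCONCLUSIVE", "NON_SENSITIZER",
                       "SENSITIZER", "NON_SENSITIZER"))
  ct5 <- build_contingency(p5, rep("POSITIVE", 5), "HAZARD")
  expect_equal(sum(ct5$counts), 4)
  expect_equal(ct5$excluded[["inconclusive prediction"]], 1)
  expect_equal(sum(ct5$counts) + sum(ct5$excluded), ct5$n)
})

test_that("potency mode excludes one-star and refuses 2o3", {
  p <- data.frame(da = "ITS",
                  hazard = c("SENSITIZER", "SENSITIZER", "NON_SENSITIZER"),
                  potency = c("GHS_1A", "ONE_STAR", "NC"),
                  blocked = FALSE, stringsAsFactors = FALSE)
  ct <- build_contingency(p, c("GHS_1A", "GHS_1B", "NC"), "POTENCY")
  expect_equal(sum(ct$counts), 2)
  expect_equal(ct$excluded[["potency unresolved (1*)"]], 1)
  p2 <- data.frame(da = "TWO_OF_THREE", hazard = "SENSITIZER",
                   potency = "NOT_APPLICABLE", blocked = FALSE,
                   stringsAsFactors = FALSE)
  expect_error(build_contingency(p2, "GHS_1A", "POTENCY"),
               "does not predict GHS potency")
})

test_that("metrics match hand arithmetic, zero denominators undefined", {
  diagonal <- build_contingency(
    hazard_preds(c("SENSITIZER", "SENSITIZER", "NON_SENSITIZER",
                   "NON_SENSITIZER")),
    c("POSITIVE", "POSITIVE", "NEGATIVE", "NEGATIVE"), "HAZARD")
  m <- compute_metrics(diagonal)
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$balanced_accuracy, 1)

  even <- build_contingency(
    hazard_preds(c("SENSITIZER", "SENSITIZER", "NON_SENSITIZER",
                   "NON_SENSITIZER")),
    c("POSITIVE", "NEGATIVE", "POSITIVE", "NEGATIVE"), "HAZARD")
  me <- compute_metrics(even)
  expect_equal(me$accuracy, 0.5)
  expect_equal(me$sensitivity, 0.5)
  expect_equal(me$specificity, 0.5)
  expect_equal(me$balanced_accuracy, 0.5)

  # TP 3, FP 1, FN 0, TN 0: sensitivity 3/3, specificity 0/1
  skew <- build_contingency(
    hazard_preds(rep("SENSITIZER", 4)),
    c("POSITIVE", "POSITIVE", "POSITIVE", "NEGATIVE"), "HAZARD")
  ms <- compute_metrics(skew)
  expect_equal(ms$sensitivity, 1)
  expect_equal(ms$specificity, 0)
  expect_equal(ms$accuracy, 0.75)

  # no negatives at all: specificity 0/0 is undefined, never zero
  allpos <- build_contingency(
    hazard_preds(rep("SENSITIZER", 3)), rep("POSITIVE", 3), "HAZARD")
  ma <- compute_metrics(allpos)
  expect_true(is.na(ma$specificity))
  expect_true(is.na(ma$balanced_accuracy))
  expect_equal(ma$sensitivity, 1)

  empty <- build_contingency(hazard_preds("INCONCLUSIVE"), "POSITIVE",
                             "HAZARD")
  expect_error(compute_metrics(empty), "no evaluable records")
})

test_that("potency metrics report accuracy and per-class sensitivity", {
  p <- data.frame(da = "ITS", hazard = "SENSITIZER",
                  potency = c("GHS_1A", "GHS_1A", "GHS_1B", "NC"),
                  blocked = FALSE, stringsAsFactors = FALSE)
  ct <- build_contingency(p, c("GHS_1A", "GHS_1B", "GHS_1B", "NC"),
                          "POTENCY")
  m <- compute_metrics(ct)
  expect_equal(m$accuracy, 0.75)
  expect_equal(unname(m$class_sensitivity["GHS_1A"]), 1)
  expect_equal(unname(m$class_sensitivity["GHS_1B"]), 0.5)
  expect_true(is.na(compute_metrics(build_contingency(
    p, c("GHS_1A", "GHS_1B", "GHS_1B", "GHS_1B"),
    "POTENCY"))$class_sensitivity[["NC"]]))
})

test_that("swapping the label convention swaps sensitivity and specificity", {
  set.seed(19)
  n <- 300
  pred <- sample(c("SENSITIZER", "NON_SENSITIZER"), n, replace = TRUE)
  ref <- sample(c("POSITIVE", "NEGATIVE"), n, replace = TRUE)
  m1 <- compute_metrics(build_contingency(hazard_preds(pred), ref, "HAZARD"))
  swap_pred <- ifelse(pred == "SENSITIZER", "NON_SENSITIZER", "SENSITIZER")
  swap_ref <- ifelse(ref == "POSITIVE", "NEGATIVE", "POSITIVE")
  m2 <- compute_metrics(build_contingency(hazard_preds(swap_pred), swap_ref,
                                          "HAZARD"))
  expect_equal(m1$sensitivity, m2$specificity)
  expect_equal(m1$specificity, m2$sensitivity)
  expect_equal(m1$accuracy, m2$accuracy)
  expect_equal(m1$balanced_accuracy, m2$balanced_accuracy)
})
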