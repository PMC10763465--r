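test_that("2o3 follows assay concordance", {
  expect_identical(predict_2o3("POSITIVE", "POSITIVE", "NEGATIVE")$hazard,
                   "SENSITIZER")
  expect_identical(predict_2o3("POSITIVE", "NEGATIVE", NA)$hazard,
                   "INCONCLUSIVE")
  expect_identical(predict_2o3("NEGATIVE", "NEGATIVE", "NEGATIVE")$hazard,
                   "NON_SENSITIZER")
  expect_identical(predict_2o3("POSITIVE", NA, NA)$hazard, "INCONCLUSIVE")
  expect_identical(predict_2o3("POSITIVE", "POSITIVE", NA)$hazard,
                   "SENSITIZER")
  # 2o3 never predicts potency
  expect_identical(predict_2o3("POSITIVE", "POSITIVE", "POSITIVE")$potency,
                   "NOT_APPLICABLE")
})

test_that("STS evaluates h-CLAT first and DPRA second", {
  p <- predict_sts(5, NA)
  expect_identical(p$hazard, "SENSITIZER")
  expect_identical(p$potency, "GHS_1A")
  expect_identical(predict_sts(10, NA)$potency, "GHS_1A")    # boundary
  expect_identical(predict_sts(10.1, NA)$potency, "GHS_1B")
  expect_identical(predict_sts(NA, "POSITIVE", "NEGATIVE")$potency, "GHS_1B")
  n <- predict_sts(NA, "NEGATIVE", "NEGATIVE")
  expect_identical(n$hazard, "NON_SENSITIZER")
  expect_identical(n$potency, "NC")
  expect_identical(predict_sts(NA, NA, "NEGATIVE")$hazard, "INCONCLUSIVE")
  expect_identical(predict_sts(NA, "POSITIVE", NA)$hazard, "INCONCLUSIVE")
  # positive call without quantitative MIT: conclusive hazard, open potency
  pc <- predict_sts(NA, "NEGATIVE", "POSITIVE")
  expect_identical(pc$hazard, "SENSITIZER")
  expect_identical(pc$potency, "INCONCLUSIVE")
})

test_that("ITS component scores band the quantitative endpoints", {
  expect_identical(score_its_hclat(NA, "NEGATIVE"), 0L)
  expect_identical(score_its_hclat(5), 3L)
  expect_identical(score_its_hclat(10), 3L)
  expect_identical(score_its_hclat(10.5), 2L)
  expect_identical(score_its_hclat(150), 2L)
  expect_identical(score_its_hclat(4000), 1L)
  expect_identical(score_its_hclat(NA, "POSITIVE"), NA_integer_)
  expect_error(score_its_hclat(0), "positive")

  expect_identical(score_its_dpra(0, 0),
                   list(score = 0L, scheme = "TWO_VALUE_DPRA"))
  expect_identical(score_its_dpra(60, 40)$score, 3L)   # mean 50 >= 42.47
  expect_identical(score_its_dpra(22.62, 22.62)$score, 2L)
  expect_identical(score_its_dpra(15, NA),
                   list(score = 1L, scheme = "CYS_ONLY_DPRA"))
  expect_identical(score_its_dpra(NA, 50),
                   list(score = NA_integer_, scheme = "NO_DPRA"))
})

test_that("ITS totals map to GHS categories per source count", {
  p <- predict_its(3, 3, 1)
  expect_identical(p$potency, "GHS_1A")
  expect_identical(p$its_total, 7L)
  expect_identical(p$its_source_count, 3L)
  expect_identical(predict_its(0, 0, 0)$potency, "NC")
  two <- predict_its(2, 1, NA)
  expect_identical(two$potency, "GHS_1B")
  expect_identical(two$its_source_count, 2L)
  # conclusive hazard, unresolved potency with two sources summing to 5
  star <- predict_its(3, 2, NA)
  expect_identical(star$potency, "ONE_STAR")
  expect_identical(star$hazard, "SENSITIZER")
  expect_identical(predict_its(1, NA, 0)$potency, "INCONCLUSIVE")
  expect_identical(predict_its(0, NA, 0)$potency, "NC")
  insufficient <- predict_its(3, NA, NA)
  expect_identical(insufficient$hazard, "INCONCLUSIVE")
  expect_match(insufficient$rationale, "insufficient sources")
})

test_that("predictions keep hazard and potency coherent", {
  fx <- generate_fixture(fixture_spec(120, seed = 31, defect_rate = 0.05))
  p <- run_dass(fx$table)$predictions
  expect_true(all(p$potency[p$da == "TWO_OF_THREE"] == "NOT_APPLICABLE"))
  ns <- p$hazard == "NON_SENSITIZER"
  expect_true(all(p$potency[ns] %in% c("NC", "NOT_APPLICABLE")))
  expect_true(all(p$hazard[p$potency == "ONE_STAR"] == "SENSITIZER"))
  sens <- p$hazard == "SENSITIZER"
  expect_false(any(p$potency[sens] %in% c("NC")))
  its <- p[p$da == "ITS" & !is.na(p$its_total), ]
  expect_true(all(its$its_total >= 0 & its$its_total <= 7))
  expect_true(all(its$its_total[its$its_source_count == 2] <= 6))
  comp <- rowSums(cbind(its$its_dpra_score, its$its_hclat_score,
                        its$its_insilico_score), na.rm = TRUE)
  expect_equal(comp, as.numeric(its$its_total))
})

test_that("run_dass composes cleanly and degrades per record", {
  # clean full record, all three DAs
  tab <- dass_table(
    unname(DASS_TEMPLATE_HEADERS),
    matrix(c("c1", "80", "60", "p", "4", "p", "p", "p", "in", "", ""),
           nrow = 1))
  res <- run_dass(tab)
  expect_equal(nrow(res$predictions), 3)
  expect_true(all(!res$predictions$blocked))
  expect_true(all(res$predictions$hazard == "SENSITIZER"))
  # empty record: every DA inconclusive, nothing blocked
  empty <- dass_table(unname(DASS_TEMPLATE_HEADERS),
                      matrix("", nrow = 1, ncol = 11))
  pe <- run_dass(empty)$predictions
  expect_true(all(pe$hazard == "INCONCLUSIVE"))
  expect_true(all(!pe$blocked))
  # DA with unsatisfiable bindings is blocked wholesale
  ks_only <- dass_table(c("ks_call"), matrix("p", nrow = 1))
  pb <- run_dass(ks_only, c("TWO_OF_THREE", "ITS"))$predictions
  expect_true(all(pb$blocked))
})

test_that("ITS rationale records the scoring trace and constants checksum", {
  p <- predict_its(2, 3, 1, scheme = "TWO_VALUE_DPRA")
  expect_match(p$rationale, "dpra=2")
  expect_match(p$rationale, "TWO_VALUE_DPRA")
  expect_match(p$rationale, dass_constants_checksum())
})
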