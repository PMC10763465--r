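test_that("call lexicon translates tokens case-insensitively", {
  expect_identical(parse_call(c("Positive", "p", "A", "sensitizer", "1")),
                   rep("POSITIVE", 5))
  expect_identical(parse_call(c("0", "N", "neg", "Inactive",
                                "non-sensitizer")),
                   rep("NEGATIVE", 5))
  expect_identical(parse_call(c("", "NA", "n/a", "NaN")),
                   rep(NA_character_, 4))
  expect_identical(parse_call("maybe"), NA_character_)
})

test_that("MIT parser separates numeric, negative-outcome, and missing", {
  p <- parse_mit(c("10", "negative", "", "Inf", "0.5"))
  expect_equal(p$mit, c(10, NA, NA, NA, 0.5))
  expect_identical(p$call,
                   c("POSITIVE", "NEGATIVE", NA, "NEGATIVE", "POSITIVE"))
})

test_that("mean depletion is the arithmetic mean, symmetric and linear", {
  expect_equal(dpra_mean(0, 0), 0)
  expect_equal(dpra_mean(30, 10), 20)
  expect_equal(dpra_mean(-2, 6), 2)
  set.seed(42)
  a <- runif(200, -100, 100); b <- runif(200, -100, 100)
  expect_equal(dpra_mean(a, b), dpra_mean(b, a))
  expect_equal(dpra_mean(a, a), a)
})

test_that("derived DPRA call applies the prediction-model thresholds", {
  expect_identical(derive_dpra_call(0, 0), "NEGATIVE")
  # boundary: mean exactly at the two-value threshold is negative
  expect_identical(derive_dpra_call(6.38, 6.38), "NEGATIVE")
  expect_identical(derive_dpra_call(6.39, 6.38), "POSITIVE")
  # Cys-only model
  expect_identical(derive_dpra_call(50, NA), "POSITIVE")
  expect_identical(derive_dpra_call(13.89, NA), "NEGATIVE")
  # Lys alone has no model
  expect_identical(derive_dpra_call(NA, 80), NA_character_)
  expect_identical(derive_dpra_call(NA, NA), NA_character_)
})

test_that("derived DPRA call is monotone in either depletion", {
  set.seed(7)
  for (i in 1:200) {
    cys <- runif(1, -5, 95); lys <- runif(1, -5, 95)
    base <- derive_dpra_call(cys, lys)
    up_c <- derive_dpra_call(cys + runif(1, 0, 5), lys)
    up_l <- derive_dpra_call(cys, lys + runif(1, 0, 5))
    if (base == "POSITIVE") {
      expect_identical(up_c, "POSITIVE")
      expect_identical(up_l, "POSITIVE")
    }
  }
})

test_that("harmonization composes translated and calculated inputs", {
  tab <- dass_table(
    c("dpra_cys_pct", "dpra_lys_pct", "hclat_mit", "ks_call"),
    matrix(c("30", "10", "negative", "p"), nrow = 1))
  h <- harmonize_records(tab, auto_map_columns(tab))
  r <- h$records
  expect_equal(r$dpra_mean_pct, 20)
  expect_identical(r$dpra_call, "POSITIVE")
  expect_identical(r$hclat_call, "NEGATIVE")
  expect_true(is.na(r$hclat_mit))
  expect_identical(r$ks_call, "POSITIVE")
})

test_that("an all-empty row harmonizes to an all-missing record", {
  tab <- dass_table(unname(DASS_TEMPLATE_HEADERS),
                    matrix("", nrow = 1, ncol = 11))
  r <- harmonize_records(tab, auto_map_columns(tab))$records
  expect_true(all(is.na(r[, setdiff(names(r), "chem_id")])))
})

test_that("quantitative data overrides a conflicting user call, with warning", {
  tab <- dass_table(
    c("dpra_cys_pct", "dpra_lys_pct", "dpra_call"),
    matrix(c("30", "10", "n"), nrow = 1))
  map <- auto_map_columns(tab)
  h <- harmonize_records(tab, map, check_values(tab, map))
  expect_identical(h$records$dpra_call, "POSITIVE")
  conflict <- h$flags[h$flags$code == "CALL_CONFLICT", ]
  expect_equal(nrow(conflict), 1)
  expect_identical(conflict$severity, "WARNING")
  # agreement: user call accepted silently
  tab2 <- dass_table(c("dpra_cys_pct", "dpra_lys_pct", "dpra_call"),
                     matrix(c("30", "10", "p"), nrow = 1))
  h2 <- harmonize_records(tab2, auto_map_columns(tab2))
  expect_identical(h2$records$dpra_call, "POSITIVE")
  expect_equal(nrow(h2$flags[h2$flags$code == "CALL_CONFLICT", ]), 0)
  # user call stands when no quantitative data is bound
  tab3 <- dass_table(c("dpra_call"), matrix("n", nrow = 1))
  h3 <- harmonize_records(tab3, auto_map_columns(tab3))
  expect_identical(h3$records$dpra_call, "NEGATIVE")
})

test_that("ERROR-flagged cells become missing in the record", {
  tab <- dass_table(c("dpra_cys_pct", "dpra_lys_pct"),
                    matrix(c("abc", "50"), nrow = 1))
  map <- auto_map_columns(tab)
  h <- harmonize_records(tab, map, check_values(tab, map))
  expect_true(is.na(h$records$cys_pct))
  expect_equal(h$records$lys_pct, 50)
  expect_true(is.na(h$records$dpra_call))  # Lys-only: no model
})

test_that("harmonization is row-local: permuting rows permutes records", {
  fx <- generate_fixture(fixture_spec(25, seed = 3))
  map <- auto_map_columns(fx$table)
  rec <- harmonize_records(fx$table, map)$records
  perm <- sample(nrow(fx$table$body))
  shuffled <- dass_table(fx$table$header,
                         fx$table$body[perm, , drop = FALSE])
  rec2 <- harmonize_records(shuffled, map)$records
  for (col in setdiff(names(rec), "chem_id")) {
    expect_identical(rec2[[col]], rec[[col]][perm], label = col)
  }
})

test_that("out-of-domain in silico predictions are unusable for ITS", {
  expect_identical(score_its_insilico("POSITIVE", FALSE), NA_integer_)
  expect_identical(score_its_insilico("POSITIVE", TRUE), 1L)
  expect_identical(score_its_insilico("NEGATIVE", TRUE), 0L)
  expect_identical(score_its_insilico(NA_character_, TRUE), NA_integer_)
  # unknown domain status: the prediction is used
  expect_identical(score_its_insilico("POSITIVE", NA), 1L)
})
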