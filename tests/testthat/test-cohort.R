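test_that("severity classification follows the principal/secondary code rules", {
  cm <- code_map()
  cases <- list(
    list(p = "486", s = character(0), want = "NON_SEVERE"),
    list(p = "486", s = c("038.9", "250.00"), want = "NON_SEVERE"),
    list(p = "481", s = character(0), want = "NON_SEVERE"),
    list(p = "482.41", s = character(0), want = "NON_SEVERE"),   # prefix family
    list(p = "487.0", s = character(0), want = "NON_SEVERE"),
    list(p = "038.9", s = "486", want = "SEVERE"),
    list(p = "0380", s = c("401.9", "482.0"), want = "SEVERE"),  # dot-stripped
    list(p = "518.81", s = "486", want = "SEVERE"),
    list(p = "799.1", s = "481", want = "SEVERE"),
    list(p = "518.81", s = "250.00", want = "NOT_CASE"),         # no pneumonia 2ndry
    list(p = "038.9", s = character(0), want = "NOT_CASE"),
    list(p = "428.0", s = "486", want = "NOT_CASE"),
    list(p = "487.1", s = character(0), want = "NOT_CASE")       # influenza, not 487.0
  )
  for (cs in cases) {
    expect_identical(classify_severity(cs$p, cs$s, cm), cs$want,
                     label = sprintf("principal %s", cs$p))
  }
  expect_true(is.na(classify_severity(NA_character_, "486", cm)))
  expect_true(is.na(classify_severity("", "486", cm)))
})

test_that("code maps must be non-empty and pneumonia-disjoint", {
  expect_error(code_map(pneumonia = character(0)), "non-empty")
  expect_error(code_map(sepsis = c("038", "486")), "disjoint")
  expect_error(classify_severity("486", matrix("", 1, 25)), "24 secondary")
})

test_that("cohort filtering partitions records with one reason each", {
  regions <- generate_regions(3, 1000, 1, seed = 1)
  nonres <- regions$region_id[!regions$residential][1]
  res <- regions$region_id[regions$residential][1]
  records <- bind_records(
    make_record(region_id = res, age = 40, admit = "2012-03-01"),              # kept
    make_record(region_id = res, age = 17, admit = "2012-03-01"),              # minor
    make_record(region_id = nonres, age = 40, admit = "2012-03-01"),           # non-residential
    make_record(region_id = "R999", age = 40, admit = "2012-03-01"),           # unknown region
    make_record(region_id = res, age = 40, admit = "2009-06-01"),              # before window
    make_record(region_id = res, age = 40, admit = "2015-06-01"),              # after window
    make_record(region_id = res, age = 40, principal = "428.0"),               # not a case
    make_record(region_id = res, age = 40, principal = ""),                    # missing principal
    make_record(region_id = res, age = 85, principal = "038.9",
                secondary = "486", admit = "2014-12-31")                       # kept, severe
  )
  fc <- filter_cohort(records, regions, 2010, 2014)
  expect_equal(nrow(fc$cohort), 2L)
  expect_equal(nrow(fc$cohort) + sum(fc$exclusions), nrow(records))
  expect_equal(unname(fc$exclusions["under_18"]), 1L)
  expect_equal(unname(fc$exclusions["non_residential"]), 1L)
  expect_equal(unname(fc$exclusions["unknown_region"]), 1L)
  expect_equal(unname(fc$exclusions["outside_study_window"]), 2L)
  expect_equal(unname(fc$exclusions["not_case"]), 1L)
  expect_equal(unname(fc$exclusions["missing_principal"]), 1L)
  expect_setequal(fc$cohort$severity, c("NON_SEVERE", "SEVERE"))
  expect_equal(fc$cohort$los, c(5L, 5L))
})

test_that("severity classes partition kept records", {
  cfg <- simulation_config(grid_side = 5, years = 2010L, seed = 21,
                           n_nonresidential = 1)
  sim <- simulate_study(cfg)
  fc <- filter_cohort(sim$records, sim$regions, 2010, 2010)
  expect_true(all(fc$cohort$severity %in% c("NON_SEVERE", "SEVERE")))
  s <- summarize_cohort(fc$cohort)
  sev_pct <- s$pct[s$class %in% c("non_severe", "severe")]
  expect_lte(abs(sum(sev_pct) - 100), 0.1)
})

test_that("cohort summaries reproduce count shares to one decimal", {
  s <- summarize_cohort(c(overall = 141730, severe = 61712, CAP = 88420,
                          HCAP = 38576, HAP = 12292, VAP = 2442))
  get <- function(cl) s$pct[s$class == cl]
  expect_identical(get("severe"), 43.5)
  expect_identical(get("CAP"), 62.4)
  expect_identical(get("HCAP"), 27.2)
  expect_identical(get("HAP"), 8.7)
  expect_identical(get("VAP"), 1.7)

  one <- make_record()
  one$severity <- "NON_SEVERE"
  class(one) <- c("cohort", "data.frame")
  s1 <- summarize_cohort(one)
  expect_identical(s1$pct[s1$class == "non_severe"], 100.0)

  expect_error(summarize_cohort(one[0, ]), "empty")
  expect_error(summarize_cohort(c(severe = 5)), "overall")
})
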