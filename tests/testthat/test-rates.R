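test_that("age-specific rates apply the 100,000 constant", {
  expect_identical(age_specific_rate(0, 50000), 0)
  expect_identical(age_specific_rate(5, 100000), 5)
  expect_identical(age_specific_rate(13, 6500), 200)
  expect_error(age_specific_rate(3, 0), "zero population")
  expect_warning(r <- age_specific_rate(0, 0), "skipped")
  expect_true(is.na(r))
  expect_error(age_specific_rate(-1, 100), ">= 0")
})

test_that("direct adjustment weights age-specific rates by standard proportions", {
  std <- standard_population(data.frame(age_group = c("g1", "g2"),
                                        lower = c(18, 45), upper = c(44, 99)),
                             weights = c(0.5, 0.5))
  expect_equal(direct_adjusted_rate(c(g1 = 100, g2 = 300), std), 200)
  # single group present: weights renormalise, adjusted equals crude
  expect_equal(direct_adjusted_rate(c(g1 = 123.4), std), 123.4)
  std3 <- standard_population(data.frame(age_group = c("g1", "g2", "g3"),
                                         lower = c(18, 45, 65),
                                         upper = c(44, 64, 99)),
                              weights = c(0.6, 0.3, 0.1))
  expect_equal(direct_adjusted_rate(c(g1 = 50, g2 = 200, g3 = 800), std3), 170)
  expect_error(direct_adjusted_rate(numeric(0), std), "no age-specific")
  expect_error(direct_adjusted_rate(c(zz = 5), std), "absent")
})

test_that("adjusted rates obey splitting and bounding invariants", {
  stdA <- standard_population(data.frame(age_group = c("a", "b"),
                                         lower = c(18, 65), upper = c(64, 99)),
                              weights = c(0.7, 0.3))
  # splitting group a into two sub-groups with the same rate leaves the
  # adjusted rate unchanged
  stdB <- standard_population(data.frame(age_group = c("a1", "a2", "b"),
                                         lower = c(18, 45, 65),
                                         upper = c(44, 64, 99)),
                              weights = c(0.35, 0.35, 0.3))
  r1 <- direct_adjusted_rate(c(a = 120, b = 480), stdA)
  r2 <- direct_adjusted_rate(c(a1 = 120, a2 = 120, b = 480), stdB)
  expect_equal(r1, r2)
  for (seed in 1:5) {
    set.seed(seed)
    rates <- stats::setNames(runif(2, 0, 1000), c("a", "b"))
    adj <- direct_adjusted_rate(rates, stdA)
    expect_gte(adj, min(rates))
    expect_lte(adj, max(rates))
  }
})

test_that("default standard weights are adult-renormalised and sum to 1", {
  std <- standard_population()
  expect_equal(sum(std$weight), 1, tolerance = 1e-12)
  expect_true(all(std$weight > 0))
  # younger adult bands dominate the US 2000 standard
  expect_gt(std$weight[std$age_group == "18-44"], 0.5)
  expect_identical(assign_age_group(c(18, 44, 45, 84, 85, 99, 17), std),
                   c("18-44", "18-44", "45-64", "75-84", "85+", "85+", NA))
})

test_that("rate surfaces match a hand-computed two-region fixture", {
  regions <- generate_regions(3, 1000, 0, seed = 1)
  A <- "R001"; B <- "R002"
  std <- standard_population(data.frame(age_group = c("18-44", "45-64"),
                                        lower = c(18, 45), upper = c(44, 64)),
                             weights = c(0.6, 0.4))
  pop <- expand.grid(region_id = c(A, B), age_group = c("18-44", "45-64"),
                     year = 2010:2011, stringsAsFactors = FALSE)
  pop$count <- c(8000, 4000, 2000, 4000, 8000, 4000, 2000, 4000)
  recs <- list()
  add <- function(region, n, age, year) {
    for (i in seq_len(n)) {
      recs[[length(recs) + 1L]] <<- make_record(
        region_id = region, age = age,
        admit = sprintf("%d-06-01", year),
        id = sprintf("D%07d", length(recs) + 1L))
    }
  }
  add(A, 12, 30, 2010); add(A, 6, 50, 2010); add(A, 8, 30, 2011); add(A, 4, 50, 2011)
  add(B, 2, 30, 2010); add(B, 8, 50, 2010); add(B, 4, 30, 2011)
  records <- do.call(rbind, recs)
  cohort <- filter_cohort(records, regions, 2010, 2011)$cohort

  surf <- build_rate_surface(cohort, pop, std, outcome = "overall")
  # hand computation:
  #  A 2010: 0.6*(12/8000) + 0.4*(6/2000), per 100k  = 0.6*150 + 0.4*300 = 210
  #  A 2011: 0.6*100 + 0.4*200 = 140;      average (210+140)/2 = 175
  #  B 2010: 0.6*50 + 0.4*200 = 110
  #  B 2011: 0.6*100 + 0.4*0  =  60;       average  85
  expect_equal(surf$rate_2010[surf$region_id == A], 210)
  expect_equal(surf$rate_2011[surf$region_id == A], 140)
  expect_equal(surf$average_annual_rate[surf$region_id == A], 175)
  expect_equal(surf$rate_2010[surf$region_id == B], 110)
  expect_equal(surf$rate_2011[surf$region_id == B], 60)
  expect_equal(surf$average_annual_rate[surf$region_id == B], 85)
  expect_equal(surf$total_count[surf$region_id == A], 30L)
  expect_equal(surf$total_count[surf$region_id == B], 14L)
})

test_that("average annual equals the pooled rate under constant conditions", {
  regions <- generate_regions(3, 1000, 0, seed = 1)
  std <- standard_population(data.frame(age_group = "18-44",
                                        lower = 18, upper = 44), weights = 1)
  pop <- expand.grid(region_id = "R001", age_group = "18-44",
                     year = 2010:2012, stringsAsFactors = FALSE)
  pop$count <- 10000
  recs <- do.call(rbind, lapply(1:9, function(i) {
    make_record(region_id = "R001", age = 30,
                admit = sprintf("%d-05-01", 2010 + (i - 1) %% 3),
                id = sprintf("D%07d", i))
  }))
  cohort <- filter_cohort(recs, regions, 2010, 2012)$cohort
  surf <- build_rate_surface(cohort, pop, std)
  pooled <- 9 / (3 * 10000) * 1e5
  expect_equal(surf$average_annual_rate[surf$region_id == "R001"], pooled)
})

test_that("the reliability screen flags outcomes dominated by small counts", {
  s <- reliability_screen(c(3, 5, 0, 12, 9))
  expect_false(s$reliable)
  expect_equal(s$fraction, 0.75)
  expect_true(reliability_screen(c(10, 25, 13, 400))$reliable)
  expect_warning(v <- reliability_screen(c(0, 0, 0)), "vacuously")
  expect_true(v$reliable)
})

test_that("quartile classes are rank-based with near-equal sizes", {
  q8 <- quartile_classes(stats::setNames(1:8, sprintf("R%03d", 1:8)))
  expect_equal(as.integer(table(q8)), rep(2L, 4))
  expect_identical(unname(q8[order(1:8)]),
                   rep(paste0("Q", 1:4), each = 2))
  q9 <- quartile_classes(stats::setNames(c(5, 3, 8, 1, 9, 2, 7, 4, 6),
                                         sprintf("R%03d", 1:9)))
  expect_equal(as.integer(table(q9)[paste0("Q", 1:4)]), c(3L, 2L, 2L, 2L))
  expect_identical(unname(q9["R004"]), "Q1")  # lowest rate
  expect_identical(unname(q9["R005"]), "Q4")  # highest rate
  expect_warning(qeq <- quartile_classes(stats::setNames(rep(7, 6),
                                                         sprintf("R%03d", 1:6))),
                 "equal")
  expect_true(all(qeq == "Q1"))
  expect_error(quartile_classes(c(a = 1, b = 2, c = 3)), "at least 4")
})
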