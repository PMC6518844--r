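test_that("region grids tile correctly and flag non-residential cells", {
  r <- generate_regions(3, 1000, 0, seed = 1)
  expect_equal(nrow(r), 9L)
  expect_true(all(r$residential))
  expect_equal(sort(unique(diff(sort(unique(r$centroid_x))))), 1000)
  expect_equal(r$centroid_x[1], 500)

  r2 <- generate_regions(3, 1000, 2, seed = 1)
  expect_equal(sum(r2$residential), 7L)
  expect_equal(sum(!r2$residential), 2L)

  expect_error(generate_regions(2, 1000, 0), "grid too small")
  expect_error(generate_regions(3, 1000, 9), "n_nonresidential")
})

test_that("region polygons are closed rings containing their centroid", {
  r <- generate_regions(4, 500, 3, seed = 2)
  polys <- attr(r, "polygons")
  for (i in seq_len(nrow(r))) {
    ring <- polys[[r$region_id[i]]]
    expect_identical(ring[1, ], ring[nrow(ring), ])
    expect_gte(r$centroid_x[i], min(ring[, 1]))
    expect_lte(r$centroid_x[i], max(ring[, 1]))
    expect_gte(r$centroid_y[i], min(ring[, 2]))
    expect_lte(r$centroid_y[i], max(ring[, 2]))
  }
  expect_false(anyDuplicated(r$region_id) > 0)
})

test_that("rate field is deterministic and mean multiplier is near 1", {
  r <- generate_regions(10, 1000, 0, seed = 1)
  gr <- list(family = "spherical", nugget = 0, psill = 0.25, range = 3000)
  m1 <- simulate_rate_field(r, gr, seed = 42)
  m2 <- simulate_rate_field(r, gr, seed = 42)
  expect_identical(m1, m2)
  expect_true(all(m1 > 0))
  means <- vapply(1:20, function(s) {
    mean(simulate_rate_field(r, gr, seed = s))
  }, numeric(1))
  expect_equal(mean(means), 1, tolerance = 0.05)
})

test_that("a vanishing range gives mutually independent multipliers", {
  r <- generate_regions(10, 1000, 0, seed = 1)
  # spherical correlation is exactly zero beyond the range, so a range below
  # the grid spacing produces an independent field
  gr <- list(family = "spherical", nugget = 0, psill = 0.3, range = 1)
  cors <- vapply(1:30, function(s) {
    f <- attr(simulate_rate_field(r, gr, seed = s), "log_field")
    g <- matrix(f, 10, 10)
    cor(as.vector(g[, -10]), as.vector(g[, -1]))
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.03)
})

test_that("discharge counts follow the programmed Poisson mean", {
  r <- generate_regions(4, 1000, 0, seed = 1)
  cfg <- simulation_config(grid_side = 4, n_nonresidential = 0, years = 2010L,
                           base_rate = 500, hot_block = NULL, seed = 1)
  pop <- data.frame(region_id = rep(r$region_id, each = 1),
                    age_group = "18-44", year = 2010L,
                    count = rep(12500, 16))  # 200,000 adult person-years
  mult <- stats::setNames(rep(1, 16), r$region_id)
  counts <- vapply(1:20, function(s) {
    cfg$seed <- s
    nrow(simulate_discharges(r, pop, mult, cfg))
  }, numeric(1))
  # E[N] = 200000 * 500 / 1e5 = 1000; mean of 20 draws has sd sqrt(1000/20)
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000 / 20))

  cfg$base_rate <- 0
  expect_equal(nrow(simulate_discharges(r, pop, mult, cfg)), 0L)
})

test_that("generated severity share matches the programmed mix", {
  cfg <- simulation_config(grid_side = 6, n_nonresidential = 0, years = 2010L,
                           hot_block = NULL, seed = 5)
  sim <- simulate_study(cfg)
  sev <- attr(sim$records, "severity_programmed")
  n <- length(sev)
  phat <- mean(sev == "SEVERE")
  expect_lt(abs(phat - 0.435), 3 * sqrt(0.435 * 0.565 / n))
})

test_that("every generated record round-trips its programmed severity label", {
  cfg <- simulation_config(grid_side = 5, n_nonresidential = 0, years = 2010L,
                           seed = 9)
  sim <- simulate_study(cfg)
  got <- classify_severity(sim$records$principal_dx,
                           sim$records[, sprintf("secondary_dx_%d", 1:24)])
  expect_identical(got, attr(sim$records, "severity_programmed"))
})

test_that("the whole synthetic study is deterministic in its config", {
  cfg <- simulation_config(grid_side = 5, years = 2010:2011, seed = 11,
                           n_nonresidential = 2)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$population, s2$population)
  expect_identical(s1$multipliers, s2$multipliers)
})

test_that("config validation rejects malformed probability mixes", {
  expect_error(simulation_config(severity_mix = c(NON_SEVERE = 0.5, SEVERE = 0.4)),
               "sum to 1")
  expect_error(simulation_config(sex_mix = c(F = -0.1, M = 1.1)), "negative")
  expect_error(simulation_config(grid_side = 2), "grid_side")
  expect_error(simulation_config(gr_field = list(family = "spherical",
                                                 nugget = 0, psill = 1,
                                                 range = -5)), "range")
  cfg <- simulation_config(grid_side = 4, n_nonresidential = 0)
  r <- generate_regions(4, 1000, 0, seed = 1)
  expect_error(simulate_discharges(r, data.frame(), rep(1, 16), cfg),
               "empty population")
})

test_that("non-residential regions receive no population and no records", {
  cfg <- simulation_config(grid_side = 5, n_nonresidential = 4, years = 2010L,
                           seed = 3)
  sim <- simulate_study(cfg)
  nonres <- sim$regions$region_id[!sim$regions$residential]
  expect_false(any(sim$population$region_id %in% nonres))
  expect_false(any(sim$records$region_id %in% nonres))
})
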