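test_that("distance-band weights follow the geometry", {
  xy <- cbind(c(0, 1000, 2000), c(0, 0, 0))
  w <- build_distance_band_weights(xy, 1000)
  expect_equal(lengths(w$nb), c(1L, 2L, 1L))
  expect_equal(vapply(w$weights, sum, numeric(1)), c(1, 1, 1))
  expect_equal(length(w$isolates), 0L)

  w500 <- build_distance_band_weights(xy, 500)
  expect_equal(length(w500$isolates), 3L)

  r <- generate_regions(20, 1000, 0, seed = 1)
  w8 <- build_distance_band_weights(r, 1500)
  interior <- which(r$row %in% 2:19 & r$col %in% 2:19)
  expect_true(all(lengths(w8$nb)[interior] == 8L))  # queen-like ring at 1.5 cells

  # symmetric neighbour relation before row standardisation
  A <- weights_matrix(build_distance_band_weights(r, 1500,
                                                  row_standardise = FALSE))
  expect_identical(A, t(A))
  expect_error(build_distance_band_weights(xy, 0), "bandwidth")
})

test_that("local Moran's I matches the hand-worked checkerboard", {
  w <- rook2x2()
  lm <- local_morans_i(c(1, 0, 0, 1), w)
  # z = (.5,-.5,-.5,.5); m2_i = 0.75/3 = 0.25; lag_i = -/+0.5 -> I_i = -1
  expect_equal(lm$I_i, rep(-1, 4), tolerance = 1e-14)
  expect_equal(lm$lag, c(-0.5, 0.5, 0.5, -0.5))
})

test_that("a region at the global mean has a zero local statistic", {
  xy <- cbind(c(0, 1, 2, 3, 4), c(0, 0, 0, 0, 0))
  v <- c(4, 2, 3, 1, 5)  # mean 3, third value at the mean
  w <- build_distance_band_weights(xy, 1)
  lm <- local_morans_i(v, w)
  expect_equal(lm$I_i[3], 0)
})

test_that("local Moran's I matches brute force under both m2 conventions", {
  for (n in c(10, 25)) {
    for (seed in 1:3) {
      fx <- random_fixture(n, seed * 17 + n)
      W <- weights_matrix(fx$w)
      for (conv in c("exclude_self", "global")) {
        lm <- local_morans_i(fx$values, fx$w, m2_convention = conv)
        expect_equal(lm$I_i, brute_local_moran(fx$values, W, conv),
                     tolerance = 1e-12,
                     label = sprintf("n=%d seed=%d conv=%s", n, seed, conv))
      }
    }
  }
})

test_that("permutation inference is deterministic and bounded below", {
  fx <- random_fixture(20, 5)
  p1 <- permutation_inference(fx$values, fx$w, B = 199, seed = 31)
  p2 <- permutation_inference(fx$values, fx$w, B = 199, seed = 31)
  expect_identical(p1$pseudo_p, p2$pseudo_p)
  expect_true(all(p1$pseudo_p >= 1 / 200 & p1$pseudo_p <= 1, na.rm = TRUE))
  expect_error(permutation_inference(fx$values, fx$w, B = 50), "99")

  # an overwhelming planted cluster attains the exact lower bound 1/(B+1)
  r <- generate_regions(8, 1000, 0, seed = 1)
  v <- rep(0, 64) + stats::rnorm(64, sd = 0.01)
  block <- r$row %in% 4:5 & r$col %in% 4:5
  v[block] <- 50
  w <- build_distance_band_weights(r, 1200)
  pp <- permutation_inference(v, w, B = 999, seed = 3)
  # pseudo p-values live on the exact grid {1/(B+1), ..., 1}
  expect_true(all(abs(pp$pseudo_p * 1000 - round(pp$pseudo_p * 1000)) < 1e-9))
  expect_gte(min(pp$pseudo_p[block]), 1 / 1000)
  expect_lte(min(pp$pseudo_p[block]), 5 / 1000)
})

test_that("cluster labels follow the quadrant and significance rules", {
  df <- data.frame(z = c(2, -2, 2, -2, 1, 0.5),
                   lag = c(1.5, -1, -1, 1.2, 0.8, NA),
                   pseudo_p = c(0.004, 0.02, 0.01, 0.03, 0.2, 0.01))
  lab <- classify_clusters(df, alpha = 0.05)
  expect_identical(lab, c("HH", "LL", "HL", "LH", "NS", "ISOLATE"))
  expect_error(classify_clusters(df[, c("z", "lag")]), "pseudo_p")
})

test_that("every region receives exactly one label and labels relabel consistently", {
  fx <- random_fixture(25, 9)
  set.seed(99)
  r1 <- lisa(fx$values, fx$w, B = 199, seed = 7)
  expect_equal(nrow(r1), 25L)
  expect_true(all(r1$label %in% c("HH", "LL", "HL", "LH", "NS", "ISOLATE")))
  expect_equal(sum(table(r1$label)), 25L)
  expect_true(all((r1$pseudo_p <= 0.05)[r1$label %in% c("HH", "LL", "HL", "LH")]))
  expect_true(all((r1$pseudo_p > 0.05)[r1$label == "NS"]))

  perm <- sample(25)
  w2 <- build_distance_band_weights(fx$xy[perm, ], fx$w$bandwidth,
                                    ids = fx$w$ids[perm])
  r2 <- lisa(fx$values[perm], w2, B = 199, seed = 7)
  expect_identical(r2$label, r1$label[perm])
  expect_equal(r2$pseudo_p, r1$pseudo_p[perm])
})

test_that("isolates are excluded from inference but reported", {
  set.seed(4)
  xy <- rbind(cbind(runif(12, 0, 1000), runif(12, 0, 1000)),
              c(50000, 50000))
  v <- rnorm(13)
  w <- build_distance_band_weights(xy, 2000)
  expect_equal(w$isolates, 13L)
  r <- lisa(v, w, B = 99, seed = 1)
  expect_identical(r$label[13], "ISOLATE")
  expect_true(is.na(r$pseudo_p[13]))
  expect_true(is.na(r$I_i[13]))
})
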