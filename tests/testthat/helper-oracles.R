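# Independent brute-force oracles and small fixtures. These deliberately use
# naive double loops so they share no code path with the package internals.

brute_global_moran <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  s0 <- 0
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s0 <- s0 + W[i, j]
      num <- num + W[i, j] * z[i] * z[j]
    }
  }
  (n / s0) * num / sum(z^2)
}

brute_local_moran <- function(values, W, convention = "exclude_self") {
  n <- length(values)
  z <- values - mean(values)
  vapply(seq_len(n), function(i) {
    m2 <- if (convention == "exclude_self") sum(z[-i]^2) / (n - 1) else sum(z^2) / n
    lag <- 0
    for (j in seq_len(n)) lag <- lag + W[i, j] * z[j]
    z[i] * lag / m2
  }, numeric(1))
}

# 2x2 rook lattice, row-standardised: cells at (0,0),(1,0),(0,1),(1,1);
# each cell's neighbours are the two orthogonally adjacent cells.
rook2x2 <- function() {
  xy <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  build_distance_band_weights(xy, bandwidth = 1, ids = paste0("C", 1:4))
}

random_fixture <- function(n, seed, bandwidth_q = 0.3) {
  set.seed(seed)
  xy <- cbind(runif(n, 0, 10000), runif(n, 0, 10000))
  D <- as.matrix(dist(xy))
  diag(D) <- Inf
  # keep every point connected so the naive oracle and the package agree on
  # the same region set
  bw <- max(stats::quantile(as.vector(dist(xy)), bandwidth_q),
            1.01 * max(apply(D, 1, min)))
  list(xy = xy, values = rnorm(n),
       w = build_distance_band_weights(xy, bw, ids = sprintf("F%02d", 1:n)))
}

# Minimal record row in the generator's schema.
make_record <- function(region_id = "R001", age = 40, principal = "486",
                        secondary = character(0), admit = "2012-03-01",
                        los = 5, sex = "F", race = "nh_white",
                        setting = "CAP", died = FALSE,
                        disposition = "home", id = "D0000001") {
  rec <- data.frame(record_id = id, region_id = region_id, age = age,
                    sex = sex, race_ethnicity = race, admit_date = admit,
                    discharge_date = format(as.Date(admit) + los, "%Y-%m-%d"),
                    principal_dx = principal, stringsAsFactors = FALSE)
  for (j in 1:24) {
    rec[[sprintf("secondary_dx_%d", j)]] <-
      if (j <= length(secondary)) secondary[j] else ""
  }
  rec$disposition <- disposition
  rec$died <- died
  rec$setting <- setting
  rec$year <- as.integer(format(as.Date(admit), "%Y"))
  rec
}

bind_records <- function(...) do.call(rbind, list(...))
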