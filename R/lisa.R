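# Fixed distance-band spatial weights and local Moran's I cluster detection.
# The bandwidth is the variogram-derived range of spatial autocorrelation;
# inference is by conditional permutation (each region's value held fixed, its
# neighbours' values redrawn from the remaining regions), and significant
# regions are classified into hot spots (HH), cold spots (LL) and spatial
# outliers (HL, LH) by the signs of their deviation and spatial lag.

#' Fixed distance-band spatial weights
#'
#' `j` is a neighbour of `i` iff `0 < dist(i, j) <= bandwidth`. Isolates
#' (regions with no neighbour within the bandwidth) are recorded, not
#' dropped. Weights are binary or row-standardised.
#'
#' @param centroids `region_set` (residential regions are used) or 2-column
#'   planar coordinate matrix.
#' @param bandwidth Band distance in metres (`> 0`).
#' @param row_standardise If `TRUE` (default) each row of weights sums to 1.
#' @param ids Optional region ids for a coordinate matrix.
#' @return A `distband_weights` object: ids, neighbour index list, weight
#'   list, `bandwidth`, `row_standardised`, `isolates` (indices).
#' @export
build_distance_band_weights <- function(centroids, bandwidth,
                                        row_standardise = TRUE, ids = NULL) {
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  cc <- resolve_centroids(centroids, ids)
  D <- pairwise_distances(cc$xy)
  n <- nrow(D)
  A <- D > 0 & D <= bandwidth
  diag(A) <- FALSE
  nb <- lapply(seq_len(n), function(i) which(A[i, ]))
  k <- lengths(nb)
  w <- lapply(seq_len(n), function(i) {
    if (k[i] == 0L) numeric(0)
    else if (row_standardise) rep(1 / k[i], k[i]) else rep(1, k[i])
  })
  structure(list(ids = cc$ids, nb = nb, weights = w, n = n,
                 bandwidth = bandwidth, row_standardised = row_standardise,
                 isolates = which(k == 0L)),
            class = "distband_weights")
}

#' Dense matrix form of a weights object
#'
#' @param weights A `distband_weights` object.
#' @return An `n x n` numeric matrix (isolate rows are all zero).
#' @export
weights_matrix <- function(weights) {
  n <- weights$n
  W <- matrix(0, n, n, dimnames = list(weights$ids, weights$ids))
  for (i in seq_len(n)) W[i, weights$nb[[i]]] <- weights$weights[[i]]
  W
}

#' @export
print.distband_weights <- function(x, ...) {
  cat(sprintf("Distance-band weights: %d regions, bandwidth %.1f m, %s\n",
              x$n, x$bandwidth,
              if (x$row_standardised) "row-standardised" else "binary"))
  cat(sprintf("  neighbours per region: min %d, median %.1f, max %d; %d isolate(s)\n",
              min(lengths(x$nb)), stats::median(lengths(x$nb)),
              max(lengths(x$nb)), length(x$isolates)))
  invisible(x)
}

#' @noRd
.lisa_m2 <- function(z, convention) {
  n <- length(z)
  if (convention == "exclude_self") (sum(z^2) - z^2) / (n - 1) else
    rep(sum(z^2) / n, n)
}

#' Local Moran's I
#'
#' `I_i = (z_i / m2_i) * sum_j w_ij z_j` with `z` the deviations from the
#' global mean. The default second-moment convention excludes the focal
#' region, `m2_i = sum_{k != i} z_k^2 / (n - 1)`; the pooled convention
#' `sum_k z_k^2 / n` is available as a switch. Isolates yield `NA`.
#'
#' @param values Numeric vector aligned with the weights object.
#' @param weights A [build_distance_band_weights()] object.
#' @param m2_convention `"exclude_self"` (default) or `"global"`.
#' @return Data frame with `region_id`, `z` (deviation), `lag`, `I_i`.
#' @export
local_morans_i <- function(values, weights,
                           m2_convention = c("exclude_self", "global")) {
  m2_convention <- match.arg(m2_convention)
  stopifnot(inherits(weights, "distband_weights"))
  n <- weights$n
  if (length(values) != n) stop("one value per region is required")
  if (n < 4L) stop("at least 4 regions are required")
  stop_if_constant(values)
  z <- values - mean(values)
  m2 <- .lisa_m2(z, m2_convention)
  lag <- vapply(seq_len(n), function(i) {
    if (length(weights$nb[[i]]) == 0L) NA_real_
    else sum(weights$weights[[i]] * z[weights$nb[[i]]])
  }, numeric(1))
  data.frame(region_id = weights$ids, z = z, lag = lag, I_i = z * lag / m2,
             stringsAsFactors = FALSE)
}

#' Conditional permutation inference for local Moran's I
#'
#' For each region the observed value is held fixed while its neighbours'
#' values are redrawn `B` times without replacement from the remaining
#' `n - 1` values; the pseudo p-value is `(G + 1)/(B + 1)` where `G` counts
#' permuted statistics at least as extreme as the observed one in the
#' direction of its sign (`alternative = "one_sided_by_sign"`, the common
#' LISA convention) or in absolute value (`"two_sided"`). Each region draws
#' from an independent seeded stream, so results do not depend on evaluation
#' order and are reproducible.
#'
#' @param values Numeric vector aligned with the weights object.
#' @param weights A [build_distance_band_weights()] object.
#' @param B Number of permutations (`>= 99`); the smallest attainable pseudo
#'   p-value is exactly `1/(B+1)`.
#' @param seed Master seed.
#' @param alternative Tail convention (see above).
#' @param m2_convention Second-moment convention, as in [local_morans_i()].
#' @return Data frame from [local_morans_i()] plus a `pseudo_p` column
#'   (`NA` for isolates).
#' @export
permutation_inference <- function(values, weights, B = 999, seed = 1L,
                                  alternative = c("one_sided_by_sign",
                                                  "two_sided"),
                                  m2_convention = c("exclude_self", "global")) {
  alternative <- match.arg(alternative)
  m2_convention <- match.arg(m2_convention)
  if (B < 99) stop("at least 99 permutations are required")
  lm <- local_morans_i(values, weights, m2_convention)
  n <- weights$n
  z <- lm$z
  m2 <- .lisa_m2(z, m2_convention)
  # Independent per-region streams keyed to the region *id* (not its row
  # position), drawing from the sorted value pool: results are invariant to
  # evaluation order and to any consistent relabelling of the regions.
  set.seed(seed)
  seed_pool <- sample.int(.Machine$integer.max - 1L, n)
  region_seeds <- seed_pool[match(weights$ids, sort(weights$ids))]
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    k <- length(weights$nb[[i]])
    if (k == 0L) next
    set.seed(region_seeds[i])
    others <- sort(z[-i], method = "radix")
    idx <- vapply(seq_len(B), function(b) sample.int(n - 1L, k), integer(k))
    perm_lag <- drop(weights$weights[[i]] %*% matrix(others[idx], nrow = k))
    perm_I <- z[i] * perm_lag / m2[i]
    obs <- lm$I_i[i]
    G <- if (alternative == "two_sided") {
      sum(abs(perm_I) >= abs(obs))
    } else if (obs >= 0) sum(perm_I >= obs) else sum(perm_I <= obs)
    p[i] <- (G + 1) / (B + 1)
  }
  lm$pseudo_p <- p
  lm
}

#' Classify LISA cluster membership
#'
#' Significant regions (`pseudo_p <= alpha`) are labelled by quadrant:
#' positive deviation and positive lag is a hot spot (`HH`), negative/negative
#' a cold spot (`LL`), and the mixed quadrants are spatial outliers (`HL`:
#' high rate amid low neighbours; `LH`: low amid high). Non-significant
#' regions are `NS`; regions without neighbours are `ISOLATE`.
#'
#' @param x Data frame with columns `z` (or `z_value`), `lag` and `pseudo_p`
#'   (e.g. from [permutation_inference()]), or a numeric deviation vector.
#' @param lag,pseudo_p Numeric vectors when `x` is numeric.
#' @param alpha Significance level.
#' @return Character vector of labels.
#' @export
classify_clusters <- function(x, lag = NULL, pseudo_p = NULL, alpha = 0.05) {
  if (is.data.frame(x)) {
    z <- x$z %||% x$z_value
    lag <- x$lag
    pseudo_p <- x$pseudo_p
  } else z <- x
  if (is.null(pseudo_p)) stop("pseudo_p is required to classify clusters")
  n <- length(z)
  label <- rep("NS", n)
  isolate <- is.na(lag)
  label[isolate] <- "ISOLATE"
  sig <- !isolate & !is.na(pseudo_p) & pseudo_p <= alpha
  label[sig & z > 0 & lag > 0] <- "HH"
  label[sig & z < 0 & lag < 0] <- "LL"
  label[sig & z > 0 & lag < 0] <- "HL"
  label[sig & z < 0 & lag > 0] <- "LH"
  label
}

#' Local Moran's I cluster analysis
#'
#' One-call fit: computes local Moran's I for every region, runs conditional
#' permutation inference, and classifies hot spots, cold spots and spatial
#' outliers at the given significance level.
#'
#' @param values Numeric vector (typically average annual age-adjusted rates),
#'   aligned with the weights object.
#' @param weights A [build_distance_band_weights()] object (bandwidth usually
#'   the variogram effective range).
#' @param B Permutations (default 999, so the minimum pseudo p is 0.001).
#' @param alpha Significance level (default 0.05).
#' @param seed Master seed for the permutation streams.
#' @param ... Passed to [permutation_inference()] (`alternative`,
#'   `m2_convention`).
#' @return A `lisa` data frame: `region_id`, `value`, `z_value` (standardised
#'   deviation), `lag`, `I_i`, `pseudo_p`, `label`; attributes carry `alpha`,
#'   `B`, `seed` and the bandwidth.
#' @export
lisa <- function(values, weights, B = 999, alpha = 0.05, seed = 1L, ...) {
  pi_df <- permutation_inference(values, weights, B = B, seed = seed, ...)
  label <- classify_clusters(pi_df, alpha = alpha)
  out <- data.frame(region_id = pi_df$region_id, value = values,
                    z_value = pi_df$z / stats::sd(values),
                    lag = pi_df$lag, I_i = pi_df$I_i,
                    pseudo_p = pi_df$pseudo_p, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  attr(out, "bandwidth") <- weights$bandwidth
  class(out) <- c("lisa", "data.frame")
  out
}

#' @export
print.lisa <- function(x, ...) {
  cat(sprintf("LISA cluster analysis: %d regions, bandwidth %.1f m, B = %d, alpha = %g\n",
              nrow(x), attr(x, "bandwidth"), attr(x, "B"), attr(x, "alpha")))
  print(table(factor(x$label, levels = c("HH", "LL", "HL", "LH", "NS", "ISOLATE"))))
  invisible(x)
}

#' @export
summary.lisa <- function(object, ...) {
  counts <- table(factor(object$label,
                         levels = c("HH", "LL", "HL", "LH", "NS", "ISOLATE")))
  out <- list(counts = counts, alpha = attr(object, "alpha"),
              B = attr(object, "B"), bandwidth = attr(object, "bandwidth"),
              min_pseudo_p = min(object$pseudo_p, na.rm = TRUE))
  class(out) <- "summary.lisa"
  out
}

#' @export
print.summary.lisa <- function(x, ...) {
  cat(sprintf("LISA summary (bandwidth %.1f m, B = %d, alpha = %g)\n",
              x$bandwidth, x$B, x$alpha))
  print(x$counts)
  cat(sprintf("smallest attainable pseudo p: %.4g; observed minimum: %.4g\n",
              1 / (x$B + 1), x$min_pseudo_p))
  invisible(x)
}

#' Map LISA labels
#'
#' Draws region polygons (if a `region_set` is supplied) or centroids,
#' coloured by cluster label.
#'
#' @param x A `lisa` object.
#' @param regions Optional `region_set` whose polygons to draw.
#' @param ... Further arguments to `plot`.
#' @export
plot.lisa <- function(x, regions = NULL, ...) {
  cols <- c(HH = "#b2182b", LL = "#2166ac", HL = "#ef8a62", LH = "#67a9cf",
            NS = "grey85", ISOLATE = "grey50")
  fill <- cols[x$label]
  if (!is.null(regions) && inherits(regions, "region_set")) {
    polys <- attr(regions, "polygons")[x$region_id]
    xr <- range(unlist(lapply(polys, function(p) p[, 1])))
    yr <- range(unlist(lapply(polys, function(p) p[, 2])))
    plot(NA, xlim = xr, ylim = yr, asp = 1, xlab = "x (m)", ylab = "y (m)", ...)
    for (i in seq_along(polys)) {
      graphics::polygon(polys[[i]][, 1], polys[[i]][, 2], col = fill[i],
                        border = "white")
    }
  } else {
    stop("supply a region_set to map labels")
  }
  graphics::legend("topright", legend = names(cols), fill = cols, cex = 0.7,
                   bg = "white")
  invisible(x)
}
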