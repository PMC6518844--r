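# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Round half away from zero, the convention used for all printed percentages.
#' @noRd
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
pairwise_distances <- function(xy) {
  as.matrix(stats::dist(xy))
}

# Probability vectors must sum to 1 within 1e-9.
#' @noRd
check_prob_vector <- function(p, name) {
  if (!is.numeric(p) || length(p) < 1L) {
    stop(sprintf("'%s' must be a numeric probability vector", name), call. = FALSE)
  }
  if (any(p < 0)) {
    stop(sprintf("'%s' contains negative probabilities", name), call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("'%s' must sum to 1 (got %.10f)", name, sum(p)), call. = FALSE)
  }
  invisible(p)
}

# Extract planar centroids + ids from a region_set (residential only) or a
# plain 2-column coordinate matrix.
#' @noRd
resolve_centroids <- function(x, ids = NULL, residential_only = TRUE) {
  if (inherits(x, "region_set")) {
    r <- if (residential_only) x[x$residential, , drop = FALSE] else x
    list(xy = cbind(r$centroid_x, r$centroid_y), ids = r$region_id)
  } else {
    xy <- as.matrix(x)
    if (ncol(xy) != 2L) stop("centroids must be a 2-column matrix of planar coordinates")
    ids <- ids %||% rownames(xy) %||% sprintf("P%03d", seq_len(nrow(xy)))
    list(xy = xy, ids = as.character(ids))
  }
}

#' @noRd
stop_if_constant <- function(values, what = "values") {
  if (length(unique(values[!is.na(values)])) < 2L) {
    stop(sprintf("%s are constant: no spatial structure is estimable", what), call. = FALSE)
  }
  invisible(values)
}
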