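# Synthetic study generator: region geometries, age-structured populations, a
# latent spatially autocorrelated rate surface, and patient-level discharge
# records. Every downstream stage of the pipeline can be exercised on these
# data, with the spatial range, hot-spot contrasts and case mix all programmed
# and therefore known.

#' Simulation configuration for the synthetic study generator
#'
#' Collects every parameter of the synthetic study in one validated object.
#' The defaults emulate the scale of a large-city discharge dataset: a 14 x 14
#' grid of 2 km neighbourhoods (8 of them non-residential, leaving 188
#' residential units), five study years, a spherical latent field with a 5 km
#' range, an adult hospitalisation rate of 440 per 100,000 person-years, a
#' 56.5/43.5 non-severe/severe split, and hot/cold contrasts in race/ethnicity,
#' length of stay, disposition and in-hospital death.
#'
#' @param grid_side Number of cells per grid side (>= 3).
#' @param cell_size Cell width in metres.
#' @param n_nonresidential Number of regions flagged non-residential.
#' @param years Integer study years.
#' @param gr_field List with `family` ("spherical", "exponential" or
#'   "gaussian"), `nugget` (c0), `psill` (partial sill c) and `range`
#'   (range parameter a, metres) of the latent Gaussian field's variogram.
#' @param base_rate Baseline events per 100,000 person-years.
#' @param mean_population Mean adult population per residential region.
#' @param age_groups Data frame of adult age bands (see [default_age_groups()]).
#' @param age_group_mix Probability vector over `age_groups`, or a list with
#'   `hot` and `cold` vectors for cluster-conditional population structure.
#' @param sex_mix,race_mix,severity_mix,setting_mix Probability vectors
#'   (race/ethnicity may be a `hot`/`cold` list).
#' @param los_model List with `hot` and `cold` components, each
#'   `list(median, sigma)` for a lognormal length of stay in days.
#' @param death_prob Named vector `c(hot = , cold = )` of in-hospital death
#'   probabilities.
#' @param disposition_mix `hot`/`cold` list of probability vectors over
#'   discharge dispositions among survivors.
#' @param hot_block `NULL`, or `list(rows =, cols =, multiplier =)` defining a
#'   contiguous block of grid cells whose rate is multiplied by `multiplier`
#'   and whose records receive the "hot" conditional mixes; everything outside
#'   the block uses the "cold" mixes.
#' @param seed Master seed; identical configurations give byte-identical data.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(grid_side = 14L,
                              cell_size = 2000,
                              n_nonresidential = 8L,
                              years = 2010:2014,
                              gr_field = list(family = "spherical", nugget = 0,
                                              psill = 0.25, range = 5000),
                              base_rate = 440,
                              mean_population = 30000,
                              age_groups = default_age_groups(),
                              age_group_mix = NULL,
                              sex_mix = c(F = 0.52, M = 0.48),
                              race_mix = NULL,
                              severity_mix = c(NON_SEVERE = 0.565, SEVERE = 0.435),
                              setting_mix = c(CAP = 0.624, HCAP = 0.272,
                                              HAP = 0.087, VAP = 0.017),
                              los_model = list(hot = list(median = 10, sigma = 0.81),
                                               cold = list(median = 5, sigma = 0.89)),
                              death_prob = c(hot = 0.245, cold = 0.101),
                              disposition_mix = NULL,
                              hot_block = list(rows = 2:5, cols = 2:5, multiplier = 2.5),
                              seed = 1L) {
  if (grid_side < 3L) stop("grid_side must be at least 3")
  if (length(years) < 1L) stop("at least one study year is required")
  fam <- match.arg(gr_field$family, c("spherical", "exponential", "gaussian"))
  gr_field$family <- fam
  if (is.null(gr_field$nugget)) gr_field$nugget <- 0
  if (gr_field$nugget < 0 || gr_field$psill < 0) stop("nugget and partial sill must be >= 0")
  if (gr_field$range <= 0) stop("variogram range parameter must be > 0")

  if (is.null(age_group_mix)) {
    age_group_mix <- list(
      # hot-spot neighbourhoods skew younger, cold spots older
      hot  = c(`18-44` = 0.58, `45-64` = 0.28, `65-74` = 0.08, `75-84` = 0.04, `85+` = 0.02),
      cold = c(`18-44` = 0.44, `45-64` = 0.31, `65-74` = 0.13, `75-84` = 0.08, `85+` = 0.04)
    )
  }
  if (is.null(race_mix)) {
    race_mix <- list(
      hot  = c(nh_white = 0.273, nh_black = 0.355, hispanic = 0.229, nh_other = 0.125) / 0.982,
      cold = c(nh_white = 0.560, nh_black = 0.079, hispanic = 0.105, nh_other = 0.204) / 0.948
    )
  }
  if (is.null(disposition_mix)) {
    disposition_mix <- list(
      hot  = c(home = 0.196, skilled_nursing = 0.485, other = 0.074) / 0.755,
      cold = c(home = 0.661, skilled_nursing = 0.130, other = 0.108) / 0.899
    )
  }

  check_mix <- function(m, name) {
    if (is.list(m)) {
      check_prob_vector(m$hot, paste0(name, "$hot"))
      check_prob_vector(m$cold, paste0(name, "$cold"))
    } else {
      check_prob_vector(m, name)
    }
  }
  check_mix(age_group_mix, "age_group_mix")
  check_mix(sex_mix, "sex_mix")
  check_mix(race_mix, "race_mix")
  check_mix(severity_mix, "severity_mix")
  check_mix(setting_mix, "setting_mix")
  check_mix(disposition_mix$hot, "disposition_mix$hot")
  check_mix(disposition_mix$cold, "disposition_mix$cold")
  if (!all(c("hot", "cold") %in% names(death_prob))) {
    stop("death_prob must be named c(hot =, cold =)")
  }

  structure(list(
    grid_side = as.integer(grid_side), cell_size = cell_size,
    n_nonresidential = as.integer(n_nonresidential), years = as.integer(years),
    gr_field = gr_field, base_rate = base_rate,
    mean_population = mean_population, age_groups = age_groups,
    age_group_mix = age_group_mix, sex_mix = sex_mix, race_mix = race_mix,
    severity_mix = severity_mix, setting_mix = setting_mix,
    los_model = los_model, death_prob = death_prob,
    disposition_mix = disposition_mix, hot_block = hot_block,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Generate a square grid of synthetic regions
#'
#' Tiles a `grid_side` x `grid_side` grid of square neighbourhoods with
#' centroids at cell centres (planar coordinates in metres). A random subset of
#' regions is flagged non-residential; those receive no population and no
#' discharge records, mirroring the exclusion of non-residential neighbourhoods
#' from the study population.
#'
#' @param grid_side Cells per side (>= 3).
#' @param cell_size Cell width in metres.
#' @param n_nonresidential How many regions to flag non-residential
#'   (`0 <= n < grid_side^2`).
#' @param seed Seed for the non-residential draw.
#'
#' @return A `region_set`: a data frame with `region_id`, grid `row`/`col`,
#'   `centroid_x`, `centroid_y` (metres) and `residential`; polygon rings are
#'   kept in the `"polygons"` attribute as closed 5 x 2 matrices.
#' @export
generate_regions <- function(grid_side, cell_size, n_nonresidential = 0L, seed = 1L) {
  if (grid_side < 3L) stop("grid too small: grid_side must be at least 3")
  n <- as.integer(grid_side)^2
  if (n_nonresidential < 0L || n_nonresidential >= n) {
    stop("n_nonresidential must satisfy 0 <= n_nonresidential < grid_side^2")
  }
  col <- rep(seq_len(grid_side), times = grid_side)
  row <- rep(seq_len(grid_side), each = grid_side)
  cx <- (col - 0.5) * cell_size
  cy <- (row - 0.5) * cell_size
  ids <- sprintf("R%03d", seq_len(n))
  set.seed(seed)
  nonres <- if (n_nonresidential > 0L) sample.int(n, n_nonresidential) else integer(0)
  residential <- !(seq_len(n) %in% nonres)
  polys <- lapply(seq_len(n), function(k) {
    x0 <- (col[k] - 1) * cell_size; x1 <- col[k] * cell_size
    y0 <- (row[k] - 1) * cell_size; y1 <- row[k] * cell_size
    cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
  })
  names(polys) <- ids
  out <- data.frame(region_id = ids, row = row, col = col,
                    centroid_x = cx, centroid_y = cy,
                    residential = residential, stringsAsFactors = FALSE)
  attr(out, "polygons") <- polys
  attr(out, "cell_size") <- cell_size
  attr(out, "grid_side") <- as.integer(grid_side)
  class(out) <- c("region_set", "data.frame")
  out
}

#' Simulate a latent spatially autocorrelated rate surface
#'
#' Draws one Gaussian random field value per residential region from the
#' covariance implied by the programmed variogram (nugget `c0`, partial sill
#' `c`, range parameter `a`), by dense Cholesky factorisation of the covariance
#' over region centroids, and transforms it to a positive rate multiplier
#' `exp(field - c/2)` so that the mean multiplier is approximately 1 and
#' `base_rate` stays interpretable.
#'
#' @param regions A `region_set`.
#' @param gr_field List with `family`, `nugget`, `psill`, `range` (metres).
#' @param base_rate Optional baseline rate; if given, the expected per-region
#'   rate `base_rate * multiplier` is attached as an attribute.
#' @param seed Seed; the same seed gives a bit-identical field.
#'
#' @return Named vector of positive multipliers (one per residential region),
#'   with the latent Gaussian field in the `"log_field"` attribute.
#' @export
simulate_rate_field <- function(regions, gr_field, base_rate = NULL, seed = 1L) {
  res <- regions[regions$residential, , drop = FALSE]
  n <- nrow(res)
  fam <- match.arg(gr_field$family, c("spherical", "exponential", "gaussian"))
  c0 <- gr_field$nugget %||% 0
  cc <- gr_field$psill
  a <- gr_field$range
  if (a <= 0) stop("variogram range parameter must be > 0")
  if (c0 < 0 || cc < 0) stop("nugget and partial sill must be >= 0")

  set.seed(seed)
  spatial <- 0
  if (cc > 0) {
    D <- pairwise_distances(cbind(res$centroid_x, res$centroid_y))
    rho <- switch(fam,
      spherical   = ifelse(D >= a, 0, 1 - 1.5 * D / a + 0.5 * (D / a)^3),
      exponential = exp(-D / a),
      gaussian    = exp(-(D / a)^2)
    )
    C <- cc * rho
    U <- NULL
    for (jit in c(1e-10, 1e-8, 1e-6)) {
      U <- tryCatch(chol(C + diag(jit * cc, n)), error = function(e) NULL)
      if (!is.null(U)) break
    }
    if (is.null(U)) {
      stop("covariance matrix is not positive definite even after jitter")
    }
    spatial <- drop(crossprod(U, stats::rnorm(n)))
  }
  nugget_part <- if (c0 > 0) stats::rnorm(n, sd = sqrt(c0)) else 0
  field <- spatial + nugget_part
  mult <- exp(field - cc / 2)
  names(mult) <- res$region_id
  attr(mult, "log_field") <- stats::setNames(field + numeric(n), res$region_id)
  if (!is.null(base_rate)) attr(mult, "expected_rate") <- base_rate * mult
  mult
}

#' Region ids inside the programmed hot block
#'
#' @param regions A `region_set` with grid `row`/`col` columns.
#' @param hot_block `list(rows =, cols =, ...)` or `NULL`.
#' @return Character vector of residential region ids in the block (empty if
#'   `hot_block` is `NULL`).
#' @export
hot_region_ids <- function(regions, hot_block) {
  if (is.null(hot_block)) return(character(0))
  sel <- regions$row %in% hot_block$rows & regions$col %in% hot_block$cols &
    regions$residential
  regions$region_id[sel]
}

#' Boost rate multipliers inside the hot block
#'
#' @param multipliers Named multiplier vector from [simulate_rate_field()].
#' @param regions A `region_set`.
#' @param hot_block `list(rows =, cols =, multiplier =)` or `NULL` (no-op).
#' @return The multiplier vector with block regions multiplied by
#'   `hot_block$multiplier`.
#' @export
apply_hot_block <- function(multipliers, regions, hot_block) {
  if (is.null(hot_block)) return(multipliers)
  ids <- hot_region_ids(regions, hot_block)
  boost <- hot_block$multiplier %||% 1
  multipliers[names(multipliers) %in% ids] <-
    multipliers[names(multipliers) %in% ids] * boost
  multipliers
}

#' Generate an age-structured population table
#'
#' Residential regions receive an adult population drawn around
#' `mean_population` (uniform between 70% and 130% of it), split across age
#' groups by the configured mix (cluster-conditional if `age_group_mix` is a
#' `hot`/`cold` list) and held constant across study years. Non-residential
#' regions receive no population.
#'
#' @param regions A `region_set`.
#' @param config A [simulation_config()].
#' @return Long data frame with `region_id`, `age_group`, `year`, `count`.
#' @export
generate_population <- function(regions, config) {
  res <- regions[regions$residential, , drop = FALSE]
  hot <- hot_region_ids(regions, config$hot_block)
  groups <- config$age_groups$age_group
  set.seed(config$seed + 1L)
  totals <- round(stats::runif(nrow(res), 0.7, 1.3) * config$mean_population)
  rows <- vector("list", nrow(res))
  for (i in seq_len(nrow(res))) {
    mix <- config$age_group_mix
    if (is.list(mix)) mix <- if (res$region_id[i] %in% hot) mix$hot else mix$cold
    counts <- as.integer(round(totals[i] * as.numeric(mix[groups])))
    rows[[i]] <- expand.grid(region_id = res$region_id[i], age_group = groups,
                             year = config$years, stringsAsFactors = FALSE)
    rows[[i]]$count <- rep(counts, times = length(config$years))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "out.attrs") <- NULL
  out
}

# ICD-9-CM codes used by the generator; chosen so that severity classification
# can round-trip the programmed label exactly.
.gen_codes <- list(
  pneumonia_principal = c("481", "482.0", "485", "486"),
  pneumonia_secondary = c("486", "481", "482.41"),
  severe_principal    = c("038.9", "518.81", "995.92", "799.1"),
  comorbidity         = c("250.00", "401.9", "428.0", "496", "585.9")
)

#' Simulate patient-level discharge records
#'
#' For every residential region x age group x study year, the number of events
#' is drawn Poisson with mean `population x base_rate x multiplier / 100000`.
#' Each event becomes one discharge record with demographics, a principal (and,
#' for severe cases, secondary) ICD-9-CM diagnosis consistent with its
#' programmed severity, a setting-of-acquisition label, length of stay,
#' disposition and death flag. Regions inside the configured hot block use the
#' "hot" conditional mixes, all others the "cold" mixes.
#'
#' @param regions A `region_set`.
#' @param population Long population table from [generate_population()].
#' @param multipliers Named per-region rate multipliers covering all
#'   residential regions.
#' @param config A [simulation_config()].
#' @return Data frame of discharge records with columns `record_id`,
#'   `region_id`, `age`, `sex`, `race_ethnicity`, `admit_date`,
#'   `discharge_date`, `principal_dx`, `secondary_dx_1` .. `secondary_dx_24`,
#'   `disposition`, `died`, `setting`, `year`.
#' @export
simulate_discharges <- function(regions, population, multipliers, config) {
  if (is.null(population) || nrow(population) == 0L) {
    stop("empty population table")
  }
  res_ids <- regions$region_id[regions$residential]
  if (!all(res_ids %in% names(multipliers))) {
    stop("multipliers must cover all residential regions")
  }
  pop <- population[population$region_id %in% res_ids, , drop = FALSE]
  lambda <- pop$count * config$base_rate * multipliers[pop$region_id] / 1e5
  set.seed(config$seed + 3L)
  nev <- stats::rpois(nrow(pop), lambda)
  total <- sum(nev)
  if (total == 0L) return(.empty_records())

  idx <- rep(seq_len(nrow(pop)), nev)
  region_id <- pop$region_id[idx]
  age_group <- pop$age_group[idx]
  year <- pop$year[idx]
  hot_ids <- hot_region_ids(regions, config$hot_block)
  is_hot <- region_id %in% hot_ids

  ag <- config$age_groups
  lo <- ag$lower[match(age_group, ag$age_group)]
  hi <- ag$upper[match(age_group, ag$age_group)]
  age <- lo + floor(stats::runif(total) * (hi - lo + 1))

  draw_mix <- function(n, mix) {
    if (n == 0L) return(character(0))
    sample(names(mix), n, replace = TRUE, prob = as.numeric(mix))
  }
  pick_cond <- function(mix, hot) if (is.list(mix)) (if (hot) mix$hot else mix$cold) else mix

  sex <- race <- severity <- setting <- disposition <- character(total)
  los <- integer(total)
  died <- logical(total)
  for (side in c(TRUE, FALSE)) {
    m <- is_hot == side
    nm <- sum(m)
    if (nm == 0L) next
    key <- if (side) "hot" else "cold"
    sex[m] <- draw_mix(nm, pick_cond(config$sex_mix, side))
    race[m] <- draw_mix(nm, pick_cond(config$race_mix, side))
    severity[m] <- draw_mix(nm, pick_cond(config$severity_mix, side))
    setting[m] <- draw_mix(nm, pick_cond(config$setting_mix, side))
    lm <- config$los_model[[key]]
    los[m] <- pmax(1L, as.integer(round(stats::rlnorm(nm, log(lm$median), lm$sigma))))
    died[m] <- stats::runif(nm) < config$death_prob[[key]]
    surv <- m & !died
    disposition[m & died] <- "expired"
    disposition[surv] <- draw_mix(sum(surv), config$disposition_mix[[key]])
  }

  principal <- character(total)
  sec <- matrix("", nrow = total, ncol = 24L)
  ns <- severity == "NON_SEVERE"
  principal[ns] <- sample(.gen_codes$pneumonia_principal, sum(ns), replace = TRUE)
  principal[!ns] <- sample(.gen_codes$severe_principal, sum(!ns), replace = TRUE)
  # severe cases carry their pneumonia diagnosis as a secondary code
  sec[!ns, 1L] <- sample(.gen_codes$pneumonia_secondary, sum(!ns), replace = TRUE)
  n_com <- sample(0:2, total, replace = TRUE)
  for (j in 1:2) {
    fill <- n_com >= j
    col <- ifelse(ns, j, j + 1L)
    picks <- sample(.gen_codes$comorbidity, sum(fill), replace = TRUE)
    sec[cbind(which(fill), col[fill])] <- picks
  }

  day0 <- as.Date(sprintf("%d-01-01", year))
  admit <- day0 + floor(stats::runif(total) * 365)
  discharge <- admit + los

  out <- data.frame(
    record_id = sprintf("D%07d", seq_len(total)),
    region_id = region_id, age = as.integer(age), sex = sex,
    race_ethnicity = race, admit_date = format(admit, "%Y-%m-%d"),
    discharge_date = format(discharge, "%Y-%m-%d"),
    principal_dx = principal, stringsAsFactors = FALSE
  )
  colnames(sec) <- sprintf("secondary_dx_%d", 1:24)
  out <- cbind(out, as.data.frame(sec, stringsAsFactors = FALSE))
  out$disposition <- disposition
  out$died <- died
  out$setting <- setting
  out$year <- as.integer(year)
  attr(out, "severity_programmed") <- severity
  out
}

#' @noRd
.empty_records <- function() {
  out <- data.frame(record_id = character(0), region_id = character(0),
                    age = integer(0), sex = character(0),
                    race_ethnicity = character(0), admit_date = character(0),
                    discharge_date = character(0), principal_dx = character(0),
                    stringsAsFactors = FALSE)
  for (j in 1:24) out[[sprintf("secondary_dx_%d", j)]] <- character(0)
  out$disposition <- character(0)
  out$died <- logical(0)
  out$setting <- character(0)
  out$year <- integer(0)
  out
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper generating regions, population, the latent rate surface
#' (with the hot-block boost applied) and discharge records from one
#' configuration. All randomness derives from `config$seed`, so identical
#' configurations yield byte-identical outputs.
#'
#' @param config A [simulation_config()].
#' @return List with `regions`, `population`, `multipliers`, `records`,
#'   `hot_regions` and the `config` itself.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  regions <- generate_regions(config$grid_side, config$cell_size,
                              config$n_nonresidential, seed = config$seed)
  population <- generate_population(regions, config)
  mult <- simulate_rate_field(regions, config$gr_field, config$base_rate,
                              seed = config$seed + 2L)
  mult <- apply_hot_block(mult, regions, config$hot_block)
  records <- simulate_discharges(regions, population, mult, config)
  list(regions = regions, population = population, multipliers = mult,
       records = records, hot_regions = hot_region_ids(regions, config$hot_block),
       config = config)
}
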