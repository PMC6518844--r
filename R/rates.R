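# Direct age standardisation of neighbourhood hospitalisation rates.
# Age-specific rates per 100,000 are weighted by the proportion of a standard
# population in each age group and summed; annual adjusted rates are averaged
# over study years.

# US 2000 standard million by 5-year age band (counts sum to 1,000,000);
# used to derive adult standard weights for arbitrary cut points.
.us2000_std_million <- data.frame(
  lower = c(0, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85),
  upper = c(4, 9, 14, 19, 24, 29, 34, 39, 44, 49, 54, 59, 64, 69, 74, 79, 84, 99),
  count = c(69135, 72533, 73032, 72169, 66478, 64529, 71044, 80762, 81851,
            72118, 62716, 48454, 38793, 34264, 31773, 26999, 17842, 15508)
)

#' Default adult age groups
#'
#' Conventional adult standardisation bands: 18-44, 45-64, 65-74, 75-84, 85+.
#'
#' @return Data frame with `age_group`, `lower`, `upper`.
#' @export
default_age_groups <- function() {
  data.frame(age_group = c("18-44", "45-64", "65-74", "75-84", "85+"),
             lower = c(18L, 45L, 65L, 75L, 85L),
             upper = c(44L, 64L, 74L, 84L, 99L),
             stringsAsFactors = FALSE)
}

#' Standard-population age weights
#'
#' Builds the standard weight `p_g` for each adult age group. By default the
#' weights are derived from the US 2000 standard million, restricted to the
#' adult groups and renormalised to sum to 1 (single years are assumed uniform
#' within each 5-year standard band). Explicit weights may be supplied instead
#' and are renormalised.
#'
#' @param groups Data frame of age bands (see [default_age_groups()]).
#' @param weights Optional numeric weights, one per group (renormalised).
#' @return Object of class `standard_population`: `groups` plus a `weight`
#'   column summing to 1.
#' @export
standard_population <- function(groups = default_age_groups(), weights = NULL) {
  if (is.null(weights)) {
    std <- .us2000_std_million
    weights <- vapply(seq_len(nrow(groups)), function(i) {
      lo <- groups$lower[i]; hi <- groups$upper[i]
      # overlap of [lo, hi] with each standard band, in whole years of age
      ov <- pmax(0, pmin(hi, std$upper) - pmax(lo, std$lower) + 1)
      sum(std$count * ov / (std$upper - std$lower + 1))
    }, numeric(1))
  }
  if (length(weights) != nrow(groups)) stop("one weight per age group is required")
  if (any(weights < 0)) stop("standard weights must be >= 0")
  if (sum(weights) <= 0) stop("standard weights must not all be zero")
  out <- groups
  out$weight <- weights / sum(weights)
  class(out) <- c("standard_population", "data.frame")
  out
}

#' Assign ages to age groups
#'
#' @param age Numeric ages.
#' @param std A [standard_population()] (or any data frame with `age_group`,
#'   `lower`, `upper`).
#' @return Character vector of group labels (`NA` outside all groups).
#' @export
assign_age_group <- function(age, std = standard_population()) {
  out <- rep(NA_character_, length(age))
  for (i in seq_len(nrow(std))) {
    out[age >= std$lower[i] & age <= std$upper[i]] <- std$age_group[i]
  }
  out
}

#' Age-specific hospitalisation rate per 100,000
#'
#' @param events Event count(s), `>= 0`.
#' @param population Person denominator(s).
#' @return `events / population * 100000`; a zero population with zero events
#'   gives `NA` with a warning (the group is skipped), a zero population with
#'   events is an error.
#' @export
age_specific_rate <- function(events, population) {
  if (any(events < 0)) stop("event counts must be >= 0")
  bad <- population == 0 & events > 0
  if (any(bad)) stop("events observed in an age group with zero population")
  und <- population == 0 & events == 0
  if (any(und)) {
    warning("zero population and zero events: rate undefined, group skipped")
  }
  out <- ifelse(und, NA_real_, events / population * 1e5)
  out
}

#' Directly age-adjusted rate
#'
#' Multiplies each age-specific rate by the standard-population proportion of
#' its age group and sums. Weights are renormalised over the groups actually
#' present, so a single-group input returns the crude rate unchanged.
#'
#' @param age_rates Named vector of age-specific rates per 100,000 (names are
#'   age-group labels, a subset of `std$age_group`). `NA` rates are dropped.
#' @param std A [standard_population()].
#' @return The adjusted rate per 100,000.
#' @export
direct_adjusted_rate <- function(age_rates, std = standard_population()) {
  age_rates <- age_rates[!is.na(age_rates)]
  if (length(age_rates) == 0L) stop("no age-specific rates supplied")
  if (!all(names(age_rates) %in% std$age_group)) {
    stop("age_rates contain groups absent from the standard population")
  }
  w <- std$weight[match(names(age_rates), std$age_group)]
  w <- w / sum(w)
  sum(w * age_rates)
}

#' Build a per-region rate surface for one outcome
#'
#' For every region in the population table: annual directly age-adjusted
#' rates per 100,000 for each study year, their arithmetic mean as the average
#' annual rate, and the total event count. Regions with zero total population
#' are flagged and carry no rate.
#'
#' @param cohort Cohort data frame from [filter_cohort()].
#' @param population Long population table (`region_id`, `age_group`, `year`,
#'   `count`).
#' @param std A [standard_population()].
#' @param outcome One of `"overall"`, `"severe"`, `"non_severe"`, `"CAP"`,
#'   `"HCAP"`, `"HAP"`, `"VAP"`.
#' @param years Study years (default: all years in `population`).
#' @return A `rate_surface` data frame: `region_id`, one `rate_<year>` column
#'   per year, `average_annual_rate`, `total_count` and `small_count`
#'   (`TRUE` when `0 < total_count < 10`).
#' @export
build_rate_surface <- function(cohort, population, std = standard_population(),
                               outcome = "overall", years = NULL) {
  years <- as.integer(years %||% sort(unique(population$year)))
  sub <- cohort[outcome_mask(cohort, outcome), , drop = FALSE]
  sub$age_group <- assign_age_group(sub$age, std)
  regions <- unique(population$region_id)
  groups <- std$age_group

  ev <- array(0, dim = c(length(regions), length(groups), length(years)),
              dimnames = list(regions, groups, years))
  if (nrow(sub) > 0L) {
    t3 <- table(factor(sub$region_id, levels = regions),
                factor(sub$age_group, levels = groups),
                factor(sub$admit_year, levels = years))
    ev <- ev + as.numeric(t3)
  }
  pop <- array(0, dim = dim(ev), dimnames = dimnames(ev))
  t3p <- tapply(population$count,
                list(factor(population$region_id, levels = regions),
                     factor(population$age_group, levels = groups),
                     factor(population$year, levels = years)), sum)
  t3p[is.na(t3p)] <- 0
  pop <- pop + t3p

  annual <- matrix(NA_real_, nrow = length(regions), ncol = length(years),
                   dimnames = list(regions, years))
  for (i in seq_along(regions)) {
    for (k in seq_along(years)) {
      pg <- pop[i, , k]
      eg <- ev[i, , k]
      use <- pg > 0
      if (!any(use)) next
      if (any(!use & eg > 0)) {
        stop(sprintf("region %s has events in an age group with zero population",
                     regions[i]))
      }
      rates <- stats::setNames(eg[use] / pg[use] * 1e5, groups[use])
      annual[i, k] <- direct_adjusted_rate(rates, std)
    }
  }
  total <- apply(ev, 1, sum)
  out <- data.frame(region_id = regions, stringsAsFactors = FALSE)
  for (k in seq_along(years)) out[[sprintf("rate_%d", years[k])]] <- annual[, k]
  out$average_annual_rate <- rowMeans(annual)
  out$total_count <- as.integer(total)
  out$small_count <- total > 0 & total < 10
  attr(out, "outcome") <- outcome
  attr(out, "years") <- years
  class(out) <- c("rate_surface", "data.frame")
  out
}

#' @noRd
outcome_mask <- function(cohort, outcome) {
  switch(outcome,
    overall = rep(TRUE, nrow(cohort)),
    severe = cohort$severity == "SEVERE",
    non_severe = cohort$severity == "NON_SEVERE",
    CAP = , HCAP = , HAP = , VAP = cohort$setting == outcome,
    stop(sprintf("unknown outcome '%s'", outcome))
  )
}

#' Small-count reliability screen for a rate surface
#'
#' An outcome is flagged unreliable when, among regions with any events, the
#' fraction with a non-zero total count below `count_floor` exceeds
#' `max_fraction`. Unreliable outcomes are excluded from clustering downstream
#' (the treatment the sparsest setting-of-acquisition category receives).
#'
#' @param surface A `rate_surface`, or a numeric vector of per-region counts.
#' @param count_floor Counts below this (but above zero) are "small".
#' @param max_fraction Tolerated fraction of small counts.
#' @return List with `reliable`, `fraction`, `n_small`, `n_nonzero`.
#' @export
reliability_screen <- function(surface, count_floor = 10, max_fraction = 0.5) {
  counts <- if (is.numeric(surface)) surface else surface$total_count
  nz <- counts > 0
  small <- counts > 0 & counts < count_floor
  if (!any(nz)) {
    warning("no regions with non-zero counts; outcome vacuously reliable")
    return(list(reliable = TRUE, fraction = NA_real_, n_small = 0L,
                n_nonzero = 0L))
  }
  fraction <- sum(small) / sum(nz)
  list(reliable = fraction <= max_fraction, fraction = fraction,
       n_small = sum(small), n_nonzero = sum(nz))
}

#' Quartile classification of a rate surface
#'
#' Rank-based assignment into Q1 (lowest rates) .. Q4 (highest), with class
#' sizes differing by at most one (the lower classes absorb the remainder) and
#' ties broken by region id order. If all rates are equal there is no rate
#' gradient to classify, so every region is placed in Q1 with a warning.
#'
#' @param surface A `rate_surface` or a named numeric vector of rates.
#' @return Named character vector of classes `Q1`-`Q4` (`NA` where the rate is
#'   undefined).
#' @export
quartile_classes <- function(surface) {
  if (is.numeric(surface)) {
    rates <- surface
    ids <- names(rates) %||% sprintf("R%03d", seq_along(rates))
  } else {
    rates <- surface$average_annual_rate
    ids <- surface$region_id
  }
  ok <- !is.na(rates)
  if (sum(ok) < 4L) stop("at least 4 regions with defined rates are required")
  out <- stats::setNames(rep(NA_character_, length(rates)), ids)
  r <- rates[ok]; rid <- ids[ok]; n <- length(r)
  if (length(unique(r)) == 1L) {
    warning("all rates are equal; assigning every region to Q1")
    out[ok] <- "Q1"
    return(out)
  }
  ord <- order(r, rid)
  sizes <- rep(n %/% 4L, 4L)
  rem <- n %% 4L
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  cls <- rep(paste0("Q", 1:4), times = sizes)
  out[ok][ord] <- cls
  out
}
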