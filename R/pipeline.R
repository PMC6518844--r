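# End-to-end orchestration: cohort -> rates -> reliability screen ->
# semivariogram -> ISA validation -> LISA clustering -> hot/cold comparison,
# per outcome. Outcomes whose rate surface fails the reliability screen, or
# whose semivariogram fit cannot define a range of spatial autocorrelation,
# skip cluster analysis with an explicit status (never silently).

#' Run the full hot-spot analysis pipeline
#'
#' @param regions A `region_set` or path to a regions GeoJSON.
#' @param records Discharge records data frame or path to a records CSV.
#' @param population Population table or path to a population CSV.
#' @param out_dir Optional output directory; when given, every stage artifact
#'   is written (CSV/JSON/GeoJSON) along with a provenance manifest.
#' @param outcomes Outcomes to analyse.
#' @param years Study years (default: the population table's years).
#' @param std A [standard_population()].
#' @param codes A [code_map()].
#' @param n_bins,max_lag Empirical variogram binning. `max_lag = NULL` uses a
#'   third of the maximum pairwise centroid distance (shorter than the
#'   standalone [empirical_variogram()] default, which is more robust when the
#'   surface carries strong localised clusters).
#' @param isa_steps Number of ISA distance bands.
#' @param B,alpha LISA permutation count and significance level.
#' @param bandwidth `"auto"` (use each outcome's fitted effective range) or a
#'   fixed bandwidth in metres.
#' @param count_floor,max_fraction Reliability screen parameters.
#' @param row_standardise Row-standardise spatial weights.
#' @param seed Master seed for permutation inference.
#' @return A `hotspot_pipeline` object: `cohort`, `exclusions`, `summary`,
#'   per-outcome results (`surface`, `screen`, `quartiles`, `variogram`,
#'   `isa`, `lisa`, `comparison`, `status`) and the provenance `manifest`.
#' @export
run_pipeline <- function(regions, records, population, out_dir = NULL,
                         outcomes = c("overall", "severe", "CAP", "HCAP",
                                      "HAP", "VAP"),
                         years = NULL, std = standard_population(),
                         codes = code_map(), n_bins = 12, max_lag = NULL,
                         isa_steps = 10, B = 999, alpha = 0.05,
                         bandwidth = "auto", count_floor = 10,
                         max_fraction = 0.5, row_standardise = TRUE,
                         seed = 1L) {
  if (is.character(regions)) regions <- read_regions(regions)
  if (is.character(records)) records <- read_records(records)
  if (is.character(population)) population <- read_population(population)
  years <- as.integer(years %||% sort(unique(population$year)))

  fc <- filter_cohort(records, regions, min(years), max(years), codes)
  cohort <- fc$cohort
  summary_tab <- summarize_cohort(cohort)

  res <- regions[regions$residential, , drop = FALSE]
  centroids <- cbind(res$centroid_x, res$centroid_y)

  results <- list()
  for (oi in seq_along(outcomes)) {
    outcome <- outcomes[oi]
    r <- list(status = "ok")
    r$surface <- build_rate_surface(cohort, population, std, outcome, years)
    r$screen <- reliability_screen(r$surface, count_floor, max_fraction)
    rates <- stats::setNames(r$surface$average_annual_rate, r$surface$region_id)
    rates <- rates[res$region_id]
    if (sum(!is.na(rates)) >= 4L) {
      r$quartiles <- suppressWarnings(quartile_classes(rates))
    }
    if (!r$screen$reliable) {
      r$status <- "skipped_unreliable"
      message(sprintf("[%s] rate surface unreliable (%.0f%% small counts); cluster analyses not performed",
                      outcome, 100 * r$screen$fraction))
      results[[outcome]] <- r
      next
    }
    ok <- !is.na(rates)
    vals <- rates[ok]
    xy <- centroids[ok, , drop = FALSE]
    ids <- res$region_id[ok]
    # Rate surfaces with strong localised hot spots contaminate long lags, so
    # the pipeline fits the variogram only out to a third of the maximum
    # pairwise distance (the conventional trend-robust cutoff) unless told
    # otherwise.
    ml <- max_lag %||% (max(stats::dist(xy)) / 3)
    r$variogram <- tryCatch({
      emp <- empirical_variogram(xy, vals, n_bins = n_bins, max_lag = ml)
      fit_variogram_model(emp)
    }, error = function(e) .fit_failure(conditionMessage(e)))
    if (is_fit_failure(r$variogram)) {
      r$status <- "no_spatial_range"
      message(sprintf("[%s] unable to define a range of spatial autocorrelation (%s); cluster analyses not performed",
                      outcome, r$variogram$reason))
      results[[outcome]] <- r
      next
    }
    r$isa <- isa_profile(xy, vals, steps = isa_steps,
                         row_standardise = row_standardise)
    bw <- if (identical(bandwidth, "auto")) r$variogram$effective_range else bandwidth
    w <- build_distance_band_weights(xy, bw, row_standardise = row_standardise,
                                     ids = ids)
    r$lisa <- lisa(vals, w, B = B, alpha = alpha, seed = seed + oi)
    cmp_vars <- c("sex", "race_ethnicity", "setting", "disposition", "died")
    if (outcome %in% c("CAP", "HCAP", "HAP", "VAP")) {
      cmp_vars <- setdiff(cmp_vars, "setting")  # single category by construction
    }
    r$comparison <- tryCatch(
      compare_clusters(cohort[outcome_mask(cohort, outcome), , drop = FALSE],
                       r$lisa, variables = cmp_vars),
      error = function(e) conditionMessage(e))
    results[[outcome]] <- r
  }

  settings <- list(outcomes = outcomes, years = years, n_bins = n_bins,
                   max_lag = max_lag, isa_steps = isa_steps, B = B,
                   alpha = alpha, bandwidth = bandwidth,
                   count_floor = count_floor, max_fraction = max_fraction,
                   row_standardise = row_standardise, seed = seed)
  manifest <- list(
    package = "hoodspot",
    version = as.character(utils::packageVersion("hoodspot")),
    settings = settings,
    settings_hash = unname(.settings_hash(settings)),
    n_records = nrow(records), n_cohort = nrow(cohort),
    exclusions = as.list(fc$exclusions),
    outcome_status = lapply(results, `[[`, "status")
  )

  out <- list(cohort = cohort, exclusions = fc$exclusions,
              summary = summary_tab, outcomes = results, manifest = manifest,
              regions = regions)
  class(out) <- "hotspot_pipeline"
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' @noRd
.settings_hash <- function(settings) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(settings, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  as.character(tools::md5sum(tmp))
}

#' Write all pipeline artifacts to a run directory
#'
#' @param pipeline A `hotspot_pipeline` object.
#' @param out_dir Directory to create/populate.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(pipeline, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(pipeline$cohort),
                   file.path(out_dir, "cohort.csv"), row.names = FALSE)
  writeLines(jsonlite::toJSON(as.list(pipeline$exclusions), auto_unbox = TRUE),
             file.path(out_dir, "exclusions.json"))
  utils::write.csv(pipeline$summary, file.path(out_dir, "cohort_summary.csv"),
                   row.names = FALSE)
  for (outcome in names(pipeline$outcomes)) {
    r <- pipeline$outcomes[[outcome]]
    pre <- file.path(out_dir, outcome)
    surf <- as.data.frame(r$surface)
    if (!is.null(r$quartiles)) {
      surf$quartile <- r$quartiles[match(surf$region_id, names(r$quartiles))]
    }
    utils::write.csv(surf, paste0(pre, "_rates.csv"), row.names = FALSE)
    vg <- if (is_fit_failure(r$variogram)) {
      list(fit = "FIT_FAILURE", reason = r$variogram$reason)
    } else if (!is.null(r$variogram)) {
      r$variogram[c("family", "nugget", "psill", "range", "sill",
                    "effective_range", "wsse")]
    }
    if (!is.null(vg)) {
      writeLines(jsonlite::toJSON(vg, auto_unbox = TRUE, digits = NA),
                 paste0(pre, "_variogram.json"))
    }
    if (!is.null(r$isa)) {
      utils::write.csv(as.data.frame(r$isa), paste0(pre, "_isa.csv"),
                       row.names = FALSE)
    }
    if (!is.null(r$lisa)) {
      utils::write.csv(as.data.frame(r$lisa), paste0(pre, "_lisa.csv"),
                       row.names = FALSE)
      write_lisa_geojson(r$lisa, pipeline$regions,
                         paste0(pre, "_lisa.geojson"))
    }
    if (!is.null(r$comparison) && inherits(r$comparison, "comparison_report")) {
      writeLines(jsonlite::toJSON(unclass(r$comparison), auto_unbox = TRUE,
                                  digits = NA, null = "null", na = "null"),
                 paste0(pre, "_comparison.json"))
    }
  }
  writeLines(jsonlite::toJSON(pipeline$manifest, auto_unbox = TRUE,
                              digits = NA, null = "null"),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' Read and validate a pipeline configuration file
#'
#' YAML or JSON with `regions`, `records`, `population` paths plus any
#' optional settings accepted by [run_pipeline()]. Referenced files must
#' exist; `alpha` must lie in (0, 1); `years`, if given, must be non-empty.
#' Validation happens before any computation.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return Named list of validated arguments for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  for (key in c("regions", "records", "population")) {
    if (is.null(cfg[[key]])) stop(sprintf("config is missing '%s'", key))
    if (!file.exists(cfg[[key]])) {
      stop(sprintf("config error: %s file '%s' does not exist", key, cfg[[key]]))
    }
  }
  if (!is.null(cfg$alpha) && (cfg$alpha <= 0 || cfg$alpha >= 1)) {
    stop("config error: alpha must lie in (0, 1)")
  }
  if (!is.null(cfg$years) && length(cfg$years) == 0L) {
    stop("config error: years must be non-empty")
  }
  allowed <- c("regions", "records", "population", "out_dir", "outcomes",
               "years", "n_bins", "max_lag", "isa_steps", "B", "alpha",
               "bandwidth", "count_floor", "max_fraction", "row_standardise",
               "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L) {
    stop(sprintf("config error: unknown setting(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  cfg
}

#' @export
print.hotspot_pipeline <- function(x, ...) {
  cat("Hot-spot analysis pipeline\n")
  cat(sprintf("cohort: %d hospitalisations kept, %d excluded\n",
              nrow(x$cohort), sum(x$exclusions)))
  for (outcome in names(x$outcomes)) {
    r <- x$outcomes[[outcome]]
    line <- sprintf("  %-8s %s", outcome, r$status)
    if (identical(r$status, "ok") && !is.null(r$lisa)) {
      line <- sprintf("%s  range %.0f m, HH %d, LL %d", line,
                      r$variogram$effective_range,
                      sum(r$lisa$label == "HH"), sum(r$lisa$label == "LL"))
    }
    cat(line, "\n")
  }
  invisible(x)
}
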