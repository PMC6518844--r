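# Readers and writers for the pipeline's artifacts. Regions travel as GeoJSON
# FeatureCollections in projected planar metres (geographic lon/lat input is
# rejected with an instruction to project first); records and population
# tables as CSV; models, profiles and reports as JSON.

#' Write regions as GeoJSON
#'
#' @param regions A `region_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  polys <- attr(regions, "polygons")
  features <- lapply(seq_len(nrow(regions)), function(i) {
    ring <- polys[[regions$region_id[i]]]
    list(type = "Feature",
         properties = list(region_id = regions$region_id[i],
                           residential = regions$residential[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(ring))))
  })
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = "planar-metres")),
             features = features)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read regions from GeoJSON
#'
#' Expects a FeatureCollection of Polygons with `region_id` and `residential`
#' properties in projected planar metres. Coordinates that all fit inside the
#' geographic lon/lat envelope are rejected: project to planar metres first.
#'
#' @param path GeoJSON file.
#' @return A `region_set` (centroids recomputed as bounding-box centres).
#' @export
read_regions <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection")
  }
  feats <- gj$features
  if (length(feats) == 0L) stop("FeatureCollection contains no features")
  ids <- character(length(feats)); res <- logical(length(feats))
  polys <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (!identical(f$geometry$type, "Polygon")) {
      stop(sprintf("feature %d: only Polygon geometries are supported", i))
    }
    ids[i] <- f$properties$region_id %||% stop(sprintf("feature %d: missing region_id", i))
    res[i] <- isTRUE(f$properties$residential)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    colnames(ring) <- c("x", "y")
    polys[[i]] <- ring
  }
  if (anyDuplicated(ids)) stop("region ids must be unique")
  allx <- unlist(lapply(polys, function(p) p[, 1]))
  ally <- unlist(lapply(polys, function(p) p[, 2]))
  if (all(abs(allx) <= 180) && all(abs(ally) <= 90)) {
    stop("coordinates look geographic (lon/lat); project to planar metres before use")
  }
  names(polys) <- ids
  cx <- vapply(polys, function(p) mean(range(p[, 1])), numeric(1))
  cy <- vapply(polys, function(p) mean(range(p[, 2])), numeric(1))
  out <- data.frame(region_id = ids, centroid_x = unname(cx),
                    centroid_y = unname(cy), residential = res,
                    stringsAsFactors = FALSE)
  attr(out, "polygons") <- polys
  class(out) <- c("region_set", "data.frame")
  out
}

#' @noRd
.record_columns <- function() {
  c("record_id", "region_id", "age", "sex", "race_ethnicity", "admit_date",
    "discharge_date", "principal_dx", sprintf("secondary_dx_%d", 1:24),
    "disposition", "died", "setting", "year")
}

#' Write discharge records as CSV
#' @param records Discharge record data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records[, .record_columns()], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read discharge records from CSV
#'
#' Validates the record schema: all required columns present, no more than 24
#' secondary diagnosis columns, numeric non-negative ages and ISO-8601 dates.
#' Violations are reported with row numbers.
#'
#' @param path CSV file.
#' @return Data frame of discharge records.
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  need <- .record_columns()
  missing_cols <- setdiff(need, names(rec))
  if (length(missing_cols) > 0L) {
    stop(sprintf("record file is missing columns: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  extra_sec <- grep("^secondary_dx_\\d+$", names(rec), value = TRUE)
  idx <- as.integer(sub("secondary_dx_", "", extra_sec))
  if (any(idx > 24L)) {
    stop("at most 24 secondary diagnosis columns are allowed")
  }
  rec$age <- suppressWarnings(as.numeric(rec$age))
  bad_age <- which(is.na(rec$age) | rec$age < 0)
  if (length(bad_age) > 0L) {
    stop(sprintf("invalid age at row(s): %s",
                 paste(utils::head(bad_age, 10), collapse = ", ")))
  }
  for (col in c("admit_date", "discharge_date")) {
    d <- as.Date(rec[[col]], format = "%Y-%m-%d")
    bad <- which(is.na(d))
    if (length(bad) > 0L) {
      stop(sprintf("invalid ISO-8601 %s at row(s): %s", col,
                   paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
  rec$died <- rec$died %in% c("TRUE", "true", "1")
  rec$year <- as.integer(rec$year)
  rec
}

#' Write a population table as CSV
#' @param population Long table (`region_id`, `age_group`, `year`, `count`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_population <- function(population, path) {
  utils::write.csv(population[, c("region_id", "age_group", "year", "count")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a population table from CSV
#'
#' @param path CSV file with `region_id`, `age_group`, `year`, `count`.
#' @return Long population data frame; negative counts are rejected with row
#'   numbers.
#' @export
read_population <- function(path) {
  pop <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_id", "age_group", "year", "count")
  missing_cols <- setdiff(need, names(pop))
  if (length(missing_cols) > 0L) {
    stop(sprintf("population file is missing columns: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(is.na(pop$count) | pop$count < 0)
  if (length(bad) > 0L) {
    stop(sprintf("negative or missing count at row(s): %s",
                 paste(utils::head(bad, 10), collapse = ", ")))
  }
  pop$count <- as.integer(pop$count)
  pop$year <- as.integer(pop$year)
  pop
}

#' Write a rate surface as CSV
#' @param surface A `rate_surface`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rate_surface <- function(surface, path) {
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE)
  invisible(path)
}

#' Write LISA labels as a GeoJSON FeatureCollection
#'
#' @param lisa_result A [lisa()] result.
#' @param regions The `region_set` the analysis ran on.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lisa_geojson <- function(lisa_result, regions, path) {
  polys <- attr(regions, "polygons")
  features <- lapply(seq_len(nrow(lisa_result)), function(i) {
    id <- lisa_result$region_id[i]
    list(type = "Feature",
         properties = list(region_id = id,
                           label = lisa_result$label[i],
                           I_i = lisa_result$I_i[i],
                           pseudo_p = lisa_result$pseudo_p[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(polys[[id]]))))
  })
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = "planar-metres")),
             features = features)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA, na = "null"),
             path)
  invisible(path)
}
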