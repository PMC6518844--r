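# Case classification of discharge records. A non-severe pneumonia-associated
# hospitalisation has a principal diagnosis of pneumonia; a severe one has a
# principal diagnosis of sepsis or respiratory failure together with a
# secondary diagnosis of pneumonia. Everything else is not a case.

#' ICD-9-CM code map for pneumonia-associated hospitalisation
#'
#' The default lists are a reconstruction of the Lindenauer-style claims-based
#' definition: pneumonia 480-486 and 487.0; sepsis 038.x, 995.91, 995.92 and
#' 785.52; respiratory failure 518.81, 518.82, 518.84 and 799.1. Codes are
#' matched exact-or-prefix on dot-stripped strings, so e.g. "482" covers the
#' whole 482.x family. All three sets are fully overridable.
#'
#' @param pneumonia,sepsis,respiratory_failure Character vectors of ICD-9-CM
#'   codes or code prefixes (dots optional).
#' @return An object of class `code_map`.
#' @export
code_map <- function(pneumonia = c("480", "481", "482", "483", "484", "485",
                                   "486", "487.0"),
                     sepsis = c("038", "995.91", "995.92", "785.52"),
                     respiratory_failure = c("518.81", "518.82", "518.84",
                                             "799.1")) {
  p <- strip_icd(pneumonia); s <- strip_icd(sepsis); r <- strip_icd(respiratory_failure)
  if (length(p) == 0L || length(s) == 0L || length(r) == 0L) {
    stop("all three code sets must be non-empty")
  }
  overlaps <- function(a, b) {
    any(outer(a, b, function(x, y) startsWith(x, y) | startsWith(y, x)))
  }
  if (overlaps(p, s) || overlaps(p, r)) {
    stop("pneumonia codes must be disjoint from sepsis and respiratory-failure codes")
  }
  structure(list(pneumonia = p, sepsis = s, respiratory_failure = r),
            class = "code_map")
}

#' @noRd
strip_icd <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub(".", "", x, fixed = TRUE)
}

# TRUE where any entry of `set` is a prefix of (or equal to) the code.
#' @noRd
match_code_set <- function(codes, set) {
  codes <- strip_icd(codes)
  out <- rep(FALSE, length(codes))
  ok <- !is.na(codes) & nzchar(codes)
  for (entry in set) out[ok] <- out[ok] | startsWith(codes[ok], entry)
  out
}

#' Classify discharge severity from diagnosis codes
#'
#' `NON_SEVERE` if the principal diagnosis is pneumonia; `SEVERE` if the
#' principal diagnosis is sepsis or respiratory failure and at least one
#' secondary diagnosis is pneumonia; otherwise `NOT_CASE`. A missing principal
#' code yields `NA` (such records are rejected with a reason by
#' [filter_cohort()]).
#'
#' @param principal Character vector of principal ICD-9-CM codes.
#' @param secondary Secondary codes: a character vector (one record), or a
#'   character matrix / data frame with one row per record (up to 24 columns).
#' @param codes A [code_map()].
#' @return Character vector in `{"NON_SEVERE", "SEVERE", "NOT_CASE", NA}`.
#' @export
classify_severity <- function(principal, secondary = NULL, codes = code_map()) {
  n <- length(principal)
  if (is.null(secondary)) {
    secondary <- matrix(character(0), nrow = n, ncol = 0)
  } else if (is.data.frame(secondary)) {
    secondary <- as.matrix(secondary)
  } else if (!is.matrix(secondary)) {
    if (n != 1L) stop("for multiple records, 'secondary' must be a matrix or data frame")
    secondary <- matrix(secondary, nrow = 1L)
  }
  if (ncol(secondary) > 24L) stop("at most 24 secondary diagnosis codes are allowed")
  if (nrow(secondary) != n && ncol(secondary) > 0L) {
    stop("'secondary' must have one row per record")
  }
  out <- rep("NOT_CASE", n)
  missing_prin <- is.na(principal) | !nzchar(trimws(as.character(principal)))
  out[missing_prin] <- NA_character_
  is_pneu <- match_code_set(principal, codes$pneumonia)
  is_sev_prin <- match_code_set(principal, codes$sepsis) |
    match_code_set(principal, codes$respiratory_failure)
  sec_pneu <- rep(FALSE, n)
  if (ncol(secondary) > 0L) {
    for (j in seq_len(ncol(secondary))) {
      sec_pneu <- sec_pneu | match_code_set(secondary[, j], codes$pneumonia)
    }
  }
  out[!missing_prin & is_pneu] <- "NON_SEVERE"
  out[!missing_prin & !is_pneu & is_sev_prin & sec_pneu] <- "SEVERE"
  out
}

#' @noRd
secondary_matrix <- function(records) {
  cols <- grep("^secondary_dx_\\d+$", names(records), value = TRUE)
  if (length(cols) == 0L) return(matrix(character(0), nrow = nrow(records), ncol = 0))
  as.matrix(records[, cols, drop = FALSE])
}

#' Apply the study inclusion filters to discharge records
#'
#' Keeps records that classify as cases (non-severe or severe), belong to an
#' adult (age >= 18), reside in a known residential region, and were admitted
#' within the study window. Every excluded record is tallied under exactly one
#' reason, evaluated in this order: `missing_principal`, `not_case`,
#' `under_18`, `unknown_region`, `non_residential`, `outside_study_window`.
#'
#' @param records Discharge record data frame (schema of
#'   [simulate_discharges()] / [read_records()]).
#' @param regions A `region_set`.
#' @param start_year,end_year Study window; inclusion is by admission year.
#' @param codes A [code_map()].
#' @return List with `cohort` (kept records plus `severity`, `admit_year` and
#'   `los` columns) and `exclusions` (named integer tally).
#' @export
filter_cohort <- function(records, regions, start_year, end_year,
                          codes = code_map()) {
  severity <- classify_severity(records$principal_dx, secondary_matrix(records),
                                codes)
  admit <- as.Date(records$admit_date)
  admit_year <- as.integer(format(admit, "%Y"))
  reason <- rep(NA_character_, nrow(records))
  mark <- function(reason, cond, label) {
    reason[is.na(reason) & cond] <- label
    reason
  }
  reason <- mark(reason, is.na(severity), "missing_principal")
  reason <- mark(reason, severity == "NOT_CASE", "not_case")
  reason <- mark(reason, records$age < 18, "under_18")
  known <- records$region_id %in% regions$region_id
  reason <- mark(reason, !known, "unknown_region")
  res_ids <- regions$region_id[regions$residential]
  reason <- mark(reason, known & !(records$region_id %in% res_ids), "non_residential")
  reason <- mark(reason, is.na(admit_year) | admit_year < start_year |
                   admit_year > end_year, "outside_study_window")
  kept <- is.na(reason)

  cohort <- records[kept, , drop = FALSE]
  cohort$severity <- severity[kept]
  cohort$admit_year <- admit_year[kept]
  cohort$los <- as.integer(as.Date(cohort$discharge_date) - as.Date(cohort$admit_date))
  rownames(cohort) <- NULL
  class(cohort) <- c("cohort", "data.frame")

  levels <- c("missing_principal", "not_case", "under_18", "unknown_region",
              "non_residential", "outside_study_window")
  tally <- table(factor(reason[!kept], levels = levels))
  list(cohort = cohort, exclusions = stats::setNames(as.integer(tally), levels))
}

#' Summarise a cohort by severity and setting of acquisition
#'
#' Reports counts and one-decimal percentages (rounded half away from zero)
#' against the overall case count. Accepts either a cohort data frame from
#' [filter_cohort()] or a named vector of counts containing `overall` plus any
#' of `severe`, `non_severe`, `CAP`, `HCAP`, `HAP`, `VAP`.
#'
#' @param x Cohort data frame or named numeric count vector.
#' @return Data frame with `class`, `count`, `pct`.
#' @export
summarize_cohort <- function(x) {
  if (is.numeric(x)) {
    counts <- x
    if (!"overall" %in% names(counts)) stop("count vector must include 'overall'")
  } else {
    if (nrow(x) == 0L) stop("cohort is empty")
    counts <- c(overall = nrow(x),
                non_severe = sum(x$severity == "NON_SEVERE"),
                severe = sum(x$severity == "SEVERE"))
    if ("setting" %in% names(x)) {
      for (s in c("CAP", "HCAP", "HAP", "VAP")) {
        counts[s] <- sum(x$setting == s, na.rm = TRUE)
      }
    }
  }
  data.frame(class = names(counts),
             count = as.numeric(counts),
             pct = round_half_up(100 * as.numeric(counts) / counts[["overall"]], 1),
             row.names = NULL, stringsAsFactors = FALSE)
}
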