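#' Derive the multimorbidity flag from chronic-condition indicators
#'
#' Multimorbidity is defined as the co-occurrence of two or more long-term
#' health conditions in the same individual. The survey instrument asks
#' about 14 doctor-diagnosed chronic conditions (hypertension, dyslipidemia,
#' diabetes, cancer, chronic lung disease, liver disease, heart disease,
#' stroke, kidney disease, digestive disease, emotional or psychiatric
#' problems, memory-related disease, arthritis or rheumatism, asthma), each
#' recorded as a 0/1 presence flag.
#'
#' @param conditions Either a vector of 14 binary flags (one subject) or a
#'   data frame / matrix with 14 columns (one row per subject).
#' @return Integer 0/1 vector: 1 where at least two condition flags are set.
#' @export
#' @examples
#' derive_mmd(rep(0, 14))                       # no conditions -> 0
#' derive_mmd(c(1, rep(0, 13)))                 # one condition -> 0
#' derive_mmd(c(1, 1, rep(0, 12)))              # two conditions -> 1
derive_mmd <- function(conditions) {
  if (is.data.frame(conditions)) conditions <- as.matrix(conditions)
  if (!is.matrix(conditions)) conditions <- matrix(conditions, nrow = 1)
  if (ncol(conditions) != 14L) {
    stop_contract(sprintf(
      "`conditions` must have exactly 14 indicators, got %d", ncol(conditions)
    ))
  }
  if (anyNA(conditions) || !all(conditions %in% c(0, 1))) {
    stop_contract("condition indicators must all be 0 or 1")
  }
  as.integer(rowSums(conditions) >= 2)
}

#' Weekly physical-activity energy expenditure in MET-minutes
#'
#' Implements the IPAQ scoring rule: each reported activity contributes
#' intensity weight x days/week x minutes/day, and the weekly total is the
#' sum over the reported intensities. Intensity weights are 8.0 (vigorous),
#' 4.0 (moderate) and 3.3 (light).
#'
#' @param records A data frame with columns `intensity` (one of `"light"`,
#'   `"moderate"`, `"vigorous"`), `days_per_week` (integer 0-7) and
#'   `minutes_per_day` (non-negative). Optionally an `id` column; when
#'   present, totals are returned per id.
#' @return A single MET-min/week total, or a tibble `(id, met_minutes)` when
#'   `records` has an `id` column.
#' @export
#' @examples
#' met_minutes(data.frame(intensity = "moderate", days_per_week = 5,
#'                        minutes_per_day = 30))  # 600
met_minutes <- function(records) {
  weights <- c(light = 3.3, moderate = 4.0, vigorous = 8.0)
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(if ("id" %in% names(records)) {
      tibble::tibble(id = records$id, met_minutes = numeric(0))
    } else 0)
  }
  need <- c("intensity", "days_per_week", "minutes_per_day")
  if (!all(need %in% names(records))) {
    stop_contract(paste("`records` needs columns:", paste(need, collapse = ", ")))
  }
  int <- tolower(as.character(records$intensity))
  if (!all(int %in% names(weights))) {
    stop_contract("`intensity` must be one of light, moderate, vigorous")
  }
  if (any(records$days_per_week < 0 | records$days_per_week > 7) ||
      any(records$minutes_per_day < 0)) {
    stop_contract("`days_per_week` must lie in 0-7 and `minutes_per_day` be non-negative")
  }
  contrib <- weights[int] * records$days_per_week * records$minutes_per_day
  if ("id" %in% names(records)) {
    agg <- dplyr::summarise(
      dplyr::group_by(dplyr::mutate(records, .met = contrib), .data$id),
      met_minutes = sum(.data$.met), .groups = "drop"
    )
    return(agg)
  }
  if (anyDuplicated(int)) {
    stop_contract("at most one record per intensity level for a single subject")
  }
  sum(contrib)
}

#' Band a weekly MET-minute total into the three activity categories
#'
#' Categories follow the IPAQ convention: Light below 600 MET-min/week,
#' Moderate in `[600, 3000)`, Vigorous at or above 3000. The bands are
#' half-open so that 600 is Moderate and 3000 is Vigorous; together they
#' partition `[0, Inf)` with no gaps.
#'
#' @param met Numeric vector of non-negative MET-min/week totals.
#' @return Integer codes: 1 (Light), 2 (Moderate), 3 (Vigorous).
#' @export
#' @examples
#' categorize_activity(c(0, 599.9, 600, 2999, 3000))
categorize_activity <- function(met) {
  if (any(!is.na(met) & met < 0)) stop_contract("MET-minutes must be non-negative")
  out <- rep(NA_integer_, length(met))
  ok <- !is.na(met)
  out[ok] <- ifelse(met[ok] < 600, 1L, ifelse(met[ok] < 3000, 2L, 3L))
  out
}

# banding rules for continuous raw fields; boundaries follow the codebook's
# "<=" convention (sleep 6.5 h -> band (6,7]; nap 30 min -> "<=30min")
band_age <- function(years) {
  ifelse(is.na(years), NA_integer_,
         ifelse(years < 55, 1L, ifelse(years < 65, 2L, ifelse(years < 75, 3L, 4L))))
}
band_sleep <- function(hours) {
  ifelse(is.na(hours), NA_integer_,
         ifelse(hours <= 5, 1L, ifelse(hours <= 6, 2L,
                ifelse(hours <= 7, 3L, ifelse(hours <= 8, 4L, 5L)))))
}
band_nap <- function(minutes) {
  ifelse(is.na(minutes), NA_integer_,
         ifelse(minutes <= 0, 1L, ifelse(minutes <= 30, 2L, 3L)))
}

encode_labels <- function(x, variable) {
  lookup <- codebook_lookup(variable)
  if (variable == "sex") {
    lookup <- c(lookup, man = 1L, male = 1L, woman = 2L, female = 2L)
  }
  key <- tolower(trimws(as.character(x)))
  out <- unname(lookup[key])
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    warn(sprintf("%d unrecognized label(s) for `%s` set to missing (e.g. \"%s\")",
                 sum(bad), variable, x[which(bad)[1]]))
  }
  as.integer(out)
}

#' Encode raw survey fields into the integer-coded study variables
#'
#' Maps a table of raw per-subject fields onto the codebook codes. Columns
#' are matched by name; any subset may be supplied and only recognized
#' columns are encoded:
#'
#' * `sex`, `education`, `residence`, `marital_status`, `smoking`,
#'   `alcohol`: category labels (lenient on case; unknown labels become
#'   missing with a warning).
#' * `age_years`, `sleep_hours`, `nap_minutes`: continuous values banded
#'   into codebook codes.
#' * `met_minutes`: weekly MET-minute total, banded by
#'   [categorize_activity()] into `physical_activity`.
#' * 14 chronic-condition flag columns named in `condition_cols`: collapsed
#'   into the `mmd` outcome via [derive_mmd()].
#' * Columns already named as a study variable and integer-coded are kept
#'   (values outside the code domain become missing with a warning).
#'
#' @param raw A data frame of raw fields, one row per subject.
#' @param condition_cols Optional character vector naming the 14 chronic
#'   condition indicator columns in `raw`.
#' @return A tibble of integer-coded study columns (missing values as `NA`).
#' @export
encode_records <- function(raw, condition_cols = NULL) {
  raw <- tibble::as_tibble(raw)
  out <- tibble::tibble(.rows = nrow(raw))
  for (v in setdiff(mmd_variables(), "mmd")) {
    if (v %in% names(raw)) {
      col <- raw[[v]]
      out[[v]] <- if (is.numeric(col)) {
        keep_coded(col, v)
      } else {
        encode_labels(col, v)
      }
    }
  }
  if ("age_years" %in% names(raw)) out$age <- band_age(raw$age_years)
  if ("sleep_hours" %in% names(raw)) out$sleep_duration <- band_sleep(raw$sleep_hours)
  if ("nap_minutes" %in% names(raw)) out$nap <- band_nap(raw$nap_minutes)
  if ("met_minutes" %in% names(raw) && !"physical_activity" %in% names(out)) {
    out$physical_activity <- categorize_activity(raw$met_minutes)
  }
  if (!is.null(condition_cols)) {
    missing_cols <- setdiff(condition_cols, names(raw))
    if (length(missing_cols)) {
      stop_contract(paste("condition columns absent from `raw`:",
                          paste(missing_cols, collapse = ", ")))
    }
    out$mmd <- derive_mmd(raw[condition_cols])
  } else if ("mmd" %in% names(raw)) {
    out$mmd <- if (is.numeric(raw$mmd)) keep_coded(raw$mmd, "mmd") else
      encode_labels(raw$mmd, "mmd")
  }
  out[intersect(mmd_variables(), names(out))]
}

keep_coded <- function(x, variable) {
  dom <- mmd_levels()[[variable]]
  bad <- !is.na(x) & !(x %in% dom)
  if (any(bad)) {
    warn(sprintf("%d out-of-domain code(s) for `%s` set to missing", sum(bad), variable))
  }
  x[bad] <- NA
  as.integer(x)
}

#' Decode integer study codes back to their labels
#'
#' @param data A data frame of integer-coded study columns.
#' @return A tibble of the same shape with codes replaced by labels.
#' @export
decode_records <- function(data) {
  data <- tibble::as_tibble(data)
  cb <- mmd_codebook()
  for (v in intersect(names(data), unique(cb$variable))) {
    map <- cb[cb$variable == v, ]
    data[[v]] <- map$label[match(data[[v]], map$code)]
  }
  data
}

#' Validate an integer-coded study dataset against the codebook
#'
#' Checks that all required study columns are present and reports, per
#' column, the number of out-of-domain codes and the missingness fraction.
#' The data itself is never modified.
#'
#' @param data A data frame holding (at least) the eleven study columns.
#' @param require Character vector of required columns; defaults to all
#'   eleven study variables.
#' @return A tibble with one row per checked column: `variable`,
#'   `n_out_of_domain`, `missing_fraction`, plus an `issues` attribute
#'   listing human-readable problems (empty when the table is clean).
#' @export
validate_dataset <- function(data, require = mmd_variables()) {
  data <- tibble::as_tibble(data)
  absent <- setdiff(require, names(data))
  if (length(absent)) {
    stop_contract(paste("required column(s) absent:", paste(absent, collapse = ", ")),
                  class = "mmdbn_structure_error")
  }
  lev <- mmd_levels()
  report <- purrr::map_dfr(require, function(v) {
    x <- data[[v]]
    tibble::tibble(
      variable = v,
      n_out_of_domain = sum(!is.na(x) & !(x %in% lev[[v]])),
      missing_fraction = mean(is.na(x))
    )
  })
  issues <- report[report$n_out_of_domain > 0, ]
  attr(report, "issues") <- sprintf(
    "%s: %d out-of-domain value(s)", issues$variable, issues$n_out_of_domain
  )
  report
}
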