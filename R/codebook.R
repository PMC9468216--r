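#' Codebook for the eleven multimorbidity study variables
#'
#' The study works on eleven integer-coded categorical variables: ten
#' predictors (physical activity, sex, age band, education, residence,
#' marital status, night-time sleep band, daytime nap band, smoking, alcohol
#' consumption) and the binary multimorbidity outcome `mmd` (two or more
#' chronic conditions). Codes are small consecutive integers; yes/no
#' variables are coded 0/1, all others start at 1.
#'
#' @return A tibble with one row per (variable, code): columns `variable`,
#'   `code` (integer), `label`, and `ordinal` (whether codes carry rank
#'   order).
#' @seealso [mmd_levels()], [validate_dataset()], [encode_records()]
#' @export
#' @examples
#' mmd_codebook()
mmd_codebook <- function() {
  tribble_var <- function(variable, ordinal, codes, labels) {
    tibble::tibble(
      variable = variable, code = as.integer(codes),
      label = labels, ordinal = ordinal
    )
  }
  dplyr::bind_rows(
    tribble_var("physical_activity", TRUE, 1:3, c("Light", "Moderate", "Vigorous")),
    tribble_var("sex", FALSE, 1:2, c("Men", "Women")),
    tribble_var("age", TRUE, 1:4, c("<55", "55-65", "65-75", ">=75")),
    tribble_var("education", TRUE, 1:4,
                c("<=Primary school", "<=Middle school", "<College", ">=College")),
    tribble_var("residence", FALSE, 1:4,
                c("Town", "Combination", "Village", "Special area")),
    tribble_var("marital_status", FALSE, 1:4,
                c("Married", "Divorced", "Widowed", "Never married")),
    tribble_var("sleep_duration", TRUE, 1:5,
                c("<=5h", "5-6h", "6-7h", "7-8h", ">8h")),
    tribble_var("nap", TRUE, 1:3, c("0min", "<=30min", ">30min")),
    tribble_var("smoking", FALSE, 0:1, c("No", "Yes")),
    tribble_var("alcohol", FALSE, 0:1, c("No", "Yes")),
    tribble_var("mmd", FALSE, 0:1, c("No", "Yes"))
  )
}

#' Variable names and code domains of the study codebook
#'
#' @return `mmd_variables()` returns the eleven variable names in codebook
#'   order (outcome `mmd` last). `mmd_levels()` returns a named list mapping
#'   each variable to its vector of valid integer codes.
#' @export
mmd_variables <- function() unique(mmd_codebook()$variable)

#' @rdname mmd_variables
#' @export
mmd_levels <- function() {
  cb <- mmd_codebook()
  split(cb$code, factor(cb$variable, levels = unique(cb$variable)))
}

#' Read the machine-readable codebook shipped with the package
#'
#' A JSON mirror of [mmd_codebook()] is installed under `extdata/`; external
#' tools can use it to validate input files against the same code domains.
#'
#' @return The codebook as a tibble, parsed from the installed JSON file.
#' @export
read_codebook_json <- function() {
  path <- system.file("extdata", "codebook.json", package = "mmdbn")
  tibble::as_tibble(jsonlite::fromJSON(path))
}

# label -> code lookup used by encode_records(); lenient on case/whitespace
codebook_lookup <- function(variable) {
  cb <- mmd_codebook()
  cb <- cb[cb$variable == variable, ]
  setNames(cb$code, tolower(trimws(cb$label)))
}
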