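#' Read a claims table
#'
#' Expects a delimited text file (comma by default, tab auto-detected) with
#' columns `patient_id`, `system`, `code`, `service_date` (ISO 8601). One
#' claim event per row. Codes are normalized on read; rows that cannot be
#' parsed (unsupported code system, malformed code, invalid date) are
#' skipped and counted in the parse report, never silently dropped.
#'
#' @param path Path to the claims file.
#' @return A list with `claims` (tibble: `patient_id`, `system`, `code`,
#'   `service_date`) and `report` (tibble: `reason`, `n`, including a
#'   `"rows_read"` row).
#' @export
read_claims <- function(path) {
  raw <- read_delim_auto(path, c("patient_id", "system", "code",
                                 "service_date"))
  raw$system <- toupper(trimws(raw$system))
  reasons <- character(0)

  supported <- raw$system %in% CODE_SYSTEMS
  reasons <- c(reasons, rep("unsupported system", sum(!supported)))
  raw <- raw[supported, , drop = FALSE]

  dates <- as.Date(raw$service_date, format = "%Y-%m-%d")
  ok_date <- !is.na(dates)
  reasons <- c(reasons, rep("invalid date", sum(!ok_date)))
  raw <- raw[ok_date, , drop = FALSE]
  dates <- dates[ok_date]

  norm <- rep(NA_character_, nrow(raw))
  for (sys in CODE_SYSTEMS) {
    idx <- raw$system == sys
    if (!any(idx)) next
    norm[idx] <- vapply(raw$code[idx], function(cd) {
      tryCatch(normalize_code(cd, sys), error = function(e) NA_character_)
    }, character(1))
  }
  ok_code <- !is.na(norm)
  reasons <- c(reasons, rep("malformed code", sum(!ok_code)))

  claims <- tibble(
    patient_id = as.character(raw$patient_id[ok_code]),
    system = raw$system[ok_code],
    code = norm[ok_code],
    service_date = dates[ok_code])

  if (length(reasons)) {
    warn(sprintf("read_claims: skipped %d unparseable row(s) (%s)",
                 length(reasons),
                 paste(names(table(reasons)), table(reasons),
                       sep = ": ", collapse = "; ")))
  }
  report <- dplyr::bind_rows(
    tibble(reason = "rows_read", n = nrow(claims) + length(reasons)),
    tibble(reason = "rows_kept", n = nrow(claims)),
    if (length(reasons)) {
      tb <- table(reasons)
      tibble(reason = names(tb), n = as.integer(tb))
    })
  list(claims = claims, report = report)
}

#' Write a claims table
#' @param claims A claims tibble (as returned in `read_claims()$claims`).
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_claims <- function(claims, path) {
  readr::write_csv(claims, path)
  invisible(path)
}

#' Read a surgical-case table
#'
#' Columns: `case_id`, `patient_id`, `surgery_date` (ISO 8601), `age_years`
#' (integer age at surgery), `panel` (`"spine"` or `"hip_knee"`, the
#' surgeon-specialty list the case came from).
#'
#' @param path Path to the cases file.
#' @return A tibble of cases.
#' @export
read_cases <- function(path) {
  raw <- read_delim_auto(path, c("case_id", "patient_id", "surgery_date",
                                 "age_years", "panel"))
  cases <- tibble(
    case_id = as.character(raw$case_id),
    patient_id = as.character(raw$patient_id),
    surgery_date = as.Date(raw$surgery_date, format = "%Y-%m-%d"),
    age_years = as.integer(raw$age_years),
    panel = trimws(raw$panel))
  if (anyNA(cases$surgery_date)) abort("cases: invalid surgery_date values")
  if (anyNA(cases$age_years) || any(cases$age_years < 0)) {
    abort("cases: age_years must be nonnegative integers")
  }
  if (!all(cases$panel %in% PANELS)) {
    abort(sprintf("cases: panel must be one of %s",
                  paste(PANELS, collapse = ", ")))
  }
  cases
}

#' Read a gold-standard label table
#'
#' Columns: `case_id`, `procedure_category` (one of `spinal_surgery`,
#' `knee_replacement`, `hip_replacement`, `other`), `indications`
#' (semicolon-joined subset of SPS;HD;KOA;HOA;other), `primary_indication`.
#'
#' @param path Path to the gold-label file.
#' @return A tibble with `indications` as a list-column of character vectors.
#' @export
read_gold <- function(path) {
  raw <- read_delim_auto(path, c("case_id", "procedure_category",
                                 "indications", "primary_indication"))
  gold <- tibble(
    case_id = as.character(raw$case_id),
    procedure_category = trimws(raw$procedure_category),
    indications = strsplit(trimws(raw$indications), ";", fixed = TRUE),
    primary_indication = trimws(raw$primary_indication))
  valid_proc <- c("spinal_surgery", "knee_replacement", "hip_replacement",
                  "other")
  if (!all(gold$procedure_category %in% valid_proc)) {
    abort("gold: unknown procedure_category value")
  }
  valid_lab <- c(COMBINATIONS, "other")
  if (!all(unlist(gold$indications) %in% valid_lab) ||
      !all(gold$primary_indication %in% valid_lab)) {
    abort("gold: indication labels must be among SPS, HD, KOA, HOA, other")
  }
  ok <- purrr::map2_lgl(gold$primary_indication, gold$indications,
                        function(p, ind) p %in% c(ind, "other"))
  if (!all(ok)) {
    abort("gold: primary_indication must be among the listed indications or 'other'")
  }
  gold
}

#' Write a gold-standard label table
#' @param gold A gold tibble (list-column `indications`).
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path) {
  flat <- gold
  flat$indications <- vapply(gold$indications, paste, character(1),
                             collapse = ";")
  readr::write_csv(flat, path)
  invisible(path)
}

read_delim_auto <- function(path, required) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  x <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(sprintf("%s: missing required column(s): %s", basename(path),
                  paste(missing, collapse = ", ")))
  }
  x
}

#' Attach each case's claim window
#'
#' Pairs every surgical case with the claim events of the same patient whose
#' service date falls in the closed span of `window_days` calendar days
#' ending on (and including) the surgery date, i.e.
#' `surgery_date - (window_days - 1) <= service_date <= surgery_date`.
#' With the default `window_days = 90` an event dated exactly 90 days before
#' surgery falls outside the window.
#'
#' @param cases A cases tibble (see [read_cases()]).
#' @param claims A claims tibble (see [read_claims()]).
#' @param window_days Length of the claim window in calendar days (>= 1).
#' @return A tibble of windowed events: `case_id` plus the claim columns,
#'   event order preserved within each case. Cases with no in-window events
#'   contribute no rows (an empty window is valid).
#' @export
window_claims <- function(cases, claims, window_days = 90) {
  stopifnot(window_days >= 1)
  joined <- dplyr::inner_join(
    cases[, c("case_id", "patient_id", "surgery_date")],
    dplyr::mutate(claims, .claim_order = dplyr::row_number()),
    by = "patient_id", relationship = "many-to-many")
  windowed <- dplyr::filter(
    joined,
    .data$service_date <= .data$surgery_date,
    .data$service_date >= .data$surgery_date - (window_days - 1))
  windowed <- dplyr::arrange(windowed, .data$case_id, .data$.claim_order)
  windowed[, c("case_id", "patient_id", "system", "code", "service_date")]
}

#' Apply the study's age-eligibility filter
#'
#' Keeps spine-panel cases aged at least `spine_min_age` years and
#' hip/knee-panel cases aged at least `hip_knee_min_age` years.
#'
#' @param cases A cases tibble.
#' @param spine_min_age Minimum age for spine surgery cases (years).
#' @param hip_knee_min_age Minimum age for hip/knee surgery cases (years).
#' @return The eligible cases; the number removed per panel is attached as
#'   attribute `"removed"` and reported via a message.
#' @export
filter_eligible <- function(cases, spine_min_age = 21, hip_knee_min_age = 40) {
  keep <- ifelse(cases$panel == "spine",
                 cases$age_years >= spine_min_age,
                 cases$age_years >= hip_knee_min_age)
  removed <- table(factor(cases$panel[!keep], levels = PANELS))
  if (any(removed > 0)) {
    inform(sprintf("filter_eligible: removed %d spine, %d hip_knee case(s)",
                   removed[["spine"]], removed[["hip_knee"]]))
  }
  out <- cases[keep, , drop = FALSE]
  attr(out, "removed") <- c(spine = unname(removed[["spine"]]),
                            hip_knee = unname(removed[["hip_knee"]]))
  out
}
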