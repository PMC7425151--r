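#' Step 1: inclusion-code matching for one combination
#'
#' A case matches a combination's indication when its claim window contains
#' at least one inclusion CPT code AND at least one inclusion ICD-10 code
#' for that combination. A window with only one of the two (or neither)
#' does not match and the case falls through to "other".
#'
#' @param events Windowed claim events for one case (tibble with `system`,
#'   `code`; codes normalized).
#' @param definition One combination definition from a codebook.
#' @return A list: `indication_matched` (logical), `matched_cpt`,
#'   `matched_icd` (character vectors of the window codes that hit).
#' @export
step1_inclusion <- function(events, definition) {
  cpt <- unique(events$code[events$system == "CPT"])
  icd <- unique(events$code[events$system == "ICD10"])
  matched_cpt <- cpt[cpt %in% definition$inclusion_cpt]
  matched_icd <- icd[pattern_matches(definition$inclusion_icd, icd, "ICD10")]
  list(indication_matched = length(matched_cpt) > 0 && length(matched_icd) > 0,
       matched_cpt = matched_cpt,
       matched_icd = matched_icd)
}

#' Age tie-break for dual-coded spine cases
#'
#' When a spine case carries inclusion codes for both spinal stenosis and
#' herniated disc, the case keeps exactly one indication by age: SpS if the
#' patient is at (or above) the threshold, HD if younger. With only one (or
#' neither) indication matched the inputs pass through unchanged.
#'
#' @param age_years Patient age at surgery, in years.
#' @param sps_matched,hd_matched Step-1 results for the two spine
#'   combinations.
#' @param threshold_years Age threshold (default 50): `age >= threshold`
#'   resolves to SpS.
#' @return A list: `sps`, `hd` (logicals after tie-break),
#'   `tie_break_applied`.
#' @export
resolve_spine_tie <- function(age_years, sps_matched, hd_matched,
                              threshold_years = 50) {
  if (sps_matched && hd_matched) {
    if (age_years >= threshold_years) {
      list(sps = TRUE, hd = FALSE, tie_break_applied = TRUE)
    } else {
      list(sps = FALSE, hd = TRUE, tie_break_applied = TRUE)
    }
  } else {
    list(sps = sps_matched, hd = hd_matched, tie_break_applied = FALSE)
  }
}

#' Step 2: exclusion-driven demotion of the primary indication
#'
#' Among cases with a matched indication, any window ICD-10 code hitting the
#' combination's exclusion patterns (fracture, neoplasm, infection and
#' similar non-elective indications) demotes the condition to a *secondary*
#' indication; the primary indication becomes "other". With no exclusion
#' hit the condition is the primary indication. Exclusions never create
#' matches.
#'
#' @param events Windowed claim events for one case.
#' @param definition One combination definition.
#' @param indication_matched Step-1 (and, for spine, tie-break) result.
#' @return A list: `status` (`"primary"`, `"secondary"`, or
#'   `"not_indicated"`) and `hits` (tibble `pattern`, `code` of every
#'   exclusion pattern fired and the window code that fired it).
#' @export
step2_exclusion <- function(events, definition, indication_matched) {
  no_hits <- tibble(pattern = character(0), code = character(0))
  if (!indication_matched) {
    return(list(status = "not_indicated", hits = no_hits))
  }
  icd <- unique(events$code[events$system == "ICD10"])
  pats <- definition$exclusion_icd
  hit_rows <- purrr::map_dfr(seq_len(nrow(pats)), function(i) {
    hit <- icd[pattern_matches(pats[i, , drop = FALSE], icd, "ICD10")]
    if (length(hit) == 0) return(NULL)
    tibble(pattern = paste0(pats$stem[i], if (pats$hierarchical[i]) "*"),
           code = hit)
  })
  if (nrow(hit_rows) > 0) {
    list(status = "secondary", hits = hit_rows)
  } else {
    list(status = "primary", hits = no_hits)
  }
}

#' Classify a single windowed surgical case
#'
#' Runs the full two-step algorithm for one case: inclusion matching over
#' the combinations of the case's surgeon panel (all four combinations when
#' `panel_restriction = FALSE`), the age tie-break when both spine
#' combinations matched, then exclusion-driven demotion per surviving
#' combination. The overall label is the unique combination left with
#' primary status, otherwise `"other"`. A hip/knee case ending with two
#' primary combinations (both hip and knee codes in one window) is labelled
#' `"ambiguous"` with a warning; the per-combination statuses remain
#' reported.
#'
#' @param case A list or one-row data frame with `case_id`, `panel`,
#'   `age_years`.
#' @param events The case's windowed claim events (see [window_claims()]).
#' @param codebook An `orthoclaims_codebook`.
#' @param panel_restriction Evaluate only the combinations of the case's
#'   panel (the validated setting). `FALSE` evaluates all four.
#' @return A one-row tibble: `case_id`, `panel`, `age_years`,
#'   `overall_label`, `tie_break_applied`, per-combination `<id>_status`,
#'   `<id>_cpt_hit`, `<id>_icd_hit`, and `exclusion_hits` (list-column of
#'   tibbles `combination`, `pattern`, `code`).
#' @export
classify_case <- function(case, events, codebook, panel_restriction = TRUE) {
  validate_codebook(codebook)
  panel <- case$panel
  stopifnot(panel %in% PANELS)
  evaluated <- if (panel_restriction) {
    COMBINATIONS[vapply(codebook$definitions, function(d) d$panel == panel,
                        logical(1))]
  } else {
    COMBINATIONS
  }

  s1 <- lapply(codebook$definitions, function(def) {
    if (def$id %in% evaluated) {
      step1_inclusion(events, def)
    } else {
      list(indication_matched = FALSE, matched_cpt = character(0),
           matched_icd = character(0))
    }
  })
  cpt_hit <- vapply(s1, function(r) length(r$matched_cpt) > 0, logical(1))
  icd_hit <- vapply(s1, function(r) length(r$matched_icd) > 0, logical(1))
  matched <- vapply(s1, `[[`, logical(1), "indication_matched")

  tie <- resolve_spine_tie(case$age_years, matched[["SPS"]], matched[["HD"]],
                           codebook$spine_age_threshold_years)
  matched[["SPS"]] <- tie$sps
  matched[["HD"]] <- tie$hd

  s2 <- lapply(COMBINATIONS, function(id) {
    step2_exclusion(events, codebook$definitions[[id]], matched[[id]])
  })
  names(s2) <- COMBINATIONS
  status <- vapply(s2, `[[`, character(1), "status")
  hits <- purrr::map_dfr(COMBINATIONS, function(id) {
    h <- s2[[id]]$hits
    if (nrow(h) == 0) return(NULL)
    tibble(combination = id, pattern = h$pattern, code = h$code)
  })
  if (nrow(hits) == 0) {
    hits <- tibble(combination = character(0), pattern = character(0),
                   code = character(0))
  }

  primaries <- COMBINATIONS[status == "primary"]
  overall <- if (length(primaries) == 1) {
    primaries
  } else if (length(primaries) == 0) {
    "other"
  } else {
    warn(sprintf("case %s matches %s as primary; labelled ambiguous",
                 case$case_id, paste(primaries, collapse = " and ")))
    "ambiguous"
  }

  tibble(
    case_id = as.character(case$case_id),
    panel = panel,
    age_years = as.integer(case$age_years),
    overall_label = overall,
    tie_break_applied = tie$tie_break_applied,
    sps_status = status[["SPS"]], hd_status = status[["HD"]],
    koa_status = status[["KOA"]], hoa_status = status[["HOA"]],
    sps_cpt_hit = cpt_hit[["SPS"]], sps_icd_hit = icd_hit[["SPS"]],
    hd_cpt_hit = cpt_hit[["HD"]], hd_icd_hit = icd_hit[["HD"]],
    koa_cpt_hit = cpt_hit[["KOA"]], koa_icd_hit = icd_hit[["KOA"]],
    hoa_cpt_hit = cpt_hit[["HOA"]], hoa_icd_hit = icd_hit[["HOA"]],
    exclusion_hits = list(hits))
}

#' Classify a cohort of surgical cases
#'
#' Windows the claims per case and applies [classify_case()] to every case,
#' order-preserving. Case ids must be unique (they are the join key for
#' validation).
#'
#' @param cases A cases tibble (`case_id`, `patient_id`, `surgery_date`,
#'   `age_years`, `panel`).
#' @param claims A claims tibble.
#' @param codebook An `orthoclaims_codebook` (default: packaged codebook).
#' @param window_days Claim-window length in days (see [window_claims()]).
#' @param panel_restriction See [classify_case()].
#' @param quiet Suppress the per-label summary message.
#' @return A tibble with one classification row per case, in input order.
#' @export
classify_cohort <- function(cases, claims, codebook = load_codebook(),
                            window_days = 90, panel_restriction = TRUE,
                            quiet = FALSE) {
  if (anyDuplicated(cases$case_id)) {
    abort(sprintf("duplicate case_id(s): %s",
                  paste(unique(cases$case_id[duplicated(cases$case_id)]),
                        collapse = ", ")))
  }
  windowed <- window_claims(cases, claims, window_days)
  by_case <- split(windowed, windowed$case_id)
  empty <- tibble(patient_id = character(0), system = character(0),
                  code = character(0))
  out <- purrr::map_dfr(seq_len(nrow(cases)), function(i) {
    case <- cases[i, ]
    events <- by_case[[case$case_id]] %||% empty
    classify_case(case, events, codebook, panel_restriction)
  })
  if (!quiet && nrow(out) > 0) {
    counts <- table(out$overall_label)
    inform(sprintf("classified %d case(s): %s", nrow(out),
                   paste(names(counts), counts, sep = "=", collapse = ", ")))
  }
  out
}

#' Write a classification table
#'
#' Serializes the list-column of exclusion hits as
#' `combination=pattern:code` entries joined by `";"`.
#'
#' @param classifications Output of [classify_cohort()].
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_classifications <- function(classifications, path) {
  flat <- classifications
  flat$exclusion_hits <- vapply(classifications$exclusion_hits, function(h) {
    if (nrow(h) == 0) return("")
    paste(sprintf("%s=%s:%s", h$combination, h$pattern, h$code),
          collapse = ";")
  }, character(1))
  readr::write_csv(flat, path)
  invisible(path)
}

#' Read a classification table written by [write_classifications()]
#' @param path Path to the classification CSV.
#' @return A classification tibble with the exclusion-hit list-column
#'   restored.
#' @export
read_classifications <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    case_id = readr::col_character(),
    exclusion_hits = readr::col_character(),
    .default = readr::col_guess()), progress = FALSE)
  x$exclusion_hits[is.na(x$exclusion_hits)] <- ""
  x$exclusion_hits <- lapply(x$exclusion_hits, function(s) {
    if (!nzchar(s)) {
      return(tibble(combination = character(0), pattern = character(0),
                    code = character(0)))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "[=:]")
    tibble(combination = vapply(parts, `[`, character(1), 1),
           pattern = vapply(parts, `[`, character(1), 2),
           code = vapply(parts, `[`, character(1), 3))
  })
  x
}
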