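#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

COMBINATIONS <- c("SPS", "HD", "KOA", "HOA")
PANELS <- c("spine", "hip_knee")
CODE_SYSTEMS <- c("ICD10", "CPT")

#' Normalize an ICD-10 or CPT code to its canonical matching form
#'
#' ICD-10 codes are uppercased and stripped of the display dot so that the
#' code hierarchy becomes a plain string prefix (`"M48.061"` becomes
#' `"M48061"`, a child of `"M48"`). CPT codes are trimmed and must be exactly
#' five characters. Normalization is idempotent.
#'
#' @param raw Character vector of raw code strings as they appear in claims
#'   extracts or code lists (dots and lower case tolerated for ICD-10).
#' @param system `"ICD10"` or `"CPT"` (scalar, applied to all of `raw`).
#' @return Character vector of normalized code values.
#' @examples
#' normalize_code("M48.061", "ICD10")  # "M48061"
#' normalize_code("27447", "CPT")      # "27447"
#' @export
normalize_code <- function(raw, system) {
  system <- match_system(system)
  if (length(raw) == 0) return(character(0))
  if (!is.character(raw)) raw <- as.character(raw)
  value <- trimws(raw)
  bad_empty <- !nzchar(value) | is.na(value)
  if (any(bad_empty)) {
    abort(sprintf("empty code string (raw: %s)",
                  paste(sQuote(raw[bad_empty]), collapse = ", ")))
  }
  if (system == "ICD10") {
    value <- gsub(".", "", toupper(value), fixed = TRUE)
    bad <- !grepl("^[A-Z][0-9A-Z]+$", value)
    if (any(bad)) {
      abort(sprintf("malformed ICD-10 code(s): %s",
                    paste(sQuote(raw[bad]), collapse = ", ")))
    }
  } else {
    value <- toupper(value)
    bad <- nchar(value) != 5L | !grepl("^[0-9A-Z]{5}$", value)
    if (any(bad)) {
      abort(sprintf("malformed CPT code(s) (must be 5 characters): %s",
                    paste(sQuote(raw[bad]), collapse = ", ")))
    }
  }
  value
}

match_system <- function(system) {
  if (!is.character(system) || length(system) != 1L ||
      !system %in% CODE_SYSTEMS) {
    abort("`system` must be \"ICD10\" or \"CPT\"")
  }
  system
}

#' Parse code-list entries into a pattern table
#'
#' A trailing asterisk on an ICD-10 entry marks a hierarchical pattern: the
#' stem and every child code in the ICD-10 hierarchy (string-prefix match on
#' normalized, dot-free values) match it. Entries without an asterisk match
#' exactly. CPT entries never carry wildcards.
#'
#' @param entries Character vector of entries as printed in a code list,
#'   e.g. `c("M48.061", "S72.0*")`.
#' @param system `"ICD10"` or `"CPT"`.
#' @return A tibble with columns `system`, `stem` (normalized), and
#'   `hierarchical` (logical).
#' @export
code_patterns <- function(entries, system) {
  system <- match_system(system)
  entries <- trimws(as.character(entries))
  hier <- grepl("\\*$", entries)
  if (system == "CPT" && any(hier)) {
    abort("hierarchical (asterisk) patterns are not supported for CPT codes")
  }
  stems <- sub("\\*$", "", entries)
  tibble(system = system,
         stem = normalize_code(stems, system),
         hierarchical = hier)
}

#' Test codes against a pattern table
#'
#' @param patterns A pattern tibble from [code_patterns()] (or a one-row
#'   subset of one).
#' @param code Character vector of *normalized* code values (see
#'   [normalize_code()]).
#' @param system Code system of `code`; must agree with the patterns.
#' @return Logical vector, one element per `code`: `TRUE` if any pattern
#'   matches (exact equality for non-hierarchical patterns, string-prefix
#'   for hierarchical ones).
#' @examples
#' pats <- code_patterns(c("M80*", "M17.11"), "ICD10")
#' pattern_matches(pats, c("M80051", "M1711", "S32401"), "ICD10")
#' @export
pattern_matches <- function(patterns, code, system = patterns$system[1]) {
  stopifnot(is.data.frame(patterns),
            all(c("system", "stem", "hierarchical") %in% names(patterns)))
  if (nrow(patterns) == 0L || length(code) == 0L) {
    return(rep(FALSE, length(code)))
  }
  if (any(patterns$system != system)) {
    abort("pattern/code system mismatch")
  }
  exact <- patterns$stem[!patterns$hierarchical]
  prefixes <- patterns$stem[patterns$hierarchical]
  out <- code %in% exact
  for (p in prefixes) {
    out <- out | startsWith(code, p)
  }
  out
}

#' Path to the packaged default codebook configuration
#' @return File path of the YAML codebook shipped with the package.
#' @export
default_codebook_path <- function() {
  system.file("extdata", "codebook.yaml", package = "orthoclaims",
              mustWork = TRUE)
}

#' Load a codebook configuration
#'
#' Reads a YAML codebook (see the packaged default at
#' [default_codebook_path()]) describing, for each of the four
#' procedure/primary-indication combinations (SPS, HD, KOA, HOA), the
#' inclusion CPT codes, inclusion ICD-10 codes, and exclusion ICD-10
#' patterns, plus the spine age threshold used to break dual SpS/HD coding
#' ties.
#'
#' Inclusion ICD-10 entries are exact matches unless the config (or the
#' `inclusion_hierarchy` argument) turns on hierarchy matching for inclusion
#' lists; exclusion entries use the asterisk wildcard convention of
#' [code_patterns()].
#'
#' @param path Path to a YAML codebook; defaults to the packaged codebook.
#' @param inclusion_hierarchy If non-`NULL`, overrides the config's
#'   `inclusion_hierarchy` flag (`FALSE` in the default codebook): when
#'   `TRUE`, inclusion ICD-10 codes also match their ICD-10 children.
#' @return An object of class `orthoclaims_codebook`: a list with
#'   `spine_age_threshold_years`, `inclusion_hierarchy`, and `definitions`
#'   (a named list of one definition per combination, each holding
#'   `id`, `label`, `panel`, `inclusion_cpt`, `inclusion_icd`,
#'   `exclusion_icd`).
#' @export
load_codebook <- function(path = default_codebook_path(),
                          inclusion_hierarchy = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("codebook not found: %s", path))
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$combinations)) {
    abort("codebook config lacks a `combinations` mapping")
  }
  incl_hier <- inclusion_hierarchy %||% cfg$inclusion_hierarchy %||% FALSE
  stopifnot(is.logical(incl_hier), length(incl_hier) == 1L)
  threshold <- cfg$spine_age_threshold_years %||% 50L
  missing <- setdiff(COMBINATIONS, names(cfg$combinations))
  if (length(missing)) {
    abort(sprintf("codebook missing combination(s): %s",
                  paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(names(cfg$combinations), COMBINATIONS)
  if (length(unknown)) {
    abort(sprintf("unknown combination id(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  definitions <- lapply(COMBINATIONS, function(id) {
    entry <- cfg$combinations[[id]]
    for (role in c("inclusion_cpt", "inclusion_icd", "exclusion_icd")) {
      if (length(entry[[role]]) == 0) {
        abort(sprintf("combination %s: empty or missing `%s` list", id, role))
      }
    }
    incl_icd <- code_patterns(unlist(entry$inclusion_icd), "ICD10")
    if (incl_hier) incl_icd$hierarchical <- TRUE
    list(
      id = id,
      label = entry$label %||% id,
      panel = match.arg(entry$panel, PANELS),
      inclusion_cpt = normalize_code(unlist(entry$inclusion_cpt), "CPT"),
      inclusion_icd = incl_icd,
      exclusion_icd = code_patterns(unlist(entry$exclusion_icd), "ICD10")
    )
  })
  names(definitions) <- COMBINATIONS
  cb <- structure(
    list(spine_age_threshold_years = as.integer(threshold),
         inclusion_hierarchy = incl_hier,
         definitions = definitions),
    class = "orthoclaims_codebook")
  validate_codebook(cb)
  cb
}

validate_codebook <- function(cb) {
  stopifnot(inherits(cb, "orthoclaims_codebook"))
  if (!identical(sort(names(cb$definitions)), sort(COMBINATIONS))) {
    abort("codebook must define exactly SPS, HD, KOA, HOA")
  }
  if (cb$spine_age_threshold_years <= 0) {
    abort("spine_age_threshold_years must be positive")
  }
  for (def in cb$definitions) {
    expected_panel <- if (def$id %in% c("SPS", "HD")) "spine" else "hip_knee"
    if (def$panel != expected_panel) {
      abort(sprintf("combination %s must have panel %s", def$id,
                    expected_panel))
    }
    if (any(duplicated(def$inclusion_cpt))) {
      abort(sprintf("combination %s: duplicate inclusion CPT codes", def$id))
    }
  }
  invisible(cb)
}

#' Serialize a codebook back to YAML
#'
#' Inverse of [load_codebook()] up to formatting: loading the written file
#' yields an identical codebook.
#'
#' @param codebook An `orthoclaims_codebook`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(codebook, path) {
  validate_codebook(codebook)
  combos <- lapply(codebook$definitions, function(def) {
    # inclusion hierarchy applied globally is carried by the top-level flag;
    # only per-entry wildcards (custom codebooks) get an asterisk back
    incl_star <- def$inclusion_icd$hierarchical & !codebook$inclusion_hierarchy
    list(label = def$label,
         panel = def$panel,
         inclusion_cpt = as.list(def$inclusion_cpt),
         inclusion_icd = as.list(paste0(def$inclusion_icd$stem,
                                        ifelse(incl_star, "*", ""))),
         exclusion_icd = as.list(paste0(def$exclusion_icd$stem,
                                        ifelse(def$exclusion_icd$hierarchical,
                                               "*", ""))))
  })
  cfg <- list(
    spine_age_threshold_years = codebook$spine_age_threshold_years,
    inclusion_hierarchy = codebook$inclusion_hierarchy,
    combinations = combos)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Validate a codebook config and summarise its code lists
#'
#' The "lint" entry point: loads the config (raising informative errors on
#' structural defects) and returns per-combination counts of inclusion CPT,
#' inclusion ICD-10, exclusion patterns, and how many exclusion patterns are
#' hierarchical.
#'
#' @param path Path to a YAML codebook config.
#' @return A tibble with one row per combination, invisibly printed.
#' @export
lint_codebook <- function(path = default_codebook_path()) {
  cb <- load_codebook(path)
  out <- purrr::map_dfr(cb$definitions, function(def) {
    tibble(combination = def$id,
           panel = def$panel,
           n_inclusion_cpt = length(def$inclusion_cpt),
           n_inclusion_icd = nrow(def$inclusion_icd),
           n_exclusion = nrow(def$exclusion_icd),
           n_exclusion_wildcard = sum(def$exclusion_icd$hierarchical))
  })
  out
}

#' @export
print.orthoclaims_codebook <- function(x, ...) {
  cat("<orthoclaims codebook>\n")
  cat(sprintf("  spine age threshold: %d years; inclusion hierarchy: %s\n",
              x$spine_age_threshold_years, x$inclusion_hierarchy))
  for (def in x$definitions) {
    cat(sprintf("  %-3s (%s, %s): %d CPT, %d inclusion ICD, %d exclusion\n",
                def$id, def$label, def$panel, length(def$inclusion_cpt),
                nrow(def$inclusion_icd), nrow(def$exclusion_icd)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
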