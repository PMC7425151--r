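# Archetype recipes for the synthetic claims cohort.
#
# Each archetype emulates a class of real surgical cases: clean elective
# cases for the four target combinations, dual-coded spine cases (both
# stenosis and herniated-disc diagnosis codes in one window, the main
# source of spine misclassification), and "other" surgeries whose codes
# never match the target combinations. Ages are drawn uniformly within
# ranges consistent with the observed mean ages per indication (~62-67 for
# the osteoarthritis and stenosis groups, ~52 for herniated disc).
ARCHETYPES <- list(
  clean_koa = list(
    panel = "hip_knee", target = "KOA", procedure = "knee_replacement",
    cpt = "27447", icd = "M1711", contaminant = "M80051",
    age = c(55L, 80L)),
  clean_hoa = list(
    panel = "hip_knee", target = "HOA", procedure = "hip_replacement",
    cpt = "27130", icd = "M1611", contaminant = "M87051",
    age = c(50L, 80L)),
  clean_sps = list(
    panel = "spine", target = "SPS", procedure = "spinal_surgery",
    cpt = "63047", icd = "M48062", contaminant = "S32001",
    age = c(55L, 85L)),
  clean_hd = list(
    panel = "spine", target = "HD", procedure = "spinal_surgery",
    cpt = "63030", icd = "M5126", contaminant = "R159",
    age = c(25L, 49L)),
  # dual-coded spine cases share CPT 63047 (in both spine inclusion lists)
  # and carry both an SpS and an HD inclusion diagnosis; the age tie-break
  # decides which indication survives, so a gold-HD dual case aged >= 50 is
  # misclassified as SpS (and vice versa)
  dual_spine_sps = list(
    panel = "spine", target = "SPS", procedure = "spinal_surgery",
    cpt = "63047", icd = "M48062", extra_icd = "M5126",
    contaminant = "S32001", age = c(50L, 85L)),
  dual_spine_hd = list(
    panel = "spine", target = "HD", procedure = "spinal_surgery",
    cpt = "63047", icd = "M5126", extra_icd = "M48062",
    contaminant = "R159", age = c(30L, 70L)),
  other_hip_knee = list(
    panel = "hip_knee", target = NA_character_, procedure = "other",
    cpt = "29881", icd = "M2550", contaminant = "M80051",
    age = c(40L, 85L)),
  other_spine = list(
    panel = "spine", target = NA_character_, procedure = "other",
    cpt = "63045", icd = "M4802", contaminant = "S32001",
    age = c(21L, 85L))
)

default_archetype_mix <- function() {
  # case mix follows the observed distribution of indications in the
  # validation cohort (~17% HOA, ~15% KOA, ~17% SpS, ~7% HD, ~44% other),
  # with a share of the spine cases dual-coded
  c(clean_hoa = 0.17, clean_koa = 0.15, clean_sps = 0.12,
    dual_spine_sps = 0.05, clean_hd = 0.05, dual_spine_hd = 0.02,
    other_hip_knee = 0.26, other_spine = 0.18)
}

#' Build and validate a simulation configuration
#'
#' @param n_cases Number of surgical cases to generate.
#' @param mix Named numeric vector of archetype proportions (must sum to 1);
#'   names among `names(archetypes())`. Default mirrors the validation
#'   cohort's indication distribution.
#' @param p_drop_cpt Probability that a positive case's inclusion CPT events
#'   are missing from the claims (unbilled procedure codes).
#' @param p_drop_icd Probability that a positive case's inclusion ICD-10
#'   events are missing.
#' @param p_add_exclusion Probability that a positive case's window is
#'   contaminated with an exclusion-matching diagnosis (fracture,
#'   osteonecrosis, incontinence, ...), demoting the indication to
#'   secondary.
#' @param p_dual_spine_coding Probability that a clean spine case also
#'   carries the other spine condition's inclusion diagnosis, triggering
#'   the age tie-break.
#' @param seed Integer seed governing all randomness of the generator.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_cases = 790,
                              mix = default_archetype_mix(),
                              p_drop_cpt = 0.08,
                              p_drop_icd = 0.03,
                              p_add_exclusion = 0.05,
                              p_dual_spine_coding = 0.10,
                              seed = 1) {
  if (n_cases < 1) abort("n_cases must be >= 1")
  if (is.null(names(mix)) || !all(names(mix) %in% names(ARCHETYPES))) {
    abort(sprintf("mix names must be among: %s",
                  paste(names(ARCHETYPES), collapse = ", ")))
  }
  if (abs(sum(mix) - 1) > 1e-9) {
    abort(sprintf("mix proportions must sum to 1 (got %.6f)", sum(mix)))
  }
  probs <- c(p_drop_cpt, p_drop_icd, p_add_exclusion, p_dual_spine_coding)
  if (any(probs < 0) || any(probs > 1)) {
    abort("corruption rates must lie in [0, 1]")
  }
  structure(list(n_cases = as.integer(n_cases), mix = mix,
                 p_drop_cpt = p_drop_cpt, p_drop_icd = p_drop_icd,
                 p_add_exclusion = p_add_exclusion,
                 p_dual_spine_coding = p_dual_spine_coding,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' The built-in archetype catalogue
#' @return Named list of archetype recipes (panel, target combination, code
#'   recipe, age range).
#' @export
archetypes <- function() ARCHETYPES

#' Generate a seeded synthetic claims cohort
#'
#' Emits a claims table, a surgical-case table, a gold-standard label table,
#' and per-case truth metadata recording the archetype and every corruption
#' applied, so the expected classifier behavior of every case is computable
#' without running the classifier (see [expected_classification()]).
#'
#' Every case additionally receives a benign in-window diagnosis (I10) and
#' an exclusion-matching diagnosis dated 100 days before surgery — outside
#' the 90-day window — so that correct windowing is observable in the
#' output.
#'
#' @param config A [simulation_config()].
#' @return A list: `claims`, `cases`, `gold`, `truth` tibbles plus the
#'   `config`. Identical configs (including seed) give identical output.
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)

  n <- config$n_cases
  arch_names <- sample(names(config$mix), n, replace = TRUE,
                       prob = config$mix)
  ids <- sprintf("C%04d", seq_len(n))
  pids <- sprintf("P%04d", seq_len(n))
  base_date <- as.Date("2018-06-01")

  rows_cases <- vector("list", n)
  rows_claims <- vector("list", n)
  rows_gold <- vector("list", n)
  rows_truth <- vector("list", n)

  for (i in seq_len(n)) {
    arch <- ARCHETYPES[[arch_names[i]]]
    positive <- !is.na(arch$target)
    dual_archetype <- !is.null(arch$extra_icd)
    age <- sample(arch$age[1]:arch$age[2], 1L)
    surgery <- base_date + sample(0:29, 1L)

    drop_cpt <- positive && stats::runif(1) < config$p_drop_cpt
    drop_icd <- positive && stats::runif(1) < config$p_drop_icd
    add_excl <- positive && stats::runif(1) < config$p_add_exclusion
    dual_corr <- positive && !dual_archetype && arch$panel == "spine" &&
      stats::runif(1) < config$p_dual_spine_coding

    ev <- list()
    if (!drop_cpt || !positive) {
      ev[[length(ev) + 1]] <- list("CPT", arch$cpt, surgery)
    }
    if (!drop_icd || !positive) {
      ev[[length(ev) + 1]] <- list("ICD10", arch$icd,
                                   surgery - sample(1:60, 1L))
      if (dual_archetype) {
        ev[[length(ev) + 1]] <- list("ICD10", arch$extra_icd,
                                     surgery - sample(1:60, 1L))
      }
      if (dual_corr) {
        partner <- if (arch$target == "SPS") "M5126" else "M48062"
        ev[[length(ev) + 1]] <- list("ICD10", partner,
                                     surgery - sample(1:60, 1L))
      }
    }
    if (add_excl) {
      ev[[length(ev) + 1]] <- list("ICD10", arch$contaminant,
                                   surgery - sample(0:30, 1L))
    }
    ev[[length(ev) + 1]] <- list("ICD10", "I10", surgery - sample(0:80, 1L))
    ev[[length(ev) + 1]] <- list("ICD10", arch$contaminant, surgery - 100)

    rows_claims[[i]] <- tibble(
      patient_id = pids[i],
      system = vapply(ev, `[[`, character(1), 1),
      code = vapply(ev, `[[`, character(1), 2),
      service_date = as.Date(vapply(ev, function(e) as.character(e[[3]]),
                                    character(1))))
    rows_cases[[i]] <- tibble(
      case_id = ids[i], patient_id = pids[i], surgery_date = surgery,
      age_years = age, panel = arch$panel)
    rows_gold[[i]] <- tibble(
      case_id = ids[i],
      procedure_category = arch$procedure,
      indications = list(if (positive) arch$target else "other"),
      primary_indication = if (positive) arch$target else "other")
    rows_truth[[i]] <- tibble(
      case_id = ids[i], archetype = arch_names[i], age_years = age,
      drop_cpt = drop_cpt, drop_icd = drop_icd, add_exclusion = add_excl,
      dual_coding = dual_archetype || dual_corr)
  }

  list(claims = dplyr::bind_rows(rows_claims),
       cases = dplyr::bind_rows(rows_cases),
       gold = dplyr::bind_rows(rows_gold),
       truth = dplyr::bind_rows(rows_truth),
       config = config)
}

#' Generate a single dual-coded spine case
#'
#' A spine case carrying the shared inclusion CPT (63047) plus inclusion
#' diagnoses for both spinal stenosis and herniated disc, with the gold
#' label set by the caller. Used to probe tie-break-induced errors: a
#' gold-HD case aged 50+ is classified SpS (an HD false negative and an SpS
#' false positive).
#'
#' @param age Patient age at surgery (>= 21).
#' @param gold_label `"SPS"` or `"HD"` — the chart-review truth.
#' @param case_id,patient_id Identifiers.
#' @param surgery_date Surgery date.
#' @return A list with one-row `cases` and `gold` tibbles and a `claims`
#'   tibble.
#' @export
generate_dual_spine_case <- function(age, gold_label = c("SPS", "HD"),
                                     case_id = "DUAL1",
                                     patient_id = "PDUAL1",
                                     surgery_date = as.Date("2018-06-15")) {
  gold_label <- match.arg(gold_label)
  stopifnot(age >= 21)
  claims <- tibble(
    patient_id = patient_id,
    system = c("CPT", "ICD10", "ICD10"),
    code = c("63047", "M48062", "M5126"),
    service_date = c(surgery_date, surgery_date - 10, surgery_date - 5))
  cases <- tibble(case_id = case_id, patient_id = patient_id,
                  surgery_date = surgery_date, age_years = as.integer(age),
                  panel = "spine")
  gold <- tibble(case_id = case_id, procedure_category = "spinal_surgery",
                 indications = list(gold_label),
                 primary_indication = gold_label)
  list(cases = cases, claims = claims, gold = gold)
}

#' Expected classification of a synthetic cohort, from truth metadata alone
#'
#' Derives, for every generated case, the classification the two-step
#' algorithm must produce — using only the archetype recipe, the recorded
#' corruptions, and the age rule, never the classification engine itself.
#' The rules: a dropped inclusion CPT or ICD makes the case "other"; a
#' dual-coded spine case resolves to SpS at age >= `threshold` else HD; an
#' exclusion contamination demotes the surviving indication to secondary
#' (primary indication "other").
#'
#' @param truth The `truth` tibble of a generated cohort.
#' @param threshold Spine age threshold (default 50).
#' @return A tibble: `case_id`, `overall_label`, `sps_status`, `hd_status`,
#'   `koa_status`, `hoa_status`.
#' @export
expected_classification <- function(truth, threshold = 50) {
  purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    arch <- ARCHETYPES[[tr$archetype]]
    status <- c(SPS = "not_indicated", HD = "not_indicated",
                KOA = "not_indicated", HOA = "not_indicated")
    if (!is.na(arch$target) && !tr$drop_cpt && !tr$drop_icd) {
      winner <- if (arch$panel == "spine" && tr$dual_coding) {
        if (tr$age_years >= threshold) "SPS" else "HD"
      } else {
        arch$target
      }
      status[[winner]] <- if (tr$add_exclusion) "secondary" else "primary"
    }
    overall <- names(status)[status == "primary"]
    tibble(case_id = tr$case_id,
           overall_label = if (length(overall)) overall else "other",
           sps_status = status[["SPS"]], hd_status = status[["HD"]],
           koa_status = status[["KOA"]], hoa_status = status[["HOA"]])
  })
}

#' Write a synthetic cohort to a directory
#'
#' Emits `claims.csv`, `cases.csv`, `gold.csv`, `truth.csv` in the formats
#' read by [read_claims()], [read_cases()], [read_gold()].
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$claims, file.path(dir, "claims.csv"))
  readr::write_csv(cohort$cases, file.path(dir, "cases.csv"))
  write_gold(cohort$gold, file.path(dir, "gold.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
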