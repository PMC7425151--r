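# Fixture builders and independent oracles used across the suite.

mk_claims <- function(patient_id, system, code, service_date) {
  tibble::tibble(patient_id = patient_id, system = system, code = code,
                 service_date = as.Date(service_date))
}

mk_case <- function(case_id, patient_id, surgery_date, age_years, panel) {
  tibble::tibble(case_id = case_id, patient_id = patient_id,
                 surgery_date = as.Date(surgery_date),
                 age_years = as.integer(age_years), panel = panel)
}

mk_gold <- function(case_id, procedure_category, indications,
                    primary_indication) {
  tibble::tibble(case_id = case_id,
                 procedure_category = procedure_category,
                 indications = indications,
                 primary_indication = primary_indication)
}

# Three-case reference fixture: an elective stenosis case (shared spine CPT
# plus both a stenosis and a disc diagnosis, resolved by age), an elective
# hip case, and the same hip codes contaminated with a bone-metastasis
# diagnosis that demotes the indication.
fixture_three_cases <- function() {
  cases <- dplyr::bind_rows(
    mk_case("S1", "P1", "2018-06-10", 62, "spine"),
    mk_case("H1", "P2", "2018-06-12", 70, "hip_knee"),
    mk_case("H2", "P3", "2018-06-14", 68, "hip_knee"))
  claims <- dplyr::bind_rows(
    mk_claims("P1", c("CPT", "ICD10", "ICD10"),
              c("63047", "M48062", "M5126"),
              c("2018-06-10", "2018-05-20", "2018-05-25")),
    mk_claims("P2", c("CPT", "ICD10"), c("27130", "M1611"),
              c("2018-06-12", "2018-05-30")),
    mk_claims("P3", c("CPT", "ICD10", "ICD10"),
              c("27130", "M1611", "C7951"),
              c("2018-06-14", "2018-06-01", "2018-06-05")))
  gold <- dplyr::bind_rows(
    mk_gold("S1", "spinal_surgery", list("SPS"), "SPS"),
    mk_gold("H1", "hip_replacement", list("HOA"), "HOA"),
    mk_gold("H2", "hip_replacement", list("HOA"), "other"))
  list(cases = cases, claims = claims, gold = gold)
}

# Independent oracle: a deliberately naive classifier built from nested
# loops over every event and every pattern, with no vectorization or
# shared matching code. Used only to cross-check the engine.
brute_pattern_hit <- function(stem, hierarchical, value) {
  if (hierarchical) {
    nchar(value) >= nchar(stem) &&
      substr(value, 1L, nchar(stem)) == stem
  } else {
    value == stem
  }
}

brute_classify <- function(cases, claims, codebook, window_days = 90,
                           panel_restriction = TRUE) {
  cl_pid <- claims$patient_id
  cl_sys <- claims$system
  cl_code <- claims$code
  cl_date <- claims$service_date
  out <- NULL
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    evs <- list()
    for (j in seq_along(cl_pid)) {
      if (cl_pid[j] == cs$patient_id &&
          cl_date[j] <= cs$surgery_date &&
          cl_date[j] >= cs$surgery_date - (window_days - 1)) {
        evs[[length(evs) + 1]] <- list(system = cl_sys[j], code = cl_code[j])
      }
    }
    matched <- cpt_hit <- icd_hit <- c(SPS = FALSE, HD = FALSE,
                                       KOA = FALSE, HOA = FALSE)
    for (id in names(codebook$definitions)) {
      def <- codebook$definitions[[id]]
      if (panel_restriction && def$panel != cs$panel) next
      for (ev in evs) {
        if (ev$system == "CPT") {
          for (cpt in def$inclusion_cpt) {
            if (ev$code == cpt) cpt_hit[[id]] <- TRUE
          }
        } else {
          for (k in seq_len(nrow(def$inclusion_icd))) {
            if (brute_pattern_hit(def$inclusion_icd$stem[k],
                                  def$inclusion_icd$hierarchical[k],
                                  ev$code)) icd_hit[[id]] <- TRUE
          }
        }
      }
      matched[[id]] <- cpt_hit[[id]] && icd_hit[[id]]
    }
    tie <- FALSE
    if (matched[["SPS"]] && matched[["HD"]]) {
      tie <- TRUE
      if (cs$age_years >= codebook$spine_age_threshold_years) {
        matched[["HD"]] <- FALSE
      } else {
        matched[["SPS"]] <- FALSE
      }
    }
    status <- c(SPS = "not_indicated", HD = "not_indicated",
                KOA = "not_indicated", HOA = "not_indicated")
    for (id in names(codebook$definitions)) {
      if (!matched[[id]]) next
      def <- codebook$definitions[[id]]
      excl <- FALSE
      for (ev in evs) {
        if (ev$system != "ICD10") next
        for (k in seq_len(nrow(def$exclusion_icd))) {
          if (brute_pattern_hit(def$exclusion_icd$stem[k],
                                def$exclusion_icd$hierarchical[k],
                                ev$code)) excl <- TRUE
        }
      }
      status[[id]] <- if (excl) "secondary" else "primary"
    }
    prim <- names(status)[status == "primary"]
    overall <- if (length(prim) == 1) prim
               else if (length(prim) == 0) "other" else "ambiguous"
    out <- rbind(out, data.frame(
      case_id = cs$case_id, overall_label = overall,
      tie_break_applied = tie,
      sps_status = status[["SPS"]], hd_status = status[["HD"]],
      koa_status = status[["KOA"]], hoa_status = status[["HOA"]],
      stringsAsFactors = FALSE))
  }
  out
}

# Independent oracle: Clopper-Pearson endpoints by bisection on the
# binomial tail probabilities (no beta quantiles).
cp_bisect <- function(x, n, alpha = 0.05, tol = 1e-12) {
  bisect <- function(f, lo, hi) {
    for (it in 1:100) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else {
    # smallest p with P(X >= x | p) >= alpha/2 ; tail increasing in p
    bisect(function(p) (1 - pbinom(x - 1, n, p)) - alpha / 2, 0, 1)
  }
  upper <- if (x == n) 1 else {
    # largest p with P(X <= x | p) >= alpha/2 ; tail decreasing in p
    bisect(function(p) alpha / 2 - pbinom(x, n, p), 0, 1)
  }
  c(lower = lower, upper = upper)
}
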