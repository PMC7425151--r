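test_that("confusion counts partition the panel-restricted case set", {
  fx <- fixture_three_cases()
  pred <- classify_cohort(fx$cases, fx$claims, load_codebook(), quiet = TRUE)

  cc <- confusion(pred, fx$gold, "HOA", "primary_indication")
  # two hip/knee cases: one true positive, one true negative (gold primary
  # "other" after demotion)
  expect_equal(c(cc$tp, cc$fp, cc$fn, cc$tn), c(1, 0, 0, 1))
  expect_equal(cc$n, 2)

  # at the indication level the demoted case is a positive on both sides
  ci <- confusion(pred, fx$gold, "HOA", "indication")
  expect_equal(c(ci$tp, ci$fp, ci$fn, ci$tn), c(2, 0, 0, 0))

  sps <- confusion(pred, fx$gold, "SPS", "primary_indication")
  expect_equal(c(sps$tp, sps$fp, sps$fn, sps$tn), c(1, 0, 0, 0))

  orphan_gold <- fx$gold[-1, ]
  expect_error(confusion(pred, orphan_gold, "HOA", "primary_indication"),
               "unmatched case_id")
})

test_that("sensitivity and specificity reproduce their count ratios", {
  cc <- confusion_from_counts(tp = 106, fp = 2, fn = 9, tn = 306,
                              combination = "KOA")
  se <- sensitivity(cc)
  expect_equal(se$point, 106 / 115)
  expect_equal(round(se$point, 2), 0.92)
  expect_equal(se$n, 115L)
  sp <- specificity(cc)
  expect_equal(sp$point, 306 / 308)
  expect_equal(sp$n, 308L)

  expect_equal(round(sensitivity(confusion_from_counts(37, 0, 16, 0,
                                                       combination = "HD"))$point,
                     2), 0.70)
  expect_equal(sensitivity(confusion_from_counts(0, 0, 5, 10))$point, 0)
  expect_error(sensitivity(confusion_from_counts(0, 3, 0, 7)), "undefined")
  expect_error(specificity(confusion_from_counts(4, 0, 1, 0)), "undefined")
  expect_error(confusion_from_counts(-1, 0, 0, 0), "nonnegative")
})

test_that("Clopper-Pearson endpoints match the published spot checks", {
  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)
  expect_equal(clopper_pearson(10, 10)[["upper"]], 1)
  hd <- clopper_pearson(37, 53)
  expect_equal(round(hd[["lower"]], 2), 0.56)
  expect_equal(round(hd[["upper"]], 2), 0.82)
  expect_equal(round(clopper_pearson(106, 115)[["lower"]], 2), 0.86)
  expect_error(clopper_pearson(5, 4), "require")
  expect_error(clopper_pearson(2, 10, alpha = 1.5), "require")
})

test_that("Clopper-Pearson equals binomial-tail bisection to 1e-8", {
  # exhaustive over small trials, spot-checked at the study denominators
  for (n in c(1:12, 25, 40, 53, 60)) {
    for (x in 0:n) {
      got <- clopper_pearson(x, n)
      want <- cp_bisect(x, n)
      expect_equal(got[["lower"]], want[["lower"]], tolerance = 1e-8)
      expect_equal(got[["upper"]], want[["upper"]], tolerance = 1e-8)
    }
  }
})

test_that("predictive values follow Bayes' rule with undefined boundaries", {
  pv <- predictive_values(1, 1, 0.5)
  expect_equal(c(pv$ppv, pv$npv), c(1, 1))
  # at p = 1 a positive call is always right; NPV collapses to 0 when Se < 1
  pv1 <- predictive_values(0.9, 0.8, 1)
  expect_equal(pv1$ppv, 1)
  expect_equal(pv1$npv, 0)
  # perfect specificity at zero prevalence: PPV has no defined value
  expect_true(is.nan(predictive_values(0.9, 1, 0)$ppv))
  expect_equal(predictive_values(0.92, 0.99, 0.27)$ppv, 0.9715,
               tolerance = 1e-4)
  expect_error(predictive_values(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("PPV is nondecreasing and NPV nonincreasing in the prior", {
  set.seed(41)
  grid <- seq(0, 1, by = 0.01)
  for (rep in 1:10) {
    se <- runif(1, 0.05, 0.99)
    sp <- runif(1, 0.05, 0.99)
    curve <- pv_curve(se, sp, grid)
    expect_false(is.unsorted(curve$ppv))
    expect_false(is.unsorted(rev(curve$npv)))
  }
  expect_equal(nrow(pv_curve(0.9, 0.9, numeric(0))), 0)
  marked <- pv_curve(0.92, 0.99, grid, combination = "KOA",
                     mark_priors = 0.27)
  expect_equal(sum(marked$marked), 1)
  expect_equal(marked$ppv[marked$marked], 0.9715, tolerance = 1e-4)
})

test_that("predictive values agree with Monte-Carlo simulation within 3 SE", {
  set.seed(42)
  n <- 2e5
  se <- 0.92; sp <- 0.99; p <- 0.27
  disease <- rbinom(n, 1, p)
  test_pos <- ifelse(disease == 1, rbinom(n, 1, se), rbinom(n, 1, 1 - sp))
  ppv_hat <- mean(disease[test_pos == 1])
  npv_hat <- mean(1 - disease[test_pos == 0])
  pv <- predictive_values(se, sp, p)
  se_ppv <- sqrt(ppv_hat * (1 - ppv_hat) / sum(test_pos == 1))
  se_npv <- sqrt(npv_hat * (1 - npv_hat) / sum(test_pos == 0))
  expect_lt(abs(pv$ppv - ppv_hat), 3 * se_ppv)
  expect_lt(abs(pv$npv - npv_hat), 3 * se_npv)
})

test_that("Cohen's kappa matches hand computation and a reference library", {
  expect_equal(cohens_kappa(diag(c(10, 20, 30))), 1)
  expect_equal(cohens_kappa(matrix(25, 2, 2)), 0)
  expect_equal(cohens_kappa(matrix(c(45, 5, 5, 45), 2)), 0.8)
  expect_error(cohens_kappa(matrix(1, 2, 3)), "square")
  expect_error(cohens_kappa(matrix(0, 2, 2)), "positive")

  set.seed(43)
  tab <- matrix(rpois(16, 20), 4, 4)
  expect_equal(cohens_kappa(tab), e1071::classAgreement(tab)$kappa,
               tolerance = 1e-12)
})

test_that("the misclassification audit recovers mechanical causes", {
  cb <- load_codebook()
  cases <- dplyr::bind_rows(
    mk_case("FN1", "P1", "2018-06-10", 66, "hip_knee"),  # demoted gold-HOA
    mk_case("FN2", "P2", "2018-06-10", 66, "hip_knee"),  # unbilled CPT
    mk_case("FN3", "P3", "2018-06-10", 62, "spine"),     # tie-break HD->SpS
    mk_case("TP1", "P4", "2018-06-10", 66, "hip_knee"))
  claims <- dplyr::bind_rows(
    mk_claims("P1", c("CPT", "ICD10", "ICD10"), c("27130", "M1611", "M87051"),
              rep("2018-06-05", 3)),
    mk_claims("P2", "ICD10", "M1611", "2018-06-05"),
    mk_claims("P3", c("CPT", "ICD10", "ICD10"), c("63047", "M5126", "M48062"),
              rep("2018-06-05", 3)),
    mk_claims("P4", c("CPT", "ICD10"), c("27130", "M1611"),
              rep("2018-06-05", 2)))
  gold <- dplyr::bind_rows(
    mk_gold("FN1", "hip_replacement", list("HOA"), "HOA"),
    mk_gold("FN2", "hip_replacement", list("HOA"), "HOA"),
    mk_gold("FN3", "spinal_surgery", list("HD"), "HD"),
    mk_gold("TP1", "hip_replacement", list("HOA"), "HOA"))
  pred <- classify_cohort(cases, claims, cb, quiet = TRUE)
  audit <- misclassification_report(pred, gold)

  expect_equal(audit$cause[audit$case_id == "FN1" & audit$error == "FN"],
               "exclusion_demotion:M87*")
  expect_equal(audit$cause[audit$case_id == "FN2" & audit$error == "FN"],
               "missing_cpt")
  fn3 <- audit[audit$case_id == "FN3", ]
  expect_equal(fn3$cause[fn3$combination == "HD" & fn3$error == "FN"],
               "tie_break_override")
  expect_equal(fn3$cause[fn3$combination == "SPS" & fn3$error == "FP"],
               "tie_break_override")
  expect_false("TP1" %in% audit$case_id)
})

test_that("cohort validation reports both levels with interval bounds ordered", {
  cohort <- generate_cohort(simulation_config(n_cases = 250, seed = 8))
  pred <- classify_cohort(cohort$cases, cohort$claims, load_codebook(),
                          quiet = TRUE)
  metrics <- validate_cohort(pred, cohort$gold)
  expect_setequal(unique(metrics$level),
                  c("indication", "primary_indication"))
  expect_true(all(metrics$ci_low <= metrics$point + 1e-12))
  expect_true(all(metrics$point <= metrics$ci_high + 1e-12))
  expect_true(all(metrics$point >= 0 & metrics$point <= 1))
  # counts partition the evaluated panel for every row
  spine_n <- sum(cohort$cases$panel == "spine")
  hip_n <- sum(cohort$cases$panel == "hip_knee")
  expect_true(all((metrics$tp + metrics$fp + metrics$fn + metrics$tn) ==
                    ifelse(metrics$combination %in% c("SPS", "HD"),
                           spine_n, hip_n)))
})
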