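small_cfg <- function(...) synthetic_config(seed = 9, n_fixed = 60L,
                                            n_unfixed = 60L, ...)

test_that("identical config and seed give identical output", {
  expect_identical(generate_claims_data(small_cfg()),
                   generate_claims_data(small_cfg()))
  # a different seed changes the draw
  expect_false(identical(generate_claims_data(small_cfg()),
                         generate_claims_data(synthetic_config(
                           seed = 10, n_fixed = 60L, n_unfixed = 60L))))
})

test_that("config validation enforces the documented invariants", {
  expect_error(synthetic_config(n_fixed = -1), ">= 0")
  expect_error(synthetic_config(regimen_mix = list(
    fixed = c("latanoprost/timolol" = 0.5),
    unfixed = c("PG+BB" = 1))), "sum to 1")
  expect_error(synthetic_config(contamination = 1.5), "contamination")
  expect_error(synthetic_config(
    refill_gap_model = list(p_zero = 0.5, geom_prob = 0.3, max_delay = 40)),
    "max_delay")
})

test_that("generated tables satisfy the inclusion design by construction", {
  dat <- generate_claims_data(small_cfg())
  cb <- build_cohorts(claims_from_frame(dat$claims), dat$diagnoses,
                      dat$procedures)
  asg <- cb$assignments
  expect_equal(sum(asg$cohort == "fixed" & !asg$withdrawn), 60L)
  expect_equal(sum(asg$cohort == "unfixed" & !asg$withdrawn), 60L)
  expect_true(all(asg$pre_index_monotherapy_days >= 365L))
  expect_true(all(startsWith(asg$index_regimen[asg$cohort == "fixed"], "fixed:")))
  expect_true(all(startsWith(asg$index_regimen[asg$cohort == "unfixed"],
                             "unfixed:")))
  # planted index dates are recovered exactly
  tr <- dat$truth[match(asg$patient_id, dat$truth$patient_id), ]
  expect_equal(asg$index_date, tr$index_date)
})

test_that("pipeline PDC and episodes equal the planted truth", {
  dat <- generate_claims_data(small_cfg())
  claims <- claims_from_frame(dat$claims)
  cb <- build_cohorts(claims, dat$diagnoses, dat$procedures)
  asg <- cb$assignments[!cb$assignments$withdrawn, ]
  norm <- normalize_dispensing(claims)
  cov <- build_coverage(norm)
  tr <- dat$truth[match(asg$patient_id, dat$truth$patient_id), ]
  adh <- compute_pdc(cov, asg)
  expect_equal(adh$pdc_percent, tr$true_pdc, tolerance = 1e-12)
  expect_equal(adh$covered_days, tr$true_covered_days)
  expect_identical(adh$adherent, tr$true_adherent)
  epi <- build_episode(cov, asg, dispensings = norm)
  expect_equal(epi$duration_days, tr$true_duration_days)
  expect_identical(epi$event, tr$true_event)
  # truth's own grace-rule bookkeeping is internally consistent
  expect_identical(tr$true_event, tr$true_duration_days < 365L)
})

test_that("planted truth applies the grace rule to the planted schedule", {
  # zero-delay refills: a patient with k supplies ends at day 30k
  cfg <- synthetic_config(seed = 4, n_fixed = 40L, n_unfixed = 0L,
                          refill_gap_model = list(p_zero = 1, geom_prob = 0.3,
                                                  max_delay = 0L))
  tr <- generate_claims_data(cfg)$truth
  expect_true(all(tr$true_covered_days %% 30L == 0L |
                    tr$true_covered_days == 365L))
  expect_identical(tr$true_event, tr$true_duration_days < 365L)
  # covered days match a day-bitmap replay of the planted claims
  dat <- generate_claims_data(small_cfg())
  claims <- claims_from_frame(dat$claims)
  norm <- normalize_dispensing(claims)
  tr <- dat$truth
  fixed_ids <- tr$patient_id[tr$cohort == "fixed"][1:10]
  for (pid in fixed_ids) {
    p <- norm[norm$patient_id == pid & norm$is_fixed_combination, ]
    idx <- as.integer(tr$index_date[tr$patient_id == pid])
    want <- bitmap_stream_days(as.integer(p$dispense_date), p$days_supplied,
                               idx, idx + 365L)
    expect_equal(tr$true_covered_days[tr$patient_id == pid], want)
  }
})

test_that("a saturated profile with no gaps and no dropout gives PDC 100", {
  cfg <- synthetic_config(
    seed = 2, n_fixed = 30L, n_unfixed = 30L,
    adherence_profile = list(
      fixed = c("80+" = 1, "60-79" = 0, "40-59" = 0, "20-39" = 0, "<20" = 0),
      unfixed = c("80+" = 1, "60-79" = 0, "40-59" = 0, "20-39" = 0, "<20" = 0)),
    refill_gap_model = list(p_zero = 1, geom_prob = 0.3, max_delay = 0L),
    dropout_hazard = 0)
  dat <- generate_claims_data(cfg)
  claims <- claims_from_frame(dat$claims)
  cb <- build_cohorts(claims, dat$diagnoses, dat$procedures)
  asg <- cb$assignments[!cb$assignments$withdrawn, ]
  adh <- compute_pdc(build_coverage(normalize_dispensing(claims)), asg)
  expect_true(all(adh$pdc_percent == 100))
})

test_that("the empirical regimen mix converges to the configured mix", {
  cfg <- synthetic_config(seed = 6)
  dat <- generate_claims_data(cfg)
  claims <- claims_from_frame(dat$claims)
  cb <- build_cohorts(claims, dat$diagnoses, dat$procedures)
  asg <- cb$assignments
  fx <- asg[asg$cohort == "fixed", ]
  mix <- cfg$regimen_mix$fixed
  z <- qnorm(0.995)
  for (prod in names(mix)) {
    phat <- mean(fx$index_products == prod)
    half <- z * sqrt(mix[[prod]] * (1 - mix[[prod]]) / nrow(fx))
    expect_lte(abs(phat - mix[[prod]]), half + 1e-12)
  }
  ux <- asg[asg$cohort == "unfixed", ]
  umix <- cfg$regimen_mix$unfixed
  for (pair in names(umix)) {  # config pair names are already canonical
    phat <- mean(ux$index_regimen == paste0("unfixed:", pair))
    half <- z * sqrt(umix[[pair]] * (1 - umix[[pair]]) / nrow(ux))
    expect_lte(abs(phat - umix[[pair]]), half + 1e-12)
  }
})

test_that("contamination plants the advertised decoys and nothing else", {
  cfg <- synthetic_config(seed = 8, n_fixed = 100L, n_unfixed = 100L,
                          contamination = 0.15)
  dat <- generate_claims_data(cfg)
  planted <- table(dat$truth$decoy_type)
  cb <- build_cohorts(claims_from_frame(dat$claims), dat$diagnoses,
                      dat$procedures)
  led <- setNames(cb$ledger$n, cb$ledger$step)
  expect_equal(led[["pre_index_monotherapy_lt_12m"]],
               unname(planted["short_run_in"]))
  expect_equal(led[["prior_glaucoma_surgery_or_laser"]],
               unname(planted["prior_surgery"]))
  expect_equal(led[["withdrawn_no_post_index"]],
               unname(planted["no_post_index"]))
  expect_equal(sum(!cb$assignments$withdrawn), 200L)
})

test_that("covariates carry plausible structure and missingness", {
  dat <- generate_claims_data(small_cfg())
  cv <- dat$covariates
  expect_true(all(is.na(cv$hba1c_percent) |
                    (cv$hba1c_percent >= 3 & cv$hba1c_percent <= 20)))
  expect_gt(mean(is.na(cv$hba1c_percent)), 0.1)
  expect_lt(mean(is.na(cv$hba1c_percent)), 0.6)
  expect_true(all(cv$sex %in% c("male", "female")))
  expect_true(all(cv$region_category %in%
    c("Hokkaido", "Tohoku", "Kanto", "Chubu", "Kinki", "Chugoku",
      "Shikoku", "Kyushu")))
})
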