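# End-to-end orchestration: simulate (or load) -> cohorts -> exposure ->
# adherence -> persistence -> switching -> risk factors, with
# publication-shaped delimited outputs, an exclusion ledger and a run log
# recording the seed and every policy flag.

#' Assemble a pipeline run configuration
#'
#' @param synthetic A [synthetic_config()] to simulate inputs, or `NULL`
#'   when `paths` are given.
#' @param paths Named list of input file paths (`claims`, `diagnoses`,
#'   `procedures`, `covariates`) when running on real tables.
#' @param window Study window (length-2 Date).
#' @param both_eyes_policy,unfixed_day_rule,pdc_count_grace,gap_anchor,
#'   t_test_variant,p_enter,p_stay Policy flags; defaults are the package's
#'   documented choices.
#' @param alpha,m_tests Family-wise error level and family size for the
#'   Bonferroni threshold.
#' @param make_plots Emit a Kaplan-Meier curve PNG.
#' @return list of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(), paths = NULL,
                       window = as.Date(c("2011-04-01", "2016-03-31")),
                       both_eyes_policy = "halve",
                       unfixed_day_rule = "both",
                       pdc_count_grace = FALSE,
                       gap_anchor = "supply_end",
                       t_test_variant = "welch",
                       p_enter = 0.05, p_stay = 0.05,
                       alpha = 0.05, m_tests = 9,
                       make_plots = TRUE) {
  structure(list(synthetic = synthetic, paths = paths, window = window,
                 both_eyes_policy = both_eyes_policy,
                 unfixed_day_rule = unfixed_day_rule,
                 pdc_count_grace = pdc_count_grace,
                 gap_anchor = gap_anchor, t_test_variant = t_test_variant,
                 p_enter = p_enter, p_stay = p_stay, alpha = alpha,
                 m_tests = m_tests, make_plots = make_plots),
            class = "run_config")
}

#' Run the full adherence/persistence pipeline
#'
#' @param config A [run_config()].
#' @param outdir Output directory for the report bundle; `NULL` skips
#'   writing and returns results only.
#' @return Invisibly, a list with the assignments, exclusion ledger,
#'   adherence results and summaries, persistence episodes / KM fits /
#'   log-rank tests, switching table and risk-factor tables.
#' @export
run_all <- function(config = run_config(), outdir = NULL) {
  dict <- drug_dictionary()
  if (!is.null(config$paths)) {
    claims <- load_claims(config$paths$claims, dict)
    diagnoses <- load_diagnoses(config$paths$diagnoses)
    procedures <- if (!is.null(config$paths$procedures))
      load_procedures(config$paths$procedures)
    covariates <- if (!is.null(config$paths$covariates))
      load_covariates(config$paths$covariates)
    truth <- NULL
  } else {
    sim <- generate_claims_data(config$synthetic)
    claims <- claims_from_frame(sim$claims, dict)
    diagnoses <- sim$diagnoses
    procedures <- sim$procedures
    covariates <- sim$covariates
    truth <- sim$truth
  }

  cb <- build_cohorts(claims, diagnoses, procedures, window = config$window,
                      both_eyes_policy = config$both_eyes_policy)
  asg <- cb$assignments[!cb$assignments$withdrawn, , drop = FALSE]
  if (nrow(asg) == 0L) stop("cohort extraction left no analyzable patients")

  norm <- normalize_dispensing(claims, both_eyes_policy = config$both_eyes_policy)
  cov <- build_coverage(norm)

  adh <- compute_pdc(cov, asg, unfixed_day_rule = config$unfixed_day_rule,
                     count_grace_days = config$pdc_count_grace)
  adh_summary <- summarize_adherence(adh)
  thr <- bonferroni_threshold(config$alpha, config$m_tests)
  fx <- adh[adh$cohort == "fixed", ]; ux <- adh[adh$cohort == "unfixed", ]
  tests <- list()
  if (nrow(fx) && nrow(ux)) {
    tests$pdc_mean <- compare_groups(fx$pdc_percent, ux$pdc_percent, "mean",
                                     var_equal = config$t_test_variant == "pooled",
                                     alpha = config$alpha, m = config$m_tests)
    tests$adherent_prop <- compare_groups(fx$adherent, ux$adherent,
                                          "proportion", alpha = config$alpha,
                                          m = config$m_tests)
  }

  # latanoprost/timolol subset (fixed product vs the unfixed pair)
  lt_ids <- asg$index_products == "latanoprost/timolol" |
    asg$index_products == "latanoprost;timolol"
  adh_lt <- adh[adh$patient_id %in% asg$patient_id[lt_ids], , drop = FALSE]
  adh_lt_summary <- if (nrow(adh_lt) && length(unique(adh_lt$cohort)) > 0)
    summarize_adherence(adh_lt) else NULL

  # within-fixed class comparison (PG/BB vs CAI/BB)
  adh_fx <- adh[adh$cohort == "fixed", , drop = FALSE]
  adh_class_summary <- if (nrow(adh_fx))
    summarize_adherence(adh_fx, group = adh_fx$index_regimen,
                        include_all = FALSE) else NULL

  epi <- build_episode(cov, asg, dispensings = norm, mode = "class",
                       gap_anchor = config$gap_anchor)
  km <- lapply(split(epi, epi$cohort),
               function(e) km_fit(e$duration_days, e$event))
  lr <- if (length(unique(epi$cohort)) == 2L)
    logrank_test(epi$duration_days, epi$event, epi$cohort) else NULL

  patterns <- classify_trajectory(norm, asg)
  pat_table <- pattern_table(patterns)

  risk <- NULL
  if (!is.null(covariates)) {
    rd <- merge(merge(asg[, c("patient_id", "cohort")], covariates,
                      by = "patient_id"),
                adh[, c("patient_id", "adherent")], by = "patient_id")
    rd$nonadherent <- !rd$adherent
    rd$treatment_fixed <- rd$cohort == "fixed"
    covs <- setdiff(names(rd), c("patient_id", "cohort", "adherent",
                                 "nonadherent"))
    uni <- univariate_screen(rd, "nonadherent", covs)
    cand <- uni$variable[uni$candidate]
    multi <- if (length(cand))
      stepwise_multivariate(rd, "nonadherent", cand,
                            p_enter = config$p_enter, p_stay = config$p_stay)
    risk <- list(univariate = uni, multivariate = multi)
  }

  out <- list(assignments = cb$assignments, ledger = cb$ledger,
              adherence = adh, adherence_summary = adh_summary,
              adherence_lat_tim = adh_lt_summary,
              adherence_fixed_classes = adh_class_summary,
              tests = tests, episodes = epi, km = km, logrank = lr,
              switching = pat_table, risk = risk, truth = truth,
              config = config)
  if (!is.null(outdir)) write_report_bundle(out, outdir)
  invisible(out)
}

write_report_bundle <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(d, f) if (!is.null(d))
    utils::write.csv(d, file.path(outdir, f), row.names = FALSE)
  wcsv(out$assignments, "assignments.csv")
  wcsv(out$ledger, "cohort_ledger.csv")
  wcsv(out$adherence, "adherence_patient.csv")
  wcsv(out$adherence_summary, "adherence_summary.csv")
  wcsv(out$adherence_lat_tim, "adherence_lat_tim.csv")
  wcsv(out$adherence_fixed_classes, "adherence_fixed_classes.csv")
  wcsv(out$episodes, "persistence_episodes.csv")
  for (co in names(out$km)) {
    k <- out$km[[co]]
    wcsv(data.frame(time = k$time, n_risk = k$n_risk, n_event = k$n_event,
                    surv = k$surv, ci_low = k$ci_low, ci_high = k$ci_high),
         paste0("persistence_km_", co, ".csv"))
    wcsv(k$rates, paste0("persistence_rates_", co, ".csv"))
  }
  wcsv(out$switching, "switching_patterns.csv")
  if (!is.null(out$risk)) {
    wcsv(out$risk$univariate, "risk_factors_univariate.csv")
    if (!is.null(out$risk$multivariate))
      wcsv(out$risk$multivariate$coefficients, "risk_factors_multivariate.csv")
  }
  log <- c(
    paste0("seed: ", if (!is.null(out$config$synthetic))
      out$config$synthetic$seed else "NA (file inputs)"),
    paste0("window: ", paste(out$config$window, collapse = " .. ")),
    paste0("both_eyes_policy: ", out$config$both_eyes_policy),
    paste0("unfixed_day_rule: ", out$config$unfixed_day_rule),
    paste0("pdc_count_grace: ", out$config$pdc_count_grace),
    paste0("gap_anchor: ", out$config$gap_anchor),
    paste0("t_test_variant: ", out$config$t_test_variant),
    paste0("stepwise_p_enter: ", out$config$p_enter),
    paste0("stepwise_p_stay: ", out$config$p_stay),
    paste0("alpha: ", out$config$alpha),
    paste0("m_tests: ", out$config$m_tests),
    if (!is.null(out$logrank))
      sprintf("logrank_fixed_vs_unfixed: chisq=%.4f p=%.6g",
              out$logrank$statistic, out$logrank$p_value))
  writeLines(log, file.path(outdir, "run_log.txt"))
  if (isTRUE(out$config$make_plots) && length(out$km)) {
    grDevices::png(file.path(outdir, "km_curves.png"), width = 800,
                   height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    cols <- c(fixed = "#1b6ca8", unfixed = "#c0392b")
    plot(NULL, xlim = c(0, 365), ylim = c(0, 1),
         xlab = "Days since index", ylab = "Persistence probability",
         main = "Treatment persistence")
    for (co in names(out$km)) {
      k <- out$km[[co]]
      graphics::lines(stats::stepfun(k$time, c(1, k$surv)),
                      do.points = FALSE, col = cols[[co]], lwd = 2)
    }
    graphics::legend("bottomleft", legend = names(out$km),
                     col = cols[names(out$km)], lwd = 2, bty = "n")
  }
  invisible(outdir)
}
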