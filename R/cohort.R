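# New-user cohort extraction. A patient enters the fixed-combination cohort
# on the first claim of a co-formulated two-class product, or the unfixed
# cohort on the first day a second distinct-class monotherapy product is
# claimed while the first drug's supply is still active. Either way the
# patient must carry a glaucoma diagnosis (ICD-10 H401/H409), have at least
# 12 months of single-class monotherapy immediately before the index date,
# and have no glaucoma surgery or laser procedure before index.

GLAUCOMA_CODES <- c("H401", "H409")

#' Extract fixed- and unfixed-combination second-line cohorts
#'
#' Reproduces the patient-extraction flowchart on loaded claims, diagnosis
#' and procedure tables. Each candidate patient is either assigned (with
#' cohort, index date, index regimen and products, and run-in length) or
#' counted in the exclusion ledger under the first rule that removed them.
#' Patients with no claim after the index date are assigned but flagged
#' `withdrawn` (and counted in the ledger); analysis steps should filter on
#' `!withdrawn`.
#'
#' Interpretations applied (all deterministic): the monotherapy run-in
#' tolerates within-class product switches and supply gaps up to the grace
#' period; a diagnosis qualifies regardless of its date; if a fixed claim
#' and a qualifying second-mono claim fall on the same day, fixed takes
#' precedence.
#'
#' @param claims Annotated claims from [claims_from_frame()].
#' @param diagnoses Diagnosis table (see [load_diagnoses()]).
#' @param procedures Procedure table or `NULL`.
#' @param window Study window (length-2 Date); claims outside it are dropped.
#' @param grace Grace period in days (default 30) used to bridge run-in
#'   supply gaps.
#' @param min_run_in Minimum pre-index monotherapy days (default 365).
#' @param both_eyes_policy Passed to [normalize_dispensing()].
#' @return list with `assignments` (one row per assigned patient) and
#'   `ledger` (exclusion counts; assigned + excluded = candidates).
#' @export
build_cohorts <- function(claims, diagnoses, procedures = NULL,
                          window = as.Date(c("2011-04-01", "2016-03-31")),
                          grace = 30L, min_run_in = 365L,
                          both_eyes_policy = "halve") {
  if (is.null(claims) || nrow(claims) == 0L) stop("empty claims table")
  window <- as.Date(window)
  keep <- claims$dispense_date >= window[1] & claims$dispense_date <= window[2]
  if (!all(keep)) {
    warning(sum(!keep), " claim(s) outside the study window dropped")
    claims <- claims[keep, , drop = FALSE]
  }
  norm <- normalize_dispensing(claims, both_eyes_policy = both_eyes_policy)
  cov <- build_coverage(norm)
  pats <- unique(claims$patient_id)
  dx_ids <- unique(diagnoses$patient_id[
    normalize_icd10(diagnoses$icd10_code) %in% GLAUCOMA_CODES])
  if (!is.null(procedures)) {
    surg <- procedures[procedures$is_glaucoma_surgery_or_laser %in% TRUE, ,
                       drop = FALSE]
    surg_by <- split(as.integer(as.Date(surg$date)), surg$patient_id)
  } else {
    surg_by <- list()
  }
  norm_by <- split(norm, norm$patient_id)
  cov_by <- split(cov, cov$patient_id)
  # any database activity (pharmacy, diagnosis, procedure) after the index
  # date counts against the "no claims for 12 months post-index" withdrawal
  act <- data.frame(
    patient_id = c(claims$patient_id, diagnoses$patient_id,
                   if (!is.null(procedures)) procedures$patient_id),
    day = as.integer(c(as.Date(claims$dispense_date),
                       as.Date(diagnoses$date),
                       if (!is.null(procedures)) as.Date(procedures$date))))
  act_by <- split(act$day, act$patient_id)

  rules <- c("no_glaucoma_diagnosis", "no_second_line_index",
             "ambiguous_index_regimen", "pre_index_monotherapy_lt_12m",
             "prior_glaucoma_surgery_or_laser")
  excl <- stats::setNames(integer(length(rules)), rules)
  rows <- vector("list", length(pats))
  n_assigned <- 0L
  for (pid in pats) {
    res <- assess_patient(norm_by[[pid]], cov_by[[pid]],
                          has_dx = pid %in% dx_ids,
                          surg_days = surg_by[[pid]],
                          act_days = act_by[[pid]],
                          grace = grace, min_run_in = min_run_in)
    if (res$rule != "assigned") {
      excl[res$rule] <- excl[res$rule] + 1L
    } else {
      n_assigned <- n_assigned + 1L
      rows[[n_assigned]] <- data.frame(
        patient_id = pid, cohort = res$cohort,
        index_date = as.Date(res$index, origin = "1970-01-01"),
        index_regimen = res$regimen, index_products = res$index_products,
        pre_index_monotherapy_days = res$pre_days,
        withdrawn = res$withdrawn)
    }
  }
  assignments <- if (n_assigned) do.call(rbind, rows[seq_len(n_assigned)]) else
    data.frame(patient_id = character(), cohort = character(),
               index_date = as.Date(character()), index_regimen = character(),
               index_products = character(),
               pre_index_monotherapy_days = integer(), withdrawn = logical())
  rownames(assignments) <- NULL
  ledger <- data.frame(
    step = c("candidates", names(excl), "assigned_fixed", "assigned_unfixed",
             "withdrawn_no_post_index"),
    n = c(length(pats), unname(excl),
          sum(assignments$cohort == "fixed"),
          sum(assignments$cohort == "unfixed"),
          sum(assignments$withdrawn)))
  list(assignments = assignments, ledger = ledger)
}

# Decide one patient's fate. `np` is the patient's normalized dispensings,
# `cp` the matching coverage rows (per product, carry-forward applied).
assess_patient <- function(np, cp, has_dx, surg_days, act_days, grace,
                           min_run_in) {
  if (!has_dx) return(list(rule = "no_glaucoma_diagnosis"))
  day <- as.integer(np$dispense_date)
  fix <- np$is_fixed_combination
  fixed_idx <- if (any(fix)) min(day[fix]) else NA_integer_

  mono_np <- np[!fix, , drop = FALSE]
  mono_cp <- cp[!cp$is_fixed_combination, , drop = FALSE]
  md <- as.integer(mono_np$dispense_date)
  mc <- mono_np$class1
  unfixed_idx <- NA_integer_
  cls <- unique(mc)
  if (length(cls) >= 2L) {
    cls_iv <- lapply(cls, function(cl)
      iv_merge(mono_cp[mono_cp$class1 == cl, c("start", "end"), drop = FALSE]))
    names(cls_iv) <- cls
    cand <- rep(FALSE, length(md))
    for (cl in cls) {
      ivs <- cls_iv[[cl]]
      if (nrow(ivs) == 0L) next
      other <- which(mc != cl)
      if (!length(other)) next
      j <- findInterval(md[other], ivs$start)
      hit <- j >= 1L & md[other] < ivs$end[pmax(j, 1L)]
      cand[other[hit]] <- TRUE
    }
    if (any(cand)) unfixed_idx <- min(md[cand])
  }

  if (is.na(fixed_idx) && is.na(unfixed_idx))
    return(list(rule = "no_second_line_index"))
  if (!is.na(fixed_idx) && (is.na(unfixed_idx) || fixed_idx <= unfixed_idx)) {
    cohort <- "fixed"; index <- fixed_idx
    prods <- sort(unique(np$generic_name[fix & day == index]))
    index_products <- prods[1L]
    regimen <- classify_regimen(index_products)
  } else {
    cohort <- "unfixed"; index <- unfixed_idx
    claimed_here <- unique(mono_np$generic_name[md == index])
    active <- character()
    for (pk in unique(mono_cp$drug_key)) {
      ivp <- iv_merge(mono_cp[mono_cp$drug_key == pk, c("start", "end"),
                              drop = FALSE])
      if (iv_contains(ivp, index)) active <- c(active, pk)
    }
    index_products <- sort(unique(c(claimed_here, active)))
    regimen <- classify_regimen(index_products)
    if (!startsWith(regimen, "unfixed:"))
      return(list(rule = "ambiguous_index_regimen"))
  }

  # Monotherapy run-in: single-class supply chain ending at (or bridging
  # into) the index date, gaps bridged up to the grace period.
  pre <- mono_np[md < index, , drop = FALSE]
  if (nrow(pre) == 0L) return(list(rule = "pre_index_monotherapy_lt_12m"))
  pday <- as.integer(pre$dispense_date)
  cstar <- pre$class1[which.max(pday)]
  other_days <- pday[pre$class1 != cstar]
  s <- if (length(other_days)) max(other_days) else -.Machine$integer.max
  runrows <- pre[pre$class1 == cstar & pday > s, , drop = FALSE]
  ivr <- iv_merge(build_coverage(runrows)[, c("start", "end"), drop = FALSE])
  nI <- nrow(ivr)
  first <- nI
  while (first > 1L && ivr$start[first] - ivr$end[first - 1L] <= grace)
    first <- first - 1L
  if (index - ivr$end[nI] > grace || index - ivr$start[first] < min_run_in)
    return(list(rule = "pre_index_monotherapy_lt_12m"))

  if (length(surg_days) && any(surg_days < index))
    return(list(rule = "prior_glaucoma_surgery_or_laser"))

  list(rule = "assigned", cohort = cohort, index = index, regimen = regimen,
       index_products = paste(index_products, collapse = ";"),
       pre_days = as.integer(index - ivr$start[first]),
       withdrawn = !any(act_days > index))
}
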