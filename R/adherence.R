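# Proportion of days covered (PDC) over the 12-month post-index window.
# Only two-drug combination supply counts as covered: for the fixed cohort a
# covered day lies inside any fixed-combination product's interval (class
# switches between fixed products allowed); for the unfixed cohort a covered
# day is, by default, a day on which two distinct-class monotherapy supplies
# overlap. Days after a third concurrent class appears do not count (the
# two-drug therapy is considered withdrawn from that day). The 30-day grace
# period used for persistence adds no covered days here: PDC counts supply,
# not allowance.

ADHERENCE_BINS <- c("<20", "20-39", "40-59", "60-79", "80+")

#' Bin a PDC value into the standard five adherence categories
#'
#' Boundaries are left-closed: `80+` means PDC >= 80, `60-79` means
#' `[60, 80)`, and so on down to `<20` meaning `[0, 20)`.
#'
#' @param pdc_percent Numeric vector in `[0, 100]`.
#' @return factor with levels `<20`, `20-39`, `40-59`, `60-79`, `80+`.
#' @export
bin_adherence <- function(pdc_percent) {
  if (any(!is.finite(pdc_percent) | pdc_percent < 0 | pdc_percent > 100))
    stop("pdc_percent must lie in [0, 100]")
  i <- findInterval(pdc_percent, c(0, 20, 40, 60, 80))
  factor(ADHERENCE_BINS[i], levels = ADHERENCE_BINS)
}

#' Compute per-patient PDC over the post-index assessment window
#'
#' @param coverage Coverage table from [build_coverage()] (all products, full
#'   history; the window restriction happens here).
#' @param assignments Cohort assignments from [build_cohorts()].
#' @param window_days Assessment window length (default 365 days from index).
#' @param unfixed_day_rule `"both"` (default; an unfixed covered day needs
#'   two distinct-class monotherapy supplies concurrently) or `"either"`
#'   (any monotherapy supply counts).
#' @param truncate_third_drug If `TRUE` (default), days from the first day on
#'   which three distinct classes are concurrently supplied do not count.
#' @param count_grace_days If `TRUE`, up to `grace` days following each
#'   supply run also count as covered (an alternative reading under which
#'   the grace period inflates the numerator; default `FALSE`: PDC counts
#'   supply only, grace affects persistence only).
#' @param grace Grace period in days used when `count_grace_days = TRUE`.
#' @param adherence_cutpoint PDC threshold for the adherent flag (default 80).
#' @return data.frame: `patient_id`, `cohort`, `index_regimen`,
#'   `covered_days`, `pdc_percent` (capped at 100), `adherent`, `bin`.
#' @export
compute_pdc <- function(coverage, assignments, window_days = 365L,
                        unfixed_day_rule = c("both", "either"),
                        truncate_third_drug = TRUE,
                        count_grace_days = FALSE, grace = 30L,
                        adherence_cutpoint = 80) {
  unfixed_day_rule <- match.arg(unfixed_day_rule)
  if (is.null(assignments) || nrow(assignments) == 0L)
    stop("assignments are required to compute PDC")
  cov_by <- split(coverage, coverage$patient_id)
  n <- nrow(assignments)
  covered <- integer(n)
  for (i in seq_len(n)) {
    pc <- cov_by[[assignments$patient_id[i]]]
    if (is.null(pc)) next
    off <- as.integer(assignments$index_date[i])
    hi <- off + as.integer(window_days)
    if (truncate_third_drug) {
      t3 <- iv_clip(iv_atleast(class_interval_sets(pc), 3L), off, hi)
      if (nrow(t3)) hi <- t3$start[1L]
    }
    if (assignments$cohort[i] == "fixed") {
      base <- pc[pc$is_fixed_combination, c("start", "end"), drop = FALSE]
    } else {
      mono <- pc[!pc$is_fixed_combination, , drop = FALSE]
      if (unfixed_day_rule == "both") {
        base <- iv_atleast(class_interval_sets(mono), 2L)
      } else {
        base <- mono[, c("start", "end"), drop = FALSE]
      }
    }
    base <- iv_merge(base)
    if (count_grace_days && nrow(base)) {
      nxt <- c(base$start[-1L], .Machine$integer.max %/% 2L)
      base$end <- pmin(base$end + as.integer(grace), nxt)
    }
    covered[i] <- iv_total(iv_clip(base, off, hi))
  }
  pdc <- pmin(100, covered / as.numeric(window_days) * 100)
  data.frame(patient_id = assignments$patient_id,
             cohort = assignments$cohort,
             index_regimen = assignments$index_regimen,
             covered_days = covered,
             pdc_percent = pdc,
             adherent = pdc >= adherence_cutpoint,
             bin = bin_adherence(pdc))
}

#' Summarize adherence by group
#'
#' For each group (by default the cohort) and for all patients pooled:
#' n, mean and SD of PDC, counts and percentages per adherence bin, and the
#' percentage adherent (PDC >= 80).
#'
#' @param results Per-patient results from [compute_pdc()].
#' @param group Grouping vector (default `results$cohort`).
#' @param include_all Prepend a pooled "all" row (default `TRUE`).
#' @return data.frame, one row per group.
#' @export
summarize_adherence <- function(results, group = results$cohort,
                                include_all = TRUE) {
  if (nrow(results) == 0L) stop("no adherence results to summarize")
  group <- as.character(group)
  groups <- unique(group)
  empty <- !groups %in% group
  if (any(empty)) warning("empty group(s) omitted: ",
                          paste(groups[empty], collapse = ", "))
  one <- function(label, r) {
    bins <- table(factor(r$bin, levels = ADHERENCE_BINS))
    out <- data.frame(group = label, n = nrow(r),
                      mean_pdc = mean(r$pdc_percent),
                      sd_pdc = stats::sd(r$pdc_percent),
                      n_adherent = sum(r$adherent),
                      pct_adherent = 100 * mean(r$adherent))
    for (b in ADHERENCE_BINS) {
      out[[paste0("n_", b)]] <- unname(bins[b])
      out[[paste0("pct_", b)]] <- 100 * unname(bins[b]) / nrow(r)
    }
    out
  }
  pieces <- lapply(groups, function(g) one(g, results[group == g, , drop = FALSE]))
  if (include_all) pieces <- c(list(one("all", results)), pieces)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
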