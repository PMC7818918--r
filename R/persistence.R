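# Persistence: time on the index therapy from the index date to supply end,
# allowing a 30-day grace period between supply exhaustion and the next
# qualifying refill. The episode ends ("discontinued") at the last covered
# day when the next refill arrives more than `grace` days after supply ends,
# or never arrives; it ends at the dispense date of a claim that adds a
# third concurrent drug class; in product-subset mode it also ends at the
# first claim of a product outside the index products. Patients whose
# qualifying supply reaches the 365-day horizon are censored at 365.

#' Build per-patient persistence episodes
#'
#' In `"class"` mode (the main analysis) the episode continues across
#' switches between two-drug regimens of different classes: the qualifying
#' supply is any fixed-combination product for the fixed cohort, and any
#' two concurrent distinct-class monotherapy supplies for the unfixed
#' cohort. In `"subset"` mode (used for product-specific analyses such as
#' latanoprost/timolol) only the index products qualify and any other
#' eye-drop claim ends the episode (`reason = "regimen_changed"`).
#'
#' Ties on the same day resolve to `third_drug_added`, then
#' `regimen_changed`, then `gap`.
#'
#' @param coverage Coverage table from [build_coverage()].
#' @param assignments Cohort assignments (filter `withdrawn` upstream).
#' @param dispensings Normalized dispensings; required for `mode = "subset"`
#'   and for `gap_anchor = "dispense"`.
#' @param mode `"class"` or `"subset"`.
#' @param grace Grace period in days (default 30). A gap of exactly `grace`
#'   days is not a discontinuation; only longer gaps are.
#' @param horizon Follow-up horizon in days (default 365).
#' @param gap_anchor Where the gap clock starts: `"supply_end"` (default) or
#'   `"dispense"` (last qualifying dispense date).
#' @return data.frame: `patient_id`, `cohort`, `duration_days`, `event`
#'   (logical; `FALSE` = censored at the horizon), `reason` (`gap`,
#'   `third_drug_added`, `regimen_changed` or `none`).
#' @export
build_episode <- function(coverage, assignments, dispensings = NULL,
                          mode = c("class", "subset"), grace = 30L,
                          horizon = 365L,
                          gap_anchor = c("supply_end", "dispense")) {
  mode <- match.arg(mode)
  gap_anchor <- match.arg(gap_anchor)
  if (mode == "subset" && is.null(dispensings))
    stop("subset mode needs the normalized dispensings")
  if (gap_anchor == "dispense" && is.null(dispensings))
    stop("gap_anchor = 'dispense' needs the normalized dispensings")
  cov_by <- split(coverage, coverage$patient_id)
  disp_by <- if (!is.null(dispensings)) split(dispensings, dispensings$patient_id)
  n <- nrow(assignments)
  dur <- integer(n); ev <- logical(n); reason <- character(n)
  for (i in seq_len(n)) {
    pid <- assignments$patient_id[i]
    pc <- cov_by[[pid]]
    off <- as.integer(assignments$index_date[i])
    prods <- strsplit(assignments$index_products[i], ";", fixed = TRUE)[[1L]]
    if (mode == "class") {
      if (assignments$cohort[i] == "fixed") {
        q <- pc[pc$is_fixed_combination, , drop = FALSE]
        Q <- iv_merge(q[, c("start", "end"), drop = FALSE])
      } else {
        mono <- pc[!pc$is_fixed_combination, , drop = FALSE]
        Q <- iv_atleast(class_interval_sets(mono), 2L)
        q <- mono
      }
    } else {
      q <- pc[pc$drug_key %in% prods, , drop = FALSE]
      Q <- if (assignments$cohort[i] == "fixed") {
        iv_merge(q[, c("start", "end"), drop = FALSE])
      } else {
        iv_atleast(lapply(split(q, q$drug_key),
                          function(x) x[, c("start", "end"), drop = FALSE]), 2L)
      }
    }
    Q <- iv_clip(Q, off, .Machine$integer.max %/% 2L)

    day_gap <- Inf
    if (nrow(Q)) {
      anchor_days <- NULL
      if (gap_anchor == "dispense") {
        pd <- disp_by[[pid]]
        pd <- pd[pd$generic_name %in% unique(q$drug_key), , drop = FALSE]
        anchor_days <- sort(as.integer(pd$dispense_date))
      }
      E <- Q$end[1L]
      if (nrow(Q) > 1L) for (j in 2L:nrow(Q)) {
        a <- E
        if (gap_anchor == "dispense") {
          cand <- anchor_days[anchor_days <= E]
          if (length(cand)) a <- max(cand)
        }
        if (Q$start[j] - a > grace) break
        E <- Q$end[j]
      }
      E_rel <- E - off
      if (E_rel < horizon) day_gap <- E_rel
    } else {
      day_gap <- 0
    }

    day_t3 <- Inf
    t3 <- iv_atleast(class_interval_sets(pc), 3L)
    t3 <- iv_clip(t3, off, off + as.integer(horizon))
    if (nrow(t3)) day_t3 <- t3$start[1L] - off

    day_chg <- Inf
    if (mode == "subset") {
      pd <- disp_by[[pid]]
      other <- as.integer(pd$dispense_date[!pd$generic_name %in% prods])
      other <- other[other > off & other - off < horizon]
      if (length(other)) day_chg <- min(other) - off
    }

    best <- min(day_t3, day_chg, day_gap)
    if (is.infinite(best)) {
      dur[i] <- as.integer(horizon); ev[i] <- FALSE; reason[i] <- "none"
    } else {
      dur[i] <- as.integer(best); ev[i] <- TRUE
      reason[i] <- if (best == day_t3) "third_drug_added"
        else if (best == day_chg) "regimen_changed" else "gap"
    }
  }
  data.frame(patient_id = assignments$patient_id,
             cohort = assignments$cohort,
             duration_days = dur, event = ev, reason = reason)
}

#' Kaplan-Meier persistence estimate for one group
#'
#' Product-limit estimator via [survival::survfit()] with complementary
#' log-log pointwise confidence intervals (stable near 0 and 1). The
#' persistence rate at a time point is `100 * S(t)`, i.e. 100% minus the
#' cumulative discontinuation rate.
#'
#' @param durations Episode durations in days.
#' @param events Logical event indicators (`FALSE` = censored).
#' @param rate_days Time points for reported persistence rates (default
#'   days 180 and 365).
#' @param conf_level Pointwise confidence level (default 0.95).
#' @return An object of class `km_estimate`: step-function times, numbers at
#'   risk, survival with CI, and a `rates` data.frame of persistence
#'   percentages at `rate_days`.
#' @export
km_fit <- function(durations, events, rate_days = c(180L, 365L),
                   conf_level = 0.95) {
  if (length(durations) == 0L) stop("no episodes to fit")
  f <- survival::survfit(survival::Surv(durations, events) ~ 1,
                         conf.type = "log-log", conf.int = conf_level)
  s <- summary(f, times = rate_days, extend = TRUE)
  rates <- data.frame(day = rate_days,
                      persistence_pct = 100 * s$surv,
                      ci_low_pct = 100 * s$lower,
                      ci_high_pct = 100 * s$upper)
  structure(list(time = f$time, n_risk = f$n.risk, n_event = f$n.event,
                 surv = f$surv, ci_low = f$lower, ci_high = f$upper,
                 rates = rates, n = length(durations), fit = f),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier persistence estimate (n = ", x$n, ")\n", sep = "")
  print(round(x$rates, 1), row.names = FALSE)
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param durations Episode durations (both groups).
#' @param events Logical event indicators.
#' @param group Group labels (exactly two distinct values).
#' @return list of class `logrank_test` with `statistic` (chi-square, 1 df)
#'   and `p_value`. Two groups with no events at all give statistic 0, p 1.
#' @export
logrank_test <- function(durations, events, group) {
  if (length(unique(group)) != 2L) stop("log-rank test needs exactly two groups")
  if (sum(events) == 0L) {
    out <- list(statistic = 0, p_value = 1)
  } else {
    sd <- survival::survdiff(survival::Surv(durations, events) ~ group)
    out <- list(statistic = unname(sd$chisq),
                p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
  }
  structure(out, class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.3f, p = %.4g\n",
              x$statistic, x$p_value))
  invisible(x)
}
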