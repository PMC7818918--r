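# Exposure normalization: claims report a dosage volume in mL and a coarse
# period field. Days supplied are derived from bottle arithmetic instead:
# dosage / unit bottle volume = bottles, one bottle = 30 days for one eye,
# and a prescription of 7+ bottles is read as treatment of both eyes
# (supply consumed twice as fast). The period field is deliberately ignored.

#' Convert raw claims into bottle counts and days supplied
#'
#' For each claim, `bottles = round(dosage_quantity / unit_bottle_volume)`,
#' floored at one bottle; e.g. a once-daily claim with dosage 7.5 is three
#' 2.5 mL bottles, 90 days of supply. A dosage that is not within 10% of a
#' whole number of bottles is rounded with a warning. Claims of 7 or more
#' bottles are flagged `both_eyes`; under the default `"halve"` policy their
#' days supplied are `ceiling(bottles * 30 / 2)`, under `"none"` the flag is
#' informational only.
#'
#' @param claims Annotated claims from [claims_from_frame()].
#' @param both_eyes_policy `"halve"` (default) or `"none"`.
#' @param days_per_bottle Days of single-eye supply per bottle (default 30).
#' @return data.frame of normalized dispensings: the claim columns plus
#'   `bottles`, `both_eyes`, `days_supplied`.
#' @export
normalize_dispensing <- function(claims, both_eyes_policy = c("halve", "none"),
                                 days_per_bottle = 30L) {
  both_eyes_policy <- match.arg(both_eyes_policy)
  unit <- claims$unit_bottle_volume
  bottles <- pmax(1L, as.integer(round(claims$dosage_quantity / unit)))
  off <- abs(claims$dosage_quantity - bottles * unit) > 0.1 * unit
  if (any(off)) {
    warning(sum(off), " claim(s) with dosage not a near-multiple of the unit ",
            "bottle volume; rounded to the nearest whole bottle")
  }
  both_eyes <- bottles >= 7L
  days <- bottles * as.integer(days_per_bottle)
  if (both_eyes_policy == "halve") {
    days[both_eyes] <- as.integer(ceiling(days[both_eyes] / 2))
  }
  out <- claims
  out$bottles <- bottles
  out$both_eyes <- both_eyes
  out$days_supplied <- days
  out
}

#' Build per-drug coverage intervals with stockpile carry-forward
#'
#' Each dispensing opens a supply interval of `days_supplied` days. When a
#' refill arrives before the previous supply is exhausted, the new supply is
#' carried forward: its interval starts when the previous supply ends, so
#' early refills are banked rather than double-counted. Within a patient and
#' drug key the resulting intervals are disjoint.
#'
#' @param dispensings Normalized dispensings from [normalize_dispensing()].
#' @param key Column defining the supply stream (default `"generic_name"`).
#' @return data.frame of coverage intervals: `patient_id`, `drug_key`,
#'   `class1`, `class2`, `is_fixed_combination`, `start`, `end`. `start`/`end`
#'   are integer days since 1970-01-01, half-open `[start, end)`.
#' @export
build_coverage <- function(dispensings, key = "generic_name") {
  if (nrow(dispensings) == 0L) {
    return(data.frame(patient_id = character(), drug_key = character(),
                      class1 = character(), class2 = character(),
                      is_fixed_combination = logical(),
                      start = integer(), end = integer()))
  }
  o <- order(dispensings$patient_id, dispensings[[key]],
             dispensings$dispense_date)
  d <- dispensings[o, , drop = FALSE]
  g <- paste(d$patient_id, d[[key]], sep = "\r")
  day <- as.integer(d$dispense_date)
  dur <- as.integer(d$days_supplied)
  # Closed form of the carry-forward recursion end_i = max(start_i,
  # end_{i-1}) + dur_i: with S the within-group cumulative supply,
  # end_i = S_i + cummax(start_i - S_{i-1}).
  S <- stats::ave(dur, g, FUN = cumsum)
  adj <- stats::ave(day - (S - dur), g, FUN = cummax)
  end <- S + adj
  data.frame(patient_id = d$patient_id, drug_key = d[[key]],
             class1 = d$class1, class2 = d$class2,
             is_fixed_combination = d$is_fixed_combination,
             start = end - dur, end = end)
}

# Per-class interval sets for one patient's coverage rows; a fixed
# combination contributes to both of its classes.
class_interval_sets <- function(cov_rows) {
  cls <- unique(c(cov_rows$class1, cov_rows$class2))
  cls <- cls[!is.na(cls)]
  sets <- lapply(cls, function(cl) {
    r <- cov_rows$class1 == cl | (!is.na(cov_rows$class2) & cov_rows$class2 == cl)
    iv_merge(cov_rows[r, c("start", "end"), drop = FALSE])
  })
  names(sets) <- cls
  sets
}

#' Total covered days of a set of coverage rows within a window
#'
#' @param coverage Coverage rows (any subset of [build_coverage()] output).
#' @param window Length-2 vector (Date or integer day) `[lo, hi)`.
#' @return Integer day count.
#' @export
covered_days <- function(coverage, window) {
  lo <- as.integer(window[1]); hi <- as.integer(window[2])
  iv_total(iv_clip(iv_merge(coverage[, c("start", "end"), drop = FALSE]), lo, hi))
}
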