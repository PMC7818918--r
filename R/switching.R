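# Post-index trajectory classification. Each patient's 12 months after the
# index date fall into exactly one category, decided by the first
# qualifying transition in time:
#   addon_third:<class>    a third distinct class becomes concurrently
#                          supplied (e.g. PG/BB -> PG/BB + AA)
#   switched_two_drug:<pair>  a different two-class regimen appears
#   discontinued_all       all eye-drop supply ceases (gap rule) without
#                          replacement
#   continued_same_class   otherwise
# Only products dispensed on or after the index date are considered, so a
# leftover pre-index monotherapy bottle cannot masquerade as an add-on.

#' Classify post-index switching trajectories
#'
#' @param dispensings Normalized dispensings from [normalize_dispensing()]
#'   (full table; the post-index restriction happens per patient).
#' @param assignments Cohort assignments from [build_cohorts()].
#' @param grace Grace period in days for the discontinuation rule.
#' @param horizon Days of follow-up (default 365).
#' @return data.frame: `patient_id`, `cohort`, `index_regimen`,
#'   `outcome_category`.
#' @export
classify_trajectory <- function(dispensings, assignments, grace = 30L,
                                horizon = 365L) {
  disp_by <- split(dispensings, dispensings$patient_id)
  n <- nrow(assignments)
  cat_out <- character(n)
  for (i in seq_len(n)) {
    pd <- disp_by[[assignments$patient_id[i]]]
    off <- as.integer(assignments$index_date[i])
    hi <- off + as.integer(horizon)
    pd <- pd[as.integer(pd$dispense_date) >= off, , drop = FALSE]
    pc <- build_coverage(pd)
    pair <- sort(regimen_classes(assignments$index_regimen[i]))

    sets <- lapply(class_interval_sets(pc), iv_clip, lo = off, hi = hi)
    sets <- Filter(nrow, sets)
    bounds <- sort(unique(c(unlist(lapply(sets, `[[`, "start"), use.names = FALSE),
                            unlist(lapply(sets, `[[`, "end"), use.names = FALSE))))
    bounds <- bounds[bounds < hi]
    day_t3 <- Inf; t3_class <- NA_character_
    day_sw <- Inf; sw_pair <- NULL
    for (b in bounds) {
      active <- names(sets)[vapply(sets, iv_contains, logical(1), day = b)]
      if (length(active) >= 3L && b < day_t3) {
        day_t3 <- b
        t3_class <- order_classes(setdiff(active, pair))[1L]
      }
      if (length(active) == 2L && !setequal(active, pair) && b < day_sw) {
        day_sw <- b
        sw_pair <- order_classes(active)
      }
    }
    day_disc <- Inf
    U <- iv_clip(iv_merge(pc[, c("start", "end"), drop = FALSE]), off, hi)
    if (nrow(U)) {
      lastE <- U$end[nrow(U)]
      if (hi - lastE > grace) day_disc <- lastE
    } else {
      day_disc <- off
    }
    best <- min(day_t3, day_sw, day_disc)
    cat_out[i] <- if (is.infinite(best)) "continued_same_class"
      else if (best == day_t3) paste0("addon_third:", t3_class)
      else if (best == day_sw) paste0("switched_two_drug:",
                                      paste(sw_pair, collapse = "+"))
      else "discontinued_all"
  }
  data.frame(patient_id = assignments$patient_id,
             cohort = assignments$cohort,
             index_regimen = assignments$index_regimen,
             outcome_category = cat_out)
}

#' Tabulate switching patterns by index regimen
#'
#' @param patterns Output of [classify_trajectory()].
#' @return data.frame of counts and within-regimen percentages per
#'   index regimen x outcome category; percentages sum to 100 per regimen.
#' @export
pattern_table <- function(patterns) {
  tab <- as.data.frame(table(index_regimen = patterns$index_regimen,
                             outcome_category = patterns$outcome_category),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "n"
  tot <- stats::ave(tab$n, tab$index_regimen, FUN = sum)
  tab$pct <- ifelse(tot > 0, 100 * tab$n / tot, NA_real_)
  tab <- tab[tab$n > 0L, , drop = FALSE]
  tab <- tab[order(tab$index_regimen, -tab$n), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
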