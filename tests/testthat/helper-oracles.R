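# Independent brute-force oracles and fixture builders. The oracles work
# day by day on logical vectors and never touch the package's interval
# arithmetic.

# Covered days in [lo, hi) for one dispensing stream under carry-forward:
# each claim's supply starts when the previous supply runs out, marking
# days one at a time.
bitmap_stream_days <- function(day, dur, lo, hi) {
  covered <- rep(FALSE, hi - lo)
  supply_end <- -Inf
  o <- order(day)
  for (i in o) {
    s <- max(day[i], supply_end)
    e <- s + dur[i]
    supply_end <- e
    ds <- seq(s, e - 1L)
    ds <- ds[ds >= lo & ds < hi]
    if (length(ds)) covered[ds - lo + 1L] <- TRUE
  }
  sum(covered)
}

# Days in [lo, hi) on which at least k of the streams are covered.
bitmap_joint_days <- function(streams, k, lo, hi) {
  cnt <- rep(0L, hi - lo)
  for (s in streams) {
    covered <- rep(FALSE, hi - lo)
    supply_end <- -Inf
    for (i in order(s$day)) {
      st <- max(s$day[i], supply_end)
      en <- st + s$dur[i]
      supply_end <- en
      ds <- seq(st, en - 1L)
      ds <- ds[ds >= lo & ds < hi]
      if (length(ds)) covered[ds - lo + 1L] <- TRUE
    }
    cnt <- cnt + covered
  }
  sum(cnt >= k)
}

# Hand product-limit estimator at the distinct event times.
hand_km <- function(time, event) {
  ts <- sort(unique(time[event]))
  s <- 1
  surv <- numeric(length(ts))
  for (j in seq_along(ts)) {
    at_risk <- sum(time >= ts[j])
    d <- sum(time == ts[j] & event)
    s <- s * (1 - d / at_risk)
    surv[j] <- s
  }
  data.frame(time = ts, surv = surv)
}

# Two-group log-rank chi-square by brute force over the risk sets.
hand_logrank <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1L]
  ts <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in ts) {
    n <- sum(time >= t); n1 <- sum(time >= t & g1)
    d <- sum(time == t & event); d1 <- sum(time == t & event & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Pearson chi-square on a 2x2 table, closed form, no correction.
hand_chisq_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

BASE_DATE <- as.Date("2013-01-15")

# Raw claims frame from day offsets relative to BASE_DATE.
mk_claims <- function(pid, offsets, generic, dosage = NULL) {
  dict <- drug_dictionary()
  generic <- rep_len(generic, length(offsets))
  if (is.null(dosage))
    dosage <- dict$unit_bottle_volume[match(generic, dict$generic_name)]
  data.frame(patient_id = pid, dispense_date = BASE_DATE + offsets,
             generic_name = generic, dosage_quantity = dosage,
             period_field = 1L)
}

mk_dx <- function(pid, offset = -100L, code = "H401") {
  data.frame(patient_id = pid, date = BASE_DATE + offset, icd10_code = code)
}

mk_px <- function(pid, offset, flag = TRUE) {
  data.frame(patient_id = pid, date = BASE_DATE + offset,
             is_glaucoma_surgery_or_laser = flag)
}

# A well-formed patient: `pre_days` of monotherapy dispensed every 30 days
# before BASE_DATE, then the index product at the given post offsets.
mk_patient <- function(pid, pre_days = 400L, pre_drug = "latanoprost",
                       post_drug = "latanoprost/timolol",
                       post_offsets = seq(0L, 330L, by = 30L)) {
  pre_off <- seq(-pre_days, by = 30L, length.out = ceiling(pre_days / 30))
  rbind(mk_claims(pid, pre_off, pre_drug),
        mk_claims(pid, post_offsets, post_drug))
}

# Assignment row for patients indexed at BASE_DATE, bypassing the cohort
# builder where a test only targets downstream arithmetic.
mk_assignment <- function(pid, cohort = "fixed",
                          regimen = if (cohort == "fixed") "fixed:PG/BB"
                                    else "unfixed:PG+BB",
                          products = if (cohort == "fixed")
                            "latanoprost/timolol" else "latanoprost;timolol") {
  data.frame(patient_id = pid, cohort = cohort, index_date = BASE_DATE,
             index_regimen = regimen, index_products = products,
             pre_index_monotherapy_days = 400L, withdrawn = FALSE)
}

# Coverage table straight from raw claims (normalize + carry-forward).
cov_of <- function(claims) build_coverage(normalize_dispensing(
  claims_from_frame(claims)))
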