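epi1 <- function(claims, cohort = "fixed", ...) {
  cl <- claims_from_frame(claims)
  norm <- normalize_dispensing(cl)
  build_episode(build_coverage(norm), mk_assignment("P1", cohort = cohort),
                dispensings = norm, ...)
}

test_that("uninterrupted refills through 12 months are censored at 365", {
  e <- epi1(mk_claims("P1", seq(0L, 360L, 30L), "latanoprost/timolol"))
  expect_false(e$event)
  expect_equal(e$duration_days, 365L)
  expect_identical(e$reason, "none")
})

test_that("a refill gap beyond the grace period discontinues at supply end", {
  # supply [0,120), refill at 160: gap 40 > 30
  e <- epi1(mk_claims("P1", c(seq(0L, 90L, 30L), 160L), "latanoprost/timolol"))
  expect_true(e$event)
  expect_equal(e$duration_days, 120L)
  expect_identical(e$reason, "gap")
  # gap of exactly 30 days is NOT a discontinuation; supply resumes at 150
  e <- epi1(mk_claims("P1", c(seq(0L, 90L, 30L), 150L), "latanoprost/timolol"))
  expect_equal(e$duration_days, 180L)  # next exhaustion, no refill after
  expect_identical(e$reason, "gap")
})

test_that("a third concurrent class ends the episode at its claim date", {
  cl <- rbind(mk_claims("P1", seq(0L, 360L, 30L), "latanoprost/timolol"),
              mk_claims("P1", 200L, "brimonidine", dosage = 15))
  e <- epi1(cl)
  expect_true(e$event)
  expect_equal(e$duration_days, 200L)
  expect_identical(e$reason, "third_drug_added")
})

test_that("class-level mode continues across two-drug regimen switches", {
  # PG+BB for 6 months, then PG+CAI seamlessly
  cl <- rbind(mk_claims("P1", seq(0L, 360L, 30L), "latanoprost"),
              mk_claims("P1", seq(0L, 150L, 30L), "timolol"),
              mk_claims("P1", seq(180L, 360L, 30L), "dorzolamide"))
  e <- epi1(cl, cohort = "unfixed")
  expect_false(e$event)
  expect_equal(e$duration_days, 365L)
})

test_that("subset mode ends the episode on any product change", {
  cl <- rbind(mk_claims("P1", seq(0L, 150L, 30L), "latanoprost/timolol"),
              mk_claims("P1", seq(180L, 360L, 30L), "tafluprost/timolol"))
  e_class <- epi1(cl, mode = "class")
  expect_false(e_class$event)
  e_sub <- epi1(cl, mode = "subset")
  expect_true(e_sub$event)
  expect_equal(e_sub$duration_days, 180L)
  expect_identical(e_sub$reason, "regimen_changed")
})

test_that("the dispense-date gap anchor is stricter than supply-end", {
  # 30-day supply at 0, refill at day 35: 5-day supply gap, 35-day
  # dispense-to-dispense gap
  cl <- mk_claims("P1", c(0L, 35L), "latanoprost/timolol")
  e_supply <- epi1(cl, gap_anchor = "supply_end")
  expect_equal(e_supply$duration_days, 65L)
  e_disp <- epi1(cl, gap_anchor = "dispense")
  expect_true(e_disp$event)
  expect_equal(e_disp$duration_days, 30L)
})

test_that("longer grace periods never shorten an episode", {
  set.seed(88)
  for (rep in 1:40) {
    offs <- sort(sample(0:360, sample(3:10, 1)))
    cl <- mk_claims("P1", offs, "latanoprost/timolol",
                    dosage = sample(1:2, length(offs), TRUE) * 2.5)
    durs <- vapply(c(10L, 30L, 60L), function(g)
      epi1(cl, grace = g)$duration_days, integer(1))
    expect_true(all(diff(durs) >= 0))
  }
})

test_that("product-limit estimates match hand computation", {
  km <- km_fit(c(100, 200, 365, 365), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(km$surv[km$time == 100], 0.75, tolerance = 1e-12)
  expect_equal(km$surv[km$time == 200], 0.50, tolerance = 1e-12)
  # S is a step function: S(180) still reflects the day-100 event only
  expect_equal(km$rates$persistence_pct, c(75, 50), tolerance = 1e-12)

  set.seed(55)
  t <- sample(30:365, 60, replace = TRUE)
  ev <- runif(60) < 0.6
  km <- km_fit(t, ev)
  hk <- hand_km(t, ev)
  expect_equal(km$surv[match(hk$time, km$time)], hk$surv, tolerance = 1e-12)

  # all censored: survival stays at 1, no error
  km <- km_fit(c(365, 365, 365), c(FALSE, FALSE, FALSE))
  expect_equal(km$rates$persistence_pct, c(100, 100))
  # single immediate event
  km <- km_fit(1, TRUE)
  expect_equal(km$rates$persistence_pct, c(0, 0))
})

test_that("log-rank agrees with the brute-force risk-set computation", {
  expect_error(logrank_test(1:3, c(TRUE, TRUE, FALSE), c("a", "a", "a")),
               "two groups")
  # identical groups: statistic 0, p 1
  t <- c(100, 200, 365, 100, 200, 365)
  ev <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  g <- rep(c("a", "b"), each = 3)
  lr <- logrank_test(t, ev, g)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  # no events at all: defined, not an error
  lr0 <- logrank_test(c(365, 365), c(FALSE, FALSE), c("a", "b"))
  expect_equal(lr0$statistic, 0)

  set.seed(66)
  t <- c(sample(30:365, 40, TRUE), sample(20:300, 40, TRUE))
  ev <- runif(80) < 0.7
  g <- rep(c("a", "b"), each = 40)
  lr <- logrank_test(t, ev, g)
  expect_equal(lr$statistic, hand_logrank(t, ev, g), tolerance = 1e-8)
})

test_that("a planted hazard difference is detected with high power", {
  set.seed(99)
  thr <- bonferroni_threshold(0.05, 9)
  hits <- 0L
  for (rep in 1:60) {
    t1 <- pmin(rexp(150, 1 / 300) * 3, 365)   # low hazard
    t2 <- pmin(rexp(150, 1 / 300), 365)       # 3x hazard
    ev1 <- t1 < 365; ev2 <- t2 < 365
    lr <- logrank_test(c(t1, t2), c(ev1, ev2), rep(c("a", "b"), each = 150))
    if (lr$p_value < thr) hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.9)
})
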