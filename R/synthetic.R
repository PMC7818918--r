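# Synthetic claims generator. Emulates the structure the analysis assumes:
# two second-line glaucoma cohorts, each patient with (i) a glaucoma
# diagnosis, (ii) a >= 12-month single-class monotherapy run-in dispensed
# every 30 days, (iii) an index regimen drawn from the configured mix
# (fixed-combination product, or a second-class product added to the
# running monotherapy), and (iv) a post-index refill stream. Refill timing
# is a zero-inflated geometric delay on top of on-time refills; how long a
# patient keeps refilling derives from the configured adherence profile
# (each PDC bin maps to a number of 30-day supplies), and the latent
# nonadherence flag is linked to HbA1c through a logistic mechanism with a
# configurable odds ratio. A ground-truth table of the planted latent
# values accompanies the tables for parameter-recovery testing.

#' Configuration for the synthetic claims generator
#'
#' Defaults reproduce the study conditions of the second-line glaucoma
#' cohorts: 309 fixed / 329 unfixed patients, the observed index-regimen
#' mix, the observed five-bin adherence profile per cohort, and an HbA1c
#' effect on nonadherence of OR 1.606 per 1%.
#'
#' @param seed Integer RNG seed; identical (config, seed) gives
#'   byte-identical output.
#' @param n_fixed,n_unfixed Cohort sizes.
#' @param study_window Length-2 Date vector bounding all generated claims.
#' @param regimen_mix Per-cohort probability tables over index regimens
#'   (fixed: product names; unfixed: class pairs such as `"PG+BB"`).
#' @param component_mix Per-class probabilities over monotherapy products.
#' @param adherence_profile Per-cohort probabilities over the five PDC bins
#'   (`80+`, `60-79`, `40-59`, `20-39`, `<20`), each summing to 1.
#' @param refill_gap_model Zero-inflated geometric inter-refill delay:
#'   `p_zero` (probability of an on-time refill), `geom_prob` (geometric
#'   parameter of the positive delay) and `max_delay` (cap in days; the
#'   default 18 keeps every delay inside the 30-day grace period and inside
#'   the second component's supply lead, so delays thin coverage without
#'   triggering discontinuation).
#' @param dropout_hazard Extra per-30-day probability of stopping refills,
#'   on top of the profile-driven stopping time (default 0).
#' @param hba1c_effect_or Odds ratio per 1% HbA1c on latent nonadherence.
#' @param hba1c_mean,hba1c_sd,hba1c_missing HbA1c distribution (NGSP %) and
#'   missingness fraction in the covariate table.
#' @param contamination Fraction of decoy patients added on top of the
#'   cohorts, cycling through the three inclusion violations (short run-in,
#'   prior surgery, no post-index claims) to exercise the cohort filter.
#' @param run_in_range Range (days) of the monotherapy run-in length.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_fixed = 309L, n_unfixed = 329L,
    study_window = as.Date(c("2011-04-01", "2016-03-31")),
    regimen_mix = list(
      fixed = c("latanoprost/timolol" = 123, "travoprost/timolol" = 60,
                "tafluprost/timolol" = 58, "dorzolamide/timolol" = 34,
                "brinzolamide/timolol" = 34) / 309,
      unfixed = c("PG+BB" = 130, "PG+AA" = 87, "PG+CAI" = 47,
                  "BB+AA" = 25, "BB+CAI" = 22, "CAI+AA" = 18) / 329),
    component_mix = list(
      PG = c(latanoprost = 0.55, tafluprost = 0.25, travoprost = 0.15,
             bimatoprost = 0.05),
      BB = c(timolol = 0.75, carteolol = 0.25),
      CAI = c(dorzolamide = 0.5, brinzolamide = 0.5),
      AA = c(brimonidine = 1)),
    adherence_profile = list(
      fixed = c("80+" = 215, "60-79" = 16, "40-59" = 24, "20-39" = 19,
                "<20" = 35) / 309,
      unfixed = c("80+" = 160, "60-79" = 30, "40-59" = 19, "20-39" = 35,
                  "<20" = 85) / 329),
    refill_gap_model = list(p_zero = 0.7, geom_prob = 0.3, max_delay = 18L),
    dropout_hazard = 0,
    hba1c_effect_or = 1.606,
    hba1c_mean = 5.6, hba1c_sd = 0.55, hba1c_missing = 0.34,
    contamination = 0,
    run_in_range = c(372L, 420L)) {
  cfg <- list(seed = as.integer(seed), n_fixed = as.integer(n_fixed),
              n_unfixed = as.integer(n_unfixed),
              study_window = as.Date(study_window),
              regimen_mix = regimen_mix, component_mix = component_mix,
              adherence_profile = adherence_profile,
              refill_gap_model = refill_gap_model,
              dropout_hazard = dropout_hazard,
              hba1c_effect_or = hba1c_effect_or,
              hba1c_mean = hba1c_mean, hba1c_sd = hba1c_sd,
              hba1c_missing = hba1c_missing,
              contamination = contamination,
              run_in_range = as.integer(run_in_range))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_fixed < 0L || cfg$n_unfixed < 0L) stop("cohort sizes must be >= 0")
  probs <- c(cfg$regimen_mix, cfg$adherence_profile,
             unname(cfg$component_mix))
  for (p in probs) {
    if (any(p < 0)) stop("probabilities must be nonnegative")
    if (abs(sum(p) - 1) > 1e-9) stop("probability tables must sum to 1")
  }
  for (pr in cfg$adherence_profile)
    if (!identical(names(pr), ADHERENCE_BINS[c(5L, 4L, 3L, 2L, 1L)]))
      stop("adherence_profile bins must be named 80+, 60-79, 40-59, 20-39, <20")
  if (cfg$contamination < 0 || cfg$contamination > 1)
    stop("contamination must be in [0, 1]")
  with(cfg$refill_gap_model, {
    if (p_zero < 0 || p_zero > 1 || geom_prob <= 0 || geom_prob > 1 ||
        max_delay < 0 || max_delay > 28)
      stop("refill_gap_model: p_zero in [0,1], geom_prob in (0,1], max_delay in [0,28]")
  })
  invisible(cfg)
}

# Number of 30-day supplies per adherence bin: 30k/365*100 lands inside the
# bin for every choice. Adherent patients refill through the full year.
BIN_SUPPLY_CHOICES <- list("80+" = 13L, "60-79" = 8:9, "40-59" = 5:7,
                           "20-39" = 3:4, "<20" = 1:2)

# Intercept making mean(plogis(a + beta * h)) hit the target rate.
solve_intercept <- function(h, beta, target) {
  if (length(h) == 0L || target <= 0 || target >= 1) return(stats::qlogis(max(min(target, 1 - 1e-12), 1e-12)))
  stats::uniroot(function(a) mean(stats::plogis(a + beta * h)) - target,
                 interval = c(-60, 60), tol = 1e-10)$root
}

#' Generate synthetic claims, diagnosis, procedure and covariate tables
#'
#' @param config A [synthetic_config()].
#' @return list with `claims`, `diagnoses`, `procedures`, `covariates` (the
#'   four raw input tables) and `truth`, the planted ground truth per
#'   patient: cohort, decoy type, index date, true covered days / PDC /
#'   adherent flag, latent nonadherence, true discontinuation day and event
#'   flag (grace rule applied to the planted schedule), and true HbA1c.
#' @export
generate_claims_data <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  dict <- drug_dictionary()
  unit_of <- stats::setNames(dict$unit_bottle_volume, dict$generic_name)
  nf <- config$n_fixed; nu <- config$n_unfixed
  n <- nf + nu
  cohort <- rep(c("fixed", "unfixed"), c(nf, nu))
  pid <- sprintf("P%05d", seq_len(n))

  win <- as.integer(config$study_window)
  idx_lo <- win[1] + max(config$run_in_range) + 10L
  # latest possible post-index claim (12 delayed refills) stays in-window
  idx_hi <- win[2] - (360L + 12L * as.integer(config$refill_gap_model$max_delay) + 1L)
  index <- idx_lo + sample.int(idx_hi - idx_lo + 1L, n, replace = TRUE) - 1L

  runin <- sample(seq(config$run_in_range[1], config$run_in_range[2]), n,
                  replace = TRUE)
  r <- runin %% 30L
  runin <- runin + ifelse(r < 5L, 5L - r, 0L)  # keep supply active at index

  # index regimen and pre-index monotherapy drug
  prod_fix <- character(n); prodA <- character(n); prodB <- character(n)
  if (nf > 0L) {
    f <- sample(names(config$regimen_mix$fixed), nf, replace = TRUE,
                prob = config$regimen_mix$fixed)
    prod_fix[1:nf] <- f
    ef <- resolve_drug(f, dict)
    pre_class <- ifelse(stats::runif(nf) < 0.8, ef$class1, ef$class2)
    prodA[1:nf] <- vapply(pre_class, function(cl)
      sample(names(config$component_mix[[cl]]), 1L,
             prob = config$component_mix[[cl]]), character(1))
  }
  if (nu > 0L) {
    pr <- sample(names(config$regimen_mix$unfixed), nu, replace = TRUE,
                 prob = config$regimen_mix$unfixed)
    cls <- strsplit(pr, "+", fixed = TRUE)
    swap <- stats::runif(nu) >= 0.8
    clsA <- vapply(seq_len(nu), function(j) cls[[j]][1L + swap[j]], character(1))
    clsB <- vapply(seq_len(nu), function(j) cls[[j]][2L - swap[j]], character(1))
    prodA[nf + 1:nu] <- vapply(clsA, function(cl)
      sample(names(config$component_mix[[cl]]), 1L,
             prob = config$component_mix[[cl]]), character(1))
    prodB[nf + 1:nu] <- vapply(clsB, function(cl)
      sample(names(config$component_mix[[cl]]), 1L,
             prob = config$component_mix[[cl]]), character(1))
  }

  # HbA1c-linked latent nonadherence
  beta <- log(config$hba1c_effect_or)
  hba <- pmin(pmax(stats::rnorm(n, config$hba1c_mean, config$hba1c_sd), 3.5), 12)
  p_non <- numeric(n)
  for (co in unique(cohort)) {
    idx_c <- cohort == co
    target <- 1 - config$adherence_profile[[co]]["80+"]
    a <- solve_intercept(hba[idx_c], beta, unname(target))
    p_non[idx_c] <- stats::plogis(a + beta * hba[idx_c])
  }
  latent_non <- stats::runif(n) < p_non

  # number of 30-day supplies from the adherence profile
  k <- rep(13L, n)
  nb <- c("60-79", "40-59", "20-39", "<20")
  for (co in unique(cohort)) {
    idx_c <- which(cohort == co & latent_non)
    if (!length(idx_c)) next
    pbin <- config$adherence_profile[[co]][nb]
    bins <- nb[sample.int(4L, length(idx_c), replace = TRUE,
                          prob = pbin / sum(pbin))]
    k[idx_c] <- vapply(bins, function(b) {
      ch <- BIN_SUPPLY_CHOICES[[b]]
      if (length(ch) == 1L) ch else sample(ch, 1L)
    }, integer(1))
  }
  if (config$dropout_hazard > 0)
    k <- pmin(k, 1L + stats::rgeom(n, config$dropout_hazard))

  gm <- config$refill_gap_model
  delays <- lapply(k, function(kk) {
    if (kk <= 1L) return(integer(0))
    m <- kk - 1L
    on_time <- stats::runif(m) < gm$p_zero
    d <- pmin(stats::rgeom(m, gm$geom_prob) + 1L, as.integer(gm$max_delay))
    ifelse(on_time, 0L, d)
  })

  # decoys violating one inclusion rule each
  nd <- round(config$contamination * n)
  decoy_type <- if (nd > 0)
    rep(c("short_run_in", "prior_surgery", "no_post_index"),
        length.out = nd) else character(0)
  d_index <- if (nd > 0)
    idx_lo + sample.int(idx_hi - idx_lo + 1L, nd, replace = TRUE) - 1L else integer(0)

  # assemble claims
  c_pid <- vector("list", n + nd); c_day <- vector("list", n + nd)
  c_name <- vector("list", n + nd); c_dos <- vector("list", n + nd)
  t_cov <- integer(n); t_end <- integer(n)
  for (i in seq_len(n)) {
    pre_off <- seq(-runin[i], by = 30L, length.out = ceiling(runin[i] / 30))
    t_post <- 30L * (seq_len(k[i]) - 1L) + cumsum(c(0L, delays[[i]]))
    t_cov[i] <- sum(pmax(0L, pmin(t_post + 30L, 365L) - pmin(t_post, 365L)))
    t_end[i] <- t_post[k[i]] + 30L
    if (cohort[i] == "fixed") {
      nm <- c(rep(prodA[i], length(pre_off)), rep(prod_fix[i], k[i]))
      off <- c(pre_off, t_post)
      dos <- unname(unit_of[nm])
    } else {
      nm <- c(rep(prodA[i], length(pre_off) + k[i]), rep(prodB[i], k[i]))
      off <- c(pre_off, t_post, t_post)
      dos <- unname(unit_of[nm])
      dos[length(pre_off) + 1L] <- 2 * dos[length(pre_off) + 1L]  # sync head start
    }
    c_pid[[i]] <- rep(pid[i], length(off))
    c_day[[i]] <- index[i] + off
    c_name[[i]] <- nm
    c_dos[[i]] <- dos
  }
  if (nd > 0) for (j in seq_len(nd)) {
    ri <- switch(decoy_type[j], short_run_in = 155L, 395L)
    kk <- if (decoy_type[j] == "no_post_index") 1L else 13L
    pre_off <- seq(-ri, by = 30L, length.out = ceiling(ri / 30))
    t_post <- 30L * (seq_len(kk) - 1L)
    nm <- c(rep("latanoprost", length(pre_off)),
            rep("latanoprost/timolol", kk))
    c_pid[[n + j]] <- rep(sprintf("D%05d", j), length(pre_off) + kk)
    c_day[[n + j]] <- d_index[j] + c(pre_off, t_post)
    c_name[[n + j]] <- nm
    c_dos[[n + j]] <- unname(unit_of[nm])
  }
  claims <- data.frame(
    patient_id = unlist(c_pid, use.names = FALSE),
    dispense_date = as.Date(unlist(c_day, use.names = FALSE),
                            origin = "1970-01-01"),
    generic_name = unlist(c_name, use.names = FALSE),
    dosage_quantity = unlist(c_dos, use.names = FALSE))
  claims$period_field <- as.integer(round(
    claims$dosage_quantity / unit_of[claims$generic_name]))

  all_pid <- c(pid, if (nd > 0) sprintf("D%05d", seq_len(nd)))
  all_index <- c(index, d_index)
  n_all <- n + nd
  dx_code <- sample(c("H401", "H409"), n_all, replace = TRUE,
                    prob = c(0.7, 0.3))
  diagnoses <- data.frame(
    patient_id = all_pid,
    date = as.Date(all_index - sample(30:300, n_all, replace = TRUE),
                   origin = "1970-01-01"),
    icd10_code = dx_code)
  # post-index follow-up visits: real patients stay in the database even if
  # they stop refilling; "no post-index data" decoys disappear after index
  fu <- c(rep(TRUE, n), decoy_type != "no_post_index")
  diagnoses <- rbind(diagnoses, data.frame(
    patient_id = all_pid[fu],
    date = as.Date(all_index[fu] + sample(30:120, sum(fu), replace = TRUE),
                   origin = "1970-01-01"),
    icd10_code = dx_code[fu]))
  extra <- stats::runif(n_all) < 0.2   # unrelated codes the filter ignores
  if (any(extra)) {
    diagnoses <- rbind(diagnoses, data.frame(
      patient_id = all_pid[extra],
      date = as.Date(all_index[extra] - 15L, origin = "1970-01-01"),
      icd10_code = "E119"))
  }

  npx <- stats::runif(n_all) < 0.1     # non-glaucoma procedures, ignored
  procedures <- data.frame(
    patient_id = all_pid[npx],
    date = as.Date(all_index[npx] - 100L, origin = "1970-01-01"),
    is_glaucoma_surgery_or_laser = FALSE)
  surg <- which(decoy_type == "prior_surgery")
  if (length(surg)) {
    procedures <- rbind(procedures, data.frame(
      patient_id = sprintf("D%05d", surg),
      date = as.Date(d_index[surg] - 60L, origin = "1970-01-01"),
      is_glaucoma_surgery_or_laser = TRUE))
  }

  covariates <- make_covariates(all_pid, c(cohort, rep("fixed", nd)), hba,
                                config)

  truth <- data.frame(
    patient_id = all_pid,
    cohort = c(cohort, rep("fixed", nd)),
    decoy_type = c(rep("none", n), decoy_type),
    index_date = as.Date(all_index, origin = "1970-01-01"),
    true_covered_days = c(t_cov, rep(NA_integer_, nd)),
    true_pdc = c(pmin(100, t_cov / 365 * 100), rep(NA_real_, nd)),
    true_adherent = c(t_cov / 365 * 100 >= 80, rep(NA, nd)),
    latent_nonadherent = c(latent_non, rep(NA, nd)),
    true_event = c(t_end < 365L, rep(NA, nd)),
    true_duration_days = c(pmin(t_end, 365L), rep(NA_integer_, nd)),
    hba1c_true = c(hba, rep(NA_real_, nd)))
  list(claims = claims, diagnoses = diagnoses, procedures = procedures,
       covariates = covariates, truth = truth)
}

make_covariates <- function(pid, cohort, hba, config) {
  n <- length(pid)
  fx <- cohort == "fixed"
  p2 <- function(pf, pu) ifelse(fx, pf, pu)
  miss <- function(x, p) { x[stats::runif(n) < p] <- NA; x }
  nh <- length(hba)
  hba_full <- c(hba, rep(stats::rnorm(max(n - nh, 0), config$hba1c_mean,
                                      config$hba1c_sd)))[seq_len(n)]
  data.frame(
    patient_id = pid,
    sex = ifelse(stats::runif(n) < p2(0.550, 0.571), "male", "female"),
    age = round(stats::rnorm(n, p2(56.5, 57.1), 10.2), 1),
    body_mass_index = miss(round(stats::rnorm(n, p2(22.9, 22.7),
                                              p2(3.5, 3.1)), 1), 0.32),
    smoking = ifelse(stats::runif(n) < 0.67,
                     ifelse(stats::runif(n) < p2(0.157, 0.142), "yes", "no"),
                     NA_character_),
    hba1c_percent = miss(round(hba_full, 1), config$hba1c_missing),
    hypertension = stats::runif(n) < p2(0.298, 0.334),
    diabetes = stats::runif(n) < p2(0.275, 0.295),
    hyperlipidemia = stats::runif(n) < p2(0.282, 0.337),
    cancer = stats::runif(n) < p2(0.291, 0.347),
    insomnia = stats::runif(n) < p2(0.142, 0.134),
    region_category = sample(c("Hokkaido", "Tohoku", "Kanto", "Chubu",
                               "Kinki", "Chugoku", "Shikoku", "Kyushu"),
                             n, replace = TRUE,
                             prob = c(0.016, 0.032, 0.600, 0.118, 0.116,
                                      0.030, 0.006, 0.082)))
}

#' Write the generated tables as delimited text files
#'
#' @param data Output of [generate_claims_data()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_synthetic_data <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("claims", "diagnoses", "procedures", "covariates", "truth")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(data[[nm]], p, row.names = FALSE, quote = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}
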