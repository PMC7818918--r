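# The statistical battery: two-group comparisons under Bonferroni
# family-wise control, and the univariate -> stepwise multivariate logistic
# screen for nonadherence risk factors. Group tests use Welch's t-test by
# default (the two cohorts' PDC spreads differ) and Pearson's chi-square
# without continuity correction. The stepwise routine is the classic
# forward-entry / backward-elimination on term p-values (likelihood-ratio),
# entry and stay thresholds 0.05 by default.

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise error level (default 0.05).
#' @param m Number of tests in the family (the primary analysis uses m = 9).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (length(m) != 1L || !is.finite(m) || m < 1) stop("m must be >= 1")
  alpha / m
}

#' Compare two groups on a mean or a proportion
#'
#' @param a,b For `kind = "mean"`: numeric vectors. For `kind =
#'   "proportion"`: either logical/0-1 vectors or length-2 count vectors
#'   `c(successes, failures)`.
#' @param kind `"mean"` (two-sample t-test) or `"proportion"` (Pearson
#'   chi-square on the 2x2 table, no continuity correction).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param alpha,m Family-wise level and family size for the significance
#'   flag: significant iff `p < alpha / m`.
#' @return list of class `group_test`: `test`, `statistic`, `p_value`,
#'   `significant`, `threshold`.
#' @export
compare_groups <- function(a, b, kind = c("mean", "proportion"),
                           var_equal = FALSE, alpha = 0.05, m = 9) {
  kind <- match.arg(kind)
  thr <- bonferroni_threshold(alpha, m)
  if (kind == "mean") {
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      stop("zero variance in both groups: t-test undefined")
    tt <- stats::t.test(a, b, var.equal = var_equal)
    out <- list(test = if (var_equal) "t (pooled)" else "t (Welch)",
                statistic = unname(tt$statistic), p_value = tt$p.value)
  } else {
    as_counts <- function(x) {
      if (length(x) == 2L && is.numeric(x) && !is.logical(x)) x
      else c(sum(x %in% c(TRUE, 1)), sum(x %in% c(FALSE, 0)))
    }
    tab <- rbind(as_counts(a), as_counts(b))
    ct <- stats::chisq.test(tab, correct = FALSE)
    out <- list(test = "Pearson chi-square",
                statistic = unname(ct$statistic), p_value = ct$p.value)
  }
  out$threshold <- thr
  out$significant <- out$p_value < thr
  structure(out, class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%ssignificant at %.4g)\n",
              x$test, x$statistic, x$p_value,
              if (x$significant) "" else "not ", x$threshold))
  invisible(x)
}

# One single-covariate logistic fit; returns NULL for degenerate input.
fit_one_logistic <- function(y, x, variable) {
  cc <- !is.na(y) & !is.na(x)
  y <- y[cc]; x <- x[cc]
  if (is.character(x)) x <- factor(x)
  if (length(unique(x)) < 2L) {
    warning("covariate '", variable, "' is constant; excluded from the screen")
    return(NULL)
  }
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  if (any(!is.finite(sm[, "Std. Error"])) || max(sm[, "Std. Error"]) > 50 ||
      max(abs(sm[, "Estimate"])) > 25) {
    warning("covariate '", variable,
            "' shows (quasi-)complete separation; excluded from the screen")
    return(NULL)
  }
  if (nrow(sm) == 2L) {
    b <- sm[2L, "Estimate"]; se <- sm[2L, "Std. Error"]
    z <- stats::qnorm(0.975)
    or <- exp(b); lo <- exp(b - z * se); hi <- exp(b + z * se)
    p <- sm[2L, "Pr(>|z|)"]
  } else {
    # multi-level factor: overall likelihood-ratio p, no single OR
    or <- lo <- hi <- NA_real_
    p <- stats::anova(fit, test = "LRT")[2L, "Pr(>Chi)"]
  }
  data.frame(variable = variable, n = length(y), odds_ratio = or,
             ci_low = lo, ci_high = hi, p_value = p)
}

#' Univariate logistic screen for nonadherence risk factors
#'
#' Fits one single-covariate logistic regression per variable (complete
#' cases per variable, so checkup variables with missing values keep their
#' own n), reporting the odds ratio with Wald 95% CI and the p-value.
#' Variables with `p < p_threshold` (default 0.1) are flagged as candidates
#' for the multivariate stage. Constant and separated covariates are
#' excluded with a warning.
#'
#' @param data data.frame holding the outcome and covariates.
#' @param outcome Name of the logical/0-1 outcome column (1 = nonadherent).
#' @param covariates Covariate column names (default: everything else).
#' @param p_threshold Candidate threshold (default 0.1).
#' @return data.frame: `variable`, `n`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `candidate`.
#' @export
univariate_screen <- function(data, outcome, covariates = NULL,
                              p_threshold = 0.1) {
  if (is.null(covariates))
    covariates <- setdiff(names(data), c(outcome, "patient_id"))
  y <- data[[outcome]]
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("outcome must have both classes")
  rows <- lapply(covariates, function(v) fit_one_logistic(y, data[[v]], v))
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(variable = character(), n = integer(),
                      odds_ratio = numeric(), ci_low = numeric(),
                      ci_high = numeric(), p_value = numeric(),
                      candidate = logical()))
  out$candidate <- out$p_value < p_threshold
  rownames(out) <- NULL
  out
}

#' Stepwise (forward and backward) multivariate logistic regression
#'
#' Classic p-value-driven selection: at each cycle the candidate with the
#' smallest likelihood-ratio p-value below `p_enter` joins the model, then
#' any included term whose removal p-value exceeds `p_stay` is dropped,
#' until the model is stable. Fitted on complete cases across all candidate
#' columns. Aliased (perfectly collinear) candidates never improve the fit,
#' so at most one member of a collinear pair is retained.
#'
#' @param data data.frame holding the outcome and candidate columns.
#' @param outcome Name of the logical/0-1 outcome column.
#' @param candidates Candidate covariate names (e.g. the `p < 0.1` screen
#'   survivors).
#' @param p_enter,p_stay Entry and stay thresholds (default 0.05 each).
#' @return list with `terms` (selected, in entry order), `coefficients`
#'   (data.frame of per-coefficient OR, Wald 95% CI, p), `term_p` (removal
#'   LRT p per selected term) and `fit` (the final `glm`). No candidate
#'   entering yields an empty model, not an error.
#' @export
stepwise_multivariate <- function(data, outcome, candidates,
                                  p_enter = 0.05, p_stay = 0.05) {
  if (length(candidates) == 0L) stop("at least one candidate is required")
  cc <- stats::complete.cases(data[, c(outcome, candidates), drop = FALSE])
  d <- data[cc, , drop = FALSE]
  d[[outcome]] <- as.numeric(d[[outcome]])
  for (v in candidates) if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
  selected <- character()
  fit <- stats::glm(stats::reformulate("1", response = outcome), data = d,
                    family = stats::binomial())
  repeat {
    changed <- FALSE
    remaining <- setdiff(candidates, selected)
    if (length(remaining)) {
      ad <- suppressWarnings(
        stats::add1(fit, scope = stats::reformulate(c(selected, remaining)),
                    test = "LRT"))
      p_add <- ad[["Pr(>Chi)"]][-1L]
      names(p_add) <- rownames(ad)[-1L]
      p_add <- p_add[is.finite(p_add)]
      if (length(p_add) && min(p_add) < p_enter) {
        selected <- c(selected, names(p_add)[which.min(p_add)])
        fit <- stats::glm(stats::reformulate(selected, response = outcome),
                          data = d, family = stats::binomial())
        changed <- TRUE
      }
    }
    repeat {
      if (length(selected) == 0L) break
      dr <- suppressWarnings(stats::drop1(fit, test = "LRT"))
      p_drop <- dr[["Pr(>Chi)"]][-1L]
      names(p_drop) <- rownames(dr)[-1L]
      if (!any(p_drop > p_stay, na.rm = TRUE)) break
      worst <- names(p_drop)[which.max(p_drop)]
      selected <- setdiff(selected, worst)
      fit <- stats::glm(
        stats::reformulate(if (length(selected)) selected else "1",
                           response = outcome),
        data = d, family = stats::binomial())
      changed <- TRUE
    }
    if (!changed) break
  }
  coefs <- data.frame(term = character(), odds_ratio = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p_value = numeric())
  term_p <- numeric()
  if (length(selected)) {
    sm <- summary(fit)$coefficients
    sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
    z <- stats::qnorm(0.975)
    coefs <- data.frame(term = rownames(sm),
                        odds_ratio = exp(sm[, "Estimate"]),
                        ci_low = exp(sm[, "Estimate"] - z * sm[, "Std. Error"]),
                        ci_high = exp(sm[, "Estimate"] + z * sm[, "Std. Error"]),
                        p_value = sm[, "Pr(>|z|)"])
    rownames(coefs) <- NULL
    dr <- suppressWarnings(stats::drop1(fit, test = "LRT"))
    term_p <- stats::setNames(dr[["Pr(>Chi)"]][-1L], rownames(dr)[-1L])
  }
  list(terms = selected, coefficients = coefs, term_p = term_p, fit = fit)
}
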