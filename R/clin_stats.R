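# Clinical statistics layer: rank-sum comparisons, Kaplan-Meier /
# log-rank survival, Cox proportional hazards, correlation, and
# multiple-testing adjustment.  Thin, contract-checked wrappers over the
# survival package and base R.

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration for small untied samples (combined n <= 20 without
#' ties), normal approximation with tie correction otherwise.
#'
#' @param x,y Non-empty numeric samples.
#' @return List of class `test_result`: `statistic`, `p_value`, `method`,
#'   `n_per_group`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  .assert(length(x) > 0 && length(y) > 0, "both samples must be non-empty")
  exact <- (length(x) + length(y) <= 20) &&
    !anyDuplicated(c(x, y))
  res <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  structure(list(statistic = unname(res$statistic),
                 p_value = res$p.value,
                 method = if (exact) "wilcoxon_exact" else "wilcoxon_normal",
                 n_per_group = c(length(x), length(y))),
            class = "test_result")
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates with right censoring per group, and
#' the log-rank chi-square test across groups.  A `significant` flag is
#' reported at p < 0.05 for convenience; it gates nothing.
#'
#' @param records `data.frame` with columns `time` (months > 0), `event`
#'   (1 = event, 0 = censored) and the grouping column.
#' @param group_field Name of the grouping column (default `"group"`).
#' @return List of class `km_logrank`: `statistic` (log-rank
#'   chi-square), `p_value`, `df`, `significant`, `curves` (per-group
#'   `data.frame`: time, n_risk, n_event, survival, lower, upper).
#' @export
km_logrank <- function(records, group_field = "group") {
  .assert(all(c("time", "event", group_field) %in% names(records)),
          "records needs time/event/group columns")
  .assert(all(records$time > 0), "survival times must be > 0")
  g <- factor(records[[group_field]])
  if (nlevels(g) < 2)
    stop("invalid input: need at least 2 groups", call. = FALSE)
  if (sum(records$event) < 1)
    stop("no events observed; log-rank test undefined", call. = FALSE)
  sv <- survival::Surv(records$time, records$event)
  sd_ <- survival::survdiff(sv ~ g)
  df <- length(sd_$n) - 1
  p <- pchisq(sd_$chisq, df, lower.tail = FALSE)
  fit <- survival::survfit(sv ~ g)
  sm <- summary(fit)
  strata <- if (is.null(sm$strata)) rep(levels(g)[1], length(sm$time))
            else sub("^g=", "", as.character(sm$strata))
  curves <- split(data.frame(time = sm$time, n_risk = sm$n.risk,
                             n_event = sm$n.event, survival = sm$surv,
                             lower = sm$lower, upper = sm$upper),
                  strata)
  structure(list(statistic = unname(sd_$chisq), p_value = p, df = df,
                 significant = p < 0.05, curves = curves,
                 observed = sd_$obs, expected = sd_$exp,
                 variance = sd_$var),
            class = "km_logrank")
}

#' Cox proportional hazards regression
#'
#' Partial-likelihood fit with Efron handling of tied event times and
#' Wald p-values, either one covariate at a time (`univariate`) or
#' jointly (`multivariate`).  Factor covariates use their first level as
#' the reference; zero-variance covariates are excluded with a warning.
#'
#' @param records `data.frame` with `time`, `event` and covariate
#'   columns.
#' @param covariates Character vector of covariate column names.
#' @param mode `"univariate"` or `"multivariate"`.
#' @param conf_level Confidence level for hazard-ratio intervals
#'   (default 0.95).
#' @return `data.frame` of class `cox_results`: one row per coefficient
#'   with `term`, `coef` (log hazard ratio), `hr`, `lower`, `upper`,
#'   `p_value`, `mode`.
#' @export
cox_ph <- function(records, covariates,
                   mode = c("univariate", "multivariate"),
                   conf_level = 0.95) {
  mode <- match.arg(mode)
  .assert(all(c("time", "event") %in% names(records)),
          "records needs time/event columns")
  .assert(all(covariates %in% names(records)), "unknown covariate(s)")
  keep <- vapply(covariates, function(v) {
    x <- records[[v]]
    length(unique(x[!is.na(x)])) > 1
  }, logical(1))
  if (any(!keep))
    warning(sprintf("zero-variance covariate(s) excluded: %s",
                    paste(covariates[!keep], collapse = ", ")))
  covariates <- covariates[keep]
  .assert(length(covariates) > 0, "no usable covariates")
  .assert(sum(records$event) >= length(covariates) + 1,
          "too few events for the number of covariates")
  fit_one <- function(covs) {
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                   paste(covs, collapse = " + ")))
    fit <- survival::coxph(fml, data = records, ties = "efron")
    s <- summary(fit, conf.int = conf_level)
    data.frame(term = rownames(s$coefficients),
               coef = s$coefficients[, "coef"],
               hr = s$coefficients[, "exp(coef)"],
               lower = s$conf.int[, 3], upper = s$conf.int[, 4],
               p_value = s$coefficients[, "Pr(>|z|)"],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- if (mode == "multivariate") fit_one(covariates)
         else do.call(rbind, lapply(covariates, fit_one))
  out$mode <- mode
  class(out) <- c("cox_results", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity
#' enforcement; the returned vector is in the input order.
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  .assert(all(!is.na(p_values)) && all(p_values >= 0 & p_values <= 1),
          "invalid input: p-values must be in [0,1]")
  p.adjust(p_values, method = "BH")
}

#' Pearson correlation with t-distribution p-value
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return List of class `test_result`: `statistic` (r), `p_value`,
#'   `method`, `n`; `r` is `NA` (with a reason attribute) when either
#'   input has zero variance.
#' @export
pearson_r <- function(x, y) {
  .assert(length(x) == length(y), "x and y must have equal length")
  .assert(length(x) >= 3, "need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    out <- structure(list(statistic = NA_real_, p_value = NA_real_,
                          method = "pearson", n = length(x)),
                     class = "test_result")
    attr(out, "reason") <- "zero variance"
    return(out)
  }
  res <- cor.test(x, y, method = "pearson")
  structure(list(statistic = unname(res$estimate), p_value = res$p.value,
                 method = "pearson", n = length(x)),
            class = "test_result")
}

#' Cohort proportion as a printed percentage
#'
#' `100 * numerator / denominator`, rounded half-up to one decimal (the
#' convention used for reported cohort percentages, e.g. 130 of 233 is
#' 55.8).
#'
#' @param numerator,denominator Non-negative counts with
#'   `numerator <= denominator`, `denominator > 0`.
#' @return Percentage at one-decimal precision.
#' @export
proportion_summary <- function(numerator, denominator) {
  .assert(denominator > 0, "invalid input: denominator must be > 0")
  .assert(numerator >= 0 && numerator <= denominator,
          "numerator must be in [0, denominator]")
  floor(1000 * numerator / denominator + 0.5 + 1e-9) / 10
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}
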