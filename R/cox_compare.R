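#' @name cox_compare
#' @title Threshold adjudication with adjusted Cox models
#'
#' @description Each candidate threshold `c` defines a binary poor-adherence
#' covariate `1(pdc < c)`. An adjusted proportional-hazards model is fitted
#' per threshold on the same rows and covariates, and models are compared by
#' `AIC = -2 logPL + 2k` with the lowest-AIC model as reference. Support for
#' non-reference models follows the Burnham-Anderson Delta-AIC categories,
#' and thresholds with `Delta-AIC < 4` (strict) define the retained range.
NULL

#' Fit the adjusted Cox model at one threshold
#'
#' Maximizes the Cox partial likelihood (Efron tie correction by default;
#' integer-day times produce heavy ties) for
#' `Surv(time_days, event) ~ I(pdc < c) + covariates`. The hazard ratio for
#' poor adherence is `exp(beta)` with a Wald 95% CI on the log scale.
#'
#' @param rows analysis table ([build_analysis_table()]).
#' @param threshold dichotomization point `c`.
#' @param covariates character vector of adjustment columns in `rows`
#'   (possibly empty).
#' @param ties_method `"efron"` or `"breslow"`.
#' @return object of class `cox_fit`: list with `threshold`, `beta`, `se`,
#'   `hr`, `ci_low`, `ci_high`, `loglik` (maximized log partial likelihood),
#'   `k` (number of estimated coefficients), `aic`, `coefficients` (all
#'   model coefficients), `n`, `n_events`.
#' @export
fit_cox_at_threshold <- function(rows, threshold, covariates = character(),
                                 ties_method = c("efron", "breslow")) {
  ties_method <- match.arg(ties_method)
  if (!any(rows$event)) stop("no events: Cox model undefined")
  poor <- rows$pdc < threshold
  if (all(poor) || !any(poor))
    stop("degenerate covariate: 1(pdc < ", format(threshold),
         ") is constant across rows")
  dat <- data.frame(time_days = rows$time_days, event = rows$event,
                    poor_adherence = poor,
                    rows[, covariates, drop = FALSE])
  fml <- stats::as.formula(paste(
    "survival::Surv(time_days, event) ~ poor_adherence",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties_method),
    warning = function(w) {
      if (grepl("out of iterations|did not converge", conditionMessage(w)))
        stop("Cox fit did not converge at threshold ", format(threshold),
             ": ", conditionMessage(w), call. = FALSE)
    })
  beta <- unname(fit$coefficients["poor_adherenceTRUE"])
  se <- sqrt(diag(fit$var))[which(names(fit$coefficients) == "poor_adherenceTRUE")]
  k <- sum(!is.na(fit$coefficients))
  logpl <- fit$loglik[2]
  structure(list(threshold = threshold,
                 beta = beta, se = unname(se),
                 hr = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 loglik = logpl, k = k,
                 aic = -2 * logpl + 2 * k,
                 coefficients = fit$coefficients,
                 n = fit$n, n_events = fit$nevent),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit at PDC < %.4g: HR %.3f (95%% CI %.3f-%.3f), AIC %.3f\n",
              x$threshold, x$hr, x$ci_low, x$ci_high, x$aic))
  invisible(x)
}

#' Delta-AIC against the best model
#'
#' Re-baselines a vector of AIC values against its minimum.
#'
#' @param aic numeric AIC values.
#' @return non-negative deltas; exactly the positions of the minimum are 0.
#' @export
delta_aic <- function(aic) {
  stopifnot(length(aic) >= 1, all(is.finite(aic)))
  aic - min(aic)
}

#' Burnham-Anderson support category for a Delta-AIC
#'
#' `<= 2` substantial support; `(2, 4)` retained but borderline; `[4, 7]`
#' considerably less support; `(7, 10]` little support; `> 10` no support.
#'
#' @param delta non-negative Delta-AIC value(s).
#' @return character label(s): `substantial`, `retained-borderline`,
#'   `considerably-less`, `little`, `none`.
#' @export
categorize_support <- function(delta) {
  if (any(!is.finite(delta) | delta < 0))
    stop("Delta-AIC must be non-negative")
  cut_lab <- function(d) {
    if (d <= 2) "substantial"
    else if (d < 4) "retained-borderline"
    else if (d <= 7) "considerably-less"
    else if (d <= 10) "little"
    else "none"
  }
  vapply(delta, cut_lab, "")
}

#' Compare candidate thresholds by AIC
#'
#' Fits one adjusted Cox model per threshold on the same rows and covariates
#' and tabulates hazard ratios, AIC, Delta-AIC (reference = minimum AIC) and
#' support categories.
#'
#' @inheritParams fit_cox_at_threshold
#' @param thresholds two or more dichotomization points.
#' @param on_error `"stop"` (default) propagates any fit error with the
#'   offending threshold named; `"skip"` drops failing thresholds with a
#'   warning (at least two must survive).
#' @return object of class `threshold_comparison`: data.frame with columns
#'   `threshold`, `hr`, `ci_low`, `ci_high`, `aic`, `delta_aic`, `support`,
#'   `is_reference`, sorted by threshold. Duplicated thresholds yield
#'   duplicated reference rows; this degenerate case is flagged with a
#'   warning.
#' @export
compare_thresholds <- function(rows, thresholds, covariates = character(),
                               ties_method = c("efron", "breslow"),
                               on_error = c("stop", "skip")) {
  ties_method <- match.arg(ties_method)
  on_error <- match.arg(on_error)
  if (length(thresholds) < 2) stop("need at least 2 thresholds to compare")
  thresholds <- sort(thresholds)
  fits <- lapply(thresholds, function(th) {
    tryCatch(fit_cox_at_threshold(rows, th, covariates, ties_method),
             error = function(e) {
               if (on_error == "stop")
                 stop("threshold ", format(th), ": ", conditionMessage(e),
                      call. = FALSE)
               warning("dropping threshold ", format(th), ": ",
                       conditionMessage(e), call. = FALSE)
               NULL
             })
  })
  ok <- !vapply(fits, is.null, TRUE)
  if (sum(ok) < 2) stop("fewer than 2 thresholds could be fitted")
  thresholds <- thresholds[ok]
  fits <- fits[ok]
  aic <- vapply(fits, `[[`, 0, "aic")
  dA <- delta_aic(aic)
  if (sum(dA == 0) > 1)
    warning("multiple reference rows (identical minimum AIC)")
  tab <- data.frame(threshold = thresholds,
                    hr = vapply(fits, `[[`, 0, "hr"),
                    ci_low = vapply(fits, `[[`, 0, "ci_low"),
                    ci_high = vapply(fits, `[[`, 0, "ci_high"),
                    aic = aic,
                    delta_aic = dA,
                    support = categorize_support(dA),
                    is_reference = dA == 0,
                    stringsAsFactors = FALSE)
  class(tab) <- c("threshold_comparison", "data.frame")
  tab
}

#' Retained thresholds and their range
#'
#' Thresholds whose models have `Delta-AIC < cut` (strict, default 4) are
#' retained to define the plausible range of the optimal threshold; the
#' reference (minimum-AIC) threshold is always part of the retained set.
#'
#' @param table a [compare_thresholds()] result (or any data.frame with
#'   `threshold` and `delta_aic`).
#' @param cut strict Delta-AIC retention cut.
#' @return list with `retained` (sorted thresholds) and `range`
#'   (`c(min, max)`).
#' @export
retain_threshold_range <- function(table, cut = 4) {
  stopifnot(nrow(table) >= 1)
  keep <- table$delta_aic < cut | table$delta_aic == 0
  retained <- sort(table$threshold[keep])
  list(retained = retained, range = range(retained))
}
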