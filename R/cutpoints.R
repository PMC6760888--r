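#' @name cutpoints
#' @title Optimal adherence-threshold estimation
#'
#' @description Three estimators of the PDC threshold separating poor from
#' good adherers (poor adherence means `pdc < c`, strict): the
#' Contal-O'Quigley maximally selected log-rank statistic for the
#' time-to-event outcome, and two ROC classification indices (Youden's J and
#' the minimum distance to the perfect-classification corner) applied to the
#' binary event indicator over follow-up.
NULL

#' Candidate threshold grid
#'
#' In `resolution` mode candidates are the multiples of `resolution` inside
#' (0, 1) (default 0.01, i.e. two-decimal thresholds); in `observed` mode
#' they are the distinct PDC values. Candidates leaving fewer than
#' `trim_fraction` of subjects on either side of the split `pdc < c` are
#' dropped, preventing degenerate groups.
#'
#' @param pdc_values numeric PDC values (at least 2 distinct).
#' @param mode `"resolution"` or `"observed"`.
#' @param resolution grid spacing for `resolution` mode.
#' @param trim_fraction minimum fraction of subjects per side, in `[0, 0.5)`.
#' @return object of class `candidate_grid`: list with `candidates` (strictly
#'   increasing), `mode`, `trim_fraction`.
#' @export
make_candidate_grid <- function(pdc_values, mode = c("resolution", "observed"),
                                resolution = 0.01, trim_fraction = 0.05) {
  mode <- match.arg(mode)
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5)
  pdc_values <- pdc_values[is.finite(pdc_values)]
  if (length(unique(pdc_values)) < 2)
    stop("need at least 2 distinct PDC values to form a candidate grid")
  if (mode == "observed") {
    cand <- sort(unique(pdc_values))
  } else {
    k <- seq(ceiling(min(pdc_values) / resolution),
             floor(max(pdc_values) / resolution))
    cand <- k * resolution
    cand <- cand[cand > 0 & cand < 1]
  }
  if (trim_fraction > 0) {
    n <- length(pdc_values)
    low <- vapply(cand, function(c) sum(pdc_values < c), 0)
    keep <- low >= trim_fraction * n & (n - low) >= trim_fraction * n
    cand <- cand[keep]
  }
  if (!length(cand)) stop("no admissible cutpoints after trimming")
  structure(list(candidates = cand, mode = mode,
                 trim_fraction = trim_fraction),
            class = "candidate_grid")
}

#' @export
print.candidate_grid <- function(x, ...) {
  cat("candidate grid (", x$mode, " mode): ", length(x$candidates),
      " thresholds in [", format(min(x$candidates)), ", ",
      format(max(x$candidates)), "], trim ", x$trim_fraction, "\n", sep = "")
  invisible(x)
}

#' Contal-O'Quigley maximally selected log-rank scan
#'
#' For each candidate `c`, computes the two-group log-rank numerator
#' \deqn{U(c) = \sum_t [d_{low}(t) - d(t) \, n_{low}(t)/n(t)]}
#' over the ordered distinct event times, where the low-adherence group is
#' `pdc < c`. The selected threshold maximizes `|U(c)|`. The scan-level
#' standardization uses the variance constant
#' \deqn{s^2 = \frac{1}{D-1} \sum_{i=1}^{D} \Big(1 - \sum_{j=1}^{i}
#'   \frac{1}{D-j+1}\Big)^2}
#' over the `D` distinct event times, giving `q = max_c |U(c)| / (s \sqrt{D-1})`
#' with the Brownian-bridge tail approximation `p = 2 exp(-2 q^2)` (reported
#' when `q > 1`; the approximation is unusable below that). The per-candidate
#' hypergeometric-variance log-rank `z = U/sqrt(V)` is reported alongside,
#' since either standardization may be wanted.
#'
#' @param rows analysis table ([build_analysis_table()]): needs `pdc`,
#'   `time_days`, `event`.
#' @param grid a [make_candidate_grid()].
#' @return list with `result` (a `cutpoint_result`: `method`, `threshold`,
#'   `statistic` = q) and `scan` (data.frame per candidate: `candidate`, `U`,
#'   `V`, `z`, `abs_U`) plus scan-level `D`, `s2`, `q`, `p_value`.
#' @export
contal_oquigley_scan <- function(rows, grid) {
  if (!any(rows$event)) stop("no events: log-rank scan undefined")
  ord <- order(rows$time_days)
  time <- rows$time_days[ord]
  status <- rows$event[ord]
  pdc <- rows$pdc[ord]
  n <- length(time)

  ev_times <- unique(time[status])
  D <- length(ev_times)
  if (D < 2) stop("variance constant undefined with a single event time")

  # at-risk index: first position with time >= t (rows sorted ascending)
  first_at_risk <- vapply(ev_times, function(t) sum(time < t), 0L) + 1L
  n_at_risk <- n - first_at_risk + 1L
  ev_groups <- split(which(status), factor(time[status], levels = ev_times))
  d_t <- lengths(ev_groups)

  cand <- grid$candidates
  U <- V <- numeric(length(cand))
  for (k in seq_along(cand)) {
    low <- pdc < cand[k]
    # n_low(t): low-group subjects still at risk at each event time
    cum_low_from_end <- rev(cumsum(rev(low)))          # count of low in [i, n]
    n_low <- cum_low_from_end[first_at_risk]
    d_low <- vapply(ev_groups, function(ix) sum(low[ix]), 0L)
    frac <- n_low / n_at_risk
    U[k] <- sum(d_low - d_t * frac)
    vt <- d_t * frac * (1 - frac) * (n_at_risk - d_t) /
      pmax(n_at_risk - 1, 1)
    V[k] <- sum(vt)
  }

  i_seq <- seq_len(D)
  inner <- cumsum(1 / (D - i_seq + 1))
  s2 <- sum((1 - inner)^2) / (D - 1)
  best <- which.max(abs(U))          # ties -> smallest candidate
  q <- abs(U[best]) / (sqrt(s2) * sqrt(D - 1))
  p <- if (q > 1) min(1, 2 * exp(-2 * q^2)) else NA_real_

  scan <- data.frame(candidate = cand, U = U, V = V,
                     z = ifelse(V > 0, U / sqrt(V), NA_real_),
                     abs_U = abs(U))
  list(result = cutpoint_result("CONTAL_OQUIGLEY", cand[best], q),
       scan = scan, D = D, s2 = s2, q = q, p_value = p)
}

cutpoint_result <- function(method, threshold, statistic) {
  structure(list(method = method, threshold = threshold,
                 statistic = statistic),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("%s: threshold %.4g (statistic %.4g)\n",
              x$method, x$threshold, x$statistic))
  invisible(x)
}

#' ROC points of the classifier "pdc < c predicts event"
#'
#' Event status is the binary indicator of the outcome within each subject's
#' follow-up (censoring-time differences are ignored; time-dependent ROC is
#' out of scope). `Sn(c)` is the fraction of event subjects with `pdc < c`;
#' `Sp(c)` the fraction of non-event subjects with `pdc >= c`.
#'
#' @inheritParams contal_oquigley_scan
#' @return data.frame with columns `candidate`, `sensitivity`, `specificity`;
#'   `sensitivity` is non-decreasing and `specificity` non-increasing in `c`.
#' @export
roc_points <- function(rows, grid) {
  ev <- rows$pdc[rows$event]
  nev <- rows$pdc[!rows$event]
  if (!length(ev) || !length(nev))
    stop("ROC undefined: need at least one event and one non-event")
  cand <- grid$candidates
  data.frame(candidate = cand,
             sensitivity = vapply(cand, function(c) mean(ev < c), 0),
             specificity = vapply(cand, function(c) mean(nev >= c), 0))
}

#' Youden's J threshold
#'
#' `J(c) = Sn(c) + Sp(c) - 1`; the selected threshold maximizes J, ties
#' broken toward the smallest candidate.
#'
#' @param roc output of [roc_points()].
#' @return a `cutpoint_result` with `statistic` = max J.
#' @export
youden_threshold <- function(roc) {
  stopifnot(nrow(roc) >= 1)
  J <- roc$sensitivity + roc$specificity - 1
  best <- which.max(J)
  cutpoint_result("YOUDEN", roc$candidate[best], J[best])
}

#' Minimum-distance ROC threshold
#'
#' Selects the candidate minimizing the Euclidean distance from the ROC
#' point to perfect classification,
#' `d = sqrt((1 - Sn)^2 + (1 - Sp)^2)`; ties broken toward the smallest
#' candidate.
#'
#' @inheritParams youden_threshold
#' @return a `cutpoint_result` with `statistic` = min d.
#' @export
min_distance_threshold <- function(roc) {
  stopifnot(nrow(roc) >= 1)
  d <- sqrt((1 - roc$sensitivity)^2 + (1 - roc$specificity)^2)
  best <- which.min(d)
  cutpoint_result("MIN_DISTANCE", roc$candidate[best], d[best])
}

#' Run all three cutpoint methods
#'
#' @inheritParams contal_oquigley_scan
#' @return list with `contal` (full scan), `youden`, `min_distance`, `roc`,
#'   and `results` (data.frame: method, threshold, statistic).
#' @export
estimate_cutpoints <- function(rows, grid) {
  co <- contal_oquigley_scan(rows, grid)
  roc <- roc_points(rows, grid)
  yj <- youden_threshold(roc)
  md <- min_distance_threshold(roc)
  res <- data.frame(method = c("CONTAL_OQUIGLEY", "YOUDEN", "MIN_DISTANCE"),
                    threshold = c(co$result$threshold, yj$threshold, md$threshold),
                    statistic = c(co$q, yj$statistic, md$statistic),
                    stringsAsFactors = FALSE)
  list(contal = co, youden = yj, min_distance = md, roc = roc, results = res)
}
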