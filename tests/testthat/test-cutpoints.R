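test_that("candidate grids respect mode and trimming", {
  g <- make_candidate_grid(c(0.2, 0.5, 0.8), "observed", trim_fraction = 0)
  expect_equal(g$candidates, c(0.2, 0.5, 0.8))
  set.seed(7)
  v <- runif(200, 0.3, 0.9)
  g2 <- make_candidate_grid(v, "resolution", 0.01, 0.05)
  expect_true(all(abs(g2$candidates / 0.01 - round(g2$candidates / 0.01)) < 1e-9))
  n <- length(v)
  low <- vapply(g2$candidates, function(c) sum(v < c), 0)
  expect_true(all(low >= 0.05 * n & (n - low) >= 0.05 * n))
  expect_error(make_candidate_grid(rep(0.5, 10), "observed"), "distinct")
  expect_error(make_candidate_grid(c(0.5, 0.500001), "resolution", 0.01, 0.2),
               "admissible")
})

test_that("log-rank scan reproduces the six-subject worked example", {
  rows <- data.frame(pdc = c(0.2, 0.3, 0.6, 0.7, 0.8, 0.9),
                     time_days = c(100, 200, 300, 400, 500, 600),
                     event = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  g <- make_candidate_grid(rows$pdc, "observed", trim_fraction = 0)
  sc <- contal_oquigley_scan(rows, g)
  expect_equal(sc$result$threshold, 0.6)
  expect_equal(sc$scan$U[sc$scan$candidate == 0.6], 22 / 15)
  expect_equal(sc$D, 3L, ignore_attr = TRUE)
  # scan-level variance constant: D = 3 event times
  a <- 1 - cumsum(1 / (3 - 1:3 + 1))
  expect_equal(sc$s2, sum(a^2) / 2)
  expect_equal(sc$q, abs(22 / 15) / (sqrt(sc$s2) * sqrt(2)))
  # per-candidate U agrees with survdiff at every admissible candidate
  for (c in g$candidates[-1]) {
    expect_equal(sc$scan$U[sc$scan$candidate == c],
                 oracle_logrank_U(rows, c), info = paste("c =", c))
  }
})

test_that("scan errors on zero events and on a single event time", {
  rows <- data.frame(pdc = c(0.2, 0.8), time_days = c(10, 20),
                     event = c(FALSE, FALSE))
  g <- list(candidates = 0.5)
  expect_error(contal_oquigley_scan(rows, g), "no events")
  rows$event <- c(TRUE, FALSE)
  expect_error(contal_oquigley_scan(rows, g), "single event time")
})

test_that("ROC points match the worked examples and stay monotone", {
  rows <- data.frame(pdc = c(0.3, 0.4, 0.7, 0.9),
                     time_days = c(100, 100, 100, 100),
                     event = c(TRUE, TRUE, FALSE, FALSE))
  roc <- roc_points(rows, list(candidates = c(0.35, 0.5, 0.95)))
  expect_equal(roc$sensitivity, c(0.5, 1, 1))
  expect_equal(roc$specificity, c(1, 1, 0))
  expect_error(roc_points(rows[rows$event, ], list(candidates = 0.5)), "ROC")
  set.seed(8)
  r2 <- random_rows(150)
  g <- make_candidate_grid(r2$pdc, "resolution", 0.01, 0.02)
  roc2 <- roc_points(r2, g)
  expect_true(all(diff(roc2$sensitivity) >= 0))
  expect_true(all(diff(roc2$specificity) <= 0))
  expect_true(all(roc2$sensitivity >= 0 & roc2$sensitivity <= 1))
})

test_that("Youden J and minimum distance follow their formulas", {
  roc <- data.frame(candidate = c(0.4, 0.6),
                    sensitivity = c(0.7, 1), specificity = c(0.6, 1))
  yj <- youden_threshold(roc[1, ])
  expect_equal(yj$statistic, 0.3)
  expect_equal(youden_threshold(roc)$statistic, 1)   # perfect point
  md <- min_distance_threshold(roc)
  expect_equal(md$statistic, 0)                      # d = 0 at (1, 1)
  expect_equal(min_distance_threshold(
    data.frame(candidate = 0.5, sensitivity = 0.8, specificity = 0.9))$statistic,
    sqrt(0.05))
  # J = 1 exactly when d = 0 on the same point
  J <- roc$sensitivity + roc$specificity - 1
  d <- sqrt((1 - roc$sensitivity)^2 + (1 - roc$specificity)^2)
  expect_equal(J == 1, d == 0)
})

test_that("selected thresholds equal exhaustive enumeration on random data", {
  set.seed(9)
  for (i in 1:10) {
    rows <- random_rows(200)
    g <- make_candidate_grid(rows$pdc, "resolution", 0.02, 0.05)
    cp <- estimate_cutpoints(rows, g)
    ss <- t(vapply(g$candidates, function(c) oracle_sens_spec(rows, c),
                   c(sn = 0, sp = 0)))
    J <- ss[, "sn"] + ss[, "sp"] - 1
    d <- sqrt((1 - ss[, "sn"])^2 + (1 - ss[, "sp"])^2)
    expect_equal(cp$youden$threshold, g$candidates[which.max(J)])
    expect_equal(cp$min_distance$threshold, g$candidates[which.min(d)])
    U <- vapply(g$candidates, function(c) oracle_logrank_U(rows, c), 0)
    expect_equal(cp$contal$result$threshold, g$candidates[which.max(abs(U))])
  }
})

test_that("flipping the direction of the positive call reflects the scan", {
  set.seed(10)
  rows <- random_rows(120)
  rows$pdc <- runif(120)    # continuous: no mass exactly on a candidate
  g <- make_candidate_grid(rows$pdc, "resolution", 0.05, 0.05)
  sc <- contal_oquigley_scan(rows, g)
  roc <- roc_points(rows, g)
  flipped <- rows
  flipped$pdc <- 1 - rows$pdc
  gf <- list(candidates = rev(1 - g$candidates))
  scf <- contal_oquigley_scan(flipped, gf)
  rocf <- roc_points(flipped, gf)
  # grouping pdc < c maps to (1 - pdc) >= 1 - c: |U| is label-antisymmetric
  expect_equal(rev(abs(scf$scan$U)), abs(sc$scan$U))
  expect_equal(rev(scf$scan$U), -sc$scan$U)
  # and the ROC reflects: Sn <-> Sp
  expect_equal(rev(rocf$sensitivity), 1 - roc$sensitivity)
  expect_equal(rev(rocf$specificity), 1 - roc$specificity)
})
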