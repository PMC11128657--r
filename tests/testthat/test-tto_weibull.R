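make_tto_caseset <- function(start_dt, event_dt) {
  n <- length(start_dt)
  ids <- as.character(seq_len(n))
  demo <- data.table::data.table(primaryid = ids)
  ev <- parse_date(event_dt)
  demo[, event_completeness := ev$completeness]
  demo[, event_date := ev$date]
  drugs <- data.table::data.table(primaryid = ids, drugname = "BENDAMUSTINE",
                                  role_cod = "PS", start_dt = start_dt)
  reac <- data.table::data.table(primaryid = ids, pt = "Pyrexia")
  extract_cases(faers_corpus(demo, drugs, reac))
}

test_that("onset is the day difference from earliest complete start; exclusions flagged", {
  cs <- make_tto_caseset(
    start_dt = c("20230101", "202301", "20230110", "20230101"),
    event_dt = c("20230114", "20230114", "20230105", "202302"))
  rec <- compute_tto(cs)
  expect_equal(rec[primaryid == "1", onset_days], 13L)
  expect_true(rec[primaryid == "1", included])
  expect_equal(rec[primaryid == "2", exclusion_reason], "incomplete_start")
  expect_equal(rec[primaryid == "3", exclusion_reason], "negative_tto")
  expect_equal(rec[primaryid == "4", exclusion_reason], "incomplete_event")
  expect_true(all(rec$included == (rec$exclusion_reason == "none")))
  # several target rows: the earliest complete start wins
  demo <- data.table::data.table(primaryid = "1",
                                 event_completeness = "full",
                                 event_date = as.Date("2023-01-20"))
  drugs <- data.table::data.table(primaryid = "1", drugname = "BENDAMUSTINE",
                                  role_cod = "PS",
                                  start_dt = c("20230115", "20230105", "202301"))
  reac <- data.table::data.table(primaryid = "1", pt = "Pyrexia")
  cs2 <- extract_cases(faers_corpus(demo, drugs, reac))
  expect_equal(compute_tto(cs2)$onset_days, 15L)
})

test_that("exclusions partition the synthetic cohort exactly as the manifest says", {
  sh <- shared_synth()
  rec <- compute_tto(sh$caseset)
  expect_equal(nrow(rec), nrow(sh$caseset$demo))
  expect_equal(sum(rec$included) + sum(!rec$included), nrow(rec))
  truth <- sh$manifest$onsets[caseid %in% sh$caseset$demo$caseid]
  expect_equal(sum(rec$included), sum(truth$expected_included))
  # included onset values equal the generator's true draws
  merged <- merge(rec, sh$caseset$demo[, .(primaryid, caseid)], by = "primaryid")
  merged <- merge(merged[included == TRUE], sh$manifest$onsets, by = "caseid")
  expect_equal(merged$onset_days.x, merged$onset_days.y)
})

test_that("summary statistics, monthly bins and ECDF", {
  rec <- data.table::data.table(primaryid = c("1", "2", "3"), soc = NA_character_,
                                onset_days = c(0L, 13L, 59L), included = TRUE,
                                exclusion_reason = "none")
  s <- summarize_tto(rec)
  expect_equal(s$median, 13)
  expect_equal(s$q1, 6.5)      # type-7 quartiles on three points
  expect_equal(s$q3, 36)
  expect_equal(s$min, 0); expect_equal(s$max, 59)
  expect_equal(s$bins[bin == "month 1", count], 2L)
  expect_equal(s$bins[bin == "month 2", count], 1L)
  expect_equal(s$ecdf$cum_prop, c(1 / 3, 2 / 3, 1))
  # all-equal sample: IQR width zero
  rec2 <- data.table::copy(rec)[, onset_days := 7L]
  s2 <- summarize_tto(rec2)
  expect_equal(s2$q3 - s2$q1, 0)
  # >1 year bin is strictly beyond 365 days
  rec3 <- data.table::data.table(primaryid = as.character(1:3), soc = NA,
                                 onset_days = c(365L, 366L, 400L),
                                 included = TRUE, exclusion_reason = "none")
  s3 <- summarize_tto(rec3)
  expect_equal(s3$bins[bin == ">1 year", count], 2L)
})

test_that("Weibull MLE matches a brute-force grid search on a small sample", {
  set.seed(31)
  x <- rweibull(50, shape = 0.8, scale = 20)
  fit <- weibull_mle(x)
  ll <- function(al, be) sum(dweibull(x, shape = be, scale = al, log = TRUE))
  grid <- expand.grid(al = seq(5, 60, length.out = 120),
                      be = seq(0.3, 2, length.out = 120))
  grid$ll <- mapply(ll, grid$al, grid$be)
  best <- grid[which.max(grid$ll), ]
  expect_lt(abs(fit$alpha - best$al), diff(range(grid$al)) / 119 * 2)
  expect_lt(abs(fit$beta - best$be), diff(range(grid$be)) / 119 * 2)
  expect_gte(fit$loglik, best$ll)
})

test_that("Weibull MLE agrees with fitdistrplus and handles the exponential case", {
  skip_if_not_installed("fitdistrplus")
  set.seed(32)
  x <- rweibull(400, shape = 0.76, scale = 30)
  fit <- weibull_mle(x)
  ref <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(fit$beta, unname(ref$estimate["shape"]), tolerance = 2e-3)
  expect_equal(fit$alpha, unname(ref$estimate["scale"]), tolerance = 2e-3)
  set.seed(33)
  e <- rweibull(2000, shape = 1, scale = 10)
  expect_true(abs(weibull_mle(e)$beta - 1) < 0.05)
})

test_that("scale equivariance and degenerate-input contracts", {
  set.seed(34)
  x <- rweibull(200, shape = 0.9, scale = 15)
  f1 <- weibull_mle(x)
  f2 <- weibull_mle(x * 3)
  expect_equal(f2$alpha / f1$alpha, 3, tolerance = 1e-5)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
  expect_error(weibull_mle(rep(5, 50)), "identical")
  expect_error(weibull_mle(rweibull(5, 1, 1)), "at least 10")
  expect_error(weibull_mle(c(rep(0, 20), 1)), "shift")
})

test_that("repeated simulation recovers the shape with small bias", {
  for (bt in c(0.6, 0.8, 1.0, 1.3)) {
    set.seed(round(1000 + bt * 10))
    bhat <- replicate(200, weibull_mle(rweibull(300, shape = bt, scale = 30))$beta)
    expect_lt(abs(mean(bhat) - bt), 0.03)
  }
})

test_that("hazard classification follows the shape CI rule", {
  mk <- function(beta, lo, hi) {
    structure(list(alpha = 10, beta = beta,
                   ci95_beta = c(lower = lo, upper = hi),
                   converged = TRUE), class = "weibull_fit")
  }
  expect_equal(classify_hazard(mk(0.74, 0.68, 0.80)), "early_failure")
  expect_equal(classify_hazard(mk(1.0, 0.9, 1.1)), "constant")
  expect_equal(classify_hazard(mk(1.4, 1.2, 1.6)), "late_failure")
})

test_that("fitted median is consistent with the sample median on clean simulations", {
  set.seed(35)
  x <- rweibull(1500, shape = 0.8, scale = 40)
  f <- weibull_mle(x)
  fitted_median <- f$alpha * log(2)^(1 / f$beta)
  boot <- replicate(200, median(sample(x, replace = TRUE)))
  expect_gt(fitted_median, quantile(boot, 0.005))
  expect_lt(fitted_median, quantile(boot, 0.995))
})

test_that("per-SOC fits classify synthetic decreasing-hazard onsets as early failure", {
  sh <- shared_synth()
  rec <- compute_tto(sh$caseset, sh$hierarchy)
  fits <- fit_tto_weibull(rec)
  big <- fits[n >= 25 & !is.na(beta)]
  expect_gt(nrow(big), 0)
  # generator draws onsets with shape 0.8 < 1
  expect_true(all(big$beta < 1.3))
  expect_true(all(big$beta_l <= big$beta & big$beta <= big$beta_u))
})
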