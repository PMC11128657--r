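# Time-to-onset extraction and Weibull hazard-shape analysis.
#
# Only fully dated records enter the analysis: onset is computed from
# the earliest complete (YYYYMMDD) therapy-start date of a target-drug
# row to the complete event date; partially dated and
# event-before-start records are flagged with an exclusion reason,
# never silently dropped.

#' Compute time-to-onset records for a case set
#'
#' @param caseset a target-drug `case_set`.
#' @param hierarchy optional [read_hierarchy()] table; when supplied,
#'   each included report is expanded to one record per distinct
#'   primary SOC of its reaction PTs (a report can contribute to
#'   several SOCs).
#' @return data.table with columns `primaryid`, `soc` (NA when no
#'   hierarchy is given), `onset_days`, `included`, `exclusion_reason`
#'   (`"none"`, `"incomplete_start"`, `"incomplete_event"`,
#'   `"negative_tto"`).
#' @export
compute_tto <- function(caseset, hierarchy = NULL) {
  stopifnot(inherits(caseset, "case_set"))
  demo <- caseset$demo
  d <- caseset$drugs
  m <- match_target(d$drugname_norm, caseset$target)
  if (!identical(caseset$role, "any")) {
    m <- m & toupper(trimws(d$role_cod)) %in% caseset$role
  }
  td <- d[m]
  st <- parse_date(td$start_dt)
  td[, start_date := st$date]
  starts <- td[!is.na(start_date), .(start_date = min(start_date)), by = primaryid]

  rec <- data.table::data.table(primaryid = demo$primaryid,
                                event_completeness = demo$event_completeness,
                                event_date = demo$event_date)
  rec <- merge(rec, starts, by = "primaryid", all.x = TRUE, sort = FALSE)
  rec[, onset_days := NA_integer_]
  rec[, exclusion_reason := "none"]
  rec[is.na(start_date), exclusion_reason := "incomplete_start"]
  rec[exclusion_reason == "none" & event_completeness != "full",
      exclusion_reason := "incomplete_event"]
  ok <- rec$exclusion_reason == "none"
  rec[ok, onset_days := as.integer(event_date - start_date)]
  rec[ok & onset_days < 0, `:=`(exclusion_reason = "negative_tto",
                                onset_days = NA_integer_)]
  rec[, included := exclusion_reason == "none"]
  rec[, c("event_completeness", "event_date", "start_date") := NULL]

  if (!is.null(hierarchy)) {
    socs <- report_soc_pairs(caseset$reactions, hierarchy)
    rec <- merge(socs, rec, by = "primaryid", allow.cartesian = TRUE)
  } else {
    rec[, soc := NA_character_]
  }
  data.table::setcolorder(rec, c("primaryid", "soc", "onset_days",
                                 "included", "exclusion_reason"))
  rec[]
}

#' Summarize time-to-onset records
#'
#' Median and IQR (type-7 quantiles), per-30-day bins for treatment
#' months 1–12 plus a ">1 year" bin, and the empirical CDF.  Month 1
#' is days 0–30 inclusive; month m covers days `(30(m-1), 30m]`
#' (month 12 extends to day 365); ">1 year" is strictly beyond 365
#' days.  Percentages use the half-up rule of [report_pct()].
#'
#' @param records a [compute_tto()] table (records with `soc`
#'   duplicates should be de-duplicated by the caller if a per-report
#'   summary is wanted; pass the `hierarchy = NULL` form for that).
#' @return list of class `tto_summary`: `n`, `median`, `q1`, `q3`,
#'   `min`, `max`, `bins` (data.table bin/count/pct) and `ecdf`
#'   (data.table days/cum_prop).
#' @export
summarize_tto <- function(records) {
  d <- records[included == TRUE, onset_days]
  stopifnot(length(d) >= 1)
  qs <- quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  edges_lo <- c(-1, seq(30, 330, by = 30), 365)           # month bins + >1y
  edges_hi <- c(seq(30, 330, by = 30), 365, Inf)
  labs <- c(sprintf("month %d", 1:12), ">1 year")
  counts <- vapply(seq_along(labs), function(i) {
    sum(d > edges_lo[i] & d <= edges_hi[i])
  }, integer(1))
  bins <- data.table::data.table(bin = labs, count = counts,
                                 pct = report_pct(counts, length(d)))
  ud <- sort(unique(d))
  ec <- data.table::data.table(days = ud,
                               cum_prop = vapply(ud, function(x) mean(d <= x), numeric(1)))
  structure(list(n = length(d), median = qs[2], q1 = qs[1], q3 = qs[3],
                 min = min(d), max = max(d), bins = bins, ecdf = ec),
            class = "tto_summary")
}

#' @export
print.tto_summary <- function(x, ...) {
  cat(sprintf("<tto_summary> n=%d | median %.0f (IQR %.0f-%.0f) | range %d-%d days\n",
              x$n, x$median, x$q1, x$q3, x$min, x$max))
  print(x$bins)
  invisible(x)
}

#' Two-parameter Weibull fit by maximum likelihood
#'
#' Fits scale `alpha` and shape `beta` by unconstrained BFGS on the
#' log-parameters.  For day-resolution onset data containing zeros set
#' `shift` (e.g. 0.5) — the interval-midpoint treatment — since a
#' continuous Weibull with `beta < 1` has unbounded density at 0.  The
#' shape CI is the observed-information normal approximation on the
#' log scale (hence always positive).
#'
#' @param x positive (after shifting) observation vector, `n >= 10`.
#' @param shift constant added to every observation before fitting.
#' @param conf confidence level of the shape CI.
#' @return object of class `weibull_fit`: `alpha`, `beta`,
#'   `ci95_beta` (lower/upper), `se_log_beta`, `loglik`, `n`, `shift`,
#'   `converged`.
#' @export
weibull_mle <- function(x, shift = 0, conf = 0.95) {
  x <- x[is.finite(x)]
  if (length(x) < 10) {
    stop(sprintf("need at least 10 observations to fit (got %d)", length(x)),
         call. = FALSE)
  }
  t <- x + shift
  if (any(t <= 0)) {
    stop("non-positive times after shifting; increase 'shift'", call. = FALSE)
  }
  if (sd(log(t)) < 1e-12) {
    stop("degenerate sample: all times identical; the Weibull likelihood is unbounded",
         call. = FALSE)
  }
  negll <- function(th) {
    -sum(dweibull(t, shape = exp(th[2]), scale = exp(th[1]), log = TRUE))
  }
  # moment-style start: shape from the log-time spread, scale from the mean
  th0 <- c(log(mean(t)), log(min(50, max(0.05, 1.2 / sd(log(t))))))
  opt <- optim(th0, negll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  opt2 <- tryCatch(optim(opt$par, negll, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-12)),
                   error = function(e) opt)
  if (opt2$value <= opt$value) opt <- opt2
  if (opt$convergence != 0) {
    stop(sprintf("Weibull MLE did not converge (optim code %d, negll %.4f)",
                 opt$convergence, opt$value), call. = FALSE)
  }
  H <- optimHess(opt$par, negll)
  cov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 2, 2))
  se_log_beta <- sqrt(cov[2, 2])
  z <- qnorm(1 - (1 - conf) / 2)
  beta <- exp(opt$par[2])
  alpha <- exp(opt$par[1])
  ci <- c(lower = beta * exp(-z * se_log_beta),
          upper = beta * exp(z * se_log_beta))
  structure(list(alpha = alpha, beta = beta, ci95_beta = ci,
                 se_log_beta = se_log_beta, loglik = -opt$value,
                 n = length(t), shift = shift, converged = TRUE),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("<weibull_fit> n=%d | scale %.3f | shape %.3f (95%% CI %.3f-%.3f) | %s\n",
              x$n, x$alpha, x$beta, x$ci95_beta[1], x$ci95_beta[2],
              classify_hazard(x)))
  invisible(x)
}

#' Classify the hazard shape of a Weibull fit
#'
#' Confidence-interval rule on the shape parameter: `early_failure`
#' (decreasing hazard) when the CI upper bound is below 1;
#' `late_failure` (increasing hazard) when the lower bound exceeds 1;
#' `constant` otherwise.
#'
#' @param fit a [weibull_mle()] result.
#' @return one of `"early_failure"`, `"constant"`, `"late_failure"`.
#' @export
classify_hazard <- function(fit) {
  stopifnot(inherits(fit, "weibull_fit"), isTRUE(fit$converged))
  if (fit$ci95_beta[["upper"]] < 1) "early_failure"
  else if (fit$ci95_beta[["lower"]] > 1) "late_failure"
  else "constant"
}

#' Per-SOC time-to-onset summaries and Weibull fits
#'
#' Groups included records by SOC and produces, per group with at
#' least `min_n` records, the onset summary plus the shifted Weibull
#' fit and its hazard classification; smaller groups are reported with
#' NA fit columns.
#'
#' @param records a [compute_tto()] table with a `soc` column.
#' @param shift day shift applied before fitting (default 0.5, the
#'   interval-midpoint treatment of day-resolution data).
#' @param min_n minimum group size to attempt a fit.
#' @return data.table with one row per SOC: `soc`, `n`, `median`,
#'   `q1`, `q3`, `min`, `max`, `alpha`, `beta`, `beta_l`, `beta_u`,
#'   `hazard_class`.
#' @export
fit_tto_weibull <- function(records, shift = 0.5, min_n = 10) {
  inc <- records[included == TRUE & !is.na(soc)]
  stopifnot(nrow(inc) >= 1)
  one <- function(d) {
    qs <- quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    base <- list(n = length(d), median = qs[2], q1 = qs[1], q3 = qs[3],
                 min = min(d), max = max(d))
    fit <- if (length(d) >= min_n) {
      tryCatch(weibull_mle(d, shift = shift), error = function(e) NULL)
    }
    if (is.null(fit)) {
      c(base, list(alpha = NA_real_, beta = NA_real_, beta_l = NA_real_,
                   beta_u = NA_real_, hazard_class = NA_character_))
    } else {
      c(base, list(alpha = fit$alpha, beta = fit$beta,
                   beta_l = fit$ci95_beta[["lower"]],
                   beta_u = fit$ci95_beta[["upper"]],
                   hazard_class = classify_hazard(fit)))
    }
  }
  out <- inc[, one(onset_days), by = soc]
  out[order(-n)]
}
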