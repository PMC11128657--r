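# Case/non-case disproportionality analysis on drug-event 2x2 tables.
#
# Cell convention (counting unit = unique deduplicated report):
#   a  reports with the target drug AND the event term
#   b  reports with the target drug, other events
#   c  reports with other drugs and the event term
#   d  reports with other drugs, other events
# N = a+b+c+d is the whole deduplicated corpus.

#' Build drug-event contingency tables
#'
#' One 2x2 table per event term (PT, or primary SOC when `level =
#' "soc"`) that occurs at least once in the case set.  A report
#' carrying a term several times counts once; at SOC level a report
#' contributes one count to each SOC its PTs map to.
#'
#' @param caseset the target-drug [extract_cases()] result.
#' @param corpus the full deduplicated background [faers_corpus()];
#'   the case set must be a subset of it.
#' @param level `"pt"` or `"soc"`.
#' @param hierarchy required for `level = "soc"`; a [read_hierarchy()]
#'   table.
#' @return data.table with columns `term`, `a`, `b`, `c_`, `d`, `N`
#'   (`c_` because `c` collides with the base function).
#' @export
build_tables <- function(caseset, corpus, level = c("pt", "soc"), hierarchy = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(caseset, "case_set"), inherits(corpus, "faers_corpus"))
  target_ids <- caseset$demo$primaryid
  all_ids <- corpus$demo$primaryid
  if (!all(target_ids %in% all_ids)) {
    stop("case set contains reports absent from the background corpus", call. = FALSE)
  }
  N <- length(all_ids)
  n_t <- length(target_ids)

  ev <- if (level == "pt") {
    unique(corpus$reactions[, .(primaryid, term = toupper(trimws(pt)))])
  } else {
    if (is.null(hierarchy)) stop("'hierarchy' is required for level = \"soc\"", call. = FALSE)
    data.table::setnames(report_soc_pairs(corpus$reactions, hierarchy),
                         "soc", "term")
  }
  ev[, is_target := primaryid %in% target_ids]
  tot <- ev[, .(n_event = .N, a = sum(is_target)), by = term]
  tab <- tot[a >= 1]
  tab[, `:=`(b = n_t - a, c_ = n_event - a)]
  tab[, d := N - n_t - c_]
  tab[, n_event := NULL]
  tab[, N := N]
  data.table::setcolorder(tab, c("term", "a", "b", "c_", "d", "N"))
  tab[]
}

# Haldane-Anscombe: add 0.5 to every cell when any cell is zero
.haldane <- function(a, b, c_, d) {
  a <- as.numeric(a); b <- as.numeric(b); c_ <- as.numeric(c_); d <- as.numeric(d)
  corrected <- a == 0 | b == 0 | c_ == 0 | d == 0
  add <- ifelse(corrected, 0.5, 0)
  list(a = a + add, b = b + add, c_ = c_ + add, d = d + add, corrected = corrected)
}

#' Reporting odds ratio with log-normal 95% CI
#'
#' `ROR = ad / bc`; `CI = exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Tables with a zero cell receive the Haldane–Anscombe 0.5 correction
#' on every cell and are flagged.
#'
#' @param a,b,c_,d cell counts (vectors of equal length).
#' @param conf confidence level (default 0.95).
#' @return data.table with columns `ror`, `ror_l`, `ror_u`, `corrected`.
#' @export
ror_ci <- function(a, b, c_, d, conf = 0.95) {
  h <- .haldane(a, b, c_, d)
  z <- qnorm(1 - (1 - conf) / 2)
  ror <- (h$a * h$d) / (h$b * h$c_)
  se <- sqrt(1 / h$a + 1 / h$b + 1 / h$c_ + 1 / h$d)
  data.table::data.table(ror = ror,
                         ror_l = exp(log(ror) - z * se),
                         ror_u = exp(log(ror) + z * se),
                         corrected = h$corrected)
}

#' Proportional reporting ratio and Yates chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`.  The chi-squared statistic is the
#' Yates-continuity-corrected Pearson statistic on the uncorrected 2x2
#' (the convention the PRR>=2 & chi2>=4 & n>=3 criterion descends
#' from); set `yates = FALSE` for the plain Pearson statistic.  PRR on
#' tables with a zero cell uses the Haldane–Anscombe correction.
#'
#' @param a,b,c_,d cell counts.
#' @param yates logical, apply the continuity correction.
#' @return data.table with columns `prr`, `chi2`.
#' @export
prr_chi2 <- function(a, b, c_, d, yates = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b); c_ <- as.numeric(c_); d <- as.numeric(d)
  h <- .haldane(a, b, c_, d)
  prr <- (h$a / (h$a + h$b)) / (h$c_ / (h$c_ + h$d))
  N <- a + b + c_ + d
  delta <- abs(a * d - b * c_)
  if (yates) delta <- pmax(0, delta - N / 2)
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chi2 <- ifelse(denom > 0, N * delta^2 / denom, 0)
  data.table::data.table(prr = prr, chi2 = chi2)
}

#' BCPNN information component with lower credibility bound
#'
#' `IC = log2((a + 0.5) / (E + 0.5))` with `E = (a+b)(a+c)/N`, the
#' expected count under row–column independence.  The default lower
#' bound is the closed-form approximation to the 2.5th percentile of
#' the gamma posterior,
#' `IC - 3.3 (a+0.5)^{-1/2} - 2 (a+0.5)^{-3/2}`;
#' `method = "quantile"` instead evaluates the exact posterior
#' quantile of `log2(lambda)` with
#' `lambda ~ Gamma(shape = a + 0.5, rate = E + 0.5)` at probability
#' `quantile` (2.5% or 5% are the conventions in use).
#'
#' @param a,b,c_,d cell counts.
#' @param method `"approx"` (closed form) or `"quantile"` (exact gamma).
#' @param quantile lower-tail probability for `method = "quantile"`.
#' @return data.table with columns `E`, `ic`, `ic_lower`.
#' @export
bcpnn_ic <- function(a, b, c_, d, method = c("approx", "quantile"), quantile = 0.025) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b); c_ <- as.numeric(c_); d <- as.numeric(d)
  N <- a + b + c_ + d
  E <- (a + b) * (a + c_) / N
  ic <- log2((a + 0.5) / (E + 0.5))
  ic_lower <- if (method == "approx") {
    ic - 3.3 * (a + 0.5)^(-1 / 2) - 2 * (a + 0.5)^(-3 / 2)
  } else {
    log2(qgamma(quantile, shape = a + 0.5, rate = E + 0.5))
  }
  data.table::data.table(E = E, ic = ic, ic_lower = ic_lower)
}

#' Signal thresholds of the combined criterion
#'
#' Defaults encode the conventional conjunction: PRR of at least 2, a
#' chi-squared of at least 4, at least 3 reported cases, IC lower
#' bound strictly above 0, and EBGM strictly above 2.
#'
#' @param prr_min,chi2_min,n_min,ic_lower_min,ebgm_min numeric thresholds.
#' @return list of class `signal_thresholds`.
#' @export
signal_thresholds <- function(prr_min = 2, chi2_min = 4, n_min = 3,
                              ic_lower_min = 0, ebgm_min = 2) {
  th <- list(prr_min = prr_min, chi2_min = chi2_min, n_min = n_min,
             ic_lower_min = ic_lower_min, ebgm_min = ebgm_min)
  stopifnot(all(vapply(th, is.finite, logical(1))))
  structure(th, class = "signal_thresholds")
}

#' Apply the combined signal criterion
#'
#' Adds per-criterion flags and the conjunction `is_signal` to a
#' statistics table.  Boundary semantics follow the wording "at least"
#' for PRR, chi-squared and case count (`>=`) and strict `>` for the
#' IC lower bound and EBGM.
#'
#' @param stats data.table containing columns `a`, `prr`, `chi2`,
#'   `ic_lower`, `ebgm`.
#' @param thresholds a [signal_thresholds()] object.
#' @return the input with logical columns `prr_flag`, `chi2_flag`,
#'   `n_flag`, `ic_flag`, `ebgm_flag`, `is_signal` appended.
#' @export
evaluate_signal <- function(stats, thresholds = signal_thresholds()) {
  s <- data.table::as.data.table(stats)
  th <- thresholds
  s[, `:=`(
    prr_flag = prr >= th$prr_min,
    chi2_flag = chi2 >= th$chi2_min,
    n_flag = a >= th$n_min,
    ic_flag = ic_lower > th$ic_lower_min,
    ebgm_flag = ebgm > th$ebgm_min
  )]
  s[, is_signal := prr_flag & chi2_flag & n_flag & ic_flag & ebgm_flag]
  s[]
}

#' Full disproportionality screen for one case set
#'
#' Builds the contingency tables, computes the four statistics (ROR
#' with 95% CI, PRR with Yates chi-squared, BCPNN IC with lower bound,
#' EBGM/EB05 under a gamma-mixture prior fitted across all drug–event
#' pairs of the corpus unless one is supplied), and applies the
#' combined criterion.
#'
#' @param caseset target-drug case set.
#' @param corpus background corpus.
#' @param level `"pt"` or `"soc"`.
#' @param hierarchy needed for SOC level, or to annotate PT rows with
#'   their primary SOC.
#' @param thresholds a [signal_thresholds()].
#' @param prior optional pre-fitted [fit_gps_prior()] object.
#' @param ic_method,ic_quantile passed to [bcpnn_ic()].
#' @return data.table, one row per term, with counts, all statistics,
#'   flags and `is_signal`; attribute `"prior"` carries the GPS prior.
#' @export
compute_signals <- function(caseset, corpus, level = c("pt", "soc"),
                            hierarchy = NULL,
                            thresholds = signal_thresholds(),
                            prior = NULL,
                            ic_method = "approx", ic_quantile = 0.025) {
  level <- match.arg(level)
  tab <- build_tables(caseset, corpus, level, hierarchy)
  if (!nrow(tab)) return(tab)
  res <- cbind(tab,
               ror_ci(tab$a, tab$b, tab$c_, tab$d),
               prr_chi2(tab$a, tab$b, tab$c_, tab$d),
               bcpnn_ic(tab$a, tab$b, tab$c_, tab$d,
                        method = ic_method, quantile = ic_quantile))
  if (is.null(prior)) {
    pairs <- all_pair_counts(corpus)
    prior <- fit_gps_prior(pairs$a, pairs$E)
  }
  res <- cbind(res, posterior_ebgm(res$a, res$E, prior))
  if (level == "pt" && !is.null(hierarchy)) {
    res[, soc := suppressWarnings(pt_to_soc(term, hierarchy))]
  }
  res <- evaluate_signal(res, thresholds)
  data.table::setattr(res, "prior", prior)
  res[]
}

#' Rank evaluated signals
#'
#' Emits the two conventional orderings of a signal table: by number
#' of reports (`by_count`) and by the ROR 95% CI lower bound
#' (`by_ror_lower`), each in descending order, ties broken by the
#' other ranking's statistic (stable sort), truncated to `k` rows.
#'
#' @param signals an evaluated signal table.
#' @param k rows to keep per ranking (the full table when larger).
#' @param signals_only rank only rows with `is_signal = TRUE`
#'   (default); set `FALSE` to rank everything.
#' @return list with data.tables `by_count` and `by_ror_lower`.
#' @export
rank_top <- function(signals, k = 30, signals_only = TRUE) {
  s <- data.table::as.data.table(signals)
  if (signals_only && "is_signal" %in% names(s)) s <- s[is_signal == TRUE]
  by_count <- s[order(-a, -ror_l)]
  by_lower <- s[order(-ror_l, -a)]
  list(by_count = head(by_count, k), by_ror_lower = head(by_lower, k))
}
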