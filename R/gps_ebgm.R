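# Multi-item-free gamma-Poisson shrinker (MGPS).  The relative
# reporting rate lambda of each drug-event pair is modelled as a draw
# from a two-component gamma mixture
#     lambda ~ w Gamma(alpha1, beta1) + (1-w) Gamma(alpha2, beta2)
# (shape/rate), with a | lambda ~ Poisson(lambda E).  Marginally a is
# a mixture of negative binomials, which gives the likelihood the
# prior is fitted on; the posterior is again a gamma mixture with
# component j updated to Gamma(alpha_j + a, beta_j + E) and weights
# proportional to w_j * NB_j(a).

#' Expected counts under drug-event independence
#'
#' `E = (a+b)(a+c)/N`: the count expected for a pair if the drug and
#' event margins were independent.  Used by both the IC and the EBGM.
#'
#' @param a,b,c_,d cell counts.
#' @return numeric vector of expected counts.
#' @export
expected_counts <- function(a, b, c_, d) {
  a <- as.numeric(a); b <- as.numeric(b); c_ <- as.numeric(c_); d <- as.numeric(d)
  (a + b) * (a + c_) / (a + b + c_ + d)
}

#' Observed/expected counts for every drug-event pair of a corpus
#'
#' The prior of the shrinker is fitted across *all* drug–event pairs,
#' not only the target drug's: for each (normalized drug name, PT)
#' pair observed in the corpus this returns the number of distinct
#' reports containing both (`a`) and the independence expectation
#' `E = n_drug * n_pt / N`.
#'
#' @param corpus a [faers_corpus()].
#' @param min_a keep pairs with at least this many reports (default 1;
#'   the likelihood itself is untruncated).
#' @return data.table with columns `drug`, `pt`, `a`, `E`.
#' @export
all_pair_counts <- function(corpus, min_a = 1) {
  stopifnot(inherits(corpus, "faers_corpus"))
  N <- nrow(corpus$demo)
  dr <- unique(corpus$drugs[, .(primaryid, drug = drugname_norm)])
  re <- unique(corpus$reactions[, .(primaryid, pt = toupper(trimws(pt)))])
  n_drug <- dr[, .(n_drug = .N), by = drug]
  n_pt <- re[, .(n_pt = .N), by = pt]
  pairs <- merge(dr, re, by = "primaryid", allow.cartesian = TRUE)[
    , .(a = .N), by = .(drug, pt)]
  pairs <- merge(pairs, n_drug, by = "drug")
  pairs <- merge(pairs, n_pt, by = "pt")
  pairs[, E := as.numeric(n_drug) * n_pt / N]
  pairs[a >= min_a, .(drug, pt, a, E)]
}

.gps_untransform <- function(theta) {
  list(alpha1 = exp(theta[1]), beta1 = exp(theta[2]),
       alpha2 = exp(theta[3]), beta2 = exp(theta[4]),
       w = plogis(theta[5]))
}

.gps_negll <- function(theta, a, E, truncate) {
  p <- .gps_untransform(theta)
  # extreme trial parameters can underflow dnbinom; the resulting penalty
  # (floored likelihood) steers the search away without spurious warnings
  f1 <- suppressWarnings(dnbinom(a, size = p$alpha1, prob = p$beta1 / (p$beta1 + E)))
  f2 <- suppressWarnings(dnbinom(a, size = p$alpha2, prob = p$beta2 / (p$beta2 + E)))
  f1[!is.finite(f1)] <- 0; f2[!is.finite(f2)] <- 0
  lik <- p$w * f1 + (1 - p$w) * f2
  if (truncate) {
    p0 <- p$w * dnbinom(0, size = p$alpha1, prob = p$beta1 / (p$beta1 + E)) +
      (1 - p$w) * dnbinom(0, size = p$alpha2, prob = p$beta2 / (p$beta2 + E))
    lik <- lik / pmax(1 - p0, 1e-12)
  }
  -sum(log(pmax(lik, 1e-300)))
}

# fixed multi-start grid on the natural scale (alpha1,beta1,alpha2,beta2,w)
.gps_starts <- rbind(
  c(0.2, 0.1, 2, 4, 1 / 3),   # the classic spreadsheet start
  c(1, 1, 2, 2, 0.5),
  c(0.5, 0.5, 3, 1, 0.2),
  c(2, 2, 1, 0.5, 0.8),
  c(0.1, 0.1, 5, 2, 0.1)
)

#' Fit the two-component gamma mixture prior
#'
#' Maximizes the marginal (negative-binomial mixture) likelihood over
#' all supplied pairs by unconstrained quasi-Newton optimization on
#' log/logit-transformed parameters, from five fixed starting points;
#' the best converged optimum wins.  Deterministic: no randomness is
#' involved beyond the data.
#'
#' @param a observed pair counts.
#' @param E expected counts under independence (all > 0).
#' @param truncate use the zero-truncated likelihood (for inputs
#'   restricted to pairs with `a >= 1`); default `FALSE`.
#' @param maxit iteration cap per start.
#' @return object of class `gps_prior`: `alpha1`, `beta1`, `alpha2`,
#'   `beta2` (shape/rate, component 1 = smaller prior mean), `w`
#'   (weight of component 1), `loglik`, `converged`, `n_pairs`.
#' @export
fit_gps_prior <- function(a, E, truncate = FALSE, maxit = 2000) {
  stopifnot(length(a) == length(E), all(E > 0), all(a >= 0))
  if (length(a) < 10) {
    stop("too few pairs to fit a mixture prior (need >= 10)", call. = FALSE)
  }
  if (length(unique(a)) < 3) {
    stop("degenerate input: observed counts are (nearly) constant; the mixture prior is not identifiable",
         call. = FALSE)
  }
  best <- NULL
  for (i in seq_len(nrow(.gps_starts))) {
    st <- .gps_starts[i, ]
    theta0 <- c(log(st[1:4]), qlogis(st[5]))
    opt <- tryCatch(
      optim(theta0, .gps_negll, a = a, E = E, truncate = truncate,
            method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    # polish with BFGS from the simplex optimum
    opt2 <- tryCatch(
      optim(opt$par, .gps_negll, a = a, E = E, truncate = truncate,
            method = "BFGS", control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) opt)
    if (opt2$value <= opt$value) opt <- opt2
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    stop("gamma-mixture prior fit failed from every starting point", call. = FALSE)
  }
  p <- .gps_untransform(best$par)
  # order components by prior mean so component 1 is the null-like one
  if (p$alpha1 / p$beta1 > p$alpha2 / p$beta2) {
    p <- list(alpha1 = p$alpha2, beta1 = p$beta2,
              alpha2 = p$alpha1, beta2 = p$beta1, w = 1 - p$w)
  }
  structure(list(alpha1 = p$alpha1, beta1 = p$beta1,
                 alpha2 = p$alpha2, beta2 = p$beta2, w = p$w,
                 loglik = -best$value,
                 converged = best$convergence == 0,
                 n_pairs = length(a), truncate = truncate),
            class = "gps_prior")
}

#' @export
print.gps_prior <- function(x, ...) {
  cat(sprintf(
    "<gps_prior> w=%.3f | comp1 Gamma(%.3g, %.3g) mean %.3g | comp2 Gamma(%.3g, %.3g) mean %.3g\n",
    x$w, x$alpha1, x$beta1, x$alpha1 / x$beta1,
    x$alpha2, x$beta2, x$alpha2 / x$beta2))
  cat(sprintf("  loglik %.2f on %d pairs | converged: %s\n",
              x$loglik, x$n_pairs, x$converged))
  invisible(x)
}

#' Persist / restore a fitted prior as JSON
#'
#' @param prior a `gps_prior`.
#' @param path JSON file location.
#' @return `read_gps_prior` returns a `gps_prior`.
#' @export
write_gps_prior <- function(prior, path) {
  stopifnot(inherits(prior, "gps_prior"))
  jsonlite::write_json(unclass(prior), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gps_prior
#' @export
read_gps_prior <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(p, class = "gps_prior")
}

# posterior mixture weights (Q1) for each pair, on the log scale for stability
.gps_post_w <- function(a, E, prior) {
  l1 <- log(prior$w) + dnbinom(a, size = prior$alpha1,
                               prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  l2 <- log(1 - prior$w) + dnbinom(a, size = prior$alpha2,
                                   prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  m <- pmax(l1, l2)
  q1 <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
  q1
}

#' Posterior EBGM and EB05 for drug-event pairs
#'
#' Under the fitted prior the posterior of the reporting-rate ratio is
#' the updated gamma mixture; `EBGM = exp(E[ln lambda | a, E])` (the
#' posterior geometric mean, identical to `2^{E[log2 lambda]}`) and
#' `EB05` is the 5th posterior percentile, found by root-finding on
#' the mixture CDF (absolute tolerance 1e-6 relative to the bracket).
#'
#' @param a observed counts.
#' @param E expected counts.
#' @param prior a converged [fit_gps_prior()] object.
#' @param p lower-tail probability of the reported percentile (0.05).
#' @return data.table with columns `ebgm`, `eb05`.
#' @export
posterior_ebgm <- function(a, E, prior, p = 0.05) {
  stopifnot(inherits(prior, "gps_prior"), all(E > 0), length(a) == length(E))
  q1 <- .gps_post_w(a, E, prior)
  s1 <- prior$alpha1 + a; r1 <- prior$beta1 + E
  s2 <- prior$alpha2 + a; r2 <- prior$beta2 + E
  mean_log <- q1 * (digamma(s1) - log(r1)) + (1 - q1) * (digamma(s2) - log(r2))
  ebgm <- exp(mean_log)
  eb05 <- vapply(seq_along(a), function(i) {
    cdf <- function(q) {
      q1[i] * pgamma(q, shape = s1[i], rate = r1[i]) +
        (1 - q1[i]) * pgamma(q, shape = s2[i], rate = r2[i]) - p
    }
    lo <- min(qgamma(p, shape = s1[i], rate = r1[i]),
              qgamma(p, shape = s2[i], rate = r2[i]))
    hi <- max(qgamma(p, shape = s1[i], rate = r1[i]),
              qgamma(p, shape = s2[i], rate = r2[i]))
    if (hi - lo < 1e-12 || cdf(lo) >= 0) return(lo)
    if (cdf(hi) <= 0) return(hi)
    uniroot(cdf, lower = lo, upper = hi, tol = 1e-6 * max(1, hi))$root
  }, numeric(1))
  data.table::data.table(ebgm = ebgm, eb05 = eb05)
}
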