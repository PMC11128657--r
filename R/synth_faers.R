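# Deterministic synthetic spontaneous-report generator.
#
# Emits DEMO/DRUG/REAC/THER/OUTC files in the quarterly "$" dialect
# plus a ground-truth manifest, so ingestion, deduplication, cohort
# extraction, disproportionality and time-to-onset stages can all be
# checked against exact known answers.  All randomness flows from one
# seed through R's default Mersenne-Twister stream in a fixed draw
# order, so a (config, seed) pair regenerates the corpus and manifest
# bit-identically on any platform.

#' Configuration of the synthetic report generator
#'
#' Defaults emulate a seven-year slice of a spontaneous-report
#' database: skewed (Zipf-like) drug and event reporting frequencies,
#' an elderly oncology-type age distribution, male-predominant
#' reporting, a handful of reporting countries, mostly-professional
#' reporters, about a quarter of reports with a serious outcome,
#' decreasing-hazard (shape < 1) onset kinetics, partially missing
#' dates, and a fraction of cases submitted twice as revised versions.
#'
#' @param n_reports number of unique cases to simulate.
#' @param seed integer seed (mandatory).
#' @param hierarchy a [read_hierarchy()] table; its PTs form the event
#'   universe and their primary SOCs drive onset sampling.
#' @param n_drugs number of background drug names.
#' @param target a [drug_dictionary()]; reports naming the target use
#'   a synonym drawn from it.
#' @param target_prob probability a report contains the target drug.
#' @param ps_prob probability the target is primary suspect when present.
#' @param drugs_per_report_lambda Poisson mean of *additional*
#'   background drugs per report (each report has at least one drug).
#' @param pts_per_report_lambda Poisson mean of additional PTs per
#'   report (at least one).
#' @param injected_pairs NULL, or a data.frame with columns `pt` and
#'   `rho` (and optionally `drug`, default the target): for reports
#'   where that drug is primary suspect the conditional probability of
#'   the PT is multiplied by `rho` and the PT weights renormalized.
#' @param age_mean,age_sd,age_missing age model (years; truncated at
#'   0.5/100).
#' @param sex_probs named probabilities for `M`, `F`, `UNK`, `missing`.
#' @param country_probs named country weights (a `missing` entry is
#'   allowed).
#' @param reporter_probs named weights over occupation codes
#'   (`MD`, `PH`, `CN`, `HP`, `OT`, `missing`).
#' @param severe_prob probability a report carries a serious outcome.
#' @param outcome_probs named weights over outcome codes given serious.
#' @param tto_alpha,tto_beta default Weibull scale (days) and shape of
#'   onset times.
#' @param tto_spec optional data.frame `soc`, `alpha`, `beta`
#'   overriding the default per SOC.
#' @param missing_date_fraction fraction of reports whose therapy
#'   start (and, independently, event) date is blanked or truncated.
#' @param negative_tto_fraction fraction of reports written with the
#'   event dated before therapy start (data-entry errors).
#' @param duplicate_fraction fraction of cases emitted twice, as
#'   caseversion 1 and a revising caseversion 2.
#' @param start_date,end_date therapy-start window (YYYY-MM-DD text).
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_reports = 10000,
                         seed,
                         hierarchy = read_hierarchy(),
                         n_drugs = 40,
                         target = drug_dictionary(),
                         target_prob = 0.05,
                         ps_prob = 0.8,
                         drugs_per_report_lambda = 1.5,
                         pts_per_report_lambda = 1.0,
                         injected_pairs = NULL,
                         age_mean = 63, age_sd = 16, age_missing = 0.18,
                         sex_probs = c(M = 0.52, F = 0.38, UNK = 0.02, missing = 0.08),
                         country_probs = c(US = 0.30, JP = 0.20, DE = 0.08, FR = 0.06,
                                           GB = 0.05, IT = 0.02, CA = 0.02,
                                           missing = 0.27),
                         reporter_probs = c(MD = 0.44, CN = 0.24, OT = 0.14,
                                            HP = 0.11, PH = 0.05, missing = 0.02),
                         severe_prob = 0.26,
                         outcome_probs = c(DE = 0.20, LT = 0.034, HO = 0.304,
                                           DS = 0.006, OT = 0.456),
                         tto_alpha = 45, tto_beta = 0.8,
                         tto_spec = NULL,
                         missing_date_fraction = 0.15,
                         negative_tto_fraction = 0.01,
                         duplicate_fraction = 0.10,
                         start_date = "2017-01-01", end_date = "2023-06-30") {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory", call. = FALSE)
  seed <- as.integer(seed)
  stopifnot(is.finite(seed), n_reports >= 1, n_drugs >= 2,
            target_prob >= 0, target_prob <= 1, ps_prob >= 0, ps_prob <= 1,
            missing_date_fraction >= 0, missing_date_fraction <= 1,
            negative_tto_fraction >= 0, negative_tto_fraction <= 1,
            duplicate_fraction >= 0, duplicate_fraction <= 1,
            tto_alpha > 0, tto_beta > 0)
  pts <- unique(hierarchy[toupper(primary_soc_flag) == "Y", pt])
  if (!is.null(injected_pairs)) {
    injected_pairs <- data.table::as.data.table(injected_pairs)
    if (!"drug" %in% names(injected_pairs)) injected_pairs[, drug := target$canonical]
    stopifnot(all(c("pt", "rho") %in% names(injected_pairs)))
    if (any(injected_pairs$rho < 1) || any(!is.finite(injected_pairs$rho))) {
      stop("injected rho values must be finite and >= 1", call. = FALSE)
    }
    bad <- setdiff(injected_pairs$pt, pts)
    if (length(bad)) {
      stop(sprintf("injected PT(s) not in the hierarchy PT universe: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(
    n_reports = as.integer(n_reports), seed = seed, hierarchy = hierarchy,
    pts = pts, n_drugs = as.integer(n_drugs), target = target,
    target_prob = target_prob, ps_prob = ps_prob,
    drugs_per_report_lambda = drugs_per_report_lambda,
    pts_per_report_lambda = pts_per_report_lambda,
    injected_pairs = injected_pairs,
    age_mean = age_mean, age_sd = age_sd, age_missing = age_missing,
    sex_probs = sex_probs, country_probs = country_probs,
    reporter_probs = reporter_probs,
    severe_prob = severe_prob, outcome_probs = outcome_probs,
    tto_alpha = tto_alpha, tto_beta = tto_beta, tto_spec = tto_spec,
    missing_date_fraction = missing_date_fraction,
    negative_tto_fraction = negative_tto_fraction,
    duplicate_fraction = duplicate_fraction,
    start_date = as.Date(start_date), end_date = as.Date(end_date)
  ), class = "synth_config")
}

# draw from named probabilities; "missing" becomes NA
.draw_cat <- function(n, probs) {
  v <- sample(names(probs), n, replace = TRUE, prob = probs)
  v[v == "missing"] <- NA_character_
  v
}

.fmt_ymd <- function(d) format(d, "%Y%m%d")

# corrupt a complete date string: code 0 keep, 1 blank, 2 truncate to YYYYMM
.corrupt_date <- function(full, code) {
  out <- full
  out[code == 1L] <- ""
  out[code == 2L] <- substr(full[code == 2L], 1, 6)
  out
}

# Single simulation pass shared by synth_generate() and
# synth_manifest(): one RNG stream, fixed draw order.
simulate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_reports
  pts <- cfg$pts
  npt <- length(pts)
  pt_w <- (1 / seq_len(npt)^0.5); pt_w <- pt_w / sum(pt_w)     # Zipf-ish
  soc_of_pt <- pt_to_soc(pts, cfg$hierarchy)
  tto_par <- data.table::data.table(soc = unique(soc_of_pt),
                                    alpha = cfg$tto_alpha, beta = cfg$tto_beta)
  if (!is.null(cfg$tto_spec)) {
    ts <- data.table::as.data.table(cfg$tto_spec)
    tto_par[ts, on = "soc", `:=`(alpha = i.alpha, beta = i.beta)]
  }
  bg_drugs <- sprintf("DRUG_%03d", seq_len(cfg$n_drugs))
  bg_w <- (1 / seq_len(cfg$n_drugs)^0.5); bg_w <- bg_w / sum(bg_w)

  caseid <- as.character(90000000 + seq_len(n))

  ## 1. demographics -------------------------------------------------------
  age_true <- pmin(100, pmax(0.5, rnorm(n, cfg$age_mean, cfg$age_sd)))
  age_na <- runif(n) < cfg$age_missing
  age_unit <- sample(c("YR", "DEC", "MON"), n, replace = TRUE,
                     prob = c(0.90, 0.05, 0.05))
  age_val <- ifelse(age_unit == "YR", round(age_true),
                    ifelse(age_unit == "DEC", round(age_true / 10, 1),
                           round(age_true * 12)))
  age_str <- ifelse(age_na, "", as.character(age_val))
  age_cod <- ifelse(age_na, "", age_unit)
  sex <- .draw_cat(n, cfg$sex_probs)
  country <- .draw_cat(n, cfg$country_probs)
  reporter <- .draw_cat(n, cfg$reporter_probs)
  severe <- runif(n) < cfg$severe_prob
  outc <- rep(NA_character_, n)
  outc[severe] <- sample(names(cfg$outcome_probs), sum(severe), replace = TRUE,
                         prob = cfg$outcome_probs)

  ## 2. drugs --------------------------------------------------------------
  has_target <- runif(n) < cfg$target_prob
  target_ps <- has_target & (runif(n) < cfg$ps_prob)
  syn <- cfg$target$synonyms
  target_name <- sample(syn, n, replace = TRUE)        # drawn for all, used when present
  n_bg <- 1L + rpois(n, cfg$drugs_per_report_lambda)
  bg_idx <- lapply(seq_len(n), function(i) {
    sample.int(cfg$n_drugs, min(n_bg[i], cfg$n_drugs), prob = bg_w)
  })

  ## 3. reactions ----------------------------------------------------------
  inj <- cfg$injected_pairs
  inj_target <- if (!is.null(inj)) inj[drug == cfg$target$canonical] else NULL
  w_inj <- pt_w
  if (!is.null(inj_target) && nrow(inj_target)) {
    ii <- match(inj_target$pt, pts)
    w_inj[ii] <- w_inj[ii] * inj_target$rho
    w_inj <- w_inj / sum(w_inj)
  }
  k_pt <- 1L + rpois(n, cfg$pts_per_report_lambda)
  pt_idx <- lapply(seq_len(n), function(i) {
    w <- if (target_ps[i]) w_inj else pt_w
    sample.int(npt, min(k_pt[i], npt), prob = w)
  })

  ## 4. onset + dates ------------------------------------------------------
  first_soc <- soc_of_pt[vapply(pt_idx, `[`, integer(1), 1L)]
  par_i <- tto_par[data.table::data.table(soc = first_soc), on = "soc"]
  onset <- floor(rweibull(n, shape = par_i$beta, scale = par_i$alpha))
  window <- as.integer(cfg$end_date - cfg$start_date)
  start_day <- floor(runif(n, 0, window + 1))
  start_date <- cfg$start_date + start_day
  neg_err <- runif(n) < cfg$negative_tto_fraction
  event_date <- start_date + ifelse(neg_err, -(1L + floor(runif(n, 0, 60))), onset)
  rept_date <- event_date + rpois(n, 20)
  # date corruption codes (never applied to the injected-error reports,
  # which must stay fully dated to exercise the negative-onset filter)
  f <- cfg$missing_date_fraction
  u_s <- runif(n); u_e <- runif(n)
  start_code <- ifelse(neg_err, 0L, ifelse(u_s < f / 2, 1L, ifelse(u_s < f, 2L, 0L)))
  event_code <- ifelse(neg_err, 0L, ifelse(u_e < f / 2, 1L, ifelse(u_e < f, 2L, 0L)))
  start_str <- .corrupt_date(.fmt_ymd(start_date), start_code)
  event_str <- .corrupt_date(.fmt_ymd(event_date), event_code)

  ## 5. duplicates ---------------------------------------------------------
  dup <- runif(n) < cfg$duplicate_fraction

  ## assemble tables (unique cases; duplicates appended at write time) -----
  drug_rows <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    nm <- bg_drugs[bg_idx[[i]]]
    role <- c("PS", sample(c("SS", "C", "I"), length(nm) - 1L, replace = TRUE))[seq_along(nm)]
    if (has_target[i]) {
      t_role <- if (target_ps[i]) "PS" else sample(c("SS", "C"), 1)
      if (t_role == "PS") role[role == "PS"] <- "SS"
      nm <- c(target_name[i], nm)
      role <- c(t_role, role)
    }
    data.table::data.table(case_i = i, drug_seq = seq_along(nm),
                           drugname = nm, role_cod = role)
  }))
  reac_rows <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    data.table::data.table(case_i = i, pt = pts[pt_idx[[i]]])
  }))

  list(cfg = cfg, n = n, caseid = caseid,
       age_str = age_str, age_cod = age_cod, sex = sex, country = country,
       reporter = reporter, outc = outc,
       has_target = has_target, target_ps = target_ps,
       drug_rows = drug_rows, reac_rows = reac_rows,
       onset = onset, neg_err = neg_err,
       start_str = start_str, event_str = event_str,
       rept_str = .fmt_ymd(rept_date),
       start_complete = start_code == 0L, event_complete = event_code == 0L,
       first_soc = first_soc, dup = dup,
       pt_w = pt_w, w_inj = w_inj)
}

.build_manifest <- function(sim) {
  cfg <- sim$cfg
  # per-PT distinct-report counts among target-PS cases (dedup ground truth)
  tp <- which(sim$target_ps)
  pt_counts <- if (length(tp)) {
    unique(sim$reac_rows[case_i %in% tp])[, .(a = .N), by = pt][order(-a)]
  } else data.table::data.table(pt = character(0), a = integer(0))
  injected <- NULL
  if (!is.null(cfg$injected_pairs)) {
    injected <- data.table::copy(cfg$injected_pairs)
    base_i <- match(injected$pt, cfg$pts)
    injected[, p_base := sim$pt_w[base_i]]
    injected[, p_injected := sim$w_inj[base_i]]
    injected[, expected_rr := p_injected / p_base]
  }
  onsets <- data.table::data.table(
    caseid = sim$caseid,
    soc = sim$first_soc,
    onset_days = ifelse(sim$neg_err, NA_integer_, as.integer(sim$onset)),
    start_complete = sim$start_complete,
    event_complete = sim$event_complete,
    negative_error = sim$neg_err,
    expected_included = sim$start_complete & sim$event_complete & !sim$neg_err,
    target_ps = sim$target_ps
  )
  n_dup <- sum(sim$dup)
  list(
    seed = cfg$seed,
    n_reports = sim$n,
    n_unique_cases = sim$n,
    n_duplicate_versions = n_dup,
    n_demo_rows = sim$n + n_dup,
    n_target_any = sum(sim$has_target),
    n_target_ps = sum(sim$target_ps),
    pt_counts = pt_counts,
    injected = injected,
    onsets = onsets
  )
}

#' Ground-truth manifest without writing files
#'
#' Runs the identical simulation pass as [synth_generate()] (same
#' seed, same draw order) and returns only the manifest.
#'
#' @param cfg a [synth_config()].
#' @return manifest list (counts, per-PT target counts, injected-pair
#'   table with expected reporting-rate ratios, per-case true onsets).
#' @export
synth_manifest <- function(cfg) {
  .build_manifest(simulate_corpus(cfg))
}

#' Generate a synthetic corpus on disk
#'
#' Writes DEMO/DRUG/REAC/THER/OUTC in the quarterly "$" dialect plus
#' `manifest.json`, and returns the manifest invisibly augmented with
#' the file paths.  Cases selected as duplicates are written twice:
#' caseversion 1 and an identical caseversion 2 under a new primaryid,
#' so deduplication must collapse them.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @return (invisibly) the manifest with an added `files` element.
#' @export
synth_generate <- function(cfg, dir) {
  sim <- simulate_corpus(cfg)
  manifest <- .build_manifest(sim)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- sim$n

  versions <- data.table::data.table(case_i = seq_len(n), caseversion = 1L)
  if (any(sim$dup)) {
    versions <- rbind(versions,
                      data.table::data.table(case_i = which(sim$dup), caseversion = 2L))
  }
  versions[, caseid := sim$caseid[case_i]]
  versions[, primaryid := paste0(caseid, caseversion)]
  data.table::setorder(versions, case_i, caseversion)

  demo <- versions[, .(
    primaryid, caseid, caseversion = as.character(caseversion),
    event_dt = sim$event_str[case_i], rept_dt = sim$rept_str[case_i],
    age = sim$age_str[case_i], age_cod = sim$age_cod[case_i],
    sex = data.table::fifelse(is.na(sim$sex[case_i]), "", sim$sex[case_i]),
    occp_cod = data.table::fifelse(is.na(sim$reporter[case_i]), "", sim$reporter[case_i]),
    occr_country = data.table::fifelse(is.na(sim$country[case_i]), "", sim$country[case_i])
  )]
  drug <- merge(versions, sim$drug_rows, by = "case_i", allow.cartesian = TRUE)[
    , .(primaryid, caseid, drug_seq = as.character(drug_seq),
        role_cod, drugname, prod_ai = drugname)]
  reac <- merge(versions, sim$reac_rows, by = "case_i", allow.cartesian = TRUE)[
    , .(primaryid, caseid, pt)]
  ther <- merge(versions, sim$drug_rows, by = "case_i", allow.cartesian = TRUE)[
    , .(primaryid, caseid, dsg_drug_seq = as.character(drug_seq),
        start_dt = sim$start_str[case_i])]
  has_outc <- !is.na(sim$outc)
  outc <- merge(versions[case_i %in% which(has_outc)],
                data.table::data.table(case_i = which(has_outc),
                                       outc_cod = sim$outc[has_outc]),
                by = "case_i")[, .(primaryid, caseid, outc_cod)]

  write_tab <- function(dt, file) {
    lines <- c(paste(names(dt), collapse = "$"),
               do.call(paste, c(as.list(dt), sep = "$")))
    writeLines(lines, file.path(dir, file), useBytes = TRUE)
  }
  write_tab(demo, "DEMO.txt")
  write_tab(drug, "DRUG.txt")
  write_tab(reac, "REAC.txt")
  write_tab(ther, "THER.txt")
  write_tab(outc, "OUTC.txt")

  manifest$file_rows <- c(demo = nrow(demo), drug = nrow(drug), reac = nrow(reac),
                          ther = nrow(ther), outc = nrow(outc))
  manifest$files <- setNames(file.path(dir, c("DEMO.txt", "DRUG.txt", "REAC.txt",
                                              "THER.txt", "OUTC.txt")),
                             c("demo", "drug", "reac", "ther", "outc"))
  jsonlite::write_json(
    manifest[c("seed", "n_reports", "n_unique_cases", "n_duplicate_versions",
               "n_target_any", "n_target_ps", "file_rows")],
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
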