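# Target-drug cohort extraction and the descriptive demographics table.

#' Normalize a drug name
#'
#' Upper-cases, trims, collapses internal whitespace, and strips common
#' salt/hydrate tokens (`HYDROCHLORIDE`, `HCL`) so that label variants
#' of the same active substance compare equal.
#'
#' @param raw character vector of verbatim drug names.
#' @return normalized character vector.
#' @examples
#' normalize_name(" bendamustine  HCl ")   # "BENDAMUSTINE"
#' @export
normalize_name <- function(raw) {
  x <- toupper(trimws(as.character(raw)))
  x <- gsub("\\b(HYDROCHLORIDE|HCL)\\b", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Build a target-drug dictionary
#'
#' The synonym list used to recognise a target medicine in free-text
#' drug-name fields.  The default dictionary is the bendamustine brand
#' family.  `match_mode` controls recognition:
#' `"substring"` (default) — a normalized synonym contained anywhere in
#' the normalized name; `"exact"` — whole-name equality;
#' `"fuzzy"` — normalized Levenshtein similarity
#' `1 - dist/max(nchar)` of at least `fuzzy_threshold` against any
#' synonym, or substring containment.
#'
#' @param canonical canonical drug name.
#' @param synonyms character vector of synonyms (brand + generic names).
#' @param match_mode one of `"substring"`, `"exact"`, `"fuzzy"`.
#' @param fuzzy_threshold similarity threshold in (0, 1], used when
#'   `match_mode = "fuzzy"`.
#' @return object of class `drug_dictionary`.
#' @export
drug_dictionary <- function(canonical = "BENDAMUSTINE",
                            synonyms = c("BENDAMUSTINE", "BELRAPZO", "BENDEKA",
                                         "TREANDA", "VIVIMUSTA"),
                            match_mode = c("substring", "exact", "fuzzy"),
                            fuzzy_threshold = 0.9) {
  match_mode <- match.arg(match_mode)
  stopifnot(length(synonyms) >= 1)
  if (match_mode == "fuzzy") {
    stopifnot(fuzzy_threshold > 0, fuzzy_threshold <= 1)
  }
  structure(list(canonical = normalize_name(canonical),
                 synonyms = unique(normalize_name(synonyms)),
                 match_mode = match_mode,
                 fuzzy_threshold = fuzzy_threshold),
            class = "drug_dictionary")
}

#' Match drug names against a target dictionary
#'
#' @param drugname character vector of verbatim drug names.
#' @param dict a [drug_dictionary()].
#' @return logical vector, `TRUE` where the name denotes the target drug.
#' @examples
#' match_target("BENDEKA 100MG", drug_dictionary())  # TRUE
#' match_target("RITUXIMAB", drug_dictionary())      # FALSE
#' @export
match_target <- function(drugname, dict) {
  stopifnot(inherits(dict, "drug_dictionary"))
  x <- normalize_name(drugname)
  syn <- dict$synonyms
  hit <- rep(FALSE, length(x))
  if (dict$match_mode == "exact") {
    hit <- x %in% syn
  } else {
    for (s in syn) hit <- hit | grepl(s, x, fixed = TRUE)
    if (dict$match_mode == "fuzzy") {
      rest <- which(!hit & nzchar(x))
      if (length(rest)) {
        d <- utils::adist(x[rest], syn)
        mx <- outer(nchar(x[rest]), nchar(syn), pmax)
        sim <- 1 - d / mx
        hit[rest] <- apply(sim, 1, max) >= dict$fuzzy_threshold
      }
    }
  }
  hit
}

#' Extract the reports naming the target drug in a given role
#'
#' A report enters the case set when at least one of its drug rows
#' matches the dictionary with the requested role code (`"PS"` primary
#' suspect by default; `"any"` accepts every role).  One report counts
#' once no matter how many matching rows it carries.
#'
#' @param corpus a deduplicated [faers_corpus()].
#' @param dict a [drug_dictionary()].
#' @param role role code filter: `"PS"`, `"SS"`, `"C"`, `"I"` or `"any"`.
#' @return object of class `case_set`: the corpus tables restricted to
#'   matching reports, plus `target` and `role`.
#' @export
extract_cases <- function(corpus, dict = drug_dictionary(), role = "PS") {
  stopifnot(inherits(corpus, "faers_corpus"))
  d <- corpus$drugs
  m <- match_target(d$drugname_norm, dict)
  if (!identical(role, "any")) {
    m <- m & toupper(trimws(d$role_cod)) %in% role
  }
  ids <- unique(d$primaryid[m])
  structure(list(
    demo = corpus$demo[primaryid %in% ids],
    drugs = corpus$drugs[primaryid %in% ids],
    reactions = corpus$reactions[primaryid %in% ids],
    outcomes = corpus$outcomes[primaryid %in% ids],
    target = dict, role = role
  ), class = "case_set")
}

#' @export
print.case_set <- function(x, ...) {
  cat("<case_set>", nrow(x$demo), "reports with", x$target$canonical,
      "in role", paste(x$role, collapse = "/"), "\n")
  invisible(x)
}

.reporter_label <- c(MD = "Physician", PH = "Pharmacist", CN = "Consumer",
                     LW = "Consumer", HP = "Health professional",
                     OT = "Other health professional")

# one severity class per report, by clinical priority
.outcome_priority <- c("DE", "LT", "HO", "DS")
.outcome_label <- c(DE = "Death", LT = "Life-threatening",
                    HO = "Hospitalization", DS = "Disability")

classify_outcome <- function(outcomes, ids) {
  oc <- outcomes[primaryid %in% ids]
  if (!nrow(oc)) {
    return(data.table::data.table(primaryid = character(0), outcome_class = character(0)))
  }
  oc[, rank := match(outc_cod, .outcome_priority)]
  oc[is.na(rank), rank := length(.outcome_priority) + 1L]
  best <- oc[order(primaryid, rank)][!duplicated(primaryid)]
  best[, outcome_class := ifelse(rank <= length(.outcome_priority),
                                 .outcome_label[outc_cod], "Other")]
  best[, .(primaryid, outcome_class)]
}

#' Descriptive demographics table of a case set
#'
#' Tabulates the cohort the way post-marketing case series are
#' reported: age bands (<18, 18–64, ≥65), gender, severe-outcome
#' levels (Death, Life-threatening, Hospitalization, Disability,
#' Other — one class per report by severity priority), reporter type,
#' the top-k reporting countries, and reporting year.  Missing values
#' are excluded from a category's available-case denominator.
#'
#' Two percentage columns are emitted: `pct` uses the category's
#' available (non-missing) count as denominator; `pct_total` uses the
#' whole cohort.  Both are rounded half-up to two decimals
#' ([report_pct()]).
#'
#' @param caseset a [extract_cases()] result.
#' @param top_k_countries number of countries to list.
#' @return data.table with columns `category`, `level`, `count`,
#'   `available_n`, `pct`, `pct_total`; attributes `n_total` and
#'   `age_summary` (named vector with median and mean age in years).
#' @export
describe_cohort <- function(caseset, top_k_countries = 5) {
  stopifnot(inherits(caseset, "case_set"), nrow(caseset$demo) >= 1)
  demo <- caseset$demo
  n_total <- nrow(demo)

  rows <- list()
  add_cat <- function(category, values, order = NULL) {
    ok <- !is.na(values)
    avail <- sum(ok)
    if (avail == 0) {
      return(data.table::data.table(
        category = character(0), level = character(0), count = integer(0),
        available_n = integer(0), pct = numeric(0), pct_total = numeric(0)))
    }
    tab <- table(values[ok])
    lv <- if (is.null(order)) names(sort(tab, decreasing = TRUE)) else intersect(order, names(tab))
    data.table::data.table(
      category = category, level = lv,
      count = as.integer(tab[lv]), available_n = avail,
      pct = report_pct(as.integer(tab[lv]), avail),
      pct_total = report_pct(as.integer(tab[lv]), n_total)
    )
  }

  age_band <- cut(demo$age_years, breaks = c(-Inf, 18, 65, Inf),
                  labels = c("<18", "18-64", ">=65"), right = FALSE)
  rows$age <- add_cat("Age (years)", as.character(age_band), c("<18", "18-64", ">=65"))

  sexv <- demo$sex
  sexv[!sexv %in% c("M", "F")] <- NA_character_
  gender <- c(M = "Male", `F` = "Female")[sexv]
  rows$gender <- add_cat("Gender", gender, c("Male", "Female"))

  oc <- classify_outcome(caseset$outcomes, demo$primaryid)
  sev <- oc$outcome_class[match(demo$primaryid, oc$primaryid)]
  rows$severe <- add_cat("Severe outcome", sev,
                         c("Death", "Life-threatening", "Hospitalization",
                           "Disability", "Other"))

  rep_lab <- .reporter_label[demo$reporter]
  rows$reporter <- add_cat("Reporters", unname(rep_lab))

  ctry <- add_cat("Reported countries", demo$country)
  rows$country <- head(ctry, top_k_countries)

  rows$year <- add_cat("Reporting year", as.character(demo$report_year))
  rows$year <- rows$year[order(level)]

  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "n_total", n_total)
  data.table::setattr(out, "age_summary",
                      c(median = as.numeric(median(demo$age_years, na.rm = TRUE)),
                        mean = as.numeric(mean(demo$age_years, na.rm = TRUE))))
  out
}
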