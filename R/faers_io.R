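# Ingestion of the FAERS quarterly ASCII dialect: one file per table
# (DEMO/DRUG/REAC/THER/OUTC), a header line, "$" as field separator, one
# record per line, no quoting.  Table roles are chosen by the caller,
# never sniffed from filenames.

.mandatory_cols <- list(
  demo = "primaryid",
  drug = c("primaryid", "drugname", "role_cod"),
  reac = c("primaryid", "pt"),
  ther = "primaryid",
  outc = "primaryid"
)

# Split one "$"-delimited table.  Rows whose field count is neither
# ncol nor ncol-1 (a trailing empty field is legal and dropped by the
# writer) are skipped and counted.
read_faers_table <- function(path, role = c("demo", "drug", "reac", "ther", "outc")) {
  role <- match.arg(role)
  if (!file.exists(path)) {
    stop(sprintf("table file does not exist: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- iconv(lines, from = "UTF-8", to = "UTF-8", sub = "�")
  if (!length(lines)) {
    stop(sprintf("file '%s' is empty (no header line)", path), call. = FALSE)
  }
  header <- tolower(trimws(strsplit(lines[[1]], "$", fixed = TRUE)[[1]]))
  missing_cols <- setdiff(.mandatory_cols[[role]], header)
  if (length(missing_cols)) {
    stop(sprintf("file '%s' (%s table) is missing mandatory column(s): %s",
                 path, toupper(role), paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  nc <- length(header)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    empty <- data.table::setnames(
      data.table::as.data.table(replicate(nc, character(0), simplify = FALSE)), header)
    return(list(rows = empty, skipped = 0L))
  }
  nfield <- nchar(body) - nchar(gsub("$", "", body, fixed = TRUE)) + 1L
  ok <- nfield == nc | nfield == nc - 1L
  skipped <- sum(!ok)
  if (skipped > 0) {
    warning(sprintf("'%s': skipped %d malformed row(s) (wrong field count)",
                    path, skipped), call. = FALSE)
  }
  body <- body[ok]
  cols <- data.table::tstrsplit(body, "$", fixed = TRUE)
  length(cols) <- nc                      # pad when every row lacked the last field
  cols <- lapply(cols, function(x) {
    if (is.null(x)) rep("", length(body)) else {
      x[is.na(x)] <- ""
      trimws(x)
    }
  })
  names(cols) <- header
  rows <- data.table::setDT(cols)
  list(rows = rows, skipped = skipped)
}

#' Read one FAERS-style quarter
#'
#' Reads the five quarterly ASCII tables ("$"-delimited, header line,
#' one record per line) and bundles them, unmodified, into a raw
#' quarter object.  Unknown columns are preserved; malformed rows
#' (wrong field count) are skipped with a warning and counted.
#'
#' @param paths named list or character vector with elements `demo`,
#'   `drug`, `reac`, and optionally `ther` and `outc`, giving the file
#'   location of each table.
#' @return An object of class `raw_quarter`: a list with data.tables
#'   `demo`, `drug`, `reac`, `ther`, `outc` (columns lower-cased),
#'   a named integer vector `skipped` of malformed-row counts, and
#'   `row_counts`.
#' @examples
#' qdir <- tempfile(); dir.create(qdir)
#' cfg <- synth_config(n_reports = 50, seed = 1)
#' synth_generate(cfg, qdir)
#' q <- read_quarter(file.path(qdir, c(
#'   demo = "DEMO.txt", drug = "DRUG.txt", reac = "REAC.txt",
#'   ther = "THER.txt", outc = "OUTC.txt")))
#' q$row_counts
#' @export
read_quarter <- function(paths) {
  paths <- as.list(paths)
  for (nm in c("demo", "drug", "reac")) {
    if (is.null(paths[[nm]])) {
      stop(sprintf("'paths' must name a '%s' table file", nm), call. = FALSE)
    }
  }
  tabs <- list()
  skipped <- integer(0)
  for (role in c("demo", "drug", "reac", "ther", "outc")) {
    if (is.null(paths[[role]])) {
      tabs[[role]] <- data.table::data.table(primaryid = character(0))
      skipped[role] <- 0L
      next
    }
    got <- read_faers_table(paths[[role]], role)
    tabs[[role]] <- got$rows
    skipped[role] <- got$skipped
  }
  # referential check: child rows must point at a demo report
  demo_ids <- unique(tabs$demo$primaryid)
  for (role in c("drug", "reac", "ther", "outc")) {
    if (nrow(tabs[[role]]) && "primaryid" %in% names(tabs[[role]])) {
      orphans <- sum(!tabs[[role]]$primaryid %in% demo_ids)
      if (orphans > 0) {
        warning(sprintf("%s table: %d row(s) reference a primaryid absent from DEMO",
                        toupper(role), orphans), call. = FALSE)
      }
    }
  }
  structure(list(
    demo = tabs$demo, drug = tabs$drug, reac = tabs$reac,
    ther = tabs$ther, outc = tabs$outc,
    skipped = skipped,
    row_counts = vapply(tabs, nrow, integer(1))
  ), class = "raw_quarter")
}

#' @export
print.raw_quarter <- function(x, ...) {
  cat("<raw_quarter>\n  rows:",
      paste(sprintf("%s=%d", names(x$row_counts), x$row_counts), collapse = " "),
      "\n  malformed rows skipped:", sum(x$skipped), "\n")
  invisible(x)
}

#' Parse a FAERS partial date
#'
#' FAERS dates are digit strings: `YYYYMMDD` (full), `YYYYMM`
#' (year-month), or `YYYY` (year only); anything else — including an
#' impossible calendar date — is `invalid`.  Never raises.
#'
#' @param raw character vector of raw date fields.
#' @return data.table with columns `raw`, `year`, `month`, `day`
#'   (integer or NA), `completeness` (one of `"full"`, `"year_month"`,
#'   `"year_only"`, `"invalid"`), and `date` (a `Date`, NA unless
#'   complete).
#' @examples
#' parse_date(c("20230115", "202301", "2023", "20230230", ""))
#' @export
parse_date <- function(raw) {
  r <- as.character(raw)
  r[is.na(r)] <- ""
  r <- trimws(r)
  n <- length(r)
  out <- data.table::data.table(
    raw = r,
    year = NA_integer_, month = NA_integer_, day = NA_integer_,
    completeness = rep("invalid", n),
    date = as.Date(rep(NA_character_, n))
  )
  yr_ok <- function(y) !is.na(y) & y >= 1900 & y <= 2100

  is8 <- grepl("^[0-9]{8}$", r)
  if (any(is8)) {
    d <- as.Date(r[is8], format = "%Y%m%d")       # NA for impossible dates
    y <- as.integer(substr(r[is8], 1, 4))
    good <- !is.na(d) & yr_ok(y)
    idx <- which(is8)[good]
    out[idx, `:=`(year = as.integer(format(d[good], "%Y")),
                  month = as.integer(format(d[good], "%m")),
                  day = as.integer(format(d[good], "%d")),
                  completeness = "full",
                  date = d[good])]
  }
  is6 <- grepl("^[0-9]{6}$", r)
  if (any(is6)) {
    y <- as.integer(substr(r[is6], 1, 4))
    m <- as.integer(substr(r[is6], 5, 6))
    good <- yr_ok(y) & m >= 1 & m <= 12
    idx <- which(is6)[good]
    out[idx, `:=`(year = y[good], month = m[good], completeness = "year_month")]
  }
  is4 <- grepl("^[0-9]{4}$", r)
  if (any(is4)) {
    y <- as.integer(r[is4])
    good <- yr_ok(y)
    idx <- which(is4)[good]
    out[idx, `:=`(year = y[good], completeness = "year_only")]
  }
  out[]
}

# age_cod unit -> years multiplier; blank codes are years by FAERS habit
.age_factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
                 DY = 1 / 365.25, HR = 1 / 8765.8)

age_to_years <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(age_cod))
  cod[cod == ""] <- "YR"
  fac <- .age_factor[cod]
  yrs <- v * fac
  yrs[!is.finite(yrs) | yrs < 0 | yrs > 130] <- NA_real_
  yrs
}

#' Collapse case versions into deduplicated report cases
#'
#' Concatenates one or more raw quarters, assembles per-report records
#' (demographics, drugs, reactions, outcomes), and keeps exactly one
#' report per case: the highest `caseversion`, ties broken by the
#' largest `primaryid`.  A case revised across quarters therefore
#' collapses to its latest version.  Reports with no reaction rows are
#' dropped (and counted) since a safety report without an event term
#' carries no analysable information.
#'
#' @param quarters a `raw_quarter` or list of them.
#' @return An object of class `faers_corpus`: data.tables `demo` (one
#'   row per retained report with parsed `age_years`, `sex`, `country`,
#'   `reporter`, `report_year`, `event_date`, `event_completeness`),
#'   `drugs` (with therapy `start_dt` joined from THER), `reactions`,
#'   `outcomes`, and a `counts` list recording input, retained,
#'   removed-duplicate, and no-reaction report numbers.
#' @export
deduplicate <- function(quarters) {
  if (inherits(quarters, "raw_quarter")) quarters <- list(quarters)
  stopifnot(length(quarters) >= 1)
  demo <- data.table::rbindlist(lapply(quarters, `[[`, "demo"), fill = TRUE)
  drug <- data.table::rbindlist(lapply(quarters, `[[`, "drug"), fill = TRUE)
  reac <- data.table::rbindlist(lapply(quarters, `[[`, "reac"), fill = TRUE)
  ther <- data.table::rbindlist(lapply(quarters, `[[`, "ther"), fill = TRUE)
  outc <- data.table::rbindlist(lapply(quarters, `[[`, "outc"), fill = TRUE)
  if (!nrow(demo)) stop("no DEMO rows in input quarters", call. = FALSE)

  n_input <- nrow(demo)
  # conflicting demographics within one primaryid: keep first occurrence
  dup_pid <- duplicated(demo$primaryid)
  n_conflict <- sum(dup_pid)
  if (n_conflict > 0) {
    warning(sprintf("%d repeated DEMO row(s) for an existing primaryid; keeping the first",
                    n_conflict), call. = FALSE)
    demo <- demo[!dup_pid]
  }

  get_col <- function(dt, nm) if (nm %in% names(dt)) dt[[nm]] else rep("", nrow(dt))

  caseid <- get_col(demo, "caseid")
  caseid[!nzchar(caseid)] <- demo$primaryid[!nzchar(caseid)]
  cv <- suppressWarnings(as.integer(get_col(demo, "caseversion")))
  cv[is.na(cv) | cv < 1] <- 1L

  ev <- parse_date(get_col(demo, "event_dt"))
  rept <- get_col(demo, "rept_dt")
  report_year <- suppressWarnings(as.integer(substr(rept, 1, 4)))
  report_year[!is.na(report_year) & (report_year < 1900 | report_year > 2100)] <- NA_integer_
  report_year[is.na(report_year)] <- ev$year[is.na(report_year)]

  sex <- toupper(trimws(get_col(demo, "sex")))
  sex[!sex %in% c("M", "F", "UNK")] <- NA_character_
  country <- toupper(trimws(get_col(demo, "occr_country")))
  country[!nzchar(country)] <- NA_character_
  reporter <- toupper(trimws(get_col(demo, "occp_cod")))
  reporter[!nzchar(reporter)] <- NA_character_

  cases <- data.table::data.table(
    primaryid = demo$primaryid,
    caseid = caseid,
    caseversion = cv,
    age_years = age_to_years(get_col(demo, "age"), get_col(demo, "age_cod")),
    sex = sex, country = country, reporter = reporter,
    report_year = report_year,
    event_dt = ev$raw, event_completeness = ev$completeness, event_date = ev$date
  )

  # a report must carry at least one reaction
  has_reac <- cases$primaryid %in% unique(reac$primaryid)
  n_no_reaction <- sum(!has_reac)
  cases <- cases[has_reac]

  # keep max caseversion per caseid; tie-break on largest primaryid
  cases[, pid_num := suppressWarnings(as.numeric(primaryid))]
  data.table::setorderv(cases, c("caseid", "caseversion", "pid_num", "primaryid"),
                        order = c(1L, -1L, -1L, -1L))
  keep <- cases[!duplicated(caseid)]
  keep[, pid_num := NULL]
  n_retained <- nrow(keep)
  n_removed <- n_input - n_conflict - n_no_reaction - n_retained

  ids <- keep$primaryid
  drugs <- drug[primaryid %in% ids]
  if (!"drug_seq" %in% names(drugs)) drugs[, drug_seq := as.character(seq_len(.N)), by = primaryid]
  if (nrow(ther) && "start_dt" %in% names(ther)) {
    tseq <- if ("dsg_drug_seq" %in% names(ther)) ther$dsg_drug_seq else ther$drug_seq
    tt <- data.table::data.table(primaryid = ther$primaryid, drug_seq = tseq,
                                 start_dt = ther$start_dt)
    tt <- tt[!duplicated(tt, by = c("primaryid", "drug_seq"))]
    drugs <- merge(drugs, tt, by = c("primaryid", "drug_seq"),
                   all.x = TRUE, sort = FALSE)
  }
  if (!"start_dt" %in% names(drugs)) drugs[, start_dt := NA_character_]
  drugs[, drugname_norm := normalize_name(drugname)]

  reactions <- unique(reac[primaryid %in% ids, .(primaryid, pt = trimws(pt))])
  reactions <- reactions[nzchar(pt)]
  outcomes <- if (nrow(outc) && "outc_cod" %in% names(outc)) {
    unique(outc[primaryid %in% ids, .(primaryid, outc_cod = toupper(trimws(outc_cod)))])
  } else data.table::data.table(primaryid = character(0), outc_cod = character(0))

  structure(list(
    demo = keep, drugs = drugs, reactions = reactions, outcomes = outcomes,
    counts = list(n_input = n_input, n_conflict = n_conflict,
                  n_no_reaction = n_no_reaction,
                  n_retained = n_retained, n_removed_duplicates = n_removed)
  ), class = "faers_corpus")
}

#' Assemble a corpus from in-memory tables
#'
#' Lightweight constructor used by tests and by callers that already
#' hold parsed tables; performs the same per-report parsing as
#' [deduplicate()] expects downstream, but no version collapsing.
#'
#' @param demo data.table with at least `primaryid`; optional parsed
#'   columns (`age_years`, `sex`, `country`, `reporter`, `report_year`,
#'   `event_date`, `event_completeness`) are taken as-is.
#' @param drugs data.table with `primaryid`, `drugname`, `role_cod`,
#'   optional `start_dt`.
#' @param reactions data.table with `primaryid`, `pt`.
#' @param outcomes data.table with `primaryid`, `outc_cod` (optional).
#' @return a `faers_corpus`.
#' @export
faers_corpus <- function(demo, drugs, reactions, outcomes = NULL) {
  demo <- data.table::as.data.table(demo)
  drugs <- data.table::as.data.table(drugs)
  reactions <- data.table::as.data.table(reactions)
  if (is.null(outcomes)) {
    outcomes <- data.table::data.table(primaryid = character(0), outc_cod = character(0))
  } else outcomes <- data.table::as.data.table(outcomes)
  stopifnot("primaryid" %in% names(demo),
            all(c("primaryid", "drugname", "role_cod") %in% names(drugs)),
            all(c("primaryid", "pt") %in% names(reactions)))
  if (!"drugname_norm" %in% names(drugs)) drugs[, drugname_norm := normalize_name(drugname)]
  if (!"start_dt" %in% names(drugs)) drugs[, start_dt := NA_character_]
  for (nm in c("age_years", "report_year")) if (!nm %in% names(demo)) demo[, (nm) := NA_real_]
  for (nm in c("sex", "country", "reporter")) if (!nm %in% names(demo)) demo[, (nm) := NA_character_]
  if (!"event_completeness" %in% names(demo)) demo[, event_completeness := "invalid"]
  if (!"event_date" %in% names(demo)) demo[, event_date := as.Date(NA)]
  structure(list(demo = demo, drugs = drugs, reactions = reactions, outcomes = outcomes,
                 counts = list(n_input = nrow(demo), n_conflict = 0L, n_no_reaction = 0L,
                               n_retained = nrow(demo), n_removed_duplicates = 0L)),
            class = "faers_corpus")
}

#' @export
print.faers_corpus <- function(x, ...) {
  cat("<faers_corpus>", nrow(x$demo), "reports |",
      nrow(x$drugs), "drug rows |", nrow(x$reactions), "reaction rows\n")
  cat("  dedup:", x$counts$n_input, "in ->", x$counts$n_retained, "retained (",
      x$counts$n_removed_duplicates, "duplicate versions removed )\n")
  invisible(x)
}
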