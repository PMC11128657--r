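# PT -> HLT -> HLGT -> SOC hierarchy lookup and SMQ membership.
#
# MedDRA itself is licensed and cannot be redistributed; the package
# bundles a small synthetic hierarchy (inst/extdata/) using the
# standard SOC names, and accepts a user-supplied TSV of the same
# shape for real analyses.

#' Load a PT hierarchy table
#'
#' Reads a tab-separated table with columns `pt`, `hlt`, `hlgt`, `soc`
#' and `primary_soc_flag` (`Y`/`N`; multiaxial PTs appear once per SOC
#' with exactly one primary row).  PT text is matched exactly after
#' trimming and case-folding.
#'
#' @param path TSV file; default is the bundled synthetic hierarchy.
#' @return data.table of class `meddra_hierarchy`.
#' @export
read_hierarchy <- function(path = system.file("extdata", "synthetic_meddra_hierarchy.tsv",
                                              package = "faersignal")) {
  if (!file.exists(path)) {
    stop(sprintf("hierarchy file does not exist: '%s'", path), call. = FALSE)
  }
  h <- data.table::fread(path, sep = "\t", colClasses = "character")
  data.table::setnames(h, tolower(names(h)))
  need <- c("pt", "hlt", "hlgt", "soc")
  miss <- setdiff(need, names(h))
  if (length(miss)) {
    stop(sprintf("hierarchy file '%s' lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!"primary_soc_flag" %in% names(h)) h[, primary_soc_flag := "Y"]
  h[, pt_key := toupper(trimws(pt))]
  # exactly one primary SOC per PT
  nprim <- h[toupper(primary_soc_flag) == "Y", .N, by = pt_key]
  bad <- c(setdiff(h$pt_key, nprim$pt_key), nprim[N != 1, pt_key])
  if (length(bad)) {
    stop(sprintf("PT(s) without a unique primary SOC flag: %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  data.table::setattr(h, "class", c("meddra_hierarchy", class(h)))
  h[]
}

#' Map PTs to their primary System Organ Class
#'
#' @param pt character vector of Preferred Terms.
#' @param hierarchy a [read_hierarchy()] table.
#' @return character vector of primary SOC names; PTs absent from the
#'   hierarchy yield the sentinel `"UNMAPPED"` with one warning.
#' @export
pt_to_soc <- function(pt, hierarchy) {
  prim <- hierarchy[toupper(primary_soc_flag) == "Y"]
  soc <- prim$soc[match(toupper(trimws(pt)), prim$pt_key)]
  n_un <- sum(is.na(soc))
  if (n_un > 0) {
    warning(sprintf("%d PT value(s) not in the hierarchy; mapped to UNMAPPED", n_un),
            call. = FALSE)
    soc[is.na(soc)] <- "UNMAPPED"
  }
  soc
}

#' Load an SMQ membership table
#'
#' Tab-separated columns `smq`, `pt`, `scope` (`narrow`/`broad`).
#'
#' @param path TSV file; default is the bundled synthetic SMQ table.
#' @return data.table of class `smq_table`.
#' @export
read_smq <- function(path = system.file("extdata", "synthetic_smq.tsv",
                                        package = "faersignal")) {
  if (!file.exists(path)) {
    stop(sprintf("SMQ file does not exist: '%s'", path), call. = FALSE)
  }
  s <- data.table::fread(path, sep = "\t", colClasses = "character")
  data.table::setnames(s, tolower(names(s)))
  miss <- setdiff(c("smq", "pt"), names(s))
  if (length(miss)) {
    stop(sprintf("SMQ file '%s' lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!"scope" %in% names(s)) s[, scope := "narrow"]
  s[, pt_key := toupper(trimws(pt))]
  data.table::setattr(s, "class", c("smq_table", class(s)))
  s[]
}

#' Per-PT case counts within one SMQ
#'
#' Counts, for each member PT of the query, the distinct reports in the
#' case set naming that PT.  PTs with zero cases are omitted.
#'
#' @param smq SMQ name (must exist in `smq_table`).
#' @param caseset a `case_set`.
#' @param smq_table a [read_smq()] table.
#' @param scope restrict to `"narrow"` members, `"broad"`, or `"all"`.
#' @return data.table with columns `smq`, `pt`, `cases`, ordered by
#'   decreasing count.
#' @export
smq_members <- function(smq, caseset, smq_table = read_smq(), scope = "all") {
  smq_name <- smq
  scope_name <- scope
  members <- smq_table[smq_table[["smq"]] == smq_name]
  if (!nrow(members)) {
    stop(sprintf("SMQ '%s' not found in the membership table", smq_name), call. = FALSE)
  }
  if (scope_name != "all") members <- members[members[["scope"]] == scope_name]
  re <- caseset$reactions
  hits <- re[toupper(trimws(pt)) %in% members$pt_key]
  if (!nrow(hits)) {
    return(data.table::data.table(smq = character(0), pt = character(0),
                                  cases = integer(0)))
  }
  out <- unique(hits, by = c("primaryid", "pt"))[, .(cases = .N), by = pt]
  out[, smq := smq_name]
  data.table::setcolorder(out, c("smq", "pt", "cases"))
  out[order(-cases)]
}

# distinct (report, SOC) pairs for a set of reaction rows
report_soc_pairs <- function(reactions, hierarchy) {
  rs <- data.table::copy(reactions)
  rs[, soc := pt_to_soc(pt, hierarchy)]
  unique(rs[, .(primaryid, soc)])
}
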