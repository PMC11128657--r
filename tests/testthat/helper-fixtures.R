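# Fixtures are built in code at test time; nothing binary is stored.

# Write a tiny handcrafted quarter in the "$" dialect.  Returns the
# path list read_quarter() expects.
write_toy_quarter <- function(dir = tempfile("quarter")) {
  dir.create(dir)
  w <- function(file, lines) writeLines(lines, file.path(dir, file))
  w("DEMO.txt", c(
    "primaryid$caseid$caseversion$event_dt$rept_dt$age$age_cod$sex$occp_cod$occr_country",
    "1001$100$1$20230110$20230120$63$YR$M$MD$US",
    "1002$100$2$20230110$20230121$63$YR$M$MD$US",
    "1003$100$3$20230110$20230122$63$YR$M$MD$US",
    "2001$200$1$20230215$20230301$7$DEC$F$CN$JP",
    "3001$300$1$202303$20230401$480$MON$F$PH$DE",
    "9999$900$1$bad$row$with$too$many$fields$x$y$z"   # malformed: 12 fields
  ))
  w("DRUG.txt", c(
    "primaryid$caseid$drug_seq$role_cod$drugname$prod_ai",
    "1001$100$1$PS$BENDAMUSTINE$BENDAMUSTINE",
    "1002$100$1$PS$BENDAMUSTINE$BENDAMUSTINE",
    "1003$100$1$PS$Bendamustine Hydrochloride$BENDAMUSTINE",
    "1003$100$2$C$RITUXIMAB$RITUXIMAB",
    "2001$200$1$PS$TREANDA 100MG$BENDAMUSTINE",
    "3001$300$1$C$BENDEKA$BENDAMUSTINE",
    "3001$300$2$PS$OTHERDRUG$OTHERDRUG"
  ))
  w("REAC.txt", c(
    "primaryid$caseid$pt",
    "1001$100$Pyrexia",
    "1002$100$Pyrexia",
    "1003$100$Pyrexia",
    "1003$100$Neutropenia",
    "2001$200$Rash",
    "3001$300$Pyrexia"
  ))
  w("THER.txt", c(
    "primaryid$caseid$dsg_drug_seq$start_dt",
    "1001$100$1$20230101",
    "1002$100$1$20230101",
    "1003$100$1$20230101",
    "2001$200$1$202302",
    "3001$300$1$20230301"
  ))
  w("OUTC.txt", c(
    "primaryid$caseid$outc_cod",
    "1003$100$HO",
    "1003$100$DE",
    "2001$200$OT"
  ))
  as.list(stats::setNames(
    file.path(dir, c("DEMO.txt", "DRUG.txt", "REAC.txt", "THER.txt", "OUTC.txt")),
    c("demo", "drug", "reac", "ther", "outc")))
}

# In-memory corpus with n reports, n_target of them carrying the target
# drug as PS, and a chosen PT distributed over target / non-target
# reports.  Everything else is filler.
make_counting_corpus <- function(n = 100, n_target = 10, pt_in_target = 4,
                                 pt_in_other = 6, pt_name = "PT X") {
  ids <- as.character(seq_len(n))
  target_ids <- ids[seq_len(n_target)]
  demo <- data.table::data.table(primaryid = ids)
  drugs <- data.table::rbindlist(list(
    data.table::data.table(primaryid = target_ids, drugname = "BENDAMUSTINE",
                           role_cod = "PS"),
    data.table::data.table(primaryid = ids, drugname = "FILLERDRUG",
                           role_cod = "SS")
  ))
  with_pt <- c(target_ids[seq_len(pt_in_target)],
               ids[n_target + seq_len(pt_in_other)])
  reactions <- data.table::rbindlist(list(
    data.table::data.table(primaryid = with_pt, pt = pt_name),
    data.table::data.table(primaryid = ids, pt = "Filler event")
  ))
  faers_corpus(demo, drugs, reactions)
}

# One shared synthetic corpus (generated once per test run) for the
# tests that only need "a realistic corpus", to keep the suite fast.
shared_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- tempfile("synthcorpus")
      cfg <- synth_config(n_reports = 2500, seed = 42)
      manifest <- synth_generate(cfg, dir)
      quarter <- read_quarter(manifest$files)
      corpus <- deduplicate(quarter)
      caseset <- extract_cases(corpus, cfg$target, "PS")
      cache <<- list(cfg = cfg, manifest = manifest, quarter = quarter,
                     corpus = corpus, caseset = caseset,
                     hierarchy = read_hierarchy())
    }
    cache
  }
})
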