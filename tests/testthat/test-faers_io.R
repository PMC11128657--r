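test_that("quarter reader parses the $ dialect, skips malformed rows, keeps counts", {
  paths <- write_toy_quarter()
  expect_warning(q <- read_quarter(paths), "malformed")
  expect_s3_class(q, "raw_quarter")
  expect_equal(nrow(q$demo), 5L)            # 6 data lines, 1 malformed
  expect_equal(unname(q$skipped["demo"]), 1L)
  expect_equal(nrow(q$drug), 7L)
  expect_true(all(c("primaryid", "drugname", "role_cod") %in% names(q$drug)))
  # unknown columns are preserved
  expect_true("prod_ai" %in% names(q$drug))
})

test_that("an event table with only a header yields zero rows", {
  paths <- write_toy_quarter()
  writeLines("primaryid$caseid$pt", paths$reac)
  q <- suppressWarnings(read_quarter(paths))
  expect_equal(nrow(q$reac), 0L)
})

test_that("a missing mandatory column is a hard error naming file and column", {
  paths <- write_toy_quarter()
  writeLines(c("primaryid$caseid$reaction", "1001$100$Pyrexia"), paths$reac)
  suppressWarnings({
    expect_error(read_quarter(paths), "pt")
    expect_error(read_quarter(paths), basename(paths$reac))
  })
  paths2 <- write_toy_quarter()
  paths2$drug <- NULL
  expect_error(read_quarter(paths2), "drug")
})

test_that("synthetic quarter row counts equal the generator manifest", {
  sh <- shared_synth()
  expect_equal(unname(sh$quarter$row_counts[c("demo", "drug", "reac", "ther", "outc")]),
               unname(sh$manifest$file_rows))
  expect_equal(nrow(sh$quarter$demo), sh$manifest$n_demo_rows)
})

test_that("partial dates are classified and full dates expose components", {
  d <- parse_date(c("20230115", "202301", "2023", "20230230", "", "1x230115", "18990101"))
  expect_equal(d$completeness,
               c("full", "year_month", "year_only", "invalid", "invalid", "invalid", "invalid"))
  expect_equal(d$year[1:3], c(2023L, 2023L, 2023L))
  expect_equal(d$month[1:2], c(1L, 1L))
  expect_equal(d$day[1], 15L)
  expect_equal(d$date[1], as.Date("2023-01-15"))
})

test_that("parse_date never raises and completeness partitions arbitrary input", {
  set.seed(9)
  junk <- c(
    replicate(50, paste(sample(c(0:9, letters, " ", "-"), sample(0:12, 1), TRUE), collapse = "")),
    format(as.Date("2017-01-01") + sample(0:2500, 50, TRUE), "%Y%m%d"),
    NA_character_)
  expect_no_error(res <- parse_date(junk))
  expect_true(all(res$completeness %in% c("full", "year_month", "year_only", "invalid")))
  # full iff 8 digits forming a valid calendar date
  valid8 <- suppressWarnings(
    !is.na(junk) & grepl("^[0-9]{8}$", junk) &
      !is.na(as.Date(junk, format = "%Y%m%d")) &
      as.integer(substr(junk, 1, 4)) >= 1900)
  valid8[is.na(valid8)] <- FALSE
  expect_equal(res$completeness == "full", unname(valid8))
})

test_that("deduplication keeps the highest caseversion, ties broken by primaryid", {
  paths <- write_toy_quarter()
  q <- suppressWarnings(read_quarter(paths))
  corpus <- deduplicate(q)
  # caseid 100 had versions 1,2,3 -> only version 3 (primaryid 1003)
  kept <- corpus$demo[caseid == "100"]
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$primaryid, "1003")
  expect_equal(kept$caseversion, 3L)
  # distinct caseids each retained once
  expect_equal(sort(corpus$demo$caseid), c("100", "200", "300"))
  # tie on caseversion: largest primaryid wins
  q2 <- q
  q2$demo <- data.table::copy(q$demo)[primaryid %in% c("1001", "1002"),
                                      caseversion := "1"][primaryid != "1003"]
  corpus2 <- deduplicate(list(q2))
  expect_equal(corpus2$demo[caseid == "100", primaryid], "1002")
})

test_that("dedup conserves counts and is idempotent", {
  sh <- shared_synth()
  cts <- sh$corpus$counts
  expect_equal(cts$n_retained + cts$n_removed_duplicates +
                 cts$n_conflict + cts$n_no_reaction, cts$n_input)
  expect_equal(cts$n_retained, sh$manifest$n_unique_cases)
  expect_equal(cts$n_removed_duplicates, sh$manifest$n_duplicate_versions)
  # feeding the retained tables back through changes nothing
  again <- deduplicate(list(list(demo = sh$corpus$demo, drug = sh$corpus$drugs,
                                 reac = sh$corpus$reactions, ther = data.table::data.table(),
                                 outc = sh$corpus$outcomes)))
  expect_setequal(again$demo$primaryid, sh$corpus$demo$primaryid)
  expect_equal(again$counts$n_removed_duplicates, 0L)
})

test_that("age units are converted to years and absurd ages dropped", {
  paths <- write_toy_quarter()
  corpus <- deduplicate(suppressWarnings(read_quarter(paths)))
  ages <- corpus$demo[order(primaryid), .(primaryid, age_years)]
  expect_equal(ages[primaryid == "1003", age_years], 63)   # YR
  expect_equal(ages[primaryid == "2001", age_years], 70)   # 7 DEC
  expect_equal(ages[primaryid == "3001", age_years], 40)   # 480 MON
  expect_true(all(is.na(faersignal:::age_to_years(c("999", "-5"), c("YR", "YR")))))
})
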