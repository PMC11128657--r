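test_that("contingency tables count unique reports per term", {
  corpus <- make_counting_corpus(n = 100, n_target = 10,
                                 pt_in_target = 4, pt_in_other = 6)
  cs <- extract_cases(corpus, drug_dictionary(), "PS")
  tab <- build_tables(cs, corpus, "pt")
  x <- tab[term == "PT X"]
  expect_equal(unlist(x[, .(a, b, c_, d)], use.names = FALSE), c(4, 6, 6, 84))
  expect_equal(x$N, 100)
  # a PT occurring only outside the target cohort yields no table
  corpus0 <- make_counting_corpus(pt_in_target = 0, pt_in_other = 6)
  cs0 <- extract_cases(corpus0, drug_dictionary(), "PS")
  expect_false("PT X" %in% build_tables(cs0, corpus0, "pt")$term)
  # case set outside the background is a hard error
  other <- make_counting_corpus(n = 8, n_target = 2, pt_in_target = 1, pt_in_other = 2)
  expect_error(build_tables(cs, other, "pt"), "absent")
})

test_that("margins of every synthetic table agree with an exhaustive recount", {
  sh <- shared_synth()
  tab <- build_tables(sh$caseset, sh$corpus, "pt")
  n_t <- nrow(sh$caseset$demo)
  N <- nrow(sh$corpus$demo)
  expect_true(all(tab$a + tab$b == n_t))
  expect_true(all(tab$a + tab$b + tab$c_ + tab$d == N))
  # recount two PTs by brute force over the reaction rows
  for (tm in tab$term[1:2]) {
    with_pt <- unique(sh$corpus$reactions[toupper(trimws(pt)) == tm, primaryid])
    expect_equal(tab[term == tm, a],
                 length(intersect(with_pt, sh$caseset$demo$primaryid)))
    expect_equal(tab[term == tm, a + c_], length(with_pt))
  }
  # generator manifest is the independent oracle for every a count
  mc <- sh$manifest$pt_counts[, .(term = toupper(pt), a_true = a)]
  merged <- merge(tab, mc, by = "term")
  expect_equal(nrow(merged), nrow(tab))
  expect_equal(merged$a, merged$a_true)
})

test_that("ROR point estimate and log-normal CI match frozen arithmetic", {
  r <- ror_ci(10, 10, 10, 10)
  expect_equal(r$ror, 1)
  expect_true(r$ror_l < 1 && r$ror_u > 1)
  r2 <- ror_ci(10, 90, 100, 9800)
  expect_equal(r2$ror, 10.888889, tolerance = 1e-6)
  expect_equal(r2$ror_l, 5.503411, tolerance = 1e-5)
  expect_equal(r2$ror_u, 21.544438, tolerance = 1e-5)
  expect_false(r2$corrected)
  # zero cell: Haldane-Anscombe on every cell, flagged
  r3 <- ror_ci(3, 0, 5, 100)
  expect_true(r3$corrected)
  expect_true(is.finite(r3$ror))
  expect_equal(r3$ror, (3.5 * 100.5) / (0.5 * 5.5), tolerance = 1e-12)
})

test_that("PRR and Yates chi-squared match their oracles", {
  p <- prr_chi2(10, 90, 100, 900)
  expect_equal(p$prr, 1)
  expect_equal(p$chi2, 0, tolerance = 1e-12)
  expect_equal(prr_chi2(10, 90, 100, 9800)$prr, (10 / 100) / (100 / 9900),
               tolerance = 1e-12)
  # chisq.test with continuity correction is the independent oracle
  ch <- prr_chi2(20, 80, 30, 870)$chi2
  expect_equal(ch, unname(chisq.test(matrix(c(20, 80, 30, 870), 2,
                                            byrow = TRUE))$statistic),
               tolerance = 1e-10)
  # invariant to transposing the 2x2
  expect_equal(prr_chi2(20, 30, 80, 870)$chi2, ch, tolerance = 1e-12)
})

test_that("information component and its closed-form lower bound", {
  # a = E exactly: (10,90,990,8910) has E = 100*1000/10000 = 10
  expect_equal(bcpnn_ic(10, 90, 990, 8910)$ic, 0, tolerance = 1e-12)
  # a=100, E=10: (100, 900, 900, 98100), N=1e5
  b <- bcpnn_ic(100, 900, 900, 98100)
  expect_equal(b$E, 10)
  expect_equal(b$ic, log2(100.5 / 10.5), tolerance = 1e-12)
  expect_equal(round(b$ic, 3), 3.259)
  expect_true(b$ic_lower <= b$ic)
  # the closed form tracks the exact gamma-posterior quantile on real tables
  sh <- shared_synth()
  tab <- build_tables(sh$caseset, sh$corpus, "pt")
  ap <- bcpnn_ic(tab$a, tab$b, tab$c_, tab$d, method = "approx")
  ex <- bcpnn_ic(tab$a, tab$b, tab$c_, tab$d, method = "quantile", quantile = 0.025)
  expect_lt(max(abs(ap$ic_lower - ex$ic_lower)), 0.06)
  expect_true(all(ap$ic_lower <= ap$ic))
})

test_that("combined criterion boundary semantics and flags", {
  base <- data.table::data.table(a = 3, prr = 2, chi2 = 4, ic_lower = 1e-9,
                                 ebgm = 2 + 1e-9)
  expect_true(evaluate_signal(base)$is_signal)
  # >= on prr/chi2/n, strict > on ic_lower and ebgm
  expect_false(evaluate_signal(data.table::copy(base)[, ic_lower := 0])$is_signal)
  expect_false(evaluate_signal(data.table::copy(base)[, ebgm := 2])$is_signal)
  expect_false(evaluate_signal(data.table::copy(base)[, prr := 1.999])$is_signal)
  # two cases with an enormous PRR still fail the n >= 3 gate
  few <- data.table::data.table(a = 2, prr = 50, chi2 = 100, ic_lower = 2, ebgm = 10)
  expect_false(evaluate_signal(few)$is_signal)
})

test_that("rankings sort by count and by ROR CI lower bound with tie-breaks", {
  s <- data.table::data.table(
    term = c("t1", "t2", "t3", "t4"),
    a = c(5, 9, 2, 5), ror_l = c(1.2, 0.8, 3.0, 2.0),
    is_signal = TRUE)
  r <- rank_top(s, k = 10)
  expect_equal(r$by_count$a, c(9, 5, 5, 2))
  expect_equal(r$by_count$term[2:3], c("t4", "t1"))   # tie on a: higher ror_l first
  expect_equal(r$by_ror_lower$ror_l, c(3.0, 2.0, 1.2, 0.8))
  expect_equal(nrow(rank_top(s, k = 2)$by_count), 2L)
  expect_equal(nrow(rank_top(s, k = 99)$by_count), 4L)
})

test_that("PRR approximates ROR for rare events and both grow with a", {
  set.seed(21)
  for (i in 1:50) {
    n_t <- sample(200:2000, 1)
    N <- n_t * sample(50:200, 1)
    a <- sample(1:floor(n_t * 0.01), 1)
    c_ <- sample(1:floor((N - n_t) * 0.01), 1)
    b <- n_t - a; d <- N - n_t - c_
    if (a / n_t > 0.01 || c_ / (c_ + d) > 0.01) next
    ror <- ror_ci(a, b, c_, d)$ror
    prr <- prr_chi2(a, b, c_, d)$prr
    expect_lt(abs(prr - ror) / ror, 0.011)
  }
  # monotonicity in a with b, c, d fixed
  a_seq <- 1:30
  stats <- cbind(ror_ci(a_seq, 100, 50, 10000),
                 prr_chi2(a_seq, 100, 50, 10000),
                 bcpnn_ic(a_seq, 100, 50, 10000))
  expect_true(all(diff(stats$ror) > 0))
  expect_true(all(diff(stats$prr) > 0))
  expect_true(all(diff(stats$ic) > 0))
})

test_that("under a null corpus the conjunction is rarer than any single criterion", {
  sh <- shared_synth()
  sig <- compute_signals(sh$caseset, sh$corpus, "pt", sh$hierarchy)
  eligible <- sig[a >= 3]
  expect_gt(nrow(eligible), 5)
  n_joint <- sum(eligible$is_signal)
  for (fl in c("prr_flag", "chi2_flag", "ic_flag", "ebgm_flag")) {
    expect_lte(n_joint, sum(eligible[[fl]]))
  }
  # raising thresholds can only shrink the signal set
  stricter <- evaluate_signal(sig, signal_thresholds(prr_min = 4, chi2_min = 8,
                                                     n_min = 5, ebgm_min = 4))
  expect_lte(sum(stricter$is_signal), n_joint)
})
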