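test_that("2o3 majority rule with missing-source handling", {
  expect_equal(da2o3("positive", "positive", "negative"), "sensitizer")
  expect_equal(da2o3("positive", "negative", "negative"), "non-sensitizer")
  expect_equal(da2o3("positive", "negative", NA), "inconclusive")
  expect_equal(da2o3("positive", NA, "positive"), "sensitizer")
  expect_equal(da2o3(NA, "negative", "negative"), "non-sensitizer")
  expect_error(da2o3("positive", NA, NA), "missing data")

  # when two sources agree the third never changes the call
  for (third in c("positive", "negative", NA)) {
    expect_equal(da2o3("positive", "positive", third), "sensitizer")
    expect_equal(da2o3("negative", "negative", third), "non-sensitizer")
  }
})

test_that("ITS component scores follow the binning tables", {
  s <- itsScore(50, 40, "positive", 5, "positive")   # mean 45 >= 42.47
  expect_equal(s$dpra_score, 3L)
  expect_equal(s$hclat_score, 3L)
  expect_equal(s$insilico_score, 1L)
  expect_equal(s$total, 7)

  z <- itsScore(0, 0, "negative", NA, "negative")
  expect_equal(z$total, 0)

  # cysteine-only bin table, in silico absent: partial two-source score
  cy <- itsScore(30, NA, "negative", NA, NA)
  expect_equal(cy$dpra_score, 2L)
  expect_equal(cy$hclat_score, 0L)
  expect_true(is.na(cy$insilico_score))
  expect_equal(cy$total, 2)
  expect_equal(cy$n_sources, 2L)

  # bin boundaries (mean-based): 6.38 starts score 1, 42.47 starts score 3
  expect_equal(itsScore(6.38, 6.38)$dpra_score, 1L)
  expect_equal(itsScore(6.37, 6.37)$dpra_score, 0L)
  expect_equal(itsScore(42.47, 42.47)$dpra_score, 3L)
  # MIT bins
  expect_equal(itsScore(0, 0, "positive", 10)$hclat_score, 3L)
  expect_equal(itsScore(0, 0, "positive", 150)$hclat_score, 2L)
  expect_equal(itsScore(0, 0, "positive", 151)$hclat_score, 1L)
  expect_equal(itsScore(0, 0, "negative", NA)$hclat_score, 0L)

  expect_error(itsScore(NA_real_, NA_real_, NA_character_, NA_real_,
                        NA_character_), "missing data")
})

test_that("ITS classification table for three and two sources", {
  mk <- function(total, n) list(total = total, n_sources = n)
  expect_equal(itsClassify(mk(7, 3)), "1A")
  expect_equal(itsClassify(mk(6, 3)), "1A")
  expect_equal(itsClassify(mk(5, 3)), "1B")
  expect_equal(itsClassify(mk(2, 3)), "1B")
  expect_equal(itsClassify(mk(1, 3)), "NC")
  expect_equal(itsClassify(mk(0, 3)), "NC")
  expect_equal(itsClassify(mk(6, 2)), "1A")
  expect_equal(itsClassify(mk(3, 2)), "1B")
  expect_equal(itsClassify(mk(1, 2)), "inconclusive")
  expect_equal(itsClassify(mk(0, 2)), "NC")
  expect_equal(itsClassify(mk(3, 1)), "inconclusive")

  # GHS class is monotone non-decreasing in the total
  lev <- c(NC = 0, `1B` = 1, `1A` = 2)
  cls <- vapply(0:7, function(t) itsClassify(mk(t, 3)), "")
  expect_true(all(diff(lev[cls]) >= 0))
})

test_that("STS decision tree is total over its input space", {
  expect_equal(stsClassify("negative", NA, "positive"), "1B")
  expect_equal(stsClassify("negative", NA, "negative"), "NC")
  expect_equal(stsClassify("positive", 5, "negative"), "1A")
  expect_equal(stsClassify("positive", 50, "negative"), "1B")
  expect_equal(stsClassify("positive", NA, "positive"), "1B")
  for (h in c("positive", "negative")) for (d in c("positive", "negative"))
    for (mit in c(5, 500, NA))
      expect_true(stsClassify(h, mit, d) %in% c("1A", "1B", "NC"))
  expect_error(stsClassify(NA, NA, NA), "missing data")
})

test_that("applyDefinedApproaches handles edge panels", {
  empty <- CompoundAssayPanel(data.frame(compound_id = character()))
  expect_equal(nrow(applyDefinedApproaches(empty)), 0)

  # hCLAT absent everywhere: STS cannot be computed
  sim <- simulateAssayPanels(20, seed = 3)
  d <- panelData(sim$panel)
  d$hclat_call <- NA_character_
  d$hclat_cd86_rfi <- d$hclat_cd54_rfi <- d$hclat_mit_ugml <- NA_real_
  da <- applyDefinedApproaches(new("CompoundAssayPanel", data = d))
  expect_true(all(da$ghs_sts == "inconclusive"))

  # out-of-domain in silico is treated as an absent source
  d2 <- panelData(sim$panel)
  d2$insilico_call <- "out_of_domain"
  da2 <- applyDefinedApproaches(new("CompoundAssayPanel", data = d2))
  expect_true(all(is.na(da2$its_insilico_score)))
})

test_that("Venn counts equal brute-force enumeration", {
  res <- data.frame(
    compound_id = paste0("C", 1:5),
    call_2o3 = c("sensitizer", "sensitizer", "non-sensitizer",
                 "non-sensitizer", "inconclusive"),
    ghs_its = c("1A", "NC", "1B", "NC", "NC"),
    ghs_sts = c("1B", "1B", "NC", "NC", "1B"))
  v <- daVennCounts(res)
  pos <- cbind(res$call_2o3 == "sensitizer",
               res$ghs_its %in% c("1A", "1B"),
               res$ghs_sts %in% c("1A", "1B"))
  expect_equal(v$positive_all3, sum(rowSums(pos) == 3))
  expect_equal(v$positive_ge2, sum(rowSums(pos) >= 2))
  expect_equal(v$positive_ge1, sum(rowSums(pos) >= 1))
  expect_equal(v$negative_all3, 1)

  # monotonicity n(>=1) >= n(>=2) >= n(=3) on random inputs
  set.seed(1)
  for (i in 1:10) {
    r <- data.frame(
      compound_id = paste0("C", 1:50),
      call_2o3 = sample(c("sensitizer", "non-sensitizer", "inconclusive"),
                        50, TRUE),
      ghs_its = sample(c("1A", "1B", "NC", "inconclusive"), 50, TRUE),
      ghs_sts = sample(c("1A", "1B", "NC", "inconclusive"), 50, TRUE))
    v <- daVennCounts(r)
    expect_true(v$positive_ge1 >= v$positive_ge2)
    expect_true(v$positive_ge2 >= v$positive_all3)
  }

  allneg <- data.frame(compound_id = "C1", call_2o3 = "non-sensitizer",
                       ghs_its = "NC", ghs_sts = "NC")
  expect_equal(daVennCounts(allneg)$positive_ge1, 0)
})

test_that("potency contingency reproduces the published agreement layout", {
  its <- rep(c("NC", "NC", "1B", "1B", "inconclusive", "1A", "1A"),
             c(96, 5, 133, 1, 12, 2, 6))
  sts <- rep(c("NC", "1B", "1B", "1A", "1B", "1B", "1A"),
             c(96, 5, 133, 1, 12, 2, 6))
  pc <- potencyContingency(its, sts, n_total = 288)
  expect_equal(pc$n_agree, 235)
  expect_equal(pc$agreement_pct, 82)
  expect_equal(as.vector(pc$table["NC", c("NC", "1B", "1A")]), c(96, 5, 0))
  expect_equal(as.vector(pc$table["1A", c("NC", "1B", "1A")]), c(0, 2, 6))

  perfect <- potencyContingency(its, its)
  expect_equal(perfect$agreement_pct_resolved, 100)

  # permuting one DA's labels does not raise agreement in expectation
  set.seed(7)
  base <- potencyContingency(its, sts)$n_agree
  perm <- replicate(200, potencyContingency(its, sample(sts))$n_agree)
  expect_lt(mean(perm), base)
})

test_that("binary agreement statistics match the confusion-matrix formulas", {
  same <- rep(c("positive", "negative"), c(4, 6))
  st <- binaryAgreementStats(same, same)
  expect_equal(st$sensitivity, 1)
  expect_equal(st$specificity, 1)
  expect_equal(st$balanced_accuracy, 1)

  a <- rep(c("positive", "negative", "positive", "negative"),
           c(5, 3, 2, 6))
  b <- rep(c("positive", "positive", "negative", "negative"),
           c(5, 3, 2, 6))
  st2 <- binaryAgreementStats(a, b)
  expect_equal(st2$sensitivity, 5 / 8)
  expect_equal(st2$specificity, 6 / 8)
  expect_equal(st2$balanced_accuracy, (5 / 8 + 6 / 8) / 2)
  expect_equal(st2$mcc,
               (5 * 6 - 2 * 3) / sqrt((5 + 2) * (5 + 3) * (6 + 2) * (6 + 3)))

  st3 <- binaryAgreementStats(b, a)
  expect_equal(st3$sensitivity, 5 / 7)
  expect_equal(st3$specificity, 6 / 9)
  expect_error(binaryAgreementStats(rep(NA_character_, 3), b[1:3]),
               "missing data")
})
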