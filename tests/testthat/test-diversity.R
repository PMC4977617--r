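test_that("closed-form diversity matches the published worked splits", {
  # 125/1 of 126 (culm angle row)
  d <- traitDiversity(c(125, 1) / 126, 126)
  expect_equal(halfUp(d$Ne), 1.016)
  expect_equal(halfUp(d$He), 0.016)
  expect_equal(halfUp(d$I), 0.046)
  # 115/11 of 126 (awns row)
  d <- traitDiversity(c(115, 11) / 126, 126)
  expect_equal(halfUp(c(d$Ne, d$He, d$I)), c(1.190, 0.159, 0.296))
  # 80/46 of 126 (secondary branching row)
  d <- traitDiversity(c(80, 46) / 126, 126)
  expect_equal(halfUp(c(d$He, d$I)), c(0.464, 0.656))
})

test_that("monomorphic and uniform traits hit their closed forms", {
  m <- traitDiversity(c(1, 0, 0), 10)
  expect_equal(unlist(m[c("Na", "Ne", "He", "I")]),
               c(Na = 1, Ne = 1, He = 0, I = 0))
  for (k in c(2, 5, 8)) {
    u <- traitDiversity(rep(1 / k, k), 100)
    expect_equal(u$Ne, k)
    expect_equal(u$I, log(k))
    expect_equal(u$He, 1 - 1 / k)
  }
  expect_error(traitDiversity(c(0.5, 0.4), 10), "sum to 1")
})

test_that("the small-sample correction behaves as documented", {
  p <- c(125, 1) / 126
  expect_equal(traitDiversity(p, 126, unbiased = TRUE)$He,
               126 / 125 * (1 - sum(p^2)))
  # for the 8-state lemma-palea profile the corrected value exceeds plug-in
  p8 <- c(.50, .10, .11, .02, .10, .14, .02, .01)
  expect_gt(traitDiversity(p8, 126, unbiased = TRUE)$He,
            traitDiversity(p8, 126)$He)
  expect_error(traitDiversity(p, unbiased = TRUE), "n >= 2")
})

test_that("He = 1 - 1/Ne identically across panels and groups", {
  tm <- simulatePanel(odishaPanelSpec(), seed = 12)
  dt <- diversityTable(tm)
  expect_equal(dt$He, 1 - 1 / dt$Ne, tolerance = 1e-12)
  per <- diversityTable(tm, byGroup = TRUE)
  for (tab in attr(per, "tables"))
    expect_equal(tab$He, 1 - 1 / tab$Ne, tolerance = 1e-12)
})

test_that("per-group tables equal brute-force recomputation", {
  cat3 <- tinyCatalog()
  spec <- panelSpec(cat3, n = 30, groupSizes = c(A = 12, B = 18))
  tm <- simulatePanel(spec, seed = 6)
  per <- diversityTable(tm, byGroup = TRUE)
  tabs <- attr(per, "tables")
  for (g in c("A", "B")) {
    rows <- which(groupLabels(tm) == g)
    for (k in traitKeys(tm)) {
      states <- tm@data[[k]][rows]
      p <- table(factor(states, traitStates_test(cat3, k))) / length(states)
      expect_equal(tabs[[g]]$He[tabs[[g]]$trait_key == k],
                   1 - sum(p^2), tolerance = 1e-12)
    }
  }
  # two identical groups give identical tables
  d <- tm@data; d$group <- rep(c("X", "Y"), each = 15)
  d[16:30, traitKeys(tm)] <- d[1:15, traitKeys(tm)]
  same <- diversityTable(traitMatrix(d, cat3), byGroup = TRUE)
  ts <- attr(same, "tables")
  expect_equal(ts$X, ts$Y)
})

test_that("statistics are invariant to genotype order and panel duplication", {
  tm <- simulatePanel(odishaPanelSpec(), seed = 15)
  dt <- diversityTable(tm)
  set.seed(1)
  perm <- sample(length(tm))
  tmp <- traitMatrix(tm@data[perm, ], tm@catalog)
  expect_equal(diversityTable(tmp)$He, dt$He)
  # doubling the panel leaves every frequency-based statistic unchanged
  d2 <- tm@data
  d2$accession_id <- paste0(d2$accession_id, "b")
  dd <- traitMatrix(rbind(tm@data, d2), tm@catalog)
  expect_equal(diversityTable(dd)$He, dt$He)
  expect_equal(attr(diversityTable(dd), "summary")$PI,
               attr(dt, "summary")$PI)
})

test_that("percent polymorphism counts segregating variables", {
  tm <- simulatePanel(odishaPanelSpec(), seed = 4, exactCounts = TRUE)
  bm <- encodeBinary(tm)
  # identical genotypes: nothing segregates
  one <- bm[rep(1L, 5), ]
  rownames(one) <- paste0("r", 1:5)
  attr(one, "codes") <- attr(bm, "codes"); attr(one, "traits") <- attr(bm, "traits")
  expect_equal(percentPolymorphic(one), 0)
  # brute-force column scan on random subsets
  set.seed(9)
  for (r in 1:5) {
    rows <- sample(nrow(bm), 10)
    cf <- colMeans(bm[rows, ])
    expect_equal(percentPolymorphic(bm, rows),
                 100 * sum(cf > 0 & cf < 1) / 70)
    expect_equal(percentPolymorphic(bm, rows, denominator = "observed"),
                 100 * sum(cf > 0 & cf < 1) / sum(cf > 0))
  }
  # 6 segregating variables over a 71-variable universe -> 8.45
  expect_equal(halfUp(100 * 6 / 71, 2), 8.45)
})

test_that("probability of identity multiplies over polymorphic traits", {
  cat3 <- tinyCatalog()
  mono <- panelSpec(cat3, n = 6, frequencies = list(
    COL = c(1, 0, 0), SHP = c(1, 0), AWN = 1))
  ftm <- traitFrequencies(simulatePanel(mono, seed = 1))
  expect_equal(probabilityOfIdentity(ftm)$PI, 1)
  expect_equal(probabilityOfIdentity(ftm)$capacity, 1)

  half <- panelSpec(cat3, n = 8, frequencies = list(
    COL = c(1, 0, 0), SHP = c(0.5, 0.5), AWN = 1))
  fth <- traitFrequencies(simulatePanel(half, seed = 2, exactCounts = TRUE))
  expect_equal(probabilityOfIdentity(fth)$PI, 0.5)

  # term-by-term product oracle on the Odisha-like fixture
  tm <- simulatePanel(odishaPanelSpec(), seed = 10, exactCounts = TRUE)
  ft <- traitFrequencies(tm)
  want <- 1
  for (k in unique(ft$trait_key)) {
    p <- ft$p[ft$trait_key == k]
    if (sum(p > 0) > 1L) want <- want * sum(p^2)
  }
  got <- probabilityOfIdentity(ft)
  expect_equal(got$PI, want, tolerance = 1e-12)
  expect_equal(got$capacity, 1 / want, tolerance = 1e-9)
  # and it matches the product of 1/Ne over polymorphic traits
  dt <- diversityTable(tm)
  expect_equal(got$PI, prod(1 / dt$Ne[dt$Na > 1]), tolerance = 1e-12)
})

test_that("the Odisha-like panel shows the reported polymorphic fraction", {
  tm <- simulatePanel(odishaPanelSpec(), seed = 1, exactCounts = TRUE)
  s <- attr(diversityTable(tm), "summary")
  expect_equal(s$percentPolymorphicTraits, 75)  # 18 of 24 traits vary
})
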