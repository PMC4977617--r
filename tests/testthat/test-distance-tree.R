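test_that("genotype distances are trait mismatch proportions", {
  cat24 <- odishaCatalog()
  tm <- simulatePanel(panelSpec(cat24, n = 3), seed = 2)
  d <- tm@data
  d[2, traitKeys(tm)] <- d[1, traitKeys(tm)]          # clone of genotype 1
  # genotype 3 differs from genotype 1 at exactly 14 traits
  d[3, traitKeys(tm)] <- d[1, traitKeys(tm)]
  flip <- traitKeys(tm)[vapply(traitKeys(tm), function(k)
    length(traitStates_test(cat24, k)) > 1, TRUE)][1:14]
  for (k in flip) {
    states <- traitStates_test(cat24, k)
    d[3, k] <- setdiff(states, d[1, k])[1L]
  }
  dm <- genotypeDistance(encodeBinary(traitMatrix(d, cat24)))
  expect_equal(dm["SIM001", "SIM002"], 0)
  expect_equal(dm["SIM001", "SIM003"], 14 / 24)
  expect_equal(attr(dm, "metric"), "mismatch")
  # the Nei-log transform is monotone in the mismatch
  dn <- genotypeDistance(encodeBinary(traitMatrix(d, cat24)), metric = "neilog")
  expect_equal(dn["SIM001", "SIM003"], -log(1 - 14 / 24))
})

test_that("distances agree with a per-pair brute-force recount", {
  tm <- simulatePanel(panelSpec(odishaCatalog(), n = 15), seed = 31)
  dm <- genotypeDistance(encodeBinary(tm))
  keys <- traitKeys(tm)
  for (i in 1:14) for (j in (i + 1):15) {
    a <- unlist(tm@data[i, keys]); b <- unlist(tm@data[j, keys])
    co <- !is.na(a) & !is.na(b)
    expect_equal(unname(dm[i, j]), mean(a[co] != b[co]))
  }
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, 15))
})

test_that("group Nei distances match hand arithmetic and edge cases", {
  cat3 <- tinyCatalog()
  d <- tinyPanel(tinyStates(c("Red", "Round", "Present"),
                            c("Red", "Oval", "Present"),
                            c("Green", "Round", "Present"),
                            c("Green", "Oval", "Present")),
                 groups = c("X", "X", "Y", "Y"))
  tm <- traitMatrix(d, cat3)
  # X: COL (1,0,0) SHP (.5,.5) AWN (1); Y: COL (0,1,0) SHP (.5,.5) AWN (1)
  # Jx = Jy = (1 + .5 + 1)/3; Jxy = (0 + .5 + 1)/3; I = 1.5/2.5 = 0.6
  dm <- groupNeiDistance(tm)
  expect_equal(dm["X", "Y"], -log(0.6))
  # identical groups -> zero distance
  d2 <- d; d2$group <- c("X", "Y", "X", "Y")
  d2[traitKeys(tm)] <- d[c(1, 1, 3, 3), traitKeys(tm)]
  expect_equal(groupNeiDistance(traitMatrix(d2, cat3))["X", "Y"], 0,
               tolerance = 1e-12)
  # groups fixed for disjoint states at every trait -> infinite distance
  dj <- tinyPanel(tinyStates(c("Red", "Round", "Present"),
                             c("Red", "Round", "Present"),
                             c("Green", "Oval", "Present"),
                             c("Green", "Oval", "Present")),
                  groups = c("X", "X", "Y", "Y"))
  djm <- traitMatrix(dj, cat3)
  # AWN is shared; make a fully-disjoint two-trait comparison instead
  dj2 <- dj[, c("accession_id", "name", "group", "COL", "SHP", "AWN")]
  dj2$AWN <- NULL
  # build a 2-trait catalogue for the disjoint case
  cdf <- data.frame(trait_key = c("COL", "COL", "SHP", "SHP"),
                    trait_name = c("Colour", "Colour", "Shape", "Shape"),
                    variable_code = 1:4,
                    variable_label = c("Red", "Green", "Round", "Oval"))
  f <- tempfile(); write.table(cdf, f, sep = "\t", quote = FALSE, row.names = FALSE)
  cat2 <- readTraitCatalog(f)
  expect_warning(dmj <- groupNeiDistance(traitMatrix(dj2, cat2)),
                 "zero identity")
  expect_equal(unname(dmj["X", "Y"]), Inf)
  # the unbiased correction shrinks within-group J and grows the identity
  expect_lte(groupNeiDistance(djm, unbiased = TRUE)["X", "Y"] -
             groupNeiDistance(djm)["X", "Y"], 0)
})

test_that("three-taxon neighbour joining hits the closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighborJoining(d)
  pl <- ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(pl, d, tolerance = 1e-12, ignore_attr = TRUE)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(el[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
})

test_that("additive matrices are recovered exactly (path-length oracle)", {
  for (n in c(4, 6, 8)) for (s in 1:3) {
    fx <- randomAdditiveMatrix(n, seed = 100 * n + s)
    tr <- neighborJoining(fx$d)
    pl <- ape::cophenetic.phylo(tr)
    pl <- pl[rownames(fx$d), colnames(fx$d)]
    expect_equal(pl, fx$d, tolerance = 1e-9, ignore_attr = TRUE)
    # topology identical to the generating tree
    expect_equal(ape::dist.topo(ape::unroot(fx$tree), tr)[1L], 0)
  }
})

test_that("neighbour joining agrees with the reference implementation", {
  # independent cross-check: ape's NJ on a generic (non-degenerate) matrix
  set.seed(77)
  x <- matrix(runif(7 * 20), 7)
  rownames(x) <- letters[1:7]
  d <- as.matrix(dist(x))
  expect_equal(ape::dist.topo(neighborJoining(d), ape::nj(d))[1L], 0)
})

test_that("degenerate distance inputs are rejected with advice", {
  d <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighborJoining(d), "impute or subset")
  expect_error(neighborJoining(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))),
               "at least 3")
})

test_that("newick export round-trips topology and lengths", {
  fx <- randomAdditiveMatrix(6, seed = 11)
  tr <- neighborJoining(fx$d)
  f <- tempfile(fileext = ".nwk")
  writeNewick(tr, f)
  txt <- readLines(f)
  expect_true(endsWith(txt[1], ";"))
  back <- ape::read.tree(f)
  expect_equal(ape::dist.topo(back, tr)[1L], 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
})

test_that("cutting the longest internal edge recovers planted clumps", {
  cat3 <- tinyCatalog()
  a <- panelSpec(cat3, n = 5, frequencies = list(
    COL = c(1, 0, 0), SHP = c(1, 0), AWN = 1))
  b <- panelSpec(cat3, n = 5, frequencies = list(
    COL = c(0, 0, 1), SHP = c(0, 1), AWN = 1))
  ta <- simulatePanel(a, seed = 1)@data
  tb <- simulatePanel(b, seed = 2)@data
  tb$accession_id <- sprintf("H%02d", 1:5)
  tm <- traitMatrix(rbind(ta, tb), cat3)
  dm <- genotypeDistance(encodeBinary(tm))
  rep_ <- clusterReport(neighborJoining(dm))
  got <- lapply(rep_$clusters, sort)
  expect_true(setequal(got[[1]], ta$accession_id) ||
              setequal(got[[1]], tb$accession_id))
})
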