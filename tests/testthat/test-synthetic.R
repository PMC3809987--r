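test_that("simulateChronogram produces seeded ultrametric Yule trees", {
  ch <- simulateChronogram(3, 100, seed = 1)
  expect_equal(length(ch@phy$tip.label), 3L)
  expect_equal(ch@phy$Nnode, 2L)
  expect_equal(rootAge(ch), 100, tolerance = 1e-9)
  expect_true(isUltrametric(ch, 1e-6))

  a <- simulateChronogram(25, 50, seed = 7)
  b <- simulateChronogram(25, 50, seed = 7)
  expect_identical(writeNewick(a), writeNewick(b))

  expect_error(simulateChronogram(2, 100, 1), "nTaxa")
  expect_error(simulateChronogram(5, -1, 1), "rootAge")
})

test_that("simulated chronograms always have n-1 ordered internal nodes", {
  for (s in 1:200) {
    ch <- simulateChronogram(20, 10, seed = s)
    expect_equal(ch@phy$Nnode, 19L)
    ages <- nodeAges(ch)
    e <- ch@phy$edge
    expect_true(all(ages[e[, 1]] > ages[e[, 2]]))
  }
})

test_that("assignRates honours each rate model", {
  ch <- simulateChronogram(15, 100, seed = 2)
  ne <- nrow(ch@phy$edge)
  expect_equal(assignRates(ch, rateModel("strict", 0.01), 1),
               rep(0.01, ne))
  # sigma = 0 reduces any kind to strict
  expect_equal(assignRates(ch, rateModel("iid_lognormal", 0.02, 0), 1),
               rep(0.02, ne))
  expect_equal(
    assignRates(ch, rateModel("autocorrelated_lognormal", 0.02, 0), 1),
    rep(0.02, ne))
  r <- assignRates(ch, rateModel("iid_lognormal", 0.01, 0.5), 3)
  expect_true(all(r > 0) && sd(log(r)) > 0)
})

test_that("autocorrelated increments have variance sigma^2 * t / T", {
  # ladder tree: a long caterpillar gives many parent-child rate steps,
  # every backbone edge with duration 1
  n <- 1800
  s <- "(t1:1,t2:1)"
  for (i in 3:n) s <- sprintf("(%s:1,t%d:%d)", s, i, i - 1)
  phy <- ape::read.tree(text = paste0(s, ";"))
  ch <- chronogram(phy)
  Troot <- rootAge(ch)
  sg <- 0.4
  incs <- numeric(0)
  for (s in 1:6) {
    r <- assignRates(ch, rateModel("autocorrelated_lognormal", 0.01, sg), s)
    # backbone edges all have duration 1; collect log-rate steps
    e <- ch@phy$edge
    edgeOfChild <- integer(max(e)); edgeOfChild[e[, 2]] <- seq_len(nrow(e))
    internal <- e[, 2] > length(ch@phy$tip.label)
    for (k in which(internal)) {
      pe <- edgeOfChild[e[k, 1]]
      if (pe > 0) incs <- c(incs, log(r[k]) - log(r[pe]))
    }
  }
  expect_gt(length(incs), 10000)
  # step variance for t = 1 is sigma^2 / T under the height-normalized walk
  expect_equal(var(incs), sg^2 / Troot, tolerance = 0.05)
})

test_that("toPhylogram multiplies durations by rates", {
  ch <- simulateChronogram(10, 50, seed = 3)
  ne <- nrow(ch@phy$edge)
  pg <- toPhylogram(ch, rep(0.02, ne))
  # strict rate: every root-to-leaf path has length r * rootAge
  d <- ape::node.depth.edgelength(pg)[1:10]
  expect_equal(d, rep(0.02 * 50, 10), tolerance = 1e-9)
  expect_true(isUltrametric(pg, 1e-9))

  r <- assignRates(ch, rateModel("iid_lognormal", 0.01, 0.3), 4)
  pg2 <- toPhylogram(ch, r)
  expect_equal(sum(pg2$edge.length), sum(r * ch@phy$edge.length))
  expect_error(toPhylogram(ch, r[-1]), "one rate per branch")

  # zero-duration branch -> zero length
  phy <- readNewick(text = "((A:0,B:0):5,C:5);")
  ch0 <- chronogram(phy)
  pg0 <- toPhylogram(ch0, rep(0.1, 4))
  expect_equal(sort(pg0$edge.length)[1:2], c(0, 0))
})

test_that("alignment simulation hits closed-form expectations", {
  # all branch lengths zero -> constant columns
  phy <- readNewick(text = "((A:0,B:0):0,C:0);")
  aln <- simulateAlignment(phy, jcModel(), 50, seed = 1)
  m <- as.character(aln)
  expect_true(all(apply(m, 2, function(col) length(unique(col)) == 1L)))

  # pInv = 1 is disallowed (must be < 1); pInv near 1 gives near-constant
  mInv <- substitutionModel(pInv = 0.999, nCat = 1L)
  phy2 <- readNewick(text = "((A:2,B:2):1,C:3);")
  aln2 <- simulateAlignment(phy2, mInv, 400, seed = 2)
  frac <- mean(apply(as.character(aln2), 2,
                     function(col) length(unique(col)) == 1L))
  expect_gt(frac, 0.98)

  # JC, two taxa at total distance 5: P(diff) = 0.75(1 - exp(-4*5/3))
  phy3 <- readNewick(text = "(A:2.5,B:2.5);")
  n <- 10000
  aln3 <- simulateAlignment(phy3, jcModel(), n, seed = 3)
  m3 <- as.character(aln3)
  pObs <- mean(m3["A", ] != m3["B", ])
  pExp <- 0.75 * (1 - exp(-4 * 5 / 3))
  se <- sqrt(pExp * (1 - pExp) / n)
  expect_lt(abs(pObs - pExp), 3 * se)

  # determinism
  expect_identical(as.character(simulateAlignment(phy3, jcModel(), 100, 9)),
                   as.character(simulateAlignment(phy3, jcModel(), 100, 9)))
})

test_that("long simulated alignments converge to the stationary freqs", {
  bf <- c(0.4, 0.3, 0.2, 0.1)
  model <- substitutionModel(rates = c(2, 4, 1.5, 1, 6, 1), baseFreqs = bf,
                             shape = 0.7, pInv = 0.1)
  ch <- simulateChronogram(8, 100, seed = 6)
  pg <- toPhylogram(ch, rep(0.005, nrow(ch@phy$edge)))
  n <- 20000
  aln <- simulateAlignment(pg, model, n, seed = 11)
  obs <- empiricalBaseFreqs(aln)
  tot <- n * 8
  for (i in 1:4) {
    se <- sqrt(bf[i] * (1 - bf[i]) / tot)
    # sites are correlated across taxa; allow 3 SE at the per-taxon scale
    expect_lt(abs(obs[i] - bf[i]), 3 * sqrt(bf[i] * (1 - bf[i]) / n))
  }
})

test_that("calibration sets mirror the three designs", {
  ch <- simulateChronogram(30, 200, seed = 9)
  ages <- nodeAges(ch)

  rootOnly <- makeCalibrationSet(ch, "root_only", seed = 1)
  expect_equal(length(rootOnly@clades), 1L)
  expect_false(is.na(rootOnly@minAge[1]) || is.na(rootOnly@maxAge[1]))

  full <- makeCalibrationSet(ch, "full", seed = 2)
  expect_equal(length(full@clades), 11L)
  expect_equal(sum(!is.na(full@maxAge)), 1L)   # only the root carries a max
  # every generated minimum underestimates the true age of the node it
  # constrains (the stem node for stem-attached entries)
  for (i in 2:11) {
    nd <- plchrono:::.resolveCalNode(ch@phy, full@clades[[i]]@taxa,
                                     full@stem[i])
    expect_lte(full@minAge[i], ages[nd])
    expect_gte(full@minAge[i], 0.6 * ages[nd] - 1e-9)
  }

  rps <- makeCalibrationSet(ch, "root_plus_shallow", seed = 3)
  expect_equal(length(rps@clades), 2L)
  nd <- mrcaNode(ch@phy, rps@clades[[2]]@taxa)
  internalAges <- ages[setdiff(31:59, 31)]
  expect_lte(ages[nd], quantile(internalAges, 0.25) + 1e-9)

  # avoid: no fossil minimum inside the avoided clade
  sub <- ch@phy$tip.label[plchrono:::.tipsBelow(ch@phy, 35)]
  if (length(sub) >= 4 && length(sub) <= 18) {
    fullAv <- makeCalibrationSet(ch, "full", seed = 4, avoid = sub)
    for (i in 2:11)
      expect_false(all(fullAv@clades[[i]]@taxa %in% sub))
  }
})

test_that("calibration validity rules hold", {
  cl <- list(cladeSpec("a", c("A", "B")))
  expect_error(calibrationSet(cl), "at least one bound")
  expect_error(calibrationSet(cl, minAge = 10, maxAge = 5), "exceeds")
  expect_error(calibrationSet(cl, minAge = 10), "maximum or fixed")
  expect_s4_class(calibrationSet(cl, minAge = 5, maxAge = 10),
                  "CalibrationSet")
})

test_that("alignment and calibration files round-trip", {
  ch <- simulateChronogram(6, 50, seed = 2)
  pg <- toPhylogram(ch, rep(0.01, nrow(ch@phy$edge)))
  aln <- simulateAlignment(pg, jcModel(), 120, seed = 5)

  fa <- tempfile(fileext = ".fasta")
  writeFasta(aln, fa)
  expect_identical(as.character(readFasta(fa)), as.character(aln))

  ph <- tempfile(fileext = ".phy")
  writePhylip(aln, ph)
  expect_identical(as.character(readPhylip(ph)), as.character(aln))

  cal <- makeCalibrationSet(ch, "root_plus_shallow", seed = 4)
  yf <- tempfile(fileext = ".yaml")
  writeCalibrations(cal, yf)
  back <- readCalibrations(yf)
  expect_equal(length(back@clades), length(cal@clades))
  expect_equal(back@minAge, cal@minAge)
  expect_equal(back@maxAge, cal@maxAge)
  expect_identical(back@clades[[2]]@taxa, cal@clades[[2]]@taxa)
})

test_that("the packaged benchmark has the documented shape", {
  bm <- simulateBenchmark(seed = 3, nSites = 200L)
  expect_equal(length(bm$chronogram@phy$tip.label), 48L)
  expect_equal(rootAge(bm$chronogram), 180, tolerance = 1e-6)
  expect_equal(crownAge(bm$chronogram, bm$clades$ingroup), 60,
               tolerance = 1e-6)
  expect_equal(length(bm$outgroupTaxa), 8L)
  expect_equal(length(bm$calibrations$full@clades), 11L)
  expect_true(isUltrametric(bm$chronogram, 1e-6))
})
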