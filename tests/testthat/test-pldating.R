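test_that("the PL objective evaluates the Poisson kernel", {
  # two-leaf tree with one informative branch: x = 10, r*t = 10, lambda 0
  phy <- readNewick(text = "(A:10,B:0.000000001);")
  cal <- calibrationSet(list(cladeSpec("root", c("A", "B"))), fixedAge = 1)
  cfg <- plConfig(nSites = 1, lambda = 0, restarts = 1L)
  pr <- plProblem(phy, cal, cfg)
  ages <- c(0, 0, 1)
  tiny <- 1e-9
  val <- plObjective(pr, ages, c(10, tiny))
  expect_equal(val, 10 * log(10) - 10 - tiny * 1 - tiny, tolerance = 1e-6)

  # equal rates: penalty contributes exactly zero
  ch <- simulateChronogram(8, 50, seed = 2)
  pg <- toPhylogram(ch, rep(0.01, nrow(ch@phy$edge)))
  cal2 <- calibrationSet(list(cladeSpec("root", ch@phy$tip.label)),
                         fixedAge = 50)
  mkpr <- function(lambda) plProblem(pg, cal2,
                                     plConfig(nSites = 100, lambda = lambda))
  ages2 <- nodeAges(ch)
  rEq <- rep(0.01, nrow(pg$edge))
  expect_equal(plObjective(mkpr(5), ages2, rEq),
               plObjective(mkpr(0), ages2, rEq))
  # unequal rates: objective decreases as lambda grows
  set.seed(1)
  rNe <- rEq * exp(rnorm(length(rEq), 0, 0.5))
  v <- vapply(c(0, 0.5, 5, 50), function(l)
    plObjective(mkpr(l), ages2, rNe), numeric(1))
  expect_true(all(diff(v) < 0))

  expect_error(plObjective(mkpr(1), rev(ages2), rEq), "non-positive")
})

test_that("ratePenalty matches hand arithmetic and a re-implementation", {
  phy <- readNewick(text = "((A:1,B:1):1,C:2);")
  # edges: root->I, I->A, I->B, root->C (ape order may differ; build map)
  root <- 4L
  e <- phy$edge
  rates <- numeric(4)
  iEdge <- which(e[, 1] == root & e[, 2] == 5L)
  cEdge <- which(e[, 1] == root & e[, 2] <= 3L)
  kidEdges <- which(e[, 1] == 5L)
  rates[iEdge] <- exp(1)
  rates[kidEdges[1]] <- exp(2)    # one squared log step of 1
  rates[kidEdges[2]] <- exp(1)
  rates[cEdge] <- exp(1)          # root children equal -> zero variance
  expect_equal(ratePenalty(rates, phy, "log"), 1)
  expect_equal(ratePenalty(rep(0.3, 4), phy, "log"), 0)
  expect_equal(ratePenalty(rep(0.3, 4), phy, "additive"), 0)

  # independent re-computation on random trees
  refPenalty <- function(rates, phy, kind) {
    v <- if (kind == "log") log(rates) else rates
    root <- length(phy$tip.label) + 1L
    tot <- 0
    for (k in seq_len(nrow(phy$edge))) {
      p <- phy$edge[k, 1]
      if (p == root) next
      pe <- which(phy$edge[, 2] == p)
      tot <- tot + (v[k] - v[pe])^2
    }
    tot + var(v[phy$edge[, 1] == root])
  }
  set.seed(10)
  for (i in 1:20) {
    phy <- ape::rtree(10)
    r <- exp(rnorm(nrow(phy$edge), -4, 1))
    for (kind in c("log", "additive"))
      expect_equal(ratePenalty(r, phy, kind), refPenalty(r, phy, kind),
                   tolerance = 1e-12)
  }
})

test_that("fitPL recovers exact strict-clock data", {
  toy <- makeToyProblem(nTaxa = 12, rootAge = 120, rate = 0.008,
                        seed = 5, nSites = 2000)
  sol <- fitPL(toy$problem)
  expect_true(sol@converged)
  at <- nodeAges(toy$chron)
  ae <- nodeAges(sol@chronogram)
  int <- 13:23
  expect_lt(max(abs(ae[int] - at[int]) / at[int]), 0.01)
  expect_lt(max(abs(sol@rates - 0.008) / 0.008), 0.01)
  expect_true(isUltrametric(sol@chronogram@phy, 1e-6))
  # best restart wins
  expect_gte(sol@objective + 1e-9, max(sol@restartObjectives))
})

test_that("a minimum above the unconstrained estimate becomes active", {
  toy <- makeToyProblem(nTaxa = 10, rootAge = 100, rate = 0.01, seed = 9,
                        nSites = 1500)
  # pick a mid-depth internal node and push its minimum above truth
  ages <- nodeAges(toy$chron)
  nd <- order(abs(ages - 50))[match(TRUE, order(abs(ages - 50)) > 10)]
  taxa <- toy$chron@phy$tip.label[plchrono:::.tipsBelow(toy$chron@phy, nd)]
  bump <- min(1.4 * ages[nd], 0.95 * 100)
  cal <- calibrationSet(
    list(cladeSpec("root", toy$chron@phy$tip.label),
         cladeSpec("pushed", taxa)),
    minAge = c(NA, bump), fixedAge = c(100, NA))
  sol <- fitPL(plProblem(toy$phylog, cal, toy$cfg))
  fitted <- nodeAges(sol@chronogram)[mrcaNode(sol@chronogram@phy, taxa)]
  expect_equal(fitted, bump, tolerance = 1e-6)
  expect_true(any(sol@activeConstraints$calibration == "pushed" &
                    sol@activeConstraints$side == "min"))
})

test_that("large smoothing shrinks the fitted rate spread", {
  ch <- simulateChronogram(14, 90, seed = 13)
  rates <- assignRates(ch, rateModel("iid_lognormal", 0.01, 0.6), 3)
  pg <- toPhylogram(ch, rates)
  cal <- calibrationSet(list(cladeSpec("root", ch@phy$tip.label)),
                        fixedAge = 90)
  fit <- function(lam) fitPL(plProblem(pg, cal,
                                       testConfig(1000, lambda = lam)))
  spread <- function(sol) max(sol@rates) / min(sol@rates)
  expect_lt(spread(fit(1e6)), spread(fit(0.1)))
  # near-clock limit: spread close to 1
  expect_lt(spread(fit(1e6)), 1.05)
})

test_that("lambda = 0 reproduces the per-branch rate MLE x/t", {
  # 3-taxon problem with the root fixed: one free internal age
  phy <- readNewick(text = "((A:0.10,B:0.14):0.05,C:0.21);")
  cal <- calibrationSet(list(cladeSpec("root", c("A", "B", "C"))),
                        fixedAge = 20)
  L <- 500
  cfg <- plConfig(nSites = L, lambda = 0, restarts = 3L, seed = 1)
  pr <- plProblem(phy, cal, cfg)
  sol <- fitPL(pr)
  ages <- nodeAges(sol@chronogram)
  t <- ages[pr@phy$edge[, 1]] - ages[pr@phy$edge[, 2]]
  expect_equal(sol@rates, pr@x / t / L, tolerance = 1e-6)

  # 2-D grid-search oracle over the free age (and rates profiled out):
  # at lambda 0 the profiled objective is constant in the ages, so the
  # fit must attain it
  expect_equal(sol@objective,
               sum(ifelse(pr@x > 0, pr@x * log(pr@x) - pr@x, 0)),
               tolerance = 1e-6)
})

test_that("fitPL objective attains a grid-search oracle on 4 taxa", {
  set.seed(77)
  ch <- simulateChronogram(4, 50, seed = 19)
  rates <- assignRates(ch, rateModel("iid_lognormal", 0.01, 0.5), 6)
  pg <- toPhylogram(ch, rates)
  cal <- calibrationSet(list(cladeSpec("root", ch@phy$tip.label)),
                        fixedAge = 50)
  lam <- 0.9
  cfg <- plConfig(nSites = 800, lambda = lam, restarts = 3L, seed = 5)
  pr <- plProblem(pg, cal, cfg)
  sol <- fitPL(pr)
  x <- pr@x
  root <- 5L
  free <- 6:7
  grid <- seq(0.5, 49.5, length.out = 50)
  best <- -Inf
  for (a6 in grid) for (a7 in grid) {
    A <- c(0, 0, 0, 0, 50, a6, a7)
    t <- A[pg$edge[, 1]] - A[pg$edge[, 2]]
    if (any(t <= 0)) next
    r0 <- pmax(x / t, 1e-8)
    o <- optim(log(r0), function(u) {
      rr <- exp(u)
      -(sum(ifelse(x > 0, x * (u + log(t)), 0) - rr * t) -
          lam * ratePenalty(rr, pg, "log"))
    }, method = "BFGS", control = list(maxit = 200))
    best <- max(best, -o$value)
  }
  expect_gte(sol@objective, best - 1e-4)
})

test_that("fitted ages scale linearly with the calibration scale", {
  # a fixed root pins the scale; the objective shape is invariant under
  # joint rescaling of ages and rates, so the solution must rescale too
  toy <- makeToyProblem(nTaxa = 8, rootAge = 60, rate = 0.01, sigma = 0.3,
                        seed = 11, nSites = 800, fixRoot = TRUE)
  sol1 <- fitPL(toy$problem)
  c_ <- 2.5
  cal2 <- calibrationSet(toy$cal@clades, fixedAge = 60 * c_)
  sol2 <- fitPL(plProblem(toy$phylog, cal2, toy$cfg))
  expect_equal(nodeAges(sol2@chronogram), c_ * nodeAges(sol1@chronogram),
               tolerance = 1e-3)
  expect_equal(sol2@rates, sol1@rates / c_, tolerance = 1e-3)
})

test_that("infeasible calibrations are rejected before optimization", {
  phy <- readNewick(text = "((A:1,B:1):1,C:2);")
  cal <- calibrationSet(
    list(cladeSpec("root", c("A", "B", "C")), cladeSpec("ab", c("A", "B"))),
    minAge = c(NA, 50), maxAge = c(40, NA))
  expect_error(plProblem(phy, cal, plConfig(nSites = 100)), "infeasible")
  # calibration reduced below two taxa
  cal2 <- calibrationSet(list(cladeSpec("root", c("A", "B", "C")),
                              cladeSpec("dead", c("A", "Z"))),
                         maxAge = c(40, 30))
  expect_error(plProblem(phy, cal2, plConfig(nSites = 100)),
               "cannot be placed")
})

test_that("every fitted chronogram satisfies its calibration bounds", {
  for (s in 1:4) {
    ch <- simulateChronogram(12, 150, seed = s)
    rates <- assignRates(ch, rateModel("autocorrelated_lognormal",
                                       0.01, 0.4), s + 50)
    pg <- toPhylogram(ch, rates)
    cal <- makeCalibrationSet(ch, "full", seed = s, nInternal = 10L)
    sol <- fitPL(plProblem(pg, cal, testConfig(1000)))
    expect_true(isUltrametric(sol@chronogram@phy, 1e-6))
    ages <- nodeAges(sol@chronogram)
    for (i in seq_along(cal@clades)) {
      nd <- plchrono:::.resolveCalNode(sol@chronogram@phy,
                                       cal@clades[[i]]@taxa, cal@stem[i])
      if (!is.na(cal@minAge[i]))
        expect_gte(ages[nd], cal@minAge[i] - 1e-6)
      if (!is.na(cal@maxAge[i]))
        expect_lte(ages[nd], cal@maxAge[i] + 1e-6)
    }
  }
})

test_that("fitPL broadly agrees with an independent PL implementation", {
  ch <- simulateChronogram(15, 100, seed = 23)
  rates <- assignRates(ch, rateModel("autocorrelated_lognormal", 0.008,
                                     0.3), 4)
  pg <- toPhylogram(ch, rates)
  cal <- calibrationSet(list(cladeSpec("root", ch@phy$tip.label)),
                        fixedAge = 100)
  sol <- fitPL(plProblem(pg, cal, testConfig(1500)))
  chr <- suppressWarnings(suppressMessages(
    ape::chronos(pg, lambda = 0.9, model = "correlated",
                 calibration = data.frame(node = 16L, age.min = 100,
                                          age.max = 100),
                 control = ape::chronos.control())))
  agesApe <- ape::branching.times(chr)
  agesOwn <- nodeAges(sol@chronogram)[16:29]
  # the two implementations weight the penalty differently, so agreement
  # is broad rather than exact; recovery of the generating ages is tight
  expect_gt(cor(agesOwn, as.numeric(agesApe)), 0.8)
  expect_gt(cor(agesOwn, nodeAges(ch)[16:29]), 0.99)
})

test_that("profileAges computes PROFILE-style summaries", {
  ch <- simulateChronogram(10, 40, seed = 31)
  cl <- cladeSpec("all", ch@phy$tip.label)
  p1 <- profileAges(list(ch), list(cl))
  expect_equal(p1@table$mean, 40, tolerance = 1e-9)
  expect_equal(p1@table$sd, 0)
  expect_equal(p1@table$nValid, 1L)

  # hand arithmetic on {10, 20}
  mk <- function(age) chronogram(readNewick(
    text = sprintf("(A:%f,B:%f);", age, age)))
  p2 <- profileAges(list(mk(10), mk(20)), list(cladeSpec("ab", c("A", "B"))))
  expect_equal(p2@table$mean, 15)
  expect_equal(p2@table$sd, sqrt(50), tolerance = 1e-9)

  # a tree where the clade keeps <2 taxa is excluded from the summary
  small <- chronogram(readNewick(text = "(A:5,(X:2,Y:2):3);"))
  p3 <- profileAges(list(mk(10), small), list(cladeSpec("ab", c("A", "B"))))
  expect_equal(p3@table$nValid, 1L)
  expect_equal(p3@table$mean, 10)
  expect_equal(p3@table$nTotal, 2L)
})

test_that("cross-validation prefers heavy smoothing on clock-true data", {
  toy <- makeToyProblem(nTaxa = 8, rootAge = 80, rate = 0.01, seed = 41,
                        nSites = 600, restarts = 1L)
  cv <- crossValidate(toy$problem, c(0.1, 10, 1000))
  expect_true(all(is.finite(cv$score) & cv$score >= 0))
  # exact clock data is predicted essentially perfectly at every lambda;
  # the largest lambda ties for the minimum
  expect_lt(max(cv$score), 1e-6)
  expect_lte(cv$score[3], min(cv$score) + 1e-9)
})

test_that("cross-validation helps on rate-variable data", {
  toy <- makeToyProblem(nTaxa = 10, rootAge = 80, rate = 0.01, sigma = 0.6,
                        seed = 43, nSites = 1200, restarts = 1L)
  grid <- c(0.01, 1, 100)
  cv <- crossValidate(toy$problem, grid)
  ageErr <- vapply(grid, function(l) {
    cfg <- toy$cfg; cfg@lambda <- l; cfg@restarts <- 1L
    sol <- fitPL(plProblem(toy$phylog, toy$cal, cfg))
    stats::median(abs(nodeAges(sol@chronogram) - nodeAges(toy$chron)))
  }, numeric(1))
  expect_lte(ageErr[which.min(cv$score)], max(ageErr))
})
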