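# Shared fixtures, all generated in code.

# Jukes-Cantor special case of the GTR+G+I family (no rate variation)
jcModel <- function() substitutionModel(nCat = 1L)

# random base frequencies bounded away from 0
randFreqs <- function() {
  x <- runif(4, 0.5, 2)
  x / sum(x)
}

# fast PL configuration for tests
testConfig <- function(nSites, restarts = 2L, ...) {
  plConfig(nSites = nSites, restarts = restarts, seed = 42L, ...)
}

# small simulated dating problem with known truth
makeToyProblem <- function(nTaxa = 10, rootAge = 100, rate = 0.01,
                           sigma = 0, seed = 7, nSites = 1000,
                           fixRoot = TRUE, lambda = 0.9, ...) {
  chron <- simulateChronogram(nTaxa, rootAge, seed)
  kind <- if (sigma > 0) "autocorrelated_lognormal" else "strict"
  rates <- assignRates(chron, rateModel(kind, rate, sigma), seed + 1)
  phylog <- toPhylogram(chron, rates)
  cal <- if (fixRoot) {
    calibrationSet(list(cladeSpec("root", chron@phy$tip.label)),
                   fixedAge = rootAge)
  } else {
    calibrationSet(list(cladeSpec("root", chron@phy$tip.label)),
                   minAge = 0.8 * rootAge, maxAge = 1.2 * rootAge)
  }
  cfg <- testConfig(nSites, lambda = lambda, ...)
  list(chron = chron, rates = rates, phylog = phylog, cal = cal,
       cfg = cfg, problem = plProblem(phylog, cal, cfg))
}

# exhaustive-enumeration likelihood oracle: sums over all internal-state
# assignments per site; independent of the pruning implementation
enumLogLik <- function(aln, tree, model) {
  m <- as.character(aln)
  states <- c(a = 1L, c = 2L, g = 3L, t = 4L)
  n <- length(tree$tip.label)
  internals <- (n + 1L):(n + tree$Nnode)
  cls <- plchrono:::.siteRateClasses(model)
  eig <- plchrono:::.gtrEigen(model)
  pi <- model@baseFreqs
  total <- 0
  for (site in seq_len(ncol(m))) {
    siteLik <- 0
    for (ci in seq_along(cls$rates)) {
      Ps <- lapply(seq_len(nrow(tree$edge)), function(e) {
        d <- tree$edge.length[e] * cls$rates[ci]
        if (d == 0) diag(4) else plchrono:::.gtrProb(eig, d)
      })
      lik <- 0
      grid <- do.call(expand.grid, rep(list(1:4), length(internals)))
      for (gi in seq_len(nrow(grid))) {
        assign_ <- integer(n + tree$Nnode)
        for (tip in seq_len(n))
          assign_[tip] <- states[[m[tree$tip.label[tip], site]]]
        assign_[internals] <- as.integer(grid[gi, ])
        p <- pi[assign_[n + 1L]]
        for (e in seq_len(nrow(tree$edge)))
          p <- p * Ps[[e]][assign_[tree$edge[e, 1L]],
                           assign_[tree$edge[e, 2L]]]
        lik <- lik + p
      }
      siteLik <- siteLik + cls$weights[ci] * lik
    }
    total <- total + log(siteLik)
  }
  total
}

# the benchmark study is shared by several acceptance checks; computed on
# first use and cached for the session
benchStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- runBenchmarkStudy()
    cache
  }
})
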