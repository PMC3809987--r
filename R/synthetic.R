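## Synthetic-data generators: pure-birth chronograms, branch rates,
## phylograms, GTR+Gamma+I alignments, and fossil-style calibration sets
## with known ground truth.  Everything is deterministic given an integer
## seed, so downstream stages are testable end to end without external data.

#' Simulate a pure-birth (Yule) chronogram
#'
#' A Yule topology with \code{nTaxa} extant leaves, node times rescaled so
#' the root sits exactly at \code{rootAge}.  Ultrametric by construction and
#' deterministic for a given seed.
#'
#' @param nTaxa number of extant leaves (>= 3).
#' @param rootAge root age in MYA (> 0).
#' @param seed integer seed.
#' @return a \linkS4class{Chronogram}.
#' @export
simulateChronogram <- function(nTaxa, rootAge, seed) {
  if (nTaxa < 3L) stop("nTaxa must be >= 3")
  if (rootAge <= 0) stop("rootAge must be > 0")
  set.seed(as.integer(seed))
  phy <- phytools::pbtree(n = nTaxa, scale = rootAge, quiet = TRUE)
  new("Chronogram", phy = phy)
}

#' Assign per-branch substitution rates
#'
#' Lays rates over a chronogram under a \linkS4class{RateModel}; see that
#' class for the three generating processes.  Rates are returned in the
#' order of \code{chronoTree(chron)$edge} rows.
#'
#' @param chron a \linkS4class{Chronogram}.
#' @param model a \linkS4class{RateModel}.
#' @param seed integer seed.
#' @return numeric vector of branch rates (substitutions/site/MY).
#' @export
assignRates <- function(chron, model, seed) {
  phy <- chron@phy
  ne <- nrow(phy$edge)
  mu <- model@meanRate
  sg <- model@sigma
  if (model@kind == "strict" || sg == 0) return(rep(mu, ne))
  set.seed(as.integer(seed))
  if (model@kind == "iid_lognormal") {
    return(exp(rnorm(ne, log(mu) - sg^2 / 2, sg)))
  }
  ## autocorrelated: geometric Brownian walk down the tree; branch-step
  ## variance sigma^2 * t / T so sigma is the root-to-tip log-rate SD
  Troot <- rootAge(chron)
  ord <- reorder(phy, "cladewise")
  perm <- match(paste(ord$edge[, 1L], ord$edge[, 2L]),
                paste(phy$edge[, 1L], phy$edge[, 2L]))
  root <- length(phy$tip.label) + 1L
  logr <- numeric(ne)              # indexed by original edge order
  nodeLog <- rep(NA_real_, max(phy$edge))
  nodeLog[root] <- log(mu)
  for (i in seq_len(ne)) {
    e <- perm[i]
    p <- phy$edge[e, 1L]
    ch <- phy$edge[e, 2L]
    t <- phy$edge.length[e]
    logr[e] <- rnorm(1L, nodeLog[p], sg * sqrt(max(t, 0) / Troot))
    nodeLog[ch] <- logr[e]
  }
  exp(logr)
}

#' Convert a chronogram plus rates into a phylogram
#'
#' Branch lengths become \eqn{b_k = r_k t_k} expected substitutions per
#' site, the quantity penalized-likelihood dating decomposes back into rate
#' and time.
#'
#' @param chron a \linkS4class{Chronogram}.
#' @param rates positive branch rates, one per edge, in edge order.
#' @return a \code{phylo} phylogram.
#' @export
toPhylogram <- function(chron, rates) {
  phy <- chron@phy
  if (length(rates) != nrow(phy$edge))
    stop("need one rate per branch (", nrow(phy$edge), " edges, got ",
         length(rates), " rates)")
  if (any(rates <= 0)) stop("rates must be positive")
  phy$edge.length <- phy$edge.length * rates
  phy
}

#' Discrete-gamma rate categories
#'
#' Category rates of the K-category discretization of a Gamma(shape, shape)
#' distribution (mean 1), using category means (default) or medians
#' rescaled to mean 1.
#'
#' @param shape gamma shape alpha (> 0).
#' @param k number of categories.
#' @param median use category medians instead of means.
#' @return numeric vector of k rates with mean 1.
#' @export
discreteGammaRates <- function(shape, k, median = FALSE) {
  if (k == 1L) return(1)
  if (median) {
    q <- qgamma((seq_len(k) * 2 - 1) / (2 * k), shape, shape)
    return(q / mean(q))
  }
  b <- qgamma(seq(0, 1, length.out = k + 1L), shape, shape)
  ## E[X ; a < X < b] for X ~ Gamma(s, s) equals
  ## pgamma(b, s + 1, s) - pgamma(a, s + 1, s)  (mean-1 identity)
  k * diff(pgamma(b, shape + 1, shape))
}

## site-rate classes for a model: values and weights; class 1 is the
## invariant class (rate 0) when pInv > 0.  Variable rates are scaled by
## 1/(1 - pInv) so the overall mean rate is 1.
.siteRateClasses <- function(model) {
  g <- discreteGammaRates(model@shape, model@nCat, model@gammaMedian)
  if (model@pInv > 0) {
    list(rates = c(0, g / (1 - model@pInv)),
         weights = c(model@pInv, rep((1 - model@pInv) / model@nCat,
                                     model@nCat)))
  } else {
    list(rates = g, weights = rep(1 / model@nCat, model@nCat))
  }
}

#' Simulate an alignment on a phylogram
#'
#' Root states are drawn from the stationary frequencies; each site is
#' assigned to the invariant class (probability \code{pInv}) or one of the
#' discrete-gamma rate classes, and evolved down every branch with the
#' GTR transition matrix for (branch length x site-rate multiplier).
#' Deterministic per seed.
#'
#' @param phylo a \code{phylo} with branch lengths in substitutions/site.
#' @param model a \linkS4class{SubstitutionModel}.
#' @param nSites number of sites (>= 1).
#' @param seed integer seed.
#' @return a \code{phangorn::phyDat} alignment (site-pattern compressed).
#' @export
simulateAlignment <- function(phylo, model, nSites, seed) {
  if (nSites < 1L) stop("nSites must be >= 1")
  set.seed(as.integer(seed))
  cls <- .siteRateClasses(model)
  siteClass <- sample.int(length(cls$rates), nSites, replace = TRUE,
                          prob = cls$weights)
  n <- length(phylo$tip.label)
  root <- n + 1L
  states <- matrix(0L, max(phylo$edge), nSites)
  states[root, ] <- sample.int(4L, nSites, replace = TRUE,
                               prob = model@baseFreqs)
  ord <- reorder(phylo, "cladewise")
  perm <- match(paste(ord$edge[, 1L], ord$edge[, 2L]),
                paste(phylo$edge[, 1L], phylo$edge[, 2L]))
  eig <- .gtrEigen(model)
  for (e in perm) {
    p <- phylo$edge[e, 1L]
    ch <- phylo$edge[e, 2L]
    b <- phylo$edge.length[e]
    states[ch, ] <- states[p, ]
    for (cl in unique(siteClass)) {
      d <- b * cls$rates[cl]
      if (d == 0) next
      P <- .gtrProb(eig, d)
      for (s in 1:4) {
        idx <- which(siteClass == cl & states[p, ] == s)
        if (length(idx))
          states[ch, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                        prob = P[s, ])
      }
    }
  }
  bases <- c("a", "c", "g", "t")
  tipSeqs <- matrix(bases[states[seq_len(n), , drop = FALSE]], nrow = n,
                    dimnames = list(phylo$tip.label, NULL))
  phangorn::phyDat(tipSeqs, type = "DNA")
}

#' Generate a fossil-style calibration set from a known chronogram
#'
#' Emulates the three calibration designs of the empirical analysis this
#' package reproduces:
#' \describe{
#'   \item{full}{a min+max window on the root (\code{rootWindow} times the
#'     true root age) plus \code{nInternal} internal nodes given minimum
#'     ages equal to a Uniform(\code{minFraction}) fraction of their true
#'     age -- fossil minima always underestimate the true age.}
#'   \item{root_only}{just the root window.}
#'   \item{root_plus_shallow}{the root window plus one minimum on a shallow
#'     (youngest-quartile) internal node.}
#' }
#' Fossil minima attach to stems: the calibration clade is the chosen
#' node's larger child subtree and the entry is stem-attached, so it keeps
#' constraining that lineage even when subsampling leaves a single member
#' (a cherry falls back to a crown constraint on its two tips).
#'
#' @param chron the true \linkS4class{Chronogram}.
#' @param strategy calibration design.
#' @param seed integer seed.
#' @param nInternal number of internal minimum-age calibrations for
#'   \code{strategy = "full"} (default 10).
#' @param minFraction range of the fossil-minimum fraction of the true age.
#' @param rootWindow multiplicative (min, max) window on the true root age.
#' @param avoid optional character vector of taxa; internal nodes whose
#'   descendants all lie inside \code{avoid} are never picked (use it to
#'   keep fossil minima outside a clade that will be subsampled).
#' @return a \linkS4class{CalibrationSet}.
#' @export
makeCalibrationSet <- function(chron,
                               strategy = c("full", "root_only",
                                            "root_plus_shallow"),
                               seed = 1L, nInternal = 10L,
                               minFraction = c(0.6, 0.95),
                               rootWindow = c(0.8, 1.2), avoid = NULL) {
  strategy <- match.arg(strategy)
  phy <- chron@phy
  n <- length(phy$tip.label)
  ages <- nodeAges(chron)
  root <- n + 1L
  set.seed(as.integer(seed))

  clades <- list(cladeSpec("root", phy$tip.label))
  minAge <- rootWindow[1L] * ages[root]
  maxAge <- rootWindow[2L] * ages[root]
  stem <- FALSE

  ## the constrained node is nd; fossil minima attach to stems, so the
  ## calibration clade is nd's larger child subtree (with >= 2 tips) and
  ## the entry is stem-attached -- it keeps constraining (the lineage
  ## through) nd even when subsampling reduces the clade to one member.
  ## When both children are single tips (a cherry) the entry falls back
  ## to a crown constraint on the pair.
  cladeFor <- function(nd) {
    kids <- phy$edge[phy$edge[, 1L] == nd, 2L]
    tipsets <- lapply(kids, function(k) phy$tip.label[.tipsBelow(phy, k)])
    big <- which.max(lengths(tipsets))
    if (lengths(tipsets)[big] >= 2L) {
      list(taxa = tipsets[[big]], stem = TRUE)
    } else {
      list(taxa = phy$tip.label[.tipsBelow(phy, nd)], stem = FALSE)
    }
  }
  pickMinima <- function(nodes) {
    u <- runif(length(nodes), minFraction[1L], minFraction[2L])
    for (i in seq_along(nodes)) {
      nd <- nodes[i]
      cf <- cladeFor(nd)
      clades[[length(clades) + 1L]] <<-
        cladeSpec(sprintf("cal%02d", i), cf$taxa)
      minAge <<- c(minAge, u[i] * ages[nd])
      maxAge <<- c(maxAge, NA_real_)
      stem <<- c(stem, cf$stem)
    }
  }

  internal <- setdiff(seq.int(n + 1L, n + phy$Nnode), root)
  if (!is.null(avoid)) {
    inside <- vapply(internal, function(nd) {
      all(cladeFor(nd)$taxa %in% avoid) ||
        all(phy$tip.label[.tipsBelow(phy, nd)] %in% avoid)
    }, logical(1L))
    internal <- internal[!inside]
  }
  if (strategy == "full") {
    if (length(internal) < nInternal)
      stop("need at least ", nInternal + 2L,
           " internal nodes for strategy 'full'")
    pickMinima(sample(internal, nInternal))
  } else if (strategy == "root_plus_shallow") {
    shallow <- internal[ages[internal] <= stats::quantile(ages[internal], 0.25)]
    pickMinima(sample(shallow, 1L))
  }
  calibrationSet(clades, minAge = minAge, maxAge = maxAge, stem = stem)
}

## tip indices below a node (the node itself when it is a tip)
.tipsBelow <- function(phy, node) {
  n <- length(phy$tip.label)
  if (node <= n) return(node)
  unlist(phangorn::Descendants(phy, node, type = "tips"))
}

#' Assemble the packaged synthetic benchmark
#'
#' A chronogram with a dated ingroup radiation and an outgroup clade joined
#' at a deep root, autocorrelated branch rates, a simulated alignment, and
#' the three calibration designs.  This is the stand-in for the empirical
#' backbone-tree analysis: the true node ages are known, so the
#' undersampling and calibration experiments can be scored against truth.
#'
#' Default dimensions: 40 ingroup taxa (crown 60 MYA), 8 outgroup taxa
#' (crown 100 MYA), root at 180 MYA, autocorrelated lognormal rates with
#' mean 0.005 substitutions/site/MY and sigma 0.4, 1500 sites under
#' GTR+Gamma+I.  The 10 fossil-style internal minima are placed on random
#' internal nodes across the whole tree; under heavy subsampling of the
#' ingroup, calibrated clades reduced below two sampled members lose their
#' constraint, which is part of the undersampling phenomenon the benchmark
#' emulates.
#'
#' @param seed integer seed driving every stochastic step.
#' @param nIngroup,nOutgroup taxon counts.
#' @param rootAge,ingroupCrownAge,outgroupCrownAge ages in MYA.
#' @param rates a \linkS4class{RateModel}.
#' @param model a \linkS4class{SubstitutionModel}.
#' @param nSites alignment length.
#' @return list with elements \code{chronogram}, \code{rates},
#'   \code{phylogram}, \code{alignment}, \code{calibrations} (named list:
#'   full, root_only, root_plus_shallow), \code{clades} (named list of
#'   \linkS4class{CladeSpec}: ingroup plus its two basal subclades), and
#'   \code{outgroupTaxa}.
#' @export
simulateBenchmark <- function(seed, nIngroup = 40L, nOutgroup = 8L,
                              rootAge = 180, ingroupCrownAge = 60,
                              outgroupCrownAge = 100,
                              rates = rateModel("autocorrelated_lognormal",
                                                meanRate = 0.005,
                                                sigma = 0.4),
                              model = substitutionModel(
                                rates = c(2, 8, 1.5, 1, 16, 1),
                                baseFreqs = c(0.35, 0.30, 0.10, 0.25),
                                shape = 0.5, pInv = 0.2),
                              nSites = 1500L) {
  seed <- as.integer(seed)
  ing <- simulateChronogram(nIngroup, ingroupCrownAge, seed)@phy
  outg <- simulateChronogram(nOutgroup, outgroupCrownAge, seed + 1L)@phy
  ing$tip.label <- sprintf("I%02d", seq_len(nIngroup))
  outg$tip.label <- sprintf("O%02d", seq_len(nOutgroup))
  nwk <- sprintf("(%s:%.10f,%s:%.10f);",
                 sub(";$", "", ape::write.tree(ing, digits = 12)),
                 rootAge - ingroupCrownAge,
                 sub(";$", "", ape::write.tree(outg, digits = 12)),
                 rootAge - outgroupCrownAge)
  chron <- new("Chronogram", phy = ape::read.tree(text = nwk))
  phy <- chron@phy

  r <- assignRates(chron, rates, seed + 2L)
  phylog <- toPhylogram(chron, r)
  aln <- simulateAlignment(phylog, model, nSites, seed + 3L)

  ingTaxa <- ing$tip.label
  cal <- list(
    full = makeCalibrationSet(chron, "full", seed + 4L),
    root_only = makeCalibrationSet(chron, "root_only", seed + 4L),
    root_plus_shallow = makeCalibrationSet(chron, "root_plus_shallow",
                                           seed + 4L))

  ## the ingroup's two basal subclades (sister-clade bias checks)
  ingRoot <- ape::getMRCA(phy, ingTaxa)
  kids <- phy$edge[phy$edge[, 1L] == ingRoot, 2L]
  sub <- lapply(kids, function(nd) phy$tip.label[.tipsBelow(phy, nd)])
  bigger <- which.max(lengths(sub))
  clades <- list(ingroup = cladeSpec("ingroup", ingTaxa))
  if (all(lengths(sub) >= 2L)) {
    clades$ingroupA <- cladeSpec("ingroupA", sub[[bigger]])
    clades$ingroupB <- cladeSpec("ingroupB", sub[[3L - bigger]])
  }
  list(chronogram = chron, rates = r, phylogram = phylog, alignment = aln,
       calibrations = cal, clades = clades, outgroupTaxa = outg$tip.label)
}

## ---------------------------------------------------------------------------
## Alignment and calibration file formats
## ---------------------------------------------------------------------------

#' Write an alignment as FASTA
#' @param aln a \code{phyDat}.
#' @param file output path.
#' @export
writeFasta <- function(aln, file) {
  phangorn::write.phyDat(aln, file, format = "fasta")
  invisible(file)
}

#' Read a FASTA alignment
#' @param file input path.
#' @return a \code{phyDat}.
#' @export
readFasta <- function(file) phangorn::read.phyDat(file, format = "fasta")

#' Write an alignment as relaxed PHYLIP
#'
#' Relaxed format: header "ntax nsites", then one "name sequence" line per
#' taxon with whitespace-separated names of any length.
#'
#' @param aln a \code{phyDat}.
#' @param file output path.
#' @export
writePhylip <- function(aln, file) {
  m <- toupper(as.character(aln))
  seqs <- apply(m, 1L, paste, collapse = "")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  writeLines(sprintf("%s  %s", rownames(m), seqs), con)
  invisible(file)
}

#' Read a relaxed PHYLIP alignment
#' @param file input path.
#' @return a \code{phyDat}.
#' @export
readPhylip <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  if (length(hdr) != 2L || anyNA(hdr)) stop("malformed PHYLIP header")
  body <- lines[-1L]
  if (length(body) != hdr[1L]) stop("expected ", hdr[1L], " sequence lines")
  parts <- strsplit(trimws(body), "\\s+")
  nm <- vapply(parts, `[`, character(1L), 1L)
  sq <- vapply(parts, function(p) paste(p[-1L], collapse = ""), character(1L))
  if (any(nchar(sq) != hdr[2L])) stop("sequence length mismatch with header")
  m <- do.call(rbind, strsplit(tolower(sq), ""))
  rownames(m) <- nm
  phangorn::phyDat(m, type = "DNA")
}

#' Write a calibration set as a YAML config
#'
#' One document with a \code{calibrations} list; each entry has
#' \code{name}, \code{taxa}, and whichever of \code{min_age},
#' \code{max_age}, \code{fixed_age} are set (MYA).
#'
#' @param calset a \linkS4class{CalibrationSet}.
#' @param file output path.
#' @export
writeCalibrations <- function(calset, file) {
  entries <- lapply(seq_along(calset@clades), function(i) {
    e <- list(name = calset@clades[[i]]@name,
              taxa = as.list(calset@clades[[i]]@taxa))
    if (!is.na(calset@minAge[i])) e$min_age <- calset@minAge[i]
    if (!is.na(calset@maxAge[i])) e$max_age <- calset@maxAge[i]
    if (!is.na(calset@fixedAge[i])) e$fixed_age <- calset@fixedAge[i]
    if (isTRUE(calset@stem[i])) e$stem <- TRUE
    e
  })
  yaml::write_yaml(list(calibrations = entries), file)
  invisible(file)
}

#' Read a calibration set from a YAML config
#' @param file input path.
#' @return a \linkS4class{CalibrationSet}.
#' @export
readCalibrations <- function(file) {
  doc <- yaml::read_yaml(file)
  entries <- doc$calibrations
  if (is.null(entries)) stop("no 'calibrations' entry in ", file)
  getage <- function(e, f) if (is.null(e[[f]])) NA_real_ else as.numeric(e[[f]])
  calibrationSet(
    clades = lapply(entries, function(e)
      cladeSpec(e$name, unlist(e$taxa))),
    minAge = vapply(entries, getage, numeric(1L), "min_age"),
    maxAge = vapply(entries, getage, numeric(1L), "max_age"),
    fixedAge = vapply(entries, getage, numeric(1L), "fixed_age"),
    stem = vapply(entries, function(e) isTRUE(e$stem), logical(1L)))
}
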