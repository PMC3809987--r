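## GTR+Gamma+I likelihood machinery on a fixed topology: transition
## matrices by symmetric eigendecomposition, Felsenstein pruning over site
## patterns and rate classes, maximum-likelihood branch-length estimation
## (delegated to phangorn's optimizer behind this module's interface), and
## the alignment-column bootstrap.

## eigendecomposition of the GTR rate matrix, scaled to mean rate 1.
## Returns V, Vi, values with P(t) = V diag(exp(values t)) Vi.
.gtrEigen <- function(model) {
  pi <- model@baseFreqs
  s <- model@rates
  S <- matrix(0, 4, 4)
  S[lower.tri(S)] <- s[c(1, 2, 3, 4, 5, 6)]  # (CA,GA,TA,GC,TC,TG) columnwise
  S <- S + t(S)
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  rt <- sqrt(pi)
  A <- diag(rt) %*% Q %*% diag(1 / rt)
  eig <- eigen((A + t(A)) / 2, symmetric = TRUE)
  list(values = eig$values,
       V = diag(1 / rt) %*% eig$vectors,
       Vi = t(eig$vectors) %*% diag(rt))
}

## P(t) from a cached eigendecomposition, cleaned of tiny negatives
.gtrProb <- function(eig, t) {
  P <- eig$V %*% (exp(eig$values * t) * eig$Vi)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' GTR transition probability matrix
#'
#' \eqn{P(t) = \exp(Qt)} for the model's rate matrix (scaled to mean rate 1
#' at stationarity), computed by symmetric eigendecomposition.  \code{t} is
#' an evolutionary distance in expected substitutions per site; among-site
#' rate multipliers are applied by the caller.
#'
#' @param model a \linkS4class{SubstitutionModel}.
#' @param t distance (>= 0).
#' @return 4x4 row-stochastic matrix over A, C, G, T.
#' @export
transitionMatrix <- function(model, t) {
  if (t < 0) stop("t must be >= 0")
  P <- .gtrProb(.gtrEigen(model), t)
  dimnames(P) <- list(c("a", "c", "g", "t"), c("a", "c", "g", "t"))
  P
}

## coerce an alignment to phyDat and order its taxa to the tree's leaves
.alnForTree <- function(aln, tree) {
  if (!inherits(aln, "phyDat")) aln <- phangorn::phyDat(aln, type = "DNA")
  missing <- setdiff(tree$tip.label, names(aln))
  if (length(missing))
    stop("alignment lacks taxa: ", paste(missing, collapse = ", "))
  aln
}

#' Log-likelihood of an alignment on a fixed tree
#'
#' Felsenstein pruning over compressed site patterns and the
#' invariant + discrete-gamma rate classes.  Gaps, N and ambiguity codes
#' contribute a partial likelihood of 1 for every compatible state
#' (missing data).  Site-pattern compression does not change the result.
#'
#' @param aln alignment (\code{phyDat} or character matrix); must contain
#'   every tree leaf.
#' @param tree a \code{phylo} with branch lengths in substitutions/site.
#' @param model a \linkS4class{SubstitutionModel}.
#' @return total log-likelihood.
#' @export
logLikelihood <- function(aln, tree, model) {
  aln <- .alnForTree(aln, tree)
  contrast <- attr(aln, "contrast")[, 1:4, drop = FALSE]
  w <- attr(aln, "weight")
  np <- length(w)
  n <- length(tree$tip.label)
  nn <- max(tree$edge)
  cls <- .siteRateClasses(model)
  eig <- .gtrEigen(model)
  ord <- reorder(tree, "postorder")
  pi <- model@baseFreqs

  siteLik <- numeric(np)
  for (ci in seq_along(cls$rates)) {
    partial <- vector("list", nn)
    for (tip in seq_len(n)) {
      codes <- aln[[tree$tip.label[tip]]]
      partial[[tip]] <- t(contrast[codes, , drop = FALSE])   # 4 x np
    }
    for (e in seq_len(nrow(ord$edge))) {
      p <- ord$edge[e, 1L]
      ch <- ord$edge[e, 2L]
      d <- ord$edge.length[e] * cls$rates[ci]
      P <- if (d == 0) diag(4) else .gtrProb(eig, d)
      contrib <- P %*% partial[[ch]]
      partial[[p]] <- if (is.null(partial[[p]])) contrib
                      else partial[[p]] * contrib
    }
    root <- n + 1L
    siteLik <- siteLik + cls$weights[ci] * colSums(pi * partial[[root]])
  }
  sum(w * log(siteLik))
}

#' Empirical base frequencies of an alignment
#' @param aln a \code{phyDat}.
#' @return frequencies of A, C, G, T.
#' @export
empiricalBaseFreqs <- function(aln) {
  bf <- phangorn::baseFreq(aln)
  as.numeric(bf / sum(bf))
}

## transfer branch lengths fitted on the unrooted version of `rooted` back
## onto the rooted topology.  The unrooted tree merges the two root-child
## edges into one; that length is split between them in proportion to the
## rooted tree's own root-child lengths (50/50 when absent or zero).
.transferUnrootedLengths <- function(rooted, fitted) {
  n <- length(rooted$tip.label)
  root <- n + 1L
  anchor <- rooted$tip.label[1L]
  key <- function(phy, node) {
    labs <- phy$tip.label[.tipsBelow(phy, node)]
    if (anchor %in% labs) labs <- setdiff(phy$tip.label, labs)
    paste(sort(labs), collapse = "\r")
  }
  fitKey <- vapply(fitted$edge[, 2L], function(nd) key(fitted, nd),
                   character(1L))
  out <- rooted
  rootKids <- which(rooted$edge[, 1L] == root)
  for (e in seq_len(nrow(rooted$edge))) {
    if (e %in% rootKids) next
    k <- key(rooted, rooted$edge[e, 2L])
    hit <- which(fitKey == k)
    if (length(hit) != 1L)
      stop("could not match edge splits between rooted and fitted trees")
    out$edge.length[e] <- fitted$edge.length[hit]
  }
  ## merged edge: the split of either root child
  k <- key(rooted, rooted$edge[rootKids[1L], 2L])
  hit <- which(fitKey == k)
  if (length(hit) != 1L) stop("could not match the root split")
  total <- fitted$edge.length[hit]
  b <- rooted$edge.length[rootKids]
  frac <- if (!is.null(b) && all(is.finite(b)) && sum(b) > 0) {
    b[1L] / sum(b)
  } else 0.5
  out$edge.length[rootKids[1L]] <- total * frac
  out$edge.length[rootKids[2L]] <- total * (1 - frac)
  out
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Optimizes branch lengths (and, unless \code{fixModelParams}, the gamma
#' shape, invariant proportion and GTR exchangeabilities) of a GTR+Gamma+I
#' model on a fixed binary topology.  Base frequencies default to empirical
#' counts.  Optimization is performed on the unrooted tree (the model is
#' reversible); fitted lengths are transferred back to the rooted input
#' topology, dividing the merged root edge between the two root-child
#' branches in proportion to the input lengths.
#'
#' @param aln alignment covering all leaves.
#' @param topology rooted binary \code{phylo}; existing positive branch
#'   lengths seed the optimizer.
#' @param model a \linkS4class{SubstitutionModel}.
#' @param fixModelParams keep shape, pInv and exchangeabilities at the
#'   values in \code{model} (default FALSE: re-optimize them).
#' @param optFrequencies also optimize base frequencies by ML instead of
#'   using empirical counts (default FALSE).
#' @param useEmpiricalFreqs start from empirical base-frequency counts
#'   (default TRUE, PAUP*-style); FALSE keeps the model's frequencies.
#' @param control list; \code{epsilon} (log-likelihood convergence
#'   tolerance, default 1e-8) and \code{maxit} (default 20 outer cycles).
#' @return a \linkS4class{BranchLengthFit}.  Non-convergence yields a
#'   flagged fit, not an error.
#' @export
estimateBranchLengths <- function(aln, topology, model = substitutionModel(),
                                  fixModelParams = FALSE,
                                  optFrequencies = FALSE,
                                  useEmpiricalFreqs = TRUE,
                                  control = list()) {
  if (!ape::is.binary(topology)) stop("topology must be binary")
  aln <- .alnForTree(aln, topology)
  eps <- if (is.null(control$epsilon)) 1e-8 else control$epsilon
  maxit <- if (is.null(control$maxit)) 20L else control$maxit
  if (length(topology$tip.label) == 2L) {
    ## a pair only identifies the total distance: 1-D ML
    if (!fixModelParams || optFrequencies)
      warning("2-taxon fit: model parameters kept fixed")
    mod2 <- model
    if (useEmpiricalFreqs) mod2@baseFreqs <- empiricalBaseFreqs(aln)
    o <- stats::optimize(function(d) {
      tr <- topology
      tr$edge.length <- c(d / 2, d / 2)
      logLikelihood(aln, tr, mod2)
    }, c(1e-9, 20), maximum = TRUE, tol = 1e-10)
    tree <- topology
    tree$edge.length <- rep(o$maximum / 2, 2L)
    return(new("BranchLengthFit", tree = tree, logLik = o$objective,
               iterations = NA_integer_, converged = TRUE, model = mod2))
  }
  start <- topology
  if (is.null(start$edge.length) || any(!is.finite(start$edge.length)) ||
      any(start$edge.length <= 0))
    start$edge.length <- rep(0.1, nrow(start$edge))
  bf <- if (optFrequencies || !useEmpiricalFreqs) model@baseFreqs
        else empiricalBaseFreqs(aln)
  fit0 <- phangorn::pml(start, aln, bf = bf, Q = model@rates,
                        k = model@nCat, shape = model@shape,
                        inv = model@pInv, model = "GTR")
  converged <- TRUE
  fit <- tryCatch(
    suppressWarnings(phangorn::optim.pml(
      fit0, optEdge = TRUE,
      optQ = !fixModelParams,
      optGamma = !fixModelParams && model@nCat > 1L,
      optInv = !fixModelParams && model@pInv > 0,
      optBf = optFrequencies,
      control = phangorn::pml.control(trace = 0, epsilon = eps,
                                      maxit = maxit))),
    error = function(e) {
      warning("branch-length optimization failed: ", conditionMessage(e))
      converged <<- FALSE
      fit0
    })
  tree <- .transferUnrootedLengths(topology, fit$tree)
  Q <- as.numeric(fit$Q)
  outModel <- substitutionModel(rates = Q / Q[6L],
                                baseFreqs = as.numeric(fit$bf),
                                shape = fit$shape, nCat = model@nCat,
                                pInv = fit$inv,
                                gammaMedian = model@gammaMedian)
  new("BranchLengthFit", tree = tree, logLik = as.numeric(fit$logLik),
      iterations = NA_integer_, converged = converged, model = outModel)
}

#' Bootstrap alignment columns
#'
#' Resamples site columns with replacement to the original alignment
#' length.  Deterministic per seed; every resampled column is a column of
#' the input.
#'
#' @param aln a \code{phyDat}.
#' @param seed integer seed.
#' @return a \code{phyDat} of the same length.
#' @export
bootstrapAlignment <- function(aln, seed) {
  idx <- attr(aln, "index")
  if (is.null(idx)) idx <- rep(seq_along(attr(aln, "weight")),
                               attr(aln, "weight"))
  if (length(idx) < 1L) stop("alignment has no sites")
  set.seed(as.integer(seed))
  draw <- sample(idx, length(idx), replace = TRUE)
  out <- aln
  attr(out, "weight") <- tabulate(draw, nbins = length(attr(aln, "weight")))
  attr(out, "index") <- draw
  out
}
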