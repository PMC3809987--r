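## Penalized-likelihood divergence dating.  The objective is the Poisson
## branch-substitution log-likelihood minus lambda times a roughness
## penalty on rate changes between adjacent branches:
##
##   sum_k [ x_k log(r_k t_k) - r_k t_k ]  -  lambda * Phi(r)
##
## with x_k the expected substitution count of branch k (branch length times
## site count), t_k its duration from the node ages, and Phi either the
## logarithmic penalty (squared differences of log rates between each branch
## and its parent branch, plus the variance of log rates among the root's
## child branches) or its additive analogue on raw rates.  Maximization is
## by block coordinate ascent: an L-BFGS-B step in log rates alternating
## with an adaptive-barrier quasi-Newton step in node ages under the
## ordering and calibration constraints, repeated from several seeded
## starting points.

#' Build a penalized-likelihood dating problem
#'
#' Converts a phylogram's branch lengths to expected substitution counts
#' (\code{x = length * nSites}; zero lengths floored at 1e-9
#' substitutions/site), resolves each calibration to a node, and verifies
#' feasibility: within every entry min <= max, and along every root-to-leaf
#' path the effective minimum (propagated up from descendants) must not
#' exceed the effective maximum (propagated down from ancestors).
#'
#' @param phylogram rooted binary \code{phylo}, lengths in
#'   substitutions/site.
#' @param calibrations a \linkS4class{CalibrationSet}; every entry must
#'   retain at least two taxa in the tree.
#' @param config a \linkS4class{PLConfig}.
#' @return a \linkS4class{PLProblem}.
#' @export
plProblem <- function(phylogram, calibrations, config) {
  if (!ape::is.rooted(phylogram)) stop("phylogram must be rooted")
  if (!ape::is.binary(phylogram)) stop("phylogram must be binary")
  if (is.null(phylogram$edge.length)) stop("phylogram has no branch lengths")
  b <- pmax(phylogram$edge.length, 1e-9)
  x <- b * config@nSites
  if (config@roundCounts) x <- round(x)
  pr <- new("PLProblem", phy = phylogram, x = x,
            calibrations = calibrations, config = config)
  .plPrep(pr)   # errors on unknown taxa / infeasible calibrations
  pr
}

## node a calibration entry attaches to: the MRCA of the clade members
## present (crown, needs >= 2) or its parent (stem, valid from 1 member).
## NA when the entry cannot be placed.
.resolveCalNode <- function(phy, taxa, stem) {
  present <- intersect(taxa, phy$tip.label)
  root <- length(phy$tip.label) + 1L
  if (stem) {
    if (length(present) < 1L) return(NA_integer_)
    nd <- if (length(present) == 1L) match(present, phy$tip.label)
          else ape::getMRCA(phy, present)
    if (nd == root) return(NA_integer_)
    phy$edge[phy$edge[, 2L] == nd, 1L]
  } else {
    if (length(present) < 2L) return(NA_integer_)
    ape::getMRCA(phy, present)
  }
}

## resolve calibrations to nodes and propagate age bounds.
## Returns node bookkeeping reused across the optimizer.
.plPrep <- function(problem) {
  phy <- problem@phy
  cal <- problem@calibrations
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  root <- n + 1L
  ep <- phy$edge[, 1L]
  ec <- phy$edge[, 2L]

  nodeMin <- rep(0, nn)
  nodeMax <- rep(Inf, nn)
  calNode <- integer(length(cal@clades))
  for (i in seq_along(cal@clades)) {
    nd <- .resolveCalNode(phy, cal@clades[[i]]@taxa, cal@stem[i])
    if (is.na(nd))
      stop("calibration '", cal@clades[[i]]@name,
           "' cannot be placed in the tree (too few surviving taxa, ",
           "or a stem entry whose members' MRCA is the root)")
    calNode[i] <- nd
    lo <- cal@minAge[i]
    hi <- cal@maxAge[i]
    if (!is.na(cal@fixedAge[i])) lo <- hi <- cal@fixedAge[i]
    if (!is.na(lo)) nodeMin[nd] <- max(nodeMin[nd], lo)
    if (!is.na(hi)) nodeMax[nd] <- min(nodeMax[nd], hi)
  }

  ord <- reorder(phy, "postorder")
  lo <- nodeMin
  for (e in seq_len(nrow(ord$edge)))   # children before parents
    lo[ord$edge[e, 1L]] <- max(lo[ord$edge[e, 1L]], lo[ord$edge[e, 2L]])
  hi <- nodeMax
  for (e in rev(seq_len(nrow(ord$edge))))  # parents before children
    hi[ord$edge[e, 2L]] <- min(hi[ord$edge[e, 2L]], hi[ord$edge[e, 1L]])
  bad <- which(lo > hi + 1e-9)
  if (length(bad))
    stop("infeasible calibrations: effective minimum exceeds effective ",
         "maximum at node(s) ", paste(bad, collapse = ", "))

  ## parent edge of each edge (NA for root children), root-child edges
  edgeOfChild <- integer(nn)
  edgeOfChild[ec] <- seq_along(ec)
  parentEdge <- ifelse(ep == root, NA_integer_, edgeOfChild[ep])
  kidsOf <- vector("list", nn)
  for (e in seq_along(ep)) kidsOf[[ep[e]]] <- c(kidsOf[[ep[e]]], ec[e])
  ## internal nodes ordered children-before-parents
  nodesPostorder <- rev(unique(rev(ord$edge[, 1L])))
  list(n = n, nn = nn, root = root, ep = ep, ec = ec,
       internal = seq.int(root, nn), lo = lo, hi = hi,
       calNode = calNode, parentEdge = parentEdge,
       rootEdges = which(ep == root), edgeOfChild = edgeOfChild,
       kidsOf = kidsOf, nodesPostorder = nodesPostorder,
       postorder = ord)
}

#' Rate-roughness penalty
#'
#' Logarithmic kind: the sum over all branches that have a parent branch of
#' the squared difference of log rates, plus the sample variance of log
#' rates among the root's child branches.  Additive kind: the same on raw
#' rates.  Zero when all rates are equal.
#'
#' @param rates positive branch rates in edge order.
#' @param tree the rooted \code{phylo} the rates live on.
#' @param kind \code{"log"} or \code{"additive"}.
#' @return the penalty value.
#' @export
ratePenalty <- function(rates, tree, kind = c("log", "additive")) {
  kind <- match.arg(kind)
  if (any(rates <= 0)) stop("rates must be positive")
  root <- length(tree$tip.label) + 1L
  ep <- tree$edge[, 1L]
  ec <- tree$edge[, 2L]
  edgeOfChild <- integer(max(tree$edge))
  edgeOfChild[ec] <- seq_along(ec)
  pe <- ifelse(ep == root, NA_integer_, edgeOfChild[ep])
  v <- if (kind == "log") log(rates) else rates
  has <- !is.na(pe)
  sum((v[has] - v[pe[has]])^2) +
    (if (sum(ep == root) > 1L) var(v[ep == root]) else 0)
}

## penalty and its gradient with respect to v (= log rates or rates),
## given the parent-edge index and the root-edge set
.penaltyGrad <- function(v, parentEdge, rootEdges) {
  has <- which(!is.na(parentEdge))
  pe <- parentEdge[has]
  d <- v[has] - v[pe]
  g <- numeric(length(v))
  g[has] <- 2 * d                          # child edges are unique
  dec <- rowsum(2 * d, pe)                 # parent edges repeat
  idx <- as.integer(rownames(dec))
  g[idx] <- g[idx] - dec[, 1L]
  val <- sum(d^2)
  k <- length(rootEdges)
  if (k > 1L) {
    m <- mean(v[rootEdges])
    val <- val + sum((v[rootEdges] - m)^2) / (k - 1)
    g[rootEdges] <- g[rootEdges] + 2 * (v[rootEdges] - m) / (k - 1)
  }
  list(value = val, grad = g)
}

#' Penalized-likelihood objective
#'
#' Evaluates the PL objective for a given age and rate assignment.
#' Branches with \eqn{x_k = 0} contribute \eqn{-r_k t_k} (the convention
#' \eqn{0 \log 0 = 0}).
#'
#' @param problem a \linkS4class{PLProblem}.
#' @param ages numeric vector of node ages (tips first, \code{phylo}
#'   numbering); every parent must be strictly older than its children.
#' @param rates positive branch rates in edge order.
#' @return the objective value.
#' @export
plObjective <- function(problem, ages, rates) {
  phy <- problem@phy
  t <- ages[phy$edge[, 1L]] - ages[phy$edge[, 2L]]
  if (any(t <= 0)) stop("invalid age vector: non-positive branch duration")
  if (any(rates <= 0)) stop("rates must be positive")
  x <- problem@x
  mu <- rates * t * problem@config@nSites   # expected counts
  lik <- sum(ifelse(x > 0, x * log(mu), 0) - mu)
  ## the additive penalty is applied on the count-scale rates (x/t units),
  ## matching the internal optimizer; the log penalty is scale-invariant
  prates <- if (problem@config@penalty == "additive")
    rates * problem@config@nSites else rates
  lik - problem@config@lambda *
    ratePenalty(prates, phy, problem@config@penalty)
}

## ---------------------------------------------------------------------------
## optimizer internals
## ---------------------------------------------------------------------------

## maximize over log rates, ages fixed (L-BFGS-B with analytic gradient)
.rateStep <- function(u, t, x, lambda, kind, parentEdge, rootEdges, bounds) {
  fn <- function(u) {
    r <- exp(u)
    v <- if (kind == "log") u else r
    pen <- .penaltyGrad(v, parentEdge, rootEdges)
    -(sum(ifelse(x > 0, x * (u + log(t)), 0) - r * t) - lambda * pen$value)
  }
  gr <- function(u) {
    r <- exp(u)
    v <- if (kind == "log") u else r
    pen <- .penaltyGrad(v, parentEdge, rootEdges)
    pgrad <- if (kind == "log") pen$grad else pen$grad * r
    -(x - r * t - lambda * pgrad)
  }
  o <- optim(u, fn, gr, method = "L-BFGS-B",
             lower = log(bounds[1L]), upper = log(bounds[2L]),
             control = list(maxit = 200L))
  o$par
}

## maximize over node ages, rates fixed, by coordinate ascent: each
## internal age solves a 1-D concave problem exactly (Brent plus explicit
## endpoint checks, so active calibration bounds are hit exactly) within
## the corridor [max child age, parent age] intersected with its
## calibration bounds.  Sweeps repeat until ages stabilize.
.ageStep <- function(ages, rates, prep, x, minDur,
                     sweeps = 5L, tol = 1e-10) {
  A <- ages
  md <- minDur * 0.5
  kidsOf <- prep$kidsOf
  edgeUp <- prep$edgeOfChild          # edge above each node (0 for root)
  nodesUp <- prep$nodesPostorder      # internal nodes, children first
  nodes2 <- c(nodesUp, rev(nodesUp))  # both directions per sweep

  for (s in seq_len(sweeps)) {
    shift <- 0
    for (nd in nodes2) {
      kids <- kidsOf[[nd]]
      eKids <- edgeUp[kids]
      eUp <- edgeUp[nd]
      xk <- x[eKids]; rk <- rates[eKids]; ak <- A[kids]
      hasUp <- eUp > 0L
      if (hasUp) {
        aP <- A[prep$ep[eUp]]; xu <- x[eUp]; ru <- rates[eUp]
      }
      ## derivative of the local objective in the node's age
      dg <- function(a) {
        v <- sum(xk / (a - ak)) - sum(rk)
        if (hasUp) v <- v - xu / (aP - a) + ru
        v
      }
      d2g <- function(a) {
        v <- -sum(xk / (a - ak)^2)
        if (hasUp) v <- v - xu / (aP - a)^2
        v
      }
      L <- max(max(ak) + md, prep$lo[nd])
      U <- min(prep$hi[nd], if (hasUp) aP - md else Inf)
      if (!is.finite(U)) {          # root without a maximum: bracket
        U <- max(2 * A[nd], L + 1)
        while (dg(U) > 0 && U < 1e12) U <- U * 2
      }
      if (U <= L) { A[nd] <- max(L, U); next }
      aNew <- if (dg(L + 1e-12 * (U - L)) <= 0) L
      else if (dg(U - 1e-12 * (U - L)) >= 0) U
      else {
        ## safeguarded Newton on the concave derivative
        lo <- L; hi <- U
        a <- min(max(A[nd], lo + 1e-9 * (U - L)), hi - 1e-9 * (U - L))
        for (it in 1:50) {
          d <- dg(a)
          if (d > 0) lo <- a else hi <- a
          step <- d / d2g(a)
          aNxt <- a - step
          if (!is.finite(aNxt) || aNxt <= lo || aNxt >= hi)
            aNxt <- (lo + hi) / 2
          if (abs(aNxt - a) < tol * max(1, a)) { a <- aNxt; break }
          a <- aNxt
        }
        a
      }
      shift <- max(shift, abs(aNew - A[nd]))
      A[nd] <- aNew
    }
    if (shift < tol * 100) break
  }
  A
}

## joint refinement: L-BFGS-B over (node-height transform of ages, log
## rates) with an analytic reverse-mode gradient.  Ages are parameterized
## top-down as a_i = lo_i + sigmoid(theta_i) * (min(a_parent, hi_i) - lo_i)
## (root: sigmoid within its window, or lo + exp(theta) when unbounded
## above), which enforces the ordering and calibration corridor
## structurally.  This removes the slow zigzag of pure block alternation.
.jointRefine <- function(ages, u, prep, x, lambda, kind, bounds,
                         control = list(maxit = 1000L, factr = 1e5)) {
  preN <- rev(prep$nodesPostorder)          # parents before children
  edgeUp <- prep$edgeOfChild
  lo <- prep$lo; hi <- prep$hi
  root <- prep$root
  fixedNode <- (hi - lo) < 1e-9
  freeN <- preN[!fixedNode[preN]]
  if (length(freeN) == 0L) return(list(ages = ages, u = u, convergence = 0L))
  rootFree <- !fixedNode[root]
  rootUnbounded <- !is.finite(hi[root])

  decode <- function(theta) {
    A <- ages
    A[seq_len(prep$n)] <- 0
    A[preN[fixedNode[preN]]] <- lo[preN[fixedNode[preN]]]
    ti <- 0L
    for (nd in preN) {
      if (fixedNode[nd]) next
      ti <- ti + 1L
      if (nd == root) {
        A[nd] <- if (rootUnbounded) lo[nd] + exp(theta[ti])
        else lo[nd] + stats::plogis(theta[ti]) * (hi[nd] - lo[nd])
      } else {
        up <- min(A[prep$ep[edgeUp[nd]]], hi[nd])
        A[nd] <- lo[nd] + stats::plogis(theta[ti]) * (up - lo[nd])
      }
    }
    A
  }

  nT <- length(freeN)
  posFree <- integer(prep$nn)
  posFree[freeN] <- seq_len(nT)
  fn <- function(par) {
    A <- decode(par[seq_len(nT)])
    r <- exp(par[-seq_len(nT)])
    t <- A[prep$ep] - A[prep$ec]
    if (any(t <= 0)) return(1e300)
    v <- if (kind == "log") log(r) else r
    pen <- .penaltyGrad(v, prep$parentEdge, prep$rootEdges)
    -(sum(ifelse(x > 0, x * log(r * t), 0) - r * t) - lambda * pen$value)
  }
  gr <- function(par) {
    theta <- par[seq_len(nT)]
    uu <- par[-seq_len(nT)]
    r <- exp(uu)
    A <- decode(theta)
    t <- A[prep$ep] - A[prep$ec]
    v <- if (kind == "log") uu else r
    pen <- .penaltyGrad(v, prep$parentEdge, prep$rootEdges)
    pgrad <- if (kind == "log") pen$grad else pen$grad * r
    gU <- -(x - r * t - lambda * pgrad)
    ## dObj/dA per node from the edge terms
    gEdge <- ifelse(x > 0, x / t, 0) - r
    dA <- numeric(prep$nn)
    inc <- rowsum(gEdge, prep$ep)
    idx <- as.integer(rownames(inc))
    dA[idx] <- inc[, 1L]
    dA[prep$ec] <- dA[prep$ec] - gEdge    # each node has one parent edge
    ## reverse accumulation: children's ages depend on the parent age
    ## through the (possibly clipped) upper end of their interval
    adj <- dA
    sig <- stats::plogis
    for (nd in prep$nodesPostorder) {       # children before parents
      if (nd == root || fixedNode[nd]) next
      par_ <- prep$ep[edgeUp[nd]]
      p <- sig(theta[posFree[nd]])
      if (A[par_] < hi[nd]) adj[par_] <- adj[par_] + adj[nd] * p
    }
    gT <- numeric(nT)
    for (ti in seq_len(nT)) {
      nd <- freeN[ti]
      if (nd == root && rootUnbounded) {
        gT[ti] <- -adj[nd] * exp(theta[ti])
      } else {
        p <- sig(theta[ti])
        width <- if (nd == root) hi[nd] - lo[nd]
        else min(A[prep$ep[edgeUp[nd]]], hi[nd]) - lo[nd]
        gT[ti] <- -adj[nd] * width * p * (1 - p)
      }
    }
    c(gT, gU)
  }

  ## encode current ages
  theta0 <- numeric(nT)
  A <- ages
  for (ti in seq_len(nT)) {
    nd <- freeN[ti]
    if (nd == root) {
      theta0[ti] <- if (rootUnbounded) log(max(A[nd] - lo[nd], 1e-8))
      else stats::qlogis(min(max((A[nd] - lo[nd]) /
                                   max(hi[nd] - lo[nd], 1e-12),
                                 1e-7), 1 - 1e-7))
    } else {
      up <- min(A[prep$ep[edgeUp[nd]]], hi[nd])
      theta0[ti] <- stats::qlogis(min(max((A[nd] - lo[nd]) /
                                            max(up - lo[nd], 1e-12),
                                          1e-7), 1 - 1e-7))
    }
  }
  par0 <- c(theta0, u)
  lower <- c(rep(-35, nT), rep(log(bounds[1L]), length(u)))
  upper <- c(rep(35, nT), rep(log(bounds[2L]), length(u)))
  if (rootFree && rootUnbounded) {
    ri <- match(root, freeN)
    lower[ri] <- -30
    upper[ri] <- 30
  }
  o <- tryCatch(
    optim(par0, fn, gr, method = "L-BFGS-B", lower = lower, upper = upper,
          control = control),
    error = function(e) NULL)
  if (is.null(o) || !is.finite(o$value))
    return(list(ages = ages, u = u, convergence = 1L))
  list(ages = decode(o$par[seq_len(nT)]), u = o$par[-seq_len(nT)],
       convergence = o$convergence)
}

## initial ages: depth-proportional clock solution inside the calibration
## corridor, then repaired to strict feasibility
.initAges <- function(prep, phy, jitterSd) {
  depth <- ape::node.depth.edgelength(phy)
  n <- prep$n
  ## mean root-to-tip depth below each node minus own depth
  sumTip <- numeric(prep$nn)
  cnt <- integer(prep$nn)
  sumTip[seq_len(n)] <- depth[seq_len(n)]
  cnt[seq_len(n)] <- 1L
  for (e in seq_len(nrow(prep$postorder$edge))) {
    p <- prep$postorder$edge[e, 1L]
    ch <- prep$postorder$edge[e, 2L]
    sumTip[p] <- sumTip[p] + sumTip[ch]
    cnt[p] <- cnt[p] + cnt[ch]
  }
  height <- sumTip / pmax(cnt, 1L) - depth   # mean subs from node to tips
  root <- prep$root
  loR <- prep$lo[root]
  hiR <- if (is.finite(prep$hi[root])) prep$hi[root] else max(2 * loR, 1)
  u <- if (jitterSd > 0) runif(1L, 0.25, 0.75) else 0.5
  a0 <- loR + u * (hiR - loR)
  if (a0 <= 0) a0 <- hiR
  ages <- numeric(prep$nn)
  ages[prep$internal] <- a0 * height[prep$internal] / max(height[root], 1e-12)
  if (jitterSd > 0) {
    jig <- exp(rnorm(length(prep$internal), 0, jitterSd))
    ages[prep$internal] <- ages[prep$internal] * jig
    ages[root] <- a0
  }
  ages
}

## push ages into the feasible corridor with strict margins
.repairAges <- function(ages, prep, minDur) {
  A <- ages
  A[seq_len(prep$n)] <- 0
  for (nd in prep$nodesPostorder) {
    kids <- prep$kidsOf[[nd]]
    floorAge <- max(A[kids]) + minDur
    lo <- max(prep$lo[nd], floorAge)
    hi <- prep$hi[nd]
    delta <- if (is.finite(hi)) min(1e-7 * (1 + hi), (hi - lo) / 4)
             else 1e-7 * (1 + lo)
    if (delta < 0) delta <- 0
    A[nd] <- min(max(A[nd], lo + delta), if (is.finite(hi)) hi - delta else Inf)
    if (A[nd] < floorAge) A[nd] <- floorAge
  }
  A
}

#' Fit a penalized-likelihood chronogram
#'
#' Maximizes the PL objective jointly over node ages and branch rates
#' subject to parent-older-than-child ordering and all calibration bounds,
#' taking the best of \code{restarts} seeded initializations (each a
#' depth-proportional clock solution with jittered ages and rates).  Ties
#' between restarts are broken by the lower penalty.  Near-active
#' calibration bounds are snapped onto the bound when doing so does not
#' lower the objective.
#'
#' @param problem a \linkS4class{PLProblem}.
#' @return a \linkS4class{PLSolution}.  Non-convergence within
#'   \code{maxIter} sweeps is flagged, not an error.
#' @export
fitPL <- function(problem) {
  prep <- .plPrep(problem)
  cfg <- problem@config
  phy <- problem@phy
  x <- problem@x
  L <- cfg@nSites
  minDur <- cfg@minDuration
  bounds <- cfg@rateBounds * L     # internal rates are count-scale

  ## internal objective on count-scale rates r (counts/MY)
  obj <- function(A, r) {
    t <- A[prep$ep] - A[prep$ec]
    v <- if (cfg@penalty == "log") log(r) else r
    pen <- .penaltyGrad(v, prep$parentEdge, prep$rootEdges)
    sum(ifelse(x > 0, x * log(r * t), 0) - r * t) - cfg@lambda * pen$value
  }

  best <- NULL
  restartObj <- numeric(cfg@restarts)
  for (s in seq_len(cfg@restarts)) {
    set.seed(cfg@seed + 9973L * s)
    ages <- .initAges(prep, phy, jitterSd = if (s == 1L) 0 else 0.08)
    ages <- .repairAges(ages, prep, minDur)
    t <- ages[prep$ep] - ages[prep$ec]
    r0 <- sum(x) / sum(t)          # count-scale rate (counts/MY)
    r0 <- min(max(r0, bounds[1L] * 10), bounds[2L] / 10)
    u <- rep(log(r0), length(x))
    if (s > 1L) u <- u + rnorm(length(u), 0, 0.1)

    ## stage 1: block alternation to get into the right basin
    cur <- -Inf
    converged <- FALSE
    for (it in seq_len(min(cfg@maxIter, 25L))) {
      t <- ages[prep$ep] - ages[prep$ec]
      u <- .rateStep(u, t, x, cfg@lambda, cfg@penalty,
                     prep$parentEdge, prep$rootEdges, bounds)
      ages <- .ageStep(ages, exp(u), prep, x, minDur)
      val <- obj(ages, exp(u))
      if (is.finite(val) && is.finite(cur) &&
          (val - cur) < cfg@tolObjective) break
      cur <- val
    }
    ## stage 2: joint quasi-Newton over (age transform, log rates)
    jr <- .jointRefine(ages, u, prep, x, cfg@lambda, cfg@penalty, bounds)
    if (obj(jr$ages, exp(jr$u)) >= obj(ages, exp(u))) {
      ages <- jr$ages
      u <- jr$u
      converged <- jr$convergence == 0L
    }
    ## stage 3: exact coordinate polish (lands active bounds exactly)
    for (it in 1:3) {
      u <- .rateStep(u, ages[prep$ep] - ages[prep$ec], x, cfg@lambda,
                     cfg@penalty, prep$parentEdge, prep$rootEdges, bounds)
      agesNew <- .ageStep(ages, exp(u), prep, x, minDur)
      shift <- max(abs(agesNew - ages))
      ages <- agesNew
      if (shift < cfg@tolAge) { converged <- TRUE; break }
    }
    val <- obj(ages, exp(u))
    restartObj[s] <- val
    cand <- list(ages = ages, rates = exp(u), objective = val,
                 converged = converged)
    if (is.null(best) || val > best$objective + 1e-9 ||
        (abs(val - best$objective) <= 1e-9 &&
         ratePenalty(cand$rates, phy, cfg@penalty) <
         ratePenalty(best$rates, phy, cfg@penalty))) {
      best <- cand
    }
  }

  ages <- best$ages
  rates <- best$rates / L          # report substitutions/site/MY
  out <- phy
  out$edge.length <- ages[prep$ep] - ages[prep$ec]
  chron <- new("Chronogram", phy = out)

  act <- .activeConstraints(ages, prep, problem@calibrations)
  penVal <- ratePenalty(best$rates, phy, cfg@penalty)
  new("PLSolution", chronogram = chron, rates = rates,
      objective = best$objective, penaltyValue = penVal,
      converged = best$converged, activeConstraints = act,
      restartObjectives = restartObj)
}

.activeConstraints <- function(ages, prep, cal) {
  rows <- list()
  for (i in seq_along(prep$calNode)) {
    nd <- prep$calNode[i]
    lo <- cal@minAge[i]; hi <- cal@maxAge[i]
    if (!is.na(cal@fixedAge[i])) lo <- hi <- cal@fixedAge[i]
    tol <- 1e-4 * (1 + ages[nd])
    if (!is.na(lo) && abs(ages[nd] - lo) < tol)
      rows[[length(rows) + 1L]] <- data.frame(
        calibration = cal@clades[[i]]@name, node = nd, side = "min",
        age = ages[nd], stringsAsFactors = FALSE)
    if (!is.na(hi) && abs(ages[nd] - hi) < tol)
      rows[[length(rows) + 1L]] <- data.frame(
        calibration = cal@clades[[i]]@name, node = nd, side = "max",
        age = ages[nd], stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(calibration = character(), node = integer(),
                  side = character(), age = numeric(),
                  stringsAsFactors = FALSE)
}

#' @rdname profileAges
#' @export
setMethod("profileAges", "list", function(x, clades) {
  if (length(x) < 1L) stop("need at least one tree")
  ages <- vapply(clades, function(cl) {
    vapply(x, function(tr) crownAge(tr, cl), numeric(1L))
  }, numeric(length(x)))
  ages <- matrix(ages, nrow = length(x))
  tab <- data.frame(
    clade = vapply(clades, function(cl) cl@name, character(1L)),
    mean = apply(ages, 2L, function(v) mean(v[!is.na(v)])),
    sd = apply(ages, 2L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) 0 else sd(v)
    }),
    nValid = apply(ages, 2L, function(v) sum(!is.na(v))),
    nTotal = length(x),
    stringsAsFactors = FALSE)
  tab$mean[tab$nValid == 0L] <- NA_real_
  new("ProfileSummary", table = tab)
})

#' Write a per-node age table
#'
#' TSV with node id, age in MYA, and any active calibration constraint.
#'
#' @param solution a \linkS4class{PLSolution}.
#' @param file output path.
#' @export
writeAgeTable <- function(solution, file) {
  phy <- solution@chronogram@phy
  ages <- nodeAges(solution@chronogram)
  n <- length(phy$tip.label)
  idx <- seq.int(n + 1L, n + phy$Nnode)
  act <- solution@activeConstraints
  lab <- vapply(idx, function(nd) {
    hit <- act$node == nd
    if (any(hit)) paste(paste0(act$calibration[hit], ":", act$side[hit]),
                        collapse = ",")
    else ""
  }, character(1L))
  df <- data.frame(node = idx, age = ages[idx], active = lab)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
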