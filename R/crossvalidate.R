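## Smoothing-parameter selection by leave-one-terminal-branch-out
## cross-validation: each terminal branch is pruned in turn, the dating is
## refit without it, and the pruned branch's substitution count is
## predicted from the fitted rate of the branch it was attached to.

#' Cross-validate the smoothing parameter
#'
#' For each value in \code{lambdaGrid} and each terminal branch whose
#' parent is not the root: prune the terminal, refit the chronogram,
#' predict the terminal's expected substitution count as
#' \eqn{\hat r \hat a_P L} (the merged branch's fitted rate times the
#' interpolated age of the attachment point times the site count), and
#' accumulate the chi-squared-style score
#' \eqn{\sum (x_{obs} - \hat x)^2 / \hat x}.  The attachment age is placed
#' on the merged branch in proportion to the two observed branch lengths.
#' Terminals attached directly to the root are skipped (removing them
#' would change the root).
#'
#' @param problem a \linkS4class{PLProblem} with at least 4 leaves.
#' @param lambdaGrid positive smoothing values to score.
#' @return data.frame with columns lambda, score, nTerminals.
#' @export
crossValidate <- function(problem, lambdaGrid) {
  phy <- problem@phy
  n <- length(phy$tip.label)
  if (n < 4L) stop("cross-validation needs at least 4 leaves")
  if (any(lambdaGrid <= 0)) stop("lambda values must be > 0")
  root <- n + 1L
  cfg <- problem@config
  L <- cfg@nSites
  cal <- problem@calibrations

  edgeOfChild <- integer(max(phy$edge))
  edgeOfChild[phy$edge[, 2L]] <- seq_len(nrow(phy$edge))

  terminals <- which(phy$edge[, 2L] <= n & phy$edge[, 1L] != root)
  out <- data.frame(lambda = lambdaGrid, score = NA_real_,
                    nTerminals = length(terminals))
  for (li in seq_along(lambdaGrid)) {
    cfgL <- cfg
    cfgL@lambda <- lambdaGrid[li]
    score <- 0
    for (e in terminals) {
      tip <- phy$edge[e, 2L]
      P <- phy$edge[e, 1L]
      G <- phy$edge[edgeOfChild[P], 1L]
      sib <- setdiff(phy$edge[phy$edge[, 1L] == P, 2L], tip)
      bGP <- phy$edge.length[edgeOfChild[P]]
      bPS <- phy$edge.length[edgeOfChild[sib]]
      xObs <- problem@x[e]

      pruned <- ape::drop.tip(phy, phy$tip.label[tip],
                              collapse.singles = TRUE)
      calP <- .restrictCalibrations(cal, pruned)
      sol <- fitPL(plProblem(pruned, calP, cfgL))
      agesP <- nodeAges(sol@chronogram)
      pphy <- sol@chronogram@phy

      ## the merged branch is the one above the sibling subtree
      sibTips <- phy$tip.label[.tipsBelow(phy, sib)]
      sNode <- if (length(sibTips) == 1L) match(sibTips, pphy$tip.label)
               else ape::getMRCA(pphy, sibTips)
      eM <- which(pphy$edge[, 2L] == sNode)
      gNode <- pphy$edge[eM, 1L]
      aS <- agesP[sNode]
      aG <- agesP[gNode]
      aP <- aS + (aG - aS) * (bPS / max(bGP + bPS, 1e-12))
      xPred <- max(sol@rates[eM] * aP * L, 1e-12)
      score <- score + (xObs - xPred)^2 / xPred
    }
    out$score[li] <- score
  }
  out
}
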