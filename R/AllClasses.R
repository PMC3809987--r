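#' @import methods
#' @importFrom stats optim rnorm runif var sd qgamma pgamma setNames
#' @importFrom utils packageVersion write.table read.delim
NULL

setOldClass("phylo")
setOldClass("phyDat")

## ---------------------------------------------------------------------------
## Trees and clades
## ---------------------------------------------------------------------------

#' Chronogram: an ultrametric, rooted, dated tree
#'
#' Wraps an \code{ape::phylo} object whose edge lengths are durations in
#' millions of years (MY).  Node ages increase toward the root; all extant
#' leaves sit at age 0.  Validity enforces a single root, non-negative
#' durations and ultrametricity.
#'
#' @slot phy a rooted \code{phylo} with edge lengths in MY.
#' @export
setClass("Chronogram", representation(phy = "phylo"))

setValidity("Chronogram", function(object) {
  phy <- object@phy
  if (!inherits(phy, "phylo")) return("slot 'phy' must be a phylo object")
  if (!ape::is.rooted(phy)) return("chronogram must be rooted")
  if (is.null(phy$edge.length)) return("chronogram has no branch durations")
  if (any(phy$edge.length < -1e-9)) return("negative branch duration")
  depth <- ape::node.depth.edgelength(phy)
  n <- length(phy$tip.label)
  span <- max(depth[seq_len(n)]) - min(depth[seq_len(n)])
  tol <- max(max(depth), 1) * 1e-6
  if (span > tol) {
    return(sprintf("not ultrametric: root-to-leaf spread %.3g exceeds %.3g",
                   span, tol))
  }
  TRUE
})

#' Named clade specification
#'
#' A clade is identified by a name and a set of leaf taxa; in any given tree
#' the clade is the most recent common ancestor (MRCA) of the members present.
#' Its crown age is defined only when at least two members survive pruning.
#'
#' @slot name single character string.
#' @slot taxa character vector of at least two leaf names.
#' @export
setClass("CladeSpec", representation(name = "character", taxa = "character"))

setValidity("CladeSpec", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("'name' must be one non-empty string")
  if (length(object@taxa) < 2L) return("a clade spec needs at least 2 taxa")
  if (anyDuplicated(object@taxa)) return("duplicated taxa in clade spec")
  TRUE
})

#' @rdname CladeSpec-class
#' @param name clade name.
#' @param taxa character vector of leaf names (>= 2).
#' @export
cladeSpec <- function(name, taxa) new("CladeSpec", name = name, taxa = taxa)

## ---------------------------------------------------------------------------
## Models
## ---------------------------------------------------------------------------

#' Branch-rate model for simulation
#'
#' Governs per-branch substitution rates laid over a chronogram:
#' \describe{
#'   \item{strict}{every branch gets \code{meanRate}.}
#'   \item{iid_lognormal}{\eqn{\log r_k \sim N(\log \mu - \sigma^2/2, \sigma^2)}
#'     independently per branch (mean-preserving on the natural scale).}
#'   \item{autocorrelated_lognormal}{a geometric Brownian walk down the tree:
#'     \eqn{\log r_{child} \sim N(\log r_{parent}, \sigma^2 t/T)} where
#'     \eqn{t} is the child branch duration and \eqn{T} the root age, so
#'     \code{sigma} is the expected root-to-tip log-rate standard deviation.}
#' }
#' \code{sigma = 0} reduces every kind to strict.
#'
#' @slot kind one of \code{"strict"}, \code{"iid_lognormal"},
#'   \code{"autocorrelated_lognormal"}.
#' @slot meanRate substitutions/site/MY, > 0.
#' @slot sigma log-scale standard deviation, >= 0.
#' @export
setClass("RateModel",
         representation(kind = "character", meanRate = "numeric",
                        sigma = "numeric"))

setValidity("RateModel", function(object) {
  kinds <- c("strict", "iid_lognormal", "autocorrelated_lognormal")
  if (!(object@kind %in% kinds))
    return(paste("kind must be one of:", paste(kinds, collapse = ", ")))
  if (object@meanRate <= 0) return("meanRate must be > 0")
  if (object@sigma < 0) return("sigma must be >= 0")
  TRUE
})

#' @rdname RateModel-class
#' @param kind rate model kind.
#' @param meanRate mean rate in substitutions/site/MY.
#' @param sigma log-scale SD.
#' @export
rateModel <- function(kind = c("strict", "iid_lognormal",
                               "autocorrelated_lognormal"),
                      meanRate, sigma = 0) {
  new("RateModel", kind = match.arg(kind), meanRate = meanRate, sigma = sigma)
}

#' GTR+Gamma+I substitution model
#'
#' General time-reversible rate matrix with discrete-gamma among-site rate
#' variation and a proportion of invariant sites.  The rate matrix is scaled
#' to one expected substitution per unit branch length at stationarity, and
#' the variable-class gamma rates are divided by \code{1 - pInv} so the
#' overall mean site rate (invariant class included) is 1: branch lengths are
#' expected substitutions per site averaged over all sites.
#'
#' @slot rates six exchangeabilities in the order AC, AG, AT, CG, CT, GT;
#'   the last (GT) is fixed at 1 for identifiability.
#' @slot baseFreqs stationary frequencies of A, C, G, T (sum to 1).
#' @slot shape gamma shape alpha (> 0).
#' @slot nCat number of discrete gamma categories (>= 1; 1 disables
#'   among-site variation).
#' @slot pInv proportion of invariant sites in [0, 1).
#' @slot gammaMedian use category medians instead of means for the discrete
#'   gamma approximation (default FALSE, i.e. category means).
#' @export
setClass("SubstitutionModel",
         representation(rates = "numeric", baseFreqs = "numeric",
                        shape = "numeric", nCat = "integer", pInv = "numeric",
                        gammaMedian = "logical"))

setValidity("SubstitutionModel", function(object) {
  if (length(object@rates) != 6L || any(object@rates <= 0))
    return("'rates' must be 6 positive exchangeabilities")
  if (abs(object@rates[6L] - 1) > 1e-12)
    return("last exchangeability (GT) must be fixed at 1")
  if (length(object@baseFreqs) != 4L || any(object@baseFreqs <= 0))
    return("'baseFreqs' must be 4 positive frequencies")
  if (abs(sum(object@baseFreqs) - 1) > 1e-8)
    return("'baseFreqs' must sum to 1")
  if (object@shape <= 0) return("gamma shape must be > 0")
  if (object@nCat < 1L) return("nCat must be >= 1")
  if (object@pInv < 0 || object@pInv >= 1) return("pInv must be in [0, 1)")
  TRUE
})

#' @rdname SubstitutionModel-class
#' @param rates,baseFreqs,shape,nCat,pInv,gammaMedian see slots.
#' @export
substitutionModel <- function(rates = rep(1, 6), baseFreqs = rep(0.25, 4),
                              shape = 1, nCat = 4L, pInv = 0,
                              gammaMedian = FALSE) {
  new("SubstitutionModel", rates = as.numeric(rates),
      baseFreqs = as.numeric(baseFreqs / sum(baseFreqs)), shape = shape,
      nCat = as.integer(nCat), pInv = pInv, gammaMedian = gammaMedian)
}

## ---------------------------------------------------------------------------
## Calibrations
## ---------------------------------------------------------------------------

#' Fossil-style calibration set
#'
#' A list of node-age constraints.  Each entry names a clade and carries a
#' minimum age, a maximum age, a fixed age, or a min+max window, all in
#' MYA.  A crown entry (\code{stem = FALSE}) attaches to the MRCA of the
#' clade's members present in the tree being dated and needs at least two
#' of them; a stem entry (\code{stem = TRUE}) attaches to the parent of
#' that MRCA — the clade's stem node — and remains valid down to a single
#' surviving member, which is how fossil minima assigned to stem groups
#' behave under taxon subsampling.  Penalized likelihood requires at least
#' one entry with a maximum or fixed age.
#'
#' @slot clades list of \linkS4class{CladeSpec}.
#' @slot minAge,maxAge,fixedAge numeric vectors (NA where absent).
#' @slot stem logical vector; TRUE attaches the constraint to the stem.
#' @export
setClass("CalibrationSet",
         representation(clades = "list", minAge = "numeric",
                        maxAge = "numeric", fixedAge = "numeric",
                        stem = "logical"))

setValidity("CalibrationSet", function(object) {
  k <- length(object@clades)
  if (length(object@minAge) != k || length(object@maxAge) != k ||
      length(object@fixedAge) != k || length(object@stem) != k)
    return("age vectors must match the number of clades")
  if (k == 0L) return("calibration set is empty")
  if (!all(vapply(object@clades, is, logical(1), "CladeSpec")))
    return("'clades' must be a list of CladeSpec")
  has <- !is.na(object@minAge) | !is.na(object@maxAge) | !is.na(object@fixedAge)
  if (!all(has)) return("every calibration needs at least one bound")
  both <- !is.na(object@minAge) & !is.na(object@maxAge)
  if (any(object@minAge[both] > object@maxAge[both]))
    return("minAge exceeds maxAge in some entry")
  if (!any(!is.na(object@maxAge) | !is.na(object@fixedAge)))
    return("at least one calibration must carry a maximum or fixed age")
  neg <- function(v) any(!is.na(v) & v < 0)
  if (neg(object@minAge) || neg(object@maxAge) || neg(object@fixedAge))
    return("ages must be >= 0")
  TRUE
})

#' @rdname CalibrationSet-class
#' @param clades list of \linkS4class{CladeSpec}.
#' @param minAge,maxAge,fixedAge numeric vectors in MYA, NA where absent.
#' @param stem logical vector, recycled; TRUE for stem-attached entries.
#' @export
calibrationSet <- function(clades, minAge = NA, maxAge = NA, fixedAge = NA,
                           stem = FALSE) {
  k <- length(clades)
  new("CalibrationSet", clades = clades,
      minAge = rep_len(as.numeric(minAge), k),
      maxAge = rep_len(as.numeric(maxAge), k),
      fixedAge = rep_len(as.numeric(fixedAge), k),
      stem = rep_len(as.logical(stem), k))
}

## ---------------------------------------------------------------------------
## Penalized likelihood
## ---------------------------------------------------------------------------

#' Penalized-likelihood configuration
#'
#' @slot lambda smoothing parameter (> 0; weight of the rate-roughness
#'   penalty; large values approach a strict clock).
#' @slot penalty \code{"log"} (penalty on log rates) or \code{"additive"}.
#' @slot nSites number of alignment sites used to convert branch lengths
#'   (substitutions/site) to expected substitution counts.
#' @slot roundCounts round expected counts to integers, r8s-style
#'   (default FALSE: counts stay continuous and the objective smooth).
#' @slot tolObjective convergence tolerance on the objective.
#' @slot tolAge convergence tolerance on ages (MY).
#' @slot restarts number of random restarts.
#' @slot seed integer seed for restart jitter.
#' @slot maxIter maximum block-coordinate sweeps.
#' @slot minDuration smallest admissible branch duration (MY).
#' @slot rateBounds lower/upper bounds on branch rates.
#' @export
setClass("PLConfig",
         representation(lambda = "numeric", penalty = "character",
                        nSites = "numeric", roundCounts = "logical",
                        tolObjective = "numeric", tolAge = "numeric",
                        restarts = "integer", seed = "integer",
                        maxIter = "integer", minDuration = "numeric",
                        rateBounds = "numeric"))

setValidity("PLConfig", function(object) {
  if (object@lambda < 0) return("lambda must be >= 0")
  if (!(object@penalty %in% c("log", "additive")))
    return("penalty must be 'log' or 'additive'")
  if (object@nSites < 1) return("nSites must be >= 1")
  if (object@restarts < 1L) return("restarts must be >= 1")
  if (length(object@rateBounds) != 2L ||
      object@rateBounds[1L] <= 0 ||
      object@rateBounds[1L] >= object@rateBounds[2L])
    return("rateBounds must be positive and increasing")
  TRUE
})

#' @rdname PLConfig-class
#' @param nSites,lambda,penalty,roundCounts,tolObjective,tolAge,restarts,seed,maxIter,minDuration,rateBounds
#'   see slots.
#' @export
plConfig <- function(nSites, lambda = 0.9, penalty = c("log", "additive"),
                     roundCounts = FALSE, tolObjective = 1e-6, tolAge = 1e-4,
                     restarts = 5L, seed = 1L, maxIter = 200L,
                     minDuration = 1e-6, rateBounds = c(1e-12, 100)) {
  new("PLConfig", lambda = lambda, penalty = match.arg(penalty),
      nSites = nSites, roundCounts = roundCounts,
      tolObjective = tolObjective, tolAge = tolAge,
      restarts = as.integer(restarts), seed = as.integer(seed),
      maxIter = as.integer(maxIter), minDuration = minDuration,
      rateBounds = rateBounds)
}

#' Penalized-likelihood dating problem
#'
#' Bundles a phylogram (rooted binary tree with branch lengths in expected
#' substitutions per site), the calibration set, and the configuration.
#' Branch lengths are converted to expected substitution counts
#' \eqn{x_k = b_k L}; zero-length branches are floored at 1e-9
#' substitutions/site to keep the Poisson log term finite.
#'
#' @slot phy rooted binary phylogram.
#' @slot x expected substitution counts per edge (ordered as \code{phy$edge}).
#' @slot calibrations a \linkS4class{CalibrationSet}.
#' @slot config a \linkS4class{PLConfig}.
#' @export
setClass("PLProblem",
         representation(phy = "phylo", x = "numeric",
                        calibrations = "CalibrationSet", config = "PLConfig"))

setValidity("PLProblem", function(object) {
  if (any(object@x < 0)) return("negative substitution counts")
  if (length(object@x) != nrow(object@phy$edge))
    return("x must have one entry per edge")
  TRUE
})

#' Penalized-likelihood solution
#'
#' @slot chronogram dated tree (\linkS4class{Chronogram}).
#' @slot rates fitted branch rates (substitutions/site/MY), ordered as the
#'   chronogram's edge matrix.
#' @slot objective penalized log-likelihood at the optimum.
#' @slot penaltyValue roughness penalty \eqn{\Phi} at the optimum.
#' @slot converged logical.
#' @slot activeConstraints data.frame of calibration bounds active at the
#'   solution (columns: calibration, node, side, age).
#' @slot restartObjectives objective reached by each restart.
#' @export
setClass("PLSolution",
         representation(chronogram = "Chronogram", rates = "numeric",
                        objective = "numeric", penaltyValue = "numeric",
                        converged = "logical",
                        activeConstraints = "data.frame",
                        restartObjectives = "numeric"))

## ---------------------------------------------------------------------------
## Branch-length estimation, profiles, experiments
## ---------------------------------------------------------------------------

#' Maximum-likelihood branch-length fit on a fixed topology
#'
#' @slot tree the rooted input topology with optimized branch lengths
#'   (substitutions/site).
#' @slot logLik final log-likelihood.
#' @slot iterations optimizer iteration count (NA when the backend does not
#'   report one).
#' @slot converged logical.
#' @slot model the substitution model actually used (with re-optimized
#'   shape / pInv / exchangeabilities when those were free).
#' @export
setClass("BranchLengthFit",
         representation(tree = "phylo", logLik = "numeric",
                        iterations = "integer", converged = "logical",
                        model = "SubstitutionModel"))

#' PROFILE-style node-age summary
#'
#' Per named clade: mean and sample standard deviation (n-1 denominator) of
#' crown ages over a set of dated trees, counting only trees in which at
#' least two clade members survive.
#'
#' @slot table data.frame with columns clade, mean, sd, nValid, nTotal.
#' @export
setClass("ProfileSummary", representation(table = "data.frame"))

setValidity("ProfileSummary", function(object) {
  need <- c("clade", "mean", "sd", "nValid", "nTotal")
  if (!all(need %in% names(object@table)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (any(object@table$nValid > object@table$nTotal))
    return("nValid cannot exceed nTotal")
  TRUE
})

#' Clade-targeted taxon-deletion scheme
#'
#' @slot targetClade the clade whose taxa are randomly deleted.
#' @slot deletionCounts numbers of taxa to delete (0 = full sampling).
#' @slot replicates replicates per deletion count (default 25).
#' @slot seed integer master seed; every replicate's deletion draw and
#'   dating restarts derive from it deterministically.
#' @slot outgroupsToDrop taxa removed after branch-length estimation and
#'   before dating (to avoid inflating the fitted evolutionary rate).
#' @slot calibrationStrategy label of the calibration design in force.
#' @export
setClass("SubsamplingScheme",
         representation(targetClade = "CladeSpec",
                        deletionCounts = "integer", replicates = "integer",
                        seed = "integer", outgroupsToDrop = "character",
                        calibrationStrategy = "character"))

setValidity("SubsamplingScheme", function(object) {
  if (any(object@deletionCounts < 0)) return("deletion counts must be >= 0")
  if (any(object@deletionCounts >= length(object@targetClade@taxa)))
    return("deletion counts must be smaller than the target clade")
  if (object@replicates < 1L) return("replicates must be >= 1")
  TRUE
})

#' @rdname SubsamplingScheme-class
#' @param targetClade,deletionCounts,replicates,seed,outgroupsToDrop,calibrationStrategy
#'   see slots.
#' @export
subsamplingScheme <- function(targetClade, deletionCounts, replicates = 25L,
                              seed = 1L, outgroupsToDrop = character(),
                              calibrationStrategy = "full") {
  new("SubsamplingScheme", targetClade = targetClade,
      deletionCounts = as.integer(deletionCounts),
      replicates = as.integer(replicates), seed = as.integer(seed),
      outgroupsToDrop = outgroupsToDrop,
      calibrationStrategy = calibrationStrategy)
}

#' Result of a resampling experiment
#'
#' @slot table per (deletionCount, clade) summary: mean, sd, nValid, nTotal.
#' @slot ages replicate-level crown ages (long format).
#' @slot provenance list of seeds, smoothing, calibration strategy and
#'   session facts needed to replay the run.
#' @export
setClass("ExperimentResult",
         representation(table = "data.frame", ages = "data.frame",
                        provenance = "list"))
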