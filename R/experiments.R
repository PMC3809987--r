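## Resampling experiments: clade-targeted taxon deletion, calibration-count
## comparisons on shared replicate streams, bootstrap node-age profiling,
## and the percent-younger bias metric.  Every replicate's deletion draw,
## branch-length fit and dating run derive deterministically from one
## master seed, and branch-length fits are cached so calibration strategies
## run on identical replicate streams differ only in the dating stage.

## deterministic sub-seed derivation (kept below 2^31)
.deriveSeed <- function(seed, i, j) {
  as.integer((as.numeric(seed) * 10007 + i * 7919 + j * 104729) %% 2147483647L)
}

## restrict a calibration set to entries still placeable in `phy`
## (crown entries need >= 2 surviving members, stem entries >= 1 with a
## non-root MRCA)
.restrictCalibrations <- function(cal, phy) {
  keep <- vapply(seq_along(cal@clades), function(i) {
    !is.na(.resolveCalNode(phy, cal@clades[[i]]@taxa, cal@stem[i]))
  }, logical(1L))
  if (!any(keep)) stop("no calibration survives the pruning")
  calibrationSet(cal@clades[keep], minAge = cal@minAge[keep],
                 maxAge = cal@maxAge[keep], fixedAge = cal@fixedAge[keep],
                 stem = cal@stem[keep])
}

## one replicate stream shared across calibration sets.
## Returns a named list (one per calibration set) of long data.frames.
.runStream <- function(aln, topology, model, scheme, focalClades,
                       calibrationSets, config, fixModelParams = FALSE,
                       verbose = FALSE) {
  stopifnot(all(topology$tip.label %in% names(aln)))
  target <- scheme@targetClade@taxa
  missing <- setdiff(target, topology$tip.label)
  if (length(missing))
    stop("target clade taxa absent from topology: ",
         paste(missing, collapse = ", "))
  cladeNames <- vapply(focalClades, function(cl) cl@name, character(1L))
  recs <- lapply(calibrationSets, function(x) list())
  blCache <- new.env(parent = emptyenv())   # keyed by the deleted-taxon set
  solCache <- new.env(parent = emptyenv())  # identical data is dated once

  for (j in seq_along(scheme@deletionCounts)) {
    d <- scheme@deletionCounts[j]
    for (r in seq_len(scheme@replicates)) {
      sseed <- .deriveSeed(scheme@seed, j, r)
      set.seed(sseed)
      removed <- if (d > 0) sample(target, d) else character()
      key <- paste0("k|", paste(sort(removed), collapse = "|"))
      if (is.null(blCache[[key]])) {
        topo <- if (d > 0) pruneTaxa(topology, removed) else topology
        blCache[[key]] <- estimateBranchLengths(
          aln, topo, model, fixModelParams = fixModelParams)
      }
      fit <- blCache[[key]]
      dated <- fit@tree
      if (length(scheme@outgroupsToDrop))
        dated <- pruneTaxa(dated,
                           intersect(scheme@outgroupsToDrop,
                                     dated$tip.label))
      for (cn in names(calibrationSets)) {
        skey <- paste0(cn, key)
        if (is.null(solCache[[skey]])) {
          calR <- .restrictCalibrations(calibrationSets[[cn]], dated)
          cfg <- config
          cfg@seed <- sseed
          solCache[[skey]] <- fitPL(plProblem(dated, calR, cfg))
        }
        sol <- solCache[[skey]]
        ages <- vapply(focalClades, function(cl) crownAge(sol, cl),
                       numeric(1L))
        recs[[cn]][[length(recs[[cn]]) + 1L]] <- data.frame(
          deletionCount = d, replicate = r, clade = cladeNames,
          age = ages, converged = sol@converged,
          nActiveMin = sum(sol@activeConstraints$side == "min"),
          stringsAsFactors = FALSE)
      }
      if (verbose)
        message(sprintf("deletion %d replicate %d done", d, r))
    }
  }
  lapply(recs, function(x) do.call(rbind, x))
}

## summarize a long age table into the Tables-1-5 shape
.summarizeAges <- function(long) {
  key <- interaction(long$deletionCount, long$clade, drop = FALSE)
  rows <- lapply(split(long, key), function(g) {
    v <- g$age[!is.na(g$age)]
    data.frame(deletionCount = g$deletionCount[1L], clade = g$clade[1L],
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2L) sd(v) else 0,
               nValid = length(v), nTotal = nrow(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$deletionCount, out$clade), ]
  rownames(out) <- NULL
  out
}

#' Run a clade-targeted taxon-deletion experiment
#'
#' Per replicate: draw the deletion set uniformly without replacement from
#' the target clade, prune the topology, re-estimate GTR+Gamma+I branch
#' lengths on the restricted alignment, drop the designated outgroups,
#' date by penalized likelihood under the given calibrations, and record
#' the focal clades' crown ages; then summarize across replicates per
#' deletion count.  Deterministic end to end for a given scheme seed.
#' Focal clades reduced below two sampled taxa in a replicate contribute
#' \code{NA} for that replicate (reported through \code{nValid}), not an
#' error.
#'
#' @param aln alignment (\code{phyDat}) covering all topology leaves.
#' @param topology rooted binary \code{phylo} backbone (branch lengths, if
#'   present, seed the optimizer).
#' @param model a \linkS4class{SubstitutionModel}.
#' @param scheme a \linkS4class{SubsamplingScheme}.
#' @param focalClades list of \linkS4class{CladeSpec} whose crown ages are
#'   tracked.
#' @param calibrations a \linkS4class{CalibrationSet}.
#' @param config a \linkS4class{PLConfig}.
#' @param fixModelParams keep substitution-model parameters fixed during
#'   branch-length estimation (default FALSE: re-optimize per replicate).
#' @param verbose log per-replicate progress.
#' @return an \linkS4class{ExperimentResult}.
#' @export
runSubsampling <- function(aln, topology, model, scheme, focalClades,
                           calibrations, config, fixModelParams = FALSE,
                           verbose = FALSE) {
  long <- .runStream(aln, topology, model, scheme, focalClades,
                     list(run = calibrations), config,
                     fixModelParams = fixModelParams,
                     verbose = verbose)$run
  new("ExperimentResult", table = .summarizeAges(long), ages = long,
      provenance = list(seed = scheme@seed,
                        lambda = config@lambda,
                        penalty = config@penalty,
                        calibrationStrategy = scheme@calibrationStrategy,
                        deletionCounts = scheme@deletionCounts,
                        replicates = scheme@replicates,
                        outgroupsToDrop = scheme@outgroupsToDrop,
                        package = as.character(packageVersion("plchrono"))))
}

#' Date identical replicate streams under several calibration designs
#'
#' Runs the same deletion replicates (same seeds, hence identical deletion
#' sets and branch-length fits) once per calibration set, so differences
#' between the results are attributable to the calibrations alone.
#'
#' @param aln,topology,model,focalClades,config,fixModelParams,verbose as
#'   in \code{\link{runSubsampling}}.
#' @param baseScheme the shared \linkS4class{SubsamplingScheme}.
#' @param calibrationSets named list of \linkS4class{CalibrationSet}.
#' @return named list of \linkS4class{ExperimentResult}, one per
#'   calibration set.
#' @export
runCalibrationExperiment <- function(aln, topology, model, baseScheme,
                                     calibrationSets, focalClades, config,
                                     fixModelParams = FALSE,
                                     verbose = FALSE) {
  longs <- .runStream(aln, topology, model, baseScheme, focalClades,
                      calibrationSets, config,
                      fixModelParams = fixModelParams, verbose = verbose)
  out <- lapply(names(longs), function(cn) {
    new("ExperimentResult", table = .summarizeAges(longs[[cn]]),
        ages = longs[[cn]],
        provenance = list(seed = baseScheme@seed, lambda = config@lambda,
                          penalty = config@penalty,
                          calibrationStrategy = cn,
                          deletionCounts = baseScheme@deletionCounts,
                          replicates = baseScheme@replicates,
                          outgroupsToDrop = baseScheme@outgroupsToDrop,
                          package = as.character(
                            packageVersion("plchrono"))))
  })
  names(out) <- names(longs)
  out
}

#' Percent younger
#'
#' \eqn{100 (a_{full} - a_{sub}) / a_{full}}: how much younger an age
#' estimated under reduced sampling or fewer calibrations is, relative to
#' the full-sampling estimate.
#'
#' @param ageFull full-sampling age in MYA (> 0).
#' @param ageSub comparison age in MYA.
#' @return percent younger (negative when the comparison age is older).
#' @export
percentChange <- function(ageFull, ageSub) {
  if (any(ageFull <= 0)) stop("ageFull must be > 0")
  100 * (ageFull - ageSub) / ageFull
}

#' Bootstrap node-age profile on a fixed topology
#'
#' Per replicate: resample alignment columns, re-estimate branch lengths
#' on the fixed topology, drop outgroups, date by penalized likelihood;
#' then summarize crown ages per clade.  Replicates whose dating run fails
#' to converge are dropped with a warning and reflected in \code{nValid}.
#'
#' @param aln,topology,model,calibrations,config,fixModelParams as in
#'   \code{\link{runSubsampling}}.
#' @param nReps number of bootstrap replicates (>= 2; the reference
#'   analysis used 100).
#' @param seed integer seed.
#' @param focalClades list of \linkS4class{CladeSpec}.
#' @param outgroupsToDrop taxa removed before dating.
#' @return a \linkS4class{ProfileSummary}.
#' @export
bootstrapProfile <- function(aln, topology, model, calibrations, config,
                             nReps, seed, focalClades,
                             outgroupsToDrop = character(),
                             fixModelParams = FALSE) {
  if (nReps < 2L) stop("nReps must be >= 2")
  sols <- vector("list", nReps)
  for (b in seq_len(nReps)) {
    bseed <- .deriveSeed(seed, b, 0L)
    baln <- bootstrapAlignment(aln, bseed)
    fit <- estimateBranchLengths(baln, topology, model,
                                 fixModelParams = fixModelParams)
    dated <- fit@tree
    if (length(outgroupsToDrop))
      dated <- pruneTaxa(dated, intersect(outgroupsToDrop,
                                          dated$tip.label))
    cfg <- config
    cfg@seed <- bseed
    sol <- tryCatch(fitPL(plProblem(dated,
                                    .restrictCalibrations(calibrations,
                                                          dated),
                                    cfg)),
                    error = function(e) NULL)
    if (is.null(sol) || !sol@converged) {
      warning("bootstrap replicate ", b, " dropped (dating did not converge)")
      next
    }
    sols[[b]] <- sol
  }
  sols <- Filter(Negate(is.null), sols)
  if (!length(sols)) stop("all bootstrap replicates failed")
  profileAges(sols, focalClades)
}

#' Run the packaged undersampling/calibration benchmark study
#'
#' For each of \code{nSeeds} independent seeds: simulate the benchmark
#' (\code{\link{simulateBenchmark}}), run the clade-targeted deletion
#' experiment on the ingroup under each calibration design on a shared
#' replicate stream, and record the ingroup's mean crown age per deletion
#' count and design.  This is the scaled-down reproduction of the
#' undersampled-clades-look-younger phenomenon; see the methods vignette
#' for the design and its rationale.
#'
#' @param nSeeds number of independent benchmark instances (default 10).
#' @param baseSeed first seed is \code{baseSeed + 1}.
#' @param deletionCounts taxa deleted from the 40-taxon ingroup per level
#'   (default 0, 30, 37).
#' @param replicates replicates per deletion level (default 10 for the
#'   desk-scale study; the full-scale design used 25).
#' @param strategies calibration designs to date each replicate under.
#' @param restarts dating restarts per fit (default 2 at desk scale).
#' @param verbose log per-seed progress.
#' @return data.frame with one row per (seed, strategy, deletionCount):
#'   columns seed, strategy, deletionCount, meanAge, sd, nValid, and
#'   anyActiveMin (TRUE when any full-design replicate at that level had
#'   an active minimum-age constraint).
#' @export
runBenchmarkStudy <- function(nSeeds = 10L, baseSeed = 100L,
                              deletionCounts = c(0L, 30L, 37L),
                              replicates = 10L,
                              strategies = c("full", "root_only",
                                             "root_plus_shallow"),
                              restarts = 2L, verbose = FALSE) {
  model <- substitutionModel(rates = c(2, 8, 1.5, 1, 16, 1),
                             baseFreqs = c(0.35, 0.30, 0.10, 0.25),
                             shape = 0.5, pInv = 0.2)
  rows <- list()
  for (s in seq_len(nSeeds)) {
    seed <- as.integer(baseSeed + s)
    bm <- simulateBenchmark(seed, model = model)
    sch <- subsamplingScheme(bm$clades$ingroup,
                             deletionCounts = deletionCounts,
                             replicates = replicates, seed = seed)
    cfg <- plConfig(nSites = 1500, restarts = as.integer(restarts),
                    seed = seed)
    res <- runCalibrationExperiment(bm$alignment, bm$phylogram, model,
                                    sch, bm$calibrations[strategies],
                                    list(bm$clades$ingroup), cfg)
    for (cn in names(res)) {
      tab <- res[[cn]]@table
      longF <- res[["full"]]@ages
      for (i in seq_len(nrow(tab))) {
        d <- tab$deletionCount[i]
        act <- if (!is.null(longF))
          any(longF$nActiveMin[longF$deletionCount == d] > 0)
        else NA
        rows[[length(rows) + 1L]] <- data.frame(
          seed = seed, strategy = cn, deletionCount = d,
          meanAge = tab$mean[i], sd = tab$sd[i], nValid = tab$nValid[i],
          anyActiveMin = act, stringsAsFactors = FALSE)
      }
    }
    if (verbose) message("benchmark seed ", seed, " done")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
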