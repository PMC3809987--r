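setMethod("show", "Chronogram", function(object) {
  phy <- object@phy
  cat(sprintf("Chronogram: %d tips, root age %.4g MYA\n",
              length(phy$tip.label), rootAge(object)))
})

setMethod("show", "CladeSpec", function(object) {
  cat(sprintf("CladeSpec '%s': %d taxa\n", object@name,
              length(object@taxa)))
})

setMethod("show", "RateModel", function(object) {
  cat(sprintf("RateModel: %s, mean %.4g subs/site/MY, sigma %.3g\n",
              object@kind, object@meanRate, object@sigma))
})

setMethod("show", "SubstitutionModel", function(object) {
  cat(sprintf(
    "GTR+G+I model: shape %.3g (%d cat%s), pInv %.3g\n  rates %s\n  freqs %s\n",
    object@shape, object@nCat,
    if (object@gammaMedian) ", medians" else "", object@pInv,
    paste(signif(object@rates, 3), collapse = " "),
    paste(signif(object@baseFreqs, 3), collapse = " ")))
})

setMethod("show", "CalibrationSet", function(object) {
  cat(sprintf("CalibrationSet: %d entries\n", length(object@clades)))
  for (i in seq_along(object@clades)) {
    parts <- c(
      if (!is.na(object@minAge[i])) sprintf("min %.4g", object@minAge[i]),
      if (!is.na(object@maxAge[i])) sprintf("max %.4g", object@maxAge[i]),
      if (!is.na(object@fixedAge[i])) sprintf("fixed %.4g",
                                              object@fixedAge[i]))
    cat(sprintf("  %-10s (%d taxa): %s MYA\n", object@clades[[i]]@name,
                length(object@clades[[i]]@taxa),
                paste(parts, collapse = ", ")))
  }
})

setMethod("show", "PLConfig", function(object) {
  cat(sprintf(
    "PLConfig: lambda %.3g, %s penalty, %g sites, %d restart(s)\n",
    object@lambda, object@penalty, object@nSites, object@restarts))
})

setMethod("show", "PLProblem", function(object) {
  cat(sprintf(
    "PLProblem: %d tips, %d calibrations, lambda %.3g\n",
    length(object@phy$tip.label), length(object@calibrations@clades),
    object@config@lambda))
})

setMethod("show", "PLSolution", function(object) {
  cat(sprintf(
    "PLSolution: root age %.4g MYA, objective %.6g, %sconverged\n",
    rootAge(object@chronogram), object@objective,
    if (object@converged) "" else "NOT "))
  if (nrow(object@activeConstraints))
    cat("  active constraints:",
        paste(unique(paste0(object@activeConstraints$calibration, ":",
                            object@activeConstraints$side)),
              collapse = ", "), "\n")
})

setMethod("show", "BranchLengthFit", function(object) {
  cat(sprintf(
    "BranchLengthFit: %d tips, logLik %.4f, %sconverged\n",
    length(object@tree$tip.label), object@logLik,
    if (object@converged) "" else "NOT "))
})

setMethod("show", "ProfileSummary", function(object) {
  cat("ProfileSummary:\n")
  print(object@table, row.names = FALSE)
})

setMethod("show", "SubsamplingScheme", function(object) {
  cat(sprintf(
    "SubsamplingScheme: target '%s' (%d taxa), deletions {%s}, %d reps\n",
    object@targetClade@name, length(object@targetClade@taxa),
    paste(object@deletionCounts, collapse = ", "), object@replicates))
})

setMethod("show", "ExperimentResult", function(object) {
  cat("ExperimentResult:\n")
  print(object@table, row.names = FALSE)
})

#' Summary table of a profile
#' @param x a \linkS4class{ProfileSummary} or \linkS4class{ExperimentResult}.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "ProfileSummary", function(x, ...) x@table)

#' @rdname as.data.frame-ProfileSummary-method
#' @export
setMethod("as.data.frame", "ExperimentResult", function(x, ...) x@table)
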