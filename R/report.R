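## Report tables in the shape of the published subsampling tables: rows are
## deletion counts ("None" for zero), columns are focal clades, cells are
## "mean (SD = s)" with an N/A footnote rule for clades reduced below two
## sampled taxa.  Means and SDs are printed at full precision so the table
## round-trips exactly; a machine-readable manifest records the run setup.

#' Write experiment report tables
#'
#' One TSV per \linkS4class{ExperimentResult} (suffixing the path with the
#' result's name when a named list is given), plus a YAML manifest of
#' seeds, smoothing and calibration strategy.  Cells with no valid
#' replicate render "N/A*", with the footnote rule appended as a trailing
#' comment line.
#'
#' @param results an \linkS4class{ExperimentResult} or a named list of
#'   them.
#' @param path output TSV path (used as a stem for named lists).
#' @param manifest also write \code{<path>.manifest.yaml} (default TRUE).
#' @return character vector of files written, invisibly.
#' @export
writeReport <- function(results, path, manifest = TRUE) {
  if (is(results, "ExperimentResult")) results <- list(results)
  if (is.null(names(results))) names(results) <- rep("", length(results))
  files <- character()
  for (i in seq_along(results)) {
    nm <- names(results)[i]
    file <- if (nzchar(nm) && length(results) > 1L)
      sub("(\\.tsv)?$", paste0(".", nm, ".tsv"), path)
    else path
    files <- c(files, .writeOneReport(results[[i]], file))
    if (manifest) {
      mf <- paste0(file, ".manifest.yaml")
      yaml::write_yaml(c(results[[i]]@provenance,
                         list(rVersion = as.character(getRversion()))), mf)
      files <- c(files, mf)
    }
  }
  invisible(files)
}

.writeOneReport <- function(result, file) {
  tab <- result@table
  con <- file(file, "w")
  on.exit(close(con))
  if (nrow(tab) == 0L) {
    writeLines("No. taxa deleted", con)
    return(invisible(file))
  }
  clades <- unique(tab$clade)
  counts <- sort(unique(tab$deletionCount))
  writeLines(paste(c("No. taxa deleted", clades), collapse = "\t"), con)
  anyNA <- FALSE
  for (d in counts) {
    cells <- vapply(clades, function(cl) {
      row <- tab[tab$deletionCount == d & tab$clade == cl, ]
      if (nrow(row) == 0L || row$nValid == 0L) {
        anyNA <<- TRUE
        "N/A*"
      } else {
        sprintf("%.17g (SD = %.17g)", row$mean, row$sd)
      }
    }, character(1L))
    lab <- if (d == 0) "None" else as.character(d)
    writeLines(paste(c(lab, cells), collapse = "\t"), con)
  }
  if (anyNA)
    writeLines(paste("# *Divergence times could not be calculated:",
                     "fewer than two taxa of the clade were sampled"), con)
  invisible(file)
}

#' Read an experiment report table back
#'
#' Parses a TSV written by \code{\link{writeReport}} into the long summary
#' format (deletionCount, clade, mean, sd); "N/A*" cells come back as NA.
#'
#' @param file path to the TSV.
#' @return data.frame.
#' @export
readReport <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 1L) stop("empty report")
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  clades <- hdr[-1L]
  rows <- list()
  for (ln in lines[-1L]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    d <- if (f[1L] == "None") 0L else as.integer(f[1L])
    for (j in seq_along(clades)) {
      cell <- f[j + 1L]
      if (cell == "N/A*") {
        m <- s <- NA_real_
      } else {
        mm <- regmatches(cell,
                         regexec("^(.+) \\(SD = (.+)\\)$", cell))[[1L]]
        m <- as.numeric(mm[2L]); s <- as.numeric(mm[3L])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        deletionCount = d, clade = clades[j], mean = m, sd = s,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
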