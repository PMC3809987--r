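## Tree input/output and topological utilities.  The tree container is
## ape's `phylo`; these wrappers add the validation this pipeline relies on
## (unique leaf labels, branch lengths present, rootedness) and the
## clade/age semantics used by the dating and resampling stages.

#' Read a Newick tree with validation
#'
#' Accepts unquoted and single-quoted labels, decimal branch lengths and
#' polytomies.  Square-bracket comments (NHX and friends) are stripped with
#' a warning.  Errors on malformed parentheses (reporting the character
#' position), a missing terminating semicolon, duplicate or empty leaf
#' labels, and (by default) missing branch lengths.
#'
#' @param file path to a Newick file (one tree).
#' @param text Newick string, alternative to \code{file}.
#' @param requireLengths error when any branch length is missing
#'   (default TRUE; the dating pipeline needs them).
#' @return a \code{phylo}.
#' @export
readNewick <- function(file = NULL, text = NULL, requireLengths = TRUE) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply 'file' or 'text'")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(paste(text, collapse = ""))
  if (!nzchar(text)) stop("empty Newick input")
  if (grepl("\\[", text)) {
    warning("square-bracket comments stripped from Newick input")
    text <- gsub("\\[[^]]*\\]", "", text)
  }
  if (!grepl(";", text)) {
    stop(sprintf("missing terminating ';' (input ends at position %d)",
                 nchar(text)))
  }
  ## parenthesis balance with position of first offence
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  inq <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") inq <- !inq
    if (inq) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("unbalanced ')' at position %d", i))
    }
    if (ch == ";" && depth != 0L)
      stop(sprintf("unbalanced '(' before ';' at position %d", i))
  }
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("Newick parse failed")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected exactly one tree")
    tr <- tr[[1L]]
  }
  unquote <- function(lab) {
    q <- grepl("^'.*'$", lab)
    lab[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", lab[q]))
    lab
  }
  tr$tip.label <- unquote(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unquote(tr$node.label)
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(tr$tip.label))) stop("empty leaf label")
  if (requireLengths) {
    if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
        anyNA(tr$edge.length))
      stop("missing branch lengths")
    if (any(tr$edge.length < 0)) stop("negative branch length")
  }
  tr
}

#' Write a tree as Newick
#'
#' @param phy a \code{phylo} or \linkS4class{Chronogram}.
#' @param file output path; when \code{NULL} the Newick string is returned.
#' @param digits significant digits for branch lengths (default 10).
#' @return the Newick string, invisibly when written to a file.
#' @export
writeNewick <- function(phy, file = NULL, digits = 10) {
  if (is(phy, "Chronogram")) phy <- phy@phy
  s <- ape::write.tree(phy, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Most recent common ancestor of a set of leaves
#'
#' @param phy a \code{phylo}.
#' @param taxa leaf names (all must be present).
#' @return node id (a tip id when a single taxon is given).
#' @export
mrcaNode <- function(phy, taxa) {
  if (is(phy, "Chronogram")) phy <- phy@phy
  taxa <- unique(as.character(taxa))
  missing <- setdiff(taxa, phy$tip.label)
  if (length(missing))
    stop("unknown taxa: ", paste(missing, collapse = ", "))
  if (length(taxa) == 1L) return(match(taxa, phy$tip.label))
  ape::getMRCA(phy, taxa)
}

#' Remove leaves, preserving surviving path lengths
#'
#' Drops the listed leaves and suppresses the resulting degree-2 nodes,
#' summing their two branch lengths, so that all pairwise path lengths
#' between surviving leaves are unchanged.
#'
#' @param phy a \code{phylo} or \linkS4class{Chronogram}.
#' @param remove leaf names to delete.
#' @return pruned tree of the same class as the input.
#' @export
pruneTaxa <- function(phy, remove) {
  chrono <- is(phy, "Chronogram")
  tr <- if (chrono) phy@phy else phy
  remove <- unique(as.character(remove))
  missing <- setdiff(remove, tr$tip.label)
  if (length(missing))
    stop("unknown taxa: ", paste(missing, collapse = ", "))
  keep <- length(tr$tip.label) - length(remove)
  if (keep < 3L)
    stop("pruning would leave fewer than 3 leaves (", keep, " remain)")
  if (length(remove) == 0L) return(phy)
  out <- ape::drop.tip(tr, remove, collapse.singles = TRUE)
  if (chrono) new("Chronogram", phy = out) else out
}

#' Test ultrametricity
#'
#' TRUE iff the difference between the largest and smallest root-to-leaf
#' path length is below \code{tol} (absolute, in the tree's length units).
#'
#' @param phy a \code{phylo} or \linkS4class{Chronogram}.
#' @param tol positive absolute tolerance.
#' @export
isUltrametric <- function(phy, tol = 1e-6) {
  if (is(phy, "Chronogram")) phy <- phy@phy
  stopifnot(tol > 0)
  depth <- ape::node.depth.edgelength(phy)
  n <- length(phy$tip.label)
  (max(depth[seq_len(n)]) - min(depth[seq_len(n)])) < tol
}

## ages for an ultrametric phylo: root age minus node depth
.phyloAges <- function(phy) {
  depth <- ape::node.depth.edgelength(phy)
  n <- length(phy$tip.label)
  ages <- max(depth[seq_len(n)]) - depth
  ages[seq_len(n)][abs(ages[seq_len(n)]) < 1e-8 * max(depth, 1)] <- 0
  ages
}

#' Construct a Chronogram from an ultrametric phylo
#'
#' @param phy rooted ultrametric \code{phylo} with branch durations in MY.
#' @return a \linkS4class{Chronogram}.
#' @export
chronogram <- function(phy) new("Chronogram", phy = phy)

#' Underlying phylo of a Chronogram
#' @param x a \linkS4class{Chronogram}.
#' @export
chronoTree <- function(x) x@phy

#' @rdname nodeAges
#' @export
setMethod("nodeAges", "Chronogram", function(x) .phyloAges(x@phy))

#' @rdname nodeAges
#' @export
setMethod("nodeAges", "phylo", function(x) .phyloAges(x))

#' @rdname rootAge
#' @export
setMethod("rootAge", "Chronogram", function(x) {
  ages <- .phyloAges(x@phy)
  ages[length(x@phy$tip.label) + 1L]
})

#' @rdname crownAge
#' @export
setMethod("crownAge", "Chronogram", function(x, clade) {
  phy <- x@phy
  members <- intersect(clade@taxa, phy$tip.label)
  if (length(members) < 2L) return(NA_real_)
  .phyloAges(phy)[ape::getMRCA(phy, members)]
})

#' @rdname crownAge
#' @export
setMethod("crownAge", "PLSolution", function(x, clade) {
  crownAge(x@chronogram, clade)
})
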