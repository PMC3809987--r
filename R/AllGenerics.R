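#' Node ages of a dated tree
#'
#' Ages in MYA for every node (tips first, then internal nodes, in
#' \code{phylo} numbering).  Leaves of an extant-only chronogram are at 0.
#'
#' @param x a \linkS4class{Chronogram} or an ultrametric \code{phylo}.
#' @return numeric vector of length \code{Ntip + Nnode}.
#' @export
setGeneric("nodeAges", function(x) standardGeneric("nodeAges"))

#' Root age in MYA
#' @param x a \linkS4class{Chronogram}.
#' @export
setGeneric("rootAge", function(x) standardGeneric("rootAge"))

#' Crown age of a named clade
#'
#' Age of the MRCA of the clade members present in the tree.  Returns
#' \code{NA} when fewer than two members survive (the crown age is then
#' undefined); non-monophyletic survivors get the age of their MRCA, which
#' may subtend non-members.
#'
#' @param x a \linkS4class{Chronogram} or \linkS4class{PLSolution}.
#' @param clade a \linkS4class{CladeSpec}.
#' @return age in MYA, or \code{NA_real_}.
#' @export
setGeneric("crownAge", function(x, clade) standardGeneric("crownAge"))

#' PROFILE-style summary of crown ages over a set of dated trees
#'
#' @param x list of \linkS4class{Chronogram} or \linkS4class{PLSolution}
#'   objects.
#' @param clades list of \linkS4class{CladeSpec}.
#' @return a \linkS4class{ProfileSummary}.
#' @export
setGeneric("profileAges", function(x, clades) standardGeneric("profileAges"))
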