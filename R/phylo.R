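#' Read and validate a phylogeny from Newick text
#'
#' Thin validating wrapper around [ape::read.tree()]. The tree must be rooted
#' (or rootable), have unique tip labels and finite, non-negative branch
#' lengths. Branch lengths are interpreted as millions of years (Myr)
#' throughout the package; no unit conversion is performed.
#'
#' @param text a Newick string, or `NULL` if `file` is given.
#' @param file path to a Newick file.
#' @return an object of class `phylo` (from \pkg{ape}).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file))
    pf_stop("pf_parse_error", "either `text` or `file` must be supplied")
  tr <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    pf_stop("pf_parse_error", "malformed Newick string near position %d",
            newick_error_pos(text %||% paste(readLines(file), collapse = "")))
  validate_tree(tr)
}

# crude locator for the first structural problem in a Newick string, used
# only to make parse errors actionable
newick_error_pos <- function(s) {
  depth <- 0L
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) return(i)
  }
  if (depth != 0L) return(length(chars))
  1L
}

validate_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label))
    pf_stop("pf_validation_error", "duplicate tip labels: %s",
            paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                  collapse = ", "))
  if (is.null(tr$edge.length))
    pf_stop("pf_validation_error", "tree has no branch lengths")
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
    pf_stop("pf_validation_error",
            "branch lengths must be finite and non-negative")
  if (any(tr$edge.length == 0))
    warning("tree contains zero-length branches; distinct tips may have ",
            "patristic distance 0", call. = FALSE)
  tr
}

#' Pairwise patristic distance matrix for a set of species
#'
#' Entry (i, j) is the sum of branch lengths along the path between tips i
#' and j, in the tree's units (Myr). The tree is pruned to the requested
#' species before distance extraction; pruning does not change patristic
#' distances.
#'
#' @param tree a `phylo` object.
#' @param species character vector of tip labels; defaults to all tips.
#' @return a symmetric numeric matrix with zero diagonal, dimnames =
#'   `species` in the order given.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' patristic_matrix(tr, c("A", "C"))["A", "C"] # 4
#' @export
patristic_matrix <- function(tree, species = tree$tip.label) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(species, tree$tip.label)
  if (length(missing) > 0)
    pf_stop("pf_lookup_error", "species not in tree: %s",
            paste(missing, collapse = ", "))
  if (anyDuplicated(species))
    pf_stop("pf_validation_error", "duplicated species in request")
  if (length(species) < ape::Ntip(tree) && length(species) >= 2)
    tree <- ape::keep.tip(tree, species)
  if (length(species) == 1L) {
    D <- matrix(0, 1, 1, dimnames = list(species, species))
    return(D)
  }
  D <- ape::cophenetic.phylo(tree)[species, species, drop = FALSE]
  D
}

genus_of <- function(name) {
  vapply(strsplit(name, "[ _]+"), `[[`, character(1), 1L)
}

#' Resolve a genus-level record to a congeneric tip
#'
#' Survey records identified only to genus are replaced by a tip drawn
#' uniformly at random from the same genus (first whitespace- or
#' underscore-delimited token of the binomial). Deterministic given `seed`.
#'
#' @param taxon genus name (or a binomial whose genus is used).
#' @param tree a `phylo` object.
#' @param seed integer seed for the random draw.
#' @return a single tip label belonging to `taxon`'s genus.
#' @export
substitute_genus <- function(taxon, tree, seed) {
  g <- genus_of(taxon)
  candidates <- tree$tip.label[genus_of(tree$tip.label) == g]
  if (length(candidates) == 0)
    pf_stop("pf_resolution_error", "no congener of genus '%s' in tree", g)
  if (length(candidates) == 1L) return(candidates)
  with_seed(seed, sample(candidates, 1L))
}
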