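#' Read and validate a dated (ultrametric) phylogeny
#'
#' Parses a Newick string or file into an \code{ape::phylo} object and checks
#' the contract assumed throughout the package: rooted, binary, strictly
#' positive branch lengths in millions of years, and ultrametric to a relative
#' tolerance of \code{1e-6} times tree height (published dated trees carry
#' rounded lengths, so an absolute tolerance would be too strict).
#'
#' @param text a Newick string, or \code{NULL} if \code{file} is given.
#' @param file path to a Newick file.
#' @param resolve_polytomies if \code{TRUE}, polytomies are broken into an
#'   arbitrary binary resolution by inserting 1e-8 My internal edges;
#'   by default polytomies are an error.
#' @return a validated \code{phylo} object.
#' @export
read_dated_tree <- function(text = NULL, file = NULL, resolve_polytomies = FALSE) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  if (!is.null(text)) {
    check_newick_syntax(text)
    tree <- tryCatch(ape::read.tree(text = text),
                     error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  } else {
    tree <- ape::read.tree(file = file)
  }
  if (is.null(tree)) stop("Newick parse error: no tree read")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    if (resolve_polytomies) {
      tree <- ape::multi2di(tree, random = FALSE)
      tree$edge.length[tree$edge.length == 0] <- 1e-8
    } else {
      stop("tree contains polytomies; set resolve_polytomies = TRUE to resolve them")
    }
  }
  validate_dated_tree(tree)
  tree
}

# cheap structural pre-check so malformed strings fail with a character offset
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("Newick parse error: unbalanced ')' at character %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("Newick parse error: %d unclosed '(' at character %d",
                 depth, length(chars)))
  if (!grepl(";\\s*$", text))
    stop("Newick parse error: missing terminal ';'")
  invisible(TRUE)
}

#' Validate the dated-tree contract
#'
#' @param tree a \code{phylo} object.
#' @param tol relative ultrametricity tolerance (fraction of tree height).
#' @return the tree, invisibly, or an error describing the violated invariant.
#' @export
validate_dated_tree <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length <= 0))
    stop("all edge lengths must be positive")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("tree must be binary")
  d <- node_depths(tree)
  td <- d[seq_len(ape::Ntip(tree))]
  h <- max(td)
  if (max(td) - min(td) > tol * h)
    stop(sprintf("tree is not ultrametric: root-to-tip spread %.3g exceeds %.3g",
                 max(td) - min(td), tol * h))
  invisible(tree)
}

# distance from the root to every node, in tree$edge order traversal
node_depths <- function(tree) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  d <- numeric(nn)
  # cladewise order guarantees parents appear before children
  tr <- reorder(tree, "cladewise")
  ord <- tr$edge
  len <- tr$edge.length
  for (i in seq_len(nrow(ord))) d[ord[i, 2L]] <- d[ord[i, 1L]] + len[i]
  d
}

#' Write a dated tree as Newick
#'
#' Thin wrapper around \code{ape::write.tree} keeping enough digits (15) that
#' parse/write round trips preserve branch lengths to better than 1e-9.
#' @param tree a dated tree.
#' @param file optional path; if omitted the Newick string is returned.
#' @return the Newick string (invisibly when writing to file).
#' @export
write_dated_tree <- function(tree, file = NULL) {
  s <- ape::write.tree(tree, digits = 15)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Tree height (root age) in My
#' @param tree a dated tree.
#' @return the maximum root-to-tip distance.
#' @export
tree_height <- function(tree) max(node_depths(tree)[seq_len(ape::Ntip(tree))])

#' Node ages, measured backwards from the present
#'
#' Extant tips have age 0; the root has age equal to the tree height.
#' @param tree a dated tree.
#' @return numeric vector over node ids (tips first, then internal nodes).
#' @export
node_ages <- function(tree) {
  d <- node_depths(tree)
  h <- max(d[seq_len(ape::Ntip(tree))])
  a <- h - d
  a[seq_len(ape::Ntip(tree))][abs(a[seq_len(ape::Ntip(tree))]) < 1e-9 * h] <- 0
  a
}

#' Sorted branch lengths of a tree
#'
#' A rooted binary tree with n tips has exactly 2n-2 edges; one length is
#' returned per edge, in ascending order.
#' @param tree a dated tree.
#' @return sorted numeric vector of edge lengths (My).
#' @export
branch_lengths <- function(tree) sort(tree$edge.length)

#' Graft an extant taxon onto a dated tree
#'
#' Attaches a new extant tip as sister to an existing tip or clade, splitting
#' the sister's stem edge at the node of age \code{divergence_age}. The new
#' pendant edge has length \code{divergence_age}, so the result remains
#' ultrametric. This mirrors the standard procedure for adding taxa missing
#' from a dated backbone at a divergence time taken from another study.
#'
#' @param tree a dated tree.
#' @param taxon new tip label (must not already be present).
#' @param sister a tip label, or a character vector of tip labels whose MRCA
#'   defines the sister clade.
#' @param divergence_age age (My before present) of the new divergence; must
#'   lie strictly within the age span of the sister's stem edge.
#' @return a dated tree with one more tip.
#' @export
graft_taxon <- function(tree, taxon, sister, divergence_age) {
  validate_dated_tree(tree)
  if (taxon %in% tree$tip.label) stop("taxon '", taxon, "' already in tree")
  n <- ape::Ntip(tree)
  if (is.character(sister) && length(sister) == 1L) {
    if (!sister %in% tree$tip.label) stop("sister tip '", sister, "' not found")
    s <- match(sister, tree$tip.label)
  } else {
    if (!all(sister %in% tree$tip.label)) stop("sister clade tips not all found")
    s <- ape::getMRCA(tree, sister)
  }
  ages <- node_ages(tree)
  row <- which(tree$edge[, 2L] == s)
  if (length(row) != 1L) stop("sister has no stem edge (is it the root?)")
  p <- tree$edge[row, 1L]
  a_lo <- ages[s]; a_hi <- ages[p]
  if (!(divergence_age > a_lo && divergence_age < a_hi))
    stop(sprintf("divergence_age %.4g outside the sister stem interval (%.4g, %.4g)",
                 divergence_age, a_lo, a_hi))
  m <- tree$Nnode
  # renumber: tips 1..n keep ids, new tip z = n+1, internal j -> j+1,
  # new internal node u = n+m+2
  z <- n + 1L
  u <- n + m + 2L
  remap <- function(v) ifelse(v > n, v + 1L, v)
  e <- cbind(remap(tree$edge[, 1L]), remap(tree$edge[, 2L]))
  len <- tree$edge.length
  sn <- remap(s); pn <- remap(p)
  keep <- setdiff(seq_len(nrow(e)), row)
  new_edge <- rbind(e[keep, , drop = FALSE],
                    c(pn, u), c(u, sn), c(u, z))
  new_len <- c(len[keep], a_hi - divergence_age, divergence_age - a_lo,
               divergence_age)
  out <- list(edge = new_edge, edge.length = new_len,
              tip.label = c(tree$tip.label, taxon), Nnode = m + 1L)
  class(out) <- "phylo"
  out <- reorder(out, "cladewise")
  validate_dated_tree(out)
  out
}

#' Remove a tip from a dated tree
#'
#' The inverse of \code{\link{graft_taxon}}: dropping a freshly grafted taxon
#' restores the original tree.
#' @param tree a dated tree.
#' @param taxon tip label to remove.
#' @return a dated tree with one fewer tip.
#' @export
prune_taxon <- function(tree, taxon) {
  if (!taxon %in% tree$tip.label) stop("taxon '", taxon, "' not in tree")
  ape::drop.tip(tree, taxon)
}

#' Serialise a tree to a JSON-ready list (edges, lengths, labels)
#' @param tree a dated tree.
#' @return a list suitable for \code{jsonlite::toJSON}; round-trips through
#'   \code{\link{tree_from_list}}.
#' @export
tree_to_list <- function(tree) {
  list(tip_label = tree$tip.label, nnode = tree$Nnode,
       edge = tree$edge, edge_length = tree$edge.length)
}

#' Rebuild a tree from \code{\link{tree_to_list}} output
#' @param x a list with fields tip_label, nnode, edge, edge_length.
#' @return a \code{phylo} object.
#' @export
tree_from_list <- function(x) {
  out <- list(edge = matrix(as.integer(unlist(x$edge)), ncol = 2L),
              edge.length = as.numeric(x$edge_length),
              tip.label = as.character(x$tip_label),
              Nnode = as.integer(x$nnode))
  class(out) <- "phylo"
  out
}
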