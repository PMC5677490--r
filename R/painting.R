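#' Regime paintings
#'
#' A regime painting assigns a selective regime to every point along every
#' branch of a dated tree. Each edge carries an ordered (rootward to tipward)
#' list of segments \code{(regime, duration)}; segment durations sum to the
#' edge length, adjacent segments differ in regime, and the first segment of
#' an edge continues the regime in force at its parent end. Edges are keyed
#' by their child node id so paintings survive edge reordering.
#'
#' @param tree a dated tree.
#' @param edge_segments named list (names = child node ids as characters);
#'   each element a data.frame with columns \code{regime} (character) and
#'   \code{duration} (positive numeric, My), rootward first.
#' @param root_regime regime label in force at the root.
#' @return an object of class \code{regime_painting}.
#' @export
regime_painting <- function(tree, edge_segments, root_regime) {
  p <- structure(list(edge_segments = edge_segments,
                      root_regime = as.character(root_regime)),
                 class = "regime_painting")
  validate_painting(tree, p)
  p
}

#' Validate a regime painting against its tree
#' @param tree a dated tree.
#' @param painting a \code{regime_painting}.
#' @param tol relative tolerance for segment-sum conservation.
#' @return the painting, invisibly.
#' @export
validate_painting <- function(tree, painting, tol = 1e-9) {
  segs <- painting$edge_segments
  e <- tree$edge
  if (length(segs) != nrow(e)) stop("painting covers ", length(segs),
                                    " edges; tree has ", nrow(e))
  key <- as.character(e[, 2L])
  if (!setequal(names(segs), key)) stop("painting edge keys do not match tree child nodes")
  for (i in seq_len(nrow(e))) {
    s <- segs[[key[i]]]
    if (is.null(s) || nrow(s) == 0L) stop("edge to node ", key[i], " has no segments")
    if (any(s$duration <= 0)) stop("non-positive segment duration on edge to node ", key[i])
    len <- tree$edge.length[i]
    if (abs(sum(s$duration) - len) > tol * max(len, 1))
      stop(sprintf("segments on edge to node %s sum to %.12g, edge length %.12g",
                   key[i], sum(s$duration), len))
    if (nrow(s) > 1L && any(s$regime[-1L] == s$regime[-nrow(s)]))
      stop("adjacent segments share a regime on edge to node ", key[i])
    par <- e[i, 1L]
    par_regime <- regime_at_node(tree, painting, par)
    if (s$regime[1L] != par_regime)
      stop(sprintf("edge to node %s starts in regime '%s' but parent end is '%s'",
                   key[i], s$regime[1L], par_regime))
  }
  invisible(painting)
}

# regime in force at the tipward end of the edge subtending `node`
# (root_regime for the root itself)
regime_at_node <- function(tree, painting, node) {
  root <- ape::Ntip(tree) + 1L
  if (node == root) return(painting$root_regime)
  s <- painting$edge_segments[[as.character(node)]]
  s$regime[nrow(s)]
}

#' Regime labels used by a painting
#' @param painting a \code{regime_painting}.
#' @return sorted character vector of distinct regime labels.
#' @export
painting_regimes <- function(painting) {
  sort(unique(c(painting$root_regime,
                unlist(lapply(painting$edge_segments, function(s) s$regime),
                       use.names = FALSE))))
}

#' Regime in force at each tip
#' @param tree a dated tree.
#' @param painting a \code{regime_painting}.
#' @return named character vector over tip labels.
#' @export
tip_regimes <- function(tree, painting) {
  n <- ape::Ntip(tree)
  out <- vapply(seq_len(n), function(i) regime_at_node(tree, painting, i), "")
  names(out) <- tree$tip.label
  out
}

#' Paint a tree with a single regime
#' @param tree a dated tree.
#' @param regime regime label.
#' @return a \code{regime_painting} with one segment per edge.
#' @export
paint_constant <- function(tree, regime = "base") {
  key <- as.character(tree$edge[, 2L])
  segs <- lapply(seq_len(nrow(tree$edge)), function(i)
    data.frame(regime = regime, duration = tree$edge.length[i]))
  names(segs) <- key
  regime_painting(tree, segs, regime)
}

#' Build a painting from regimes assigned to nodes
#'
#' Every node (tips and internal nodes) is assigned one regime. An edge whose
#' parent and child share a regime becomes a single segment; otherwise the
#' edge is split at its midpoint, the rootward half taking the parent's
#' regime. The midpoint split is a deterministic, symmetric convention for
#' paintings that carry no sampled change points (stochastic mappings carry
#' their own change points and never pass through this rule).
#'
#' @param tree a dated tree.
#' @param node_states character vector of regimes indexed by node id
#'   (tips \code{1..n}, then internal nodes), length \code{Ntip + Nnode}.
#' @return a \code{regime_painting}.
#' @export
paint_from_node_states <- function(tree, node_states) {
  nn <- ape::Ntip(tree) + tree$Nnode
  if (length(node_states) != nn || anyNA(node_states))
    stop("node_states must assign a regime to every node (length ", nn, ")")
  node_states <- as.character(node_states)
  segs <- vector("list", nrow(tree$edge))
  names(segs) <- as.character(tree$edge[, 2L])
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; c_ <- tree$edge[i, 2L]; len <- tree$edge.length[i]
    if (node_states[p] == node_states[c_]) {
      segs[[i]] <- data.frame(regime = node_states[c_], duration = len)
    } else {
      segs[[i]] <- data.frame(regime = c(node_states[p], node_states[c_]),
                              duration = c(len / 2, len / 2))
    }
  }
  root <- ape::Ntip(tree) + 1L
  regime_painting(tree, segs, node_states[root])
}

#' Annotated Newick string for a painted tree
#'
#' Writes standard Newick with a comment block per edge recording its
#' segments tipward to rootward, e.g. \code{A:2[&regimes={X:1,Y:1}]}.
#' Used for mapping archives; readable by eye and by simple parsers.
#'
#' @param tree a dated tree.
#' @param painting a \code{regime_painting}.
#' @return a single Newick string.
#' @export
painting_to_newick <- function(tree, painting) {
  n <- ape::Ntip(tree)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  build <- function(node) {
    lab <- if (node <= n) tree$tip.label[node] else ""
    rows <- children[[as.character(node)]]
    inner <- if (is.null(rows)) lab else
      paste0("(", paste(vapply(tree$edge[rows, 2L], build, ""), collapse = ","), ")", lab)
    row <- which(tree$edge[, 2L] == node)
    if (length(row) == 0L) return(inner)  # root
    s <- painting$edge_segments[[as.character(node)]]
    ann <- paste(sprintf("%s:%.9g", s$regime, s$duration), collapse = ",")
    sprintf("%s:%.9g[&regimes={%s}]", inner, tree$edge.length[row], ann)
  }
  paste0(build(n + 1L), ";")
}

# --- internal geometry used by the evolutionary models ---------------------

# For each tip, the root-to-tip sequence of painted intervals in
# depth-from-root coordinates: data.frame(regime, t0, t1), t0 < t1.
painting_paths <- function(tree, painting) {
  n <- ape::Ntip(tree)
  d <- node_depths(tree)
  tr <- reorder(tree, "cladewise")
  paths <- vector("list", n + tree$Nnode)
  root <- n + 1L
  paths[[root]] <- data.frame(regime = character(0), t0 = numeric(0), t1 = numeric(0))
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1L]; c_ <- tr$edge[i, 2L]
    s <- painting$edge_segments[[as.character(c_)]]
    ends <- d[p] + cumsum(s$duration)
    paths[[c_]] <- rbind(paths[[p]],
                         data.frame(regime = s$regime,
                                    t0 = c(d[p], ends[-length(ends)]),
                                    t1 = ends))
  }
  paths[seq_len(n)]
}

# Per-regime shared-time matrices: C[[r]][i,j] = time the root paths of tips
# i and j spend together in regime r. Sum over regimes = shared time matrix.
painting_shared_times <- function(tree, painting) {
  n <- ape::Ntip(tree)
  regs <- painting_regimes(painting)
  C <- lapply(regs, function(r) matrix(0, n, n))
  names(C) <- regs
  desc <- descendant_tips(tree)
  for (i in seq_len(nrow(tree$edge))) {
    c_ <- tree$edge[i, 2L]
    tips <- desc[[c_]]
    s <- painting$edge_segments[[as.character(c_)]]
    for (j in seq_len(nrow(s)))
      C[[s$regime[j]]][tips, tips] <- C[[s$regime[j]]][tips, tips] + s$duration[j]
  }
  C
}

# list over all nodes of the tip ids descending from (and including) the node
descendant_tips <- function(tree) {
  n <- ape::Ntip(tree)
  out <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) out[[i]] <- i
  tr <- reorder(tree, "postorder")
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1L]; c_ <- tr$edge[i, 2L]
    out[[p]] <- c(out[[p]], out[[c_]])
  }
  out
}

# plain shared-time (BM) matrix among tips, computed by edge accumulation
shared_time_matrix <- function(tree) {
  n <- ape::Ntip(tree)
  V <- matrix(0, n, n)
  desc <- descendant_tips(tree)
  for (i in seq_len(nrow(tree$edge))) {
    tips <- desc[[tree$edge[i, 2L]]]
    V[tips, tips] <- V[tips, tips] + tree$edge.length[i]
  }
  dimnames(V) <- list(tree$tip.label, tree$tip.label)
  V
}
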