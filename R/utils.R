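# Run expr with a temporary RNG state: seeds reproducibly when `seed` is
# given, and never disturbs the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a per-stage child seed from a master seed; keeps results < 2^31
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

# stable fingerprint of a numeric data vector, used to guard comparisons of
# fits that must share data
data_fingerprint <- function(x) {
  v <- as.numeric(x)
  paste(length(v), format(sum(v), digits = 15), format(sum(v^2), digits = 15),
        format(stats::median(v), digits = 15), sep = "|")
}

# match a named data vector against tree tips, returning it in tip order
align_to_tips <- function(tree, x) {
  if (is.null(names(x))) {
    if (length(x) != ape::Ntip(tree)) stop("data length does not match tip count")
    names(x) <- tree$tip.label
    return(x)
  }
  if (!setequal(names(x), tree$tip.label))
    stop("data names do not match tree tip labels")
  x[tree$tip.label]
}
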