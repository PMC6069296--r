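## Pairwise machinery -------------------------------------------------------
##
## Distances are computed from per-column mismatch indicators so that the
## bootstrap can resample columns as a single matrix product: with M (columns
## x pairs) the 0/1 mismatch indicators and S (columns x reps) multinomial
## resampling counts, crossprod(M, S) gives mismatch counts for every pair in
## every replicate at once.

taxon_pairs <- function(taxa) {
  n <- length(taxa)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ## column-major upper triangle: (1,2), (1,3), (2,3), ... matches dist order
  ## when filled below
  idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
}

DNA_BASES <- c("A", "C", "G", "T")

## M: mismatch indicator, V: both-bases-comparable indicator (gaps and
## ambiguity codes excluded pairwise), each columns x pairs
mismatch_matrices <- function(mat) {
  pairs <- taxon_pairs(rownames(mat))
  L <- ncol(mat)
  P <- nrow(pairs)
  ok <- matrix(mat %in% DNA_BASES, nrow = nrow(mat))
  M <- matrix(0, L, P)
  V <- matrix(0, L, P)
  for (k in seq_len(P)) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    valid <- ok[i, ] & ok[j, ]
    V[, k] <- as.numeric(valid)
    M[, k] <- as.numeric(valid & (mat[i, ] != mat[j, ]))
  }
  list(M = M, V = V, pairs = pairs, taxa = rownames(mat))
}

## Jukes-Cantor correction with saturation cap; pairs with no comparable
## columns are set to the cap so NJ stays defined on degenerate inputs.
jc_distance <- function(mismatch, valid, cap = 5) {
  p <- ifelse(valid > 0, mismatch / valid, 1)
  d <- rep.int(cap, length(p))
  ok <- p < 0.75
  d[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  pmin(d, cap)
}

dist_object <- function(dvec, taxa) {
  n <- length(taxa)
  m <- matrix(0, n, n, dimnames = list(taxa, taxa))
  m[upper.tri(m)] <- dvec
  stats::as.dist(t(m))
}

## Canonical non-trivial splits of a tree, each labelled by the sorted taxa
## of the side NOT containing the reference taxon (so labels read as rooted
## clades when the reference is the outgroup).
tree_splits <- function(tree, ref) {
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  n <- length(labels)
  out <- character(0)
  for (part in pp) {
    side <- labels[part]
    if (ref %in% side) side <- setdiff(labels, side)
    if (length(side) >= 2L && length(side) <= n - 2L) {
      out <- c(out, paste(sort(side, method = "radix"), collapse = ","))
    }
  }
  unique(out)
}

#' Infer a neighbor-joining tree with bootstrap supports
#'
#' The built-in evaluation backend: pairwise mismatch proportions over
#' comparable (non-gap, unambiguous) columns, Jukes-Cantor correction with a
#' saturation cap, neighbor joining, Felsenstein bootstrap (columns resampled
#' with replacement to the original length), and rooting on the outgroup.
#' Each internal branch's support is 100 times the fraction of replicate
#' trees containing the same bipartition. The split fixed by rooting on the
#' outgroup is not an inferred branch and is excluded from the lowest-support
#' summary.
#'
#' @param matrix character matrix of aligned sequences (rows = taxa, row
#'   names = taxon labels), e.g. from [concatenate_genes()].
#' @param reps number of bootstrap replicates (>= 1).
#' @param outgroup taxon label used to root the tree.
#' @param cap maximum Jukes-Cantor distance for saturated pairs
#'   (substitutions/site).
#' @return An object of class `support_tree`: the rooted `phylo` tree with
#'   supports as internal node labels, the named support vector (one entry
#'   per internal clade, keyed by its sorted taxon list), the minimum support
#'   `b`, and the outgroup.
#' @export
infer_support_tree <- function(matrix, reps = 100, outgroup, cap = 5) {
  mat <- as.matrix(matrix)
  if (nrow(mat) < 4L) {
    stop("at least 4 taxa are required", call. = FALSE)
  }
  if (is.null(rownames(mat)) || !(outgroup %in% rownames(mat))) {
    stop("outgroup '", outgroup, "' not found among taxa", call. = FALSE)
  }
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  mat <- toupper(mat)[sort(rownames(mat), method = "radix"), , drop = FALSE]
  mm <- mismatch_matrices(mat)
  nj_bootstrap(mm$M, mm$V, mm$taxa, reps = reps, outgroup = outgroup,
               cap = cap)
}

## Core backend shared by infer_support_tree() and the cached evaluator
## (which pre-computes M and V per gene and stacks them per word).
nj_bootstrap <- function(M, V, taxa, reps, outgroup, cap = 5) {
  L <- nrow(M)
  d0 <- jc_distance(colSums(M), colSums(V), cap = cap)
  point <- ape::nj(dist_object(d0, taxa))

  S <- stats::rmultinom(reps, size = L, prob = rep.int(1, L))
  bm <- crossprod(M, S)          # pairs x reps mismatch counts
  bv <- crossprod(V, S)          # pairs x reps comparable counts
  boot_splits <- vector("list", reps)
  for (r in seq_len(reps)) {
    dr <- jc_distance(bm[, r], bv[, r], cap = cap)
    boot_splits[[r]] <- tree_splits(ape::nj(dist_object(dr, taxa)), outgroup)
  }

  clades <- tree_splits(point, outgroup)
  supports <- vapply(clades, function(cl) {
    100 * mean(vapply(boot_splits, function(s) cl %in% s, logical(1)))
  }, numeric(1))

  rooted <- ape::root(point, outgroup = outgroup, resolve.root = TRUE)
  rooted$node.label <- node_support_labels(rooted, supports, outgroup)
  structure(list(tree = rooted, supports = supports,
                 b = if (length(supports)) min(supports) else 100,
                 outgroup = outgroup, taxa = taxa),
            class = "support_tree")
}

## Attach the support of each internal clade to its node in the rooted tree;
## the root and the outgroup-implied split carry empty labels.
node_support_labels <- function(rooted, supports, outgroup) {
  pp <- ape::prop.part(rooted)
  labels <- attr(pp, "labels")
  vapply(seq_along(pp), function(i) {
    side <- labels[pp[[i]]]
    if (outgroup %in% side) side <- setdiff(labels, side)
    key <- paste(sort(side, method = "radix"), collapse = ",")
    if (key %in% names(supports)) format(supports[[key]]) else ""
  }, character(1))
}

#' @export
print.support_tree <- function(x, ...) {
  cat("Support tree over", length(x$taxa), "taxa (outgroup:", x$outgroup,
      ")\n  lowest internal support b =", x$b, "\n")
  invisible(x)
}

#' Canonical topology key of a rooted tree
#'
#' Encodes the tree shape as the sorted set of its non-trivial clades (each a
#' sorted taxon list); two trees get equal keys exactly when they induce the
#' same clade sets. Branch lengths and supports are ignored.
#'
#' @param tree a `support_tree` or a rooted `phylo`.
#' @return character scalar key.
#' @export
topology_key <- function(tree) {
  if (inherits(tree, "support_tree")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"))
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  clades <- vapply(pp, function(part) {
    paste(sort(labels[part], method = "radix"), collapse = ",")
  }, character(1))
  paste(sort(unique(clades), method = "radix"), collapse = "|")
}
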