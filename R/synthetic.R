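#' Simulate a random rooted species tree with an outgroup
#'
#' Builds a rooted binary ingroup tree by random sequential joins
#' (coalescent-style), draws branch lengths uniformly from `bl_range`
#' (substitutions/site), and attaches the designated outgroup on a long basal
#' branch.
#'
#' @param n_taxa total number of leaves including the outgroup (>= 4).
#' @param bl_range range of ingroup branch lengths.
#' @param outgroup_bl length of the basal outgroup branch.
#' @return A rooted `phylo`; leaf labels are `taxon01`, `taxon02`, ... and
#'   `outgroup`; the outgroup name is stored in `attr(, "outgroup")`.
#' @export
simulate_tree <- function(n_taxa, bl_range = c(0.03, 0.15),
                          outgroup_bl = 0.4) {
  if (n_taxa < 4L) stop("n_taxa must be >= 4", call. = FALSE)
  n_in <- n_taxa - 1L
  nodes <- sprintf("taxon%02d", seq_len(n_in))
  bl <- function(k) stats::runif(k, bl_range[1L], bl_range[2L])
  while (length(nodes) > 1L) {
    pick <- sample.int(length(nodes), 2L)
    len <- bl(2L)
    joined <- sprintf("(%s:%f,%s:%f)", nodes[pick[1L]], len[1L],
                      nodes[pick[2L]], len[2L])
    nodes <- c(nodes[-pick], joined)
  }
  newick <- sprintf("(%s:%f,outgroup:%f);", nodes, bl(1L), outgroup_bl)
  tree <- ape::read.tree(text = newick)
  attr(tree, "outgroup") <- "outgroup"
  tree
}

## shorten the shortest non-trivial internal branch to the requested length
## (the branch spr_conflict() attacks first)
set_weakest_branch <- function(tree, len) {
  outgroup <- attr(tree, "outgroup")
  n <- length(tree$tip.label)
  child <- tree$edge[, 2L]
  internal <- which(child > n)
  ok <- vapply(internal, function(e) {
    tp <- ape::extract.clade(tree, child[e])$tip.label
    sz <- length(setdiff(tp, outgroup))
    sz >= 2L && sz <= n - 2L && !(outgroup %in% tp)
  }, logical(1))
  cand <- internal[ok]
  if (length(cand)) {
    e <- cand[which.min(tree$edge.length[cand])]
    tree$edge.length[e] <- len
  }
  tree
}

#' Conflicting topology by a nearest-neighbor interchange at the weakest
#' branch
#'
#' Swaps the two subtrees adjacent to the species tree's shortest internal
#' branch (the radiation that is hard to resolve) and sets that branch to
#' `stem` in the conflict tree. An NNI is the minimal topological
#' perturbation: the discordant signal it creates scales with the central
#' branch lengths only, so the conflict contests the weak branch without
#' overwhelming the rest of the tree.
#'
#' @param tree a rooted `phylo` with an `outgroup` attribute.
#' @param stem length of the conflicting resolution's central branch
#'   (`NULL` keeps the original length).
#' @return A `phylo` with the same leaves and a different [topology_key()].
#' @export
nni_conflict <- function(tree, stem = NULL) {
  outgroup <- attr(tree, "outgroup")
  n <- length(tree$tip.label)
  child <- tree$edge[, 2L]
  internal <- which(child > n)
  ok <- vapply(internal, function(e) {
    tp <- ape::extract.clade(tree, child[e])$tip.label
    sz <- length(setdiff(tp, outgroup))
    sz >= 2L && sz <= n - 2L && !(outgroup %in% tp)
  }, logical(1))
  cand <- internal[ok]
  if (!length(cand)) stop("no non-trivial internal branch", call. = FALSE)
  e <- cand[which.min(tree$edge.length[cand])]
  p <- tree$edge[e, 1L]
  cc <- tree$edge[e, 2L]
  c_edges <- which(tree$edge[, 1L] == cc)
  s_edge <- setdiff(which(tree$edge[, 1L] == p), e)
  s_edge <- s_edge[tree$edge[s_edge, 2L] != match(outgroup, tree$tip.label)]
  if (!length(s_edge) || length(c_edges) < 2L) {
    stop("weakest branch has no swappable neighborhood", call. = FALSE)
  }
  s_edge <- s_edge[1L]
  x2_edge <- c_edges[2L]
  tmp <- tree$edge[x2_edge, 2L]
  tree$edge[x2_edge, 2L] <- tree$edge[s_edge, 2L]
  tree$edge[s_edge, 2L] <- tmp
  if (!is.null(stem)) tree$edge.length[e] <- stem
  out <- ape::read.tree(text = ape::write.tree(tree))
  out <- ape::root(out, outgroup = outgroup, resolve.root = TRUE)
  attr(out, "outgroup") <- outgroup
  out
}

#' Conflicting topology by a subtree prune-regraft move
#'
#' Plants a topological conflict across the tree's weakest relationship: a
#' leaf is pruned from one side of the shortest internal branch and regrafted
#' onto a leaf branch on the other side, breaking that split. This mirrors
#' where support problems arise in practice (homoplasy erodes the shortest
#' internal branches first). Retries until the rooted topology actually
#' changes.
#'
#' @param tree a rooted `phylo` with an `outgroup` attribute.
#' @param target_rank which internal branch to attack, by increasing length
#'   (1 = shortest; wraps around when larger than the number of non-trivial
#'   internal branches).
#' @param stem length of the new internal branch created by the regraft
#'   (the strength of the alternative resolution); `NULL` places the tip
#'   halfway along the destination branch.
#' @param max_tries attempts before giving up.
#' @return A `phylo` with the same leaves and a different [topology_key()].
#' @export
spr_conflict <- function(tree, target_rank = 1L, stem = NULL,
                         max_tries = 100L) {
  outgroup <- attr(tree, "outgroup")
  key0 <- topology_key(tree)
  n <- length(tree$tip.label)
  ## internal edges inducing non-trivial splits, weakest first
  child <- tree$edge[, 2L]
  internal <- which(child > n)
  clade_tips <- lapply(internal, function(e) {
    ape::extract.clade(tree, child[e])$tip.label
  })
  nontrivial <- vapply(clade_tips, function(tp) {
    sz <- length(setdiff(tp, outgroup))
    sz >= 2L && sz <= n - 2L && !(outgroup %in% tp)
  }, logical(1))
  cand_edges <- internal[nontrivial][order(tree$edge.length[internal[nontrivial]])]
  if (!length(cand_edges)) stop("no non-trivial internal branch", call. = FALSE)
  for (i in seq_len(max_tries)) {
    e <- cand_edges[1L + (target_rank - 1L + i - 1L) %% length(cand_edges)]
    clade <- ape::extract.clade(tree, tree$edge[e, 2L])$tip.label
    tip <- sample(clade, 1L)
    dest <- setdiff(tree$tip.label, c(clade, outgroup))
    if (!length(dest)) next
    dest_tip <- sample(dest, 1L)
    pruned <- ape::drop.tip(tree, tip)
    el <- pruned$edge.length[pruned$edge.length > 0]
    graft <- ape::read.tree(text = sprintf("(%s:%f);", tip,
                                           stats::median(el)))
    target <- match(dest_tip, pruned$tip.label)
    dest_edge <- which(pruned$edge[, 2L] == target)
    dest_bl <- pruned$edge.length[dest_edge]
    pos <- if (is.null(stem)) 0.5 * dest_bl else min(stem, 0.9 * dest_bl)
    out <- ape::bind.tree(pruned, graft, where = target, position = pos)
    out <- ape::root(out, outgroup = outgroup, resolve.root = TRUE)
    if (topology_key(out) != key0) {
      attr(out, "outgroup") <- outgroup
      return(out)
    }
  }
  stop("could not find a conflicting topology", call. = FALSE)
}

#' Evolve a gap-free alignment along a tree under Jukes-Cantor
#'
#' The root sequence is uniform over A/C/G/T and each site evolves
#' independently; along a branch of length `l` the substitution probability
#' is `(3/4) (1 - exp(-(4/3) rate l))`.
#'
#' @param tree a `phylo` with branch lengths.
#' @param length number of sites.
#' @param rate rate scaling applied to all branch lengths.
#' @return character matrix (taxa x sites) of upper-case bases.
#' @export
evolve_alignment <- function(tree, length, rate = 1) {
  stopifnot(length >= 1, rate > 0)
  sim <- phangorn::simSeq(tree, l = length, rate = rate)
  m <- toupper(as.character(sim))
  rownames(m) <- names(sim)
  m
}

#' Synthetic dataset with planted problematic genes
#'
#' Good genes evolve on the species tree; each planted "bad" gene evolves on
#' its own conflicting topology (one subtree prune-regraft away) at an
#' elevated rate, emulating core genes that disturb the phylogenetic signal
#' (homoplasy, transfer; discordant genes rarely share a single alternative
#' history). Ground truth is recorded.
#'
#' @param n_taxa leaves including the outgroup (default 6).
#' @param n_genes number of core genes (default 20).
#' @param n_bad number of planted problematic genes (1 <= n_bad < n_genes;
#'   0 plants no conflict).
#' @param gene_length alignment columns per gene (default 300).
#' @param rate substitution-rate scaling of good genes.
#' @param bad_rate_mult rate multiplier of the planted genes (default 3).
#' @param bl_range branch-length range of the species (and conflict) tree;
#'   short branches emulate the close species for which support problems
#'   arise in practice.
#' @param weak_branch length assigned to the species tree's shortest
#'   internal branch: a near-zero "rapid radiation" branch that the good
#'   genes alone cannot resolve decisively, the hard branch real datasets
#'   exhibit. The planted conflict attacks exactly this branch.
#' @param conflict_scale the conflict tree's central branch is
#'   `conflict_scale * weak_branch` (strength of the alternative
#'   resolution relative to the true one).
#' @return An object of class `planted_dataset`: `alignments` (a
#'   `gene_alignment_set`), `species_tree`, `conflict_trees` (one per planted
#'   gene), `bad_genes` (character), `outgroup`, `params`.
#' @export
planted_dataset <- function(n_taxa = 6, n_genes = 20, n_bad = 3,
                            gene_length = 300, rate = 1, bad_rate_mult = 3,
                            bl_range = c(0.015, 0.03), weak_branch = 0.004,
                            conflict_scale = 1.5) {
  stopifnot(n_genes >= 2, n_bad >= 0, n_bad < n_genes)
  species <- simulate_tree(n_taxa, bl_range = bl_range)
  species <- set_weakest_branch(species, weak_branch)
  gene_names <- sprintf("gene%02d", seq_len(n_genes))
  bad <- if (n_bad > 0) sort(sample(gene_names, n_bad)) else character(0)
  ## the discordant history carries its own, stronger, internal signal
  ## (HGT-like coherent conflict shared by the planted genes, as when a
  ## linked block was transferred together): the conflict tree's internal
  ## branches are scaled up, terminal branches untouched
  conflicts <- if (n_bad > 0) {
    ## nearest-neighbor interchange at the radiation: the alternative
    ## resolution is about as weak as the true one, so no gene subset can
    ## resolve the branch decisively either way
    ct <- nni_conflict(species, stem = conflict_scale * weak_branch)
    stats::setNames(rep(list(ct), n_bad), bad)
  } else {
    stats::setNames(list(), character(0))
  }
  genes <- list()
  for (g in gene_names) {
    if (g %in% bad) {
      genes[[g]] <- evolve_alignment(conflicts[[g]], gene_length,
                                     rate = rate * bad_rate_mult)
    } else {
      genes[[g]] <- evolve_alignment(species, gene_length, rate = rate)
    }
  }
  structure(list(alignments = gene_alignment_set(genes),
                 species_tree = species, conflict_trees = conflicts,
                 bad_genes = bad, outgroup = attr(species, "outgroup"),
                 params = list(n_taxa = n_taxa, n_genes = n_genes,
                               n_bad = n_bad, gene_length = gene_length,
                               rate = rate, bad_rate_mult = bad_rate_mult)),
            class = "planted_dataset")
}

#' @export
print.planted_dataset <- function(x, ...) {
  cat("Planted dataset:", x$params$n_genes, "genes x",
      length(x$alignments$taxa), "taxa;",
      length(x$bad_genes), "planted problematic gene(s)\n")
  invisible(x)
}

#' Write a planted dataset to disk
#'
#' One FASTA file per gene, the true and conflicting trees as newick, and a
#' ground-truth JSON sidecar (planted genes, outgroup, parameters).
#'
#' @param dataset a `planted_dataset`.
#' @param directory output directory.
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "planted_dataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  write_gene_alignments(dataset$alignments, directory)
  ape::write.tree(dataset$species_tree,
                  file.path(directory, "species_tree.nwk"))
  for (g in names(dataset$conflict_trees)) {
    ape::write.tree(dataset$conflict_trees[[g]],
                    file.path(directory, paste0("conflict_", g, ".nwk")))
  }
  jsonlite::write_json(
    list(bad_genes = dataset$bad_genes, outgroup = dataset$outgroup,
         params = dataset$params),
    file.path(directory, "ground_truth.json"), auto_unbox = TRUE
  )
  invisible(directory)
}

#' All-ones and good-genes-only words of a planted dataset
#'
#' @param dataset a `planted_dataset`.
#' @return list with `all_ones` and `good_only` integer words aligned to the
#'   dataset's catalogue.
#' @export
dataset_words <- function(dataset) {
  stopifnot(inherits(dataset, "planted_dataset"))
  catalog <- dataset$alignments$catalog
  all_ones <- rep(1L, catalog$n)
  good_only <- as.integer(!(catalog$names %in% dataset$bad_genes))
  list(all_ones = all_ones, good_only = good_only)
}
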