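test_that("gene alignments load from a FASTA directory with sorted catalog", {
  taxa <- c("t1", "t2", "t3", "t4")
  mk <- function(L) matrix(sample(c("A", "C", "G", "T"), 4 * L,
                                  replace = TRUE),
                           4, L, dimnames = list(taxa, NULL))
  set.seed(1)
  dir <- write_fasta_dir(list(zeta = mk(12), alpha = mk(30), mid = mk(9)))
  aln <- load_gene_alignments(dir)
  expect_identical(aln$catalog$names, c("alpha", "mid", "zeta"))
  expect_length(aln$taxa, 4L)
  expect_identical(unname(aln$n_col), c(30L, 9L, 12L))
})

test_that("ragged alignments, taxon mismatches and empty dirs are rejected", {
  dir <- withr::local_tempdir()
  expect_error(load_gene_alignments(dir), "no FASTA")
  writeLines(c(">a", "ACGT", ">b", "ACG"), file.path(dir, "g1.fasta"))
  expect_error(load_gene_alignments(dir), "ragged")

  dir2 <- withr::local_tempdir()
  writeLines(c(">a", "ACGT", ">b", "ACGT"), file.path(dir2, "g1.fasta"))
  writeLines(c(">a", "ACGT", ">c", "ACGT"), file.path(dir2, "g2.fasta"))
  expect_error(load_gene_alignments(dir2), "taxon sets differ")
})

test_that("concatenation appends active genes in catalog order", {
  taxa <- c("x", "y", "z", "w")
  g1 <- matrix("A", 4, 10, dimnames = list(taxa, NULL))
  g2 <- matrix("C", 4, 20, dimnames = list(taxa, NULL))
  aln <- gene_alignment_set(list(b_gene = g2, a_gene = g1))
  both <- concatenate_genes(aln, c(1L, 1L))
  expect_equal(ncol(both), 30)
  expect_identical(attr(both, "genes"), c("a_gene", "b_gene"))
  one <- concatenate_genes(aln, c(1L, 0L))
  expect_equal(ncol(one), 10)
  expect_identical(attr(one, "genes"), "a_gene")
  expect_error(concatenate_genes(aln, c(0L, 0L)), "empty")
  ## discovery order must not matter: same set, permuted input list
  aln2 <- gene_alignment_set(list(a_gene = g1, b_gene = g2))
  expect_identical(concatenate_genes(aln2, c(1L, 1L)), both)
})

test_that("neighbor joining recovers each quartet topology from block signal", {
  taxa <- c("A", "B", "C", "D")
  pairs <- list(c("A", "B"), c("A", "C"), c("A", "D"))
  keys <- character(0)
  for (p1 in pairs) {
    aln <- quartet_alignment(p1, setdiff(taxa, p1))
    tr <- infer_support_tree(aln, reps = 25, outgroup = "D")
    expect_s3_class(tr, "support_tree")
    ## the pair not containing D must be a clade in the rooted tree
    pair_in <- setdiff(taxa, c(p1, "D"))
    expected_clade <- if ("D" %in% p1) pair_in else p1
    expect_true(paste(sort(expected_clade), collapse = ",") %in%
                  names(tr$supports))
    keys <- c(keys, topology_key(tr))
  }
  expect_length(unique(keys), 3L)
})

test_that("fixed block differences give full bootstrap support", {
  aln <- clean_six_taxon_alignment()
  tr <- infer_support_tree(aln, reps = 100, outgroup = "F")
  expect_true(all(tr$supports == 100))
  expect_equal(tr$b, 100)
  ## a single replicate can only give 0 or 100
  tr1 <- infer_support_tree(aln, reps = 1, outgroup = "F")
  expect_true(all(tr1$supports %in% c(0, 100)))
})

test_that("degenerate inputs are rejected", {
  aln <- clean_six_taxon_alignment()
  expect_error(infer_support_tree(aln[1:3, ], reps = 10, outgroup = "A"),
               "4 taxa")
  expect_error(infer_support_tree(aln, reps = 10, outgroup = "nope"),
               "outgroup")
})

test_that("topology keys ignore branch lengths, supports and rotation", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- ape::read.tree(text = "((A:2,B:2):2,(C:2,D:2):2);")
  t3 <- ape::read.tree(text = "((D:1,C:1):5,(B:1,A:1):5);")
  expect_identical(topology_key(t1), topology_key(t2))
  expect_identical(topology_key(t1), topology_key(t3))
  shapes <- c("((A,B),(C,D));", "(((A,B),C),D);", "(((A,C),B),D);")
  keys <- vapply(shapes, function(s) topology_key(ape::read.tree(text = s)),
                 character(1))
  expect_length(unique(keys), 3L)
})

test_that("evaluation is cached, reproducible and order-insensitive", {
  aln <- clean_six_taxon_alignment()
  gset <- gene_alignment_set(list(g1 = aln[, 1:80], g2 = aln[, 81:160]))
  ctx <- eval_context(alignments = gset, outgroup = "F", reps = 20, seed = 3)
  r1 <- evaluate_word(ctx, c(1L, 1L))
  r1again <- evaluate_word(ctx, c(1L, 1L))
  expect_equal(ctx$state$n_evals, 1L)
  expect_equal(ctx$state$cache_hits, 1L)
  expect_identical(r1$score, r1again$score)

  ## fresh context, same seed: identical record
  ctx2 <- eval_context(alignments = gset, outgroup = "F", reps = 20, seed = 3)
  r2 <- evaluate_word(ctx2, c(1L, 1L))
  expect_identical(r1$supports, r2$supports)
  expect_identical(r1$topology, r2$topology)

  ## taxon input order must not matter
  perm <- c("D", "F", "A", "C", "B", "E")
  gset3 <- gene_alignment_set(list(g1 = aln[perm, 1:80],
                                   g2 = aln[perm, 81:160]))
  ctx3 <- eval_context(alignments = gset3, outgroup = "F", reps = 20, seed = 3)
  r3 <- evaluate_word(ctx3, c(1L, 1L))
  expect_identical(r1$supports, r3$supports)
  expect_identical(r1$topology, r3$topology)
})

test_that("evaluation records carry consistent score fields", {
  spec <- landscape_spec(10, bad = 3, penalty = 20)
  ctx <- eval_context(landscape = spec, seed = 1)
  rec <- evaluate_word(ctx, rep(1L, 10))
  expect_equal(rec$b, 80)
  expect_equal(rec$p, 100)
  expect_equal(rec$score, 90)
  expect_false(rec$well_supported)
  expect_error(evaluate_word(ctx, rep(0L, 10)), "no active gene")
})
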