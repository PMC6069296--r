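#' Build a per-gene alignment set from character matrices
#'
#' @param genes named list of character matrices (rows = taxa, columns =
#'   alignment positions; row names are taxon labels). All genes must carry
#'   exactly the same taxon set.
#' @return An object of class `gene_alignment_set`: per-gene matrices with
#'   rows ordered by the shared (sorted) taxon list, a [gene_catalog] over the
#'   gene names, and per-gene column counts.
#' @export
gene_alignment_set <- function(genes) {
  if (!is.list(genes) || length(genes) < 1L || is.null(names(genes)) ||
      any(!nzchar(names(genes)))) {
    stop("genes must be a non-empty named list of alignment matrices",
         call. = FALSE)
  }
  genes <- lapply(genes, function(m) {
    m <- as.matrix(m)
    if (is.null(rownames(m)) || nrow(m) < 1L) {
      stop("each gene alignment needs taxon row names", call. = FALSE)
    }
    toupper(m)
  })
  taxa <- sort(rownames(genes[[1L]]), method = "radix")
  for (g in names(genes)) {
    tg <- sort(rownames(genes[[g]]), method = "radix")
    if (!identical(tg, taxa)) {
      stop("taxon sets differ across genes (gene '", g, "')", call. = FALSE)
    }
    genes[[g]] <- genes[[g]][taxa, , drop = FALSE]
  }
  catalog <- gene_catalog(names(genes))
  genes <- genes[catalog$names]
  structure(list(genes = genes, taxa = taxa, catalog = catalog,
                 n_col = vapply(genes, ncol, integer(1))),
            class = "gene_alignment_set")
}

#' Load per-gene FASTA alignments from a directory
#'
#' Each `.fasta`/`.fa`/`.fna` file holds the multiple alignment of one core
#' gene; the gene name is the file stem. All genes must contain exactly the
#' same taxa and, within a gene, sequences of equal length.
#'
#' @param directory path containing the FASTA files.
#' @return A `gene_alignment_set`.
#' @export
load_gene_alignments <- function(directory) {
  if (!dir.exists(directory)) {
    stop("alignment directory not found: ", directory, call. = FALSE)
  }
  files <- list.files(directory, pattern = "\\.(fasta|fa|fna)$",
                      full.names = TRUE)
  if (length(files) < 1L) {
    stop("no FASTA files found in ", directory, call. = FALSE)
  }
  genes <- list()
  for (f in files) {
    gene <- sub("\\.(fasta|fa|fna)$", "", basename(f))
    seqs <- ape::read.FASTA(f)
    if (length(seqs) < 1L) {
      stop("empty FASTA file: ", f, call. = FALSE)
    }
    lens <- lengths(seqs)
    if (length(unique(lens)) != 1L) {
      stop("ragged alignment in gene '", gene,
           "': sequence lengths differ", call. = FALSE)
    }
    m <- toupper(do.call(rbind, lapply(as.character(seqs), identity)))
    rownames(m) <- names(seqs)
    genes[[gene]] <- m
  }
  gene_alignment_set(genes)
}

#' Concatenate the selected genes into a supermatrix
#'
#' Columns of active genes are appended in catalogue order, so the result is
#' independent of file-discovery order.
#'
#' @param alignments a `gene_alignment_set`.
#' @param word integer 0/1 vector aligned to `alignments$catalog`.
#' @return character matrix (taxa x total columns) with attribute `genes`
#'   listing the contributing genes in order.
#' @export
concatenate_genes <- function(alignments, word) {
  stopifnot(inherits(alignments, "gene_alignment_set"))
  word <- assert_word(word, alignments$catalog$n)
  if (sum(word) == 0L) {
    stop("cannot concatenate an empty gene subset", call. = FALSE)
  }
  active <- alignments$catalog$names[word == 1L]
  mat <- do.call(cbind, alignments$genes[active])
  rownames(mat) <- alignments$taxa
  attr(mat, "genes") <- active
  mat
}

#' Write a gene alignment set as one FASTA file per gene
#'
#' @param alignments a `gene_alignment_set`.
#' @param directory output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_gene_alignments <- function(alignments, directory) {
  stopifnot(inherits(alignments, "gene_alignment_set"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (g in alignments$catalog$names) {
    m <- alignments$genes[[g]]
    path <- file.path(directory, paste0(g, ".fasta"))
    lines <- as.vector(rbind(paste0(">", rownames(m)),
                             apply(m, 1L, paste, collapse = "")))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
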