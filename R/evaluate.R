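## Per-word bootstrap seed: a deterministic 31-bit hash of (context seed,
## word bits), so resampling is reproducible and word-specific regardless of
## the order in which a metaheuristic reaches the word.
word_seed <- function(seed, bits) {
  mod <- 2147483647
  h <- as.numeric(seed) %% mod
  for (b in bits) h <- (h * 31 + b + 1) %% mod
  as.integer(h)
}

## Run code under its own RNG stream without disturbing the caller's; keeps
## evaluation results independent of when (or whether) the cache is hit.
with_isolated_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Evaluation context: alignments or landscape, plus cache and history
#'
#' Holds everything [evaluate_word()] needs: either a `gene_alignment_set`
#' (with outgroup and bootstrap settings) or a [landscape_spec], the
#' well-supported threshold, the base seed from which per-word bootstrap
#' seeds are derived, and mutable state (memoization cache, run history,
#' counters). Repeated evaluation of the same word never re-invokes the
#' backend.
#'
#' @param alignments a `gene_alignment_set`, or `NULL` when a landscape is
#'   used.
#' @param landscape a [landscape_spec], or `NULL` when alignments are used.
#' @param outgroup taxon label used to root trees (alignment contexts only).
#' @param reps bootstrap replicates per evaluation.
#' @param support_threshold a tree is flagged well supported when all its
#'   internal supports exceed this value (default 95).
#' @param seed base seed for per-word bootstrap resampling.
#' @param cap saturation cap for Jukes-Cantor distances.
#' @return An object of class `eval_context`.
#' @export
eval_context <- function(alignments = NULL, landscape = NULL, outgroup = NULL,
                         reps = 100, support_threshold = 95, seed = 1L,
                         cap = 5) {
  if (is.null(alignments) == is.null(landscape)) {
    stop("provide exactly one of alignments or landscape", call. = FALSE)
  }
  ctx <- list(landscape = landscape, outgroup = outgroup, reps = reps,
              support_threshold = support_threshold, seed = as.integer(seed),
              cap = cap)
  if (!is.null(alignments)) {
    stopifnot(inherits(alignments, "gene_alignment_set"))
    if (is.null(outgroup) || !(outgroup %in% alignments$taxa)) {
      stop("outgroup must be one of the alignment taxa", call. = FALSE)
    }
    if (length(alignments$taxa) < 4L) {
      stop("at least 4 taxa are required", call. = FALSE)
    }
    ctx$alignments <- alignments
    ctx$n <- alignments$catalog$n
    ctx$catalog <- alignments$catalog
    ## per-gene mismatch/comparable indicators, stacked per word at
    ## evaluation time (avoids rebuilding supermatrices)
    mm <- lapply(alignments$genes, mismatch_matrices)
    ctx$gene_M <- lapply(mm, `[[`, "M")
    ctx$gene_V <- lapply(mm, `[[`, "V")
    ctx$taxa <- mm[[1L]]$taxa
  } else {
    stopifnot(inherits(landscape, "landscape_spec"))
    ctx$n <- landscape$n
    ctx$catalog <- gene_catalog(sprintf("gene%03d", seq_len(landscape$n)))
  }
  state <- new.env(parent = emptyenv())
  state$cache <- new.env(parent = emptyenv())
  state$records <- list()
  state$n_evals <- 0L
  state$cache_hits <- 0L
  ctx$state <- state
  class(ctx) <- "eval_context"
  ctx
}

#' @export
print.eval_context <- function(x, ...) {
  kind <- if (is.null(x$landscape)) "alignment" else "landscape"
  cat("Evaluation context (", kind, "), ", x$n, " genes, ",
      x$state$n_evals, " backend evaluations, ", x$state$cache_hits,
      " cache hits\n", sep = "")
  invisible(x)
}

#' Evaluate a subset word
#'
#' Turns a word into an evaluation record: the backend (NJ bootstrap on the
#' concatenated active genes, or the landscape formula) yields the lowest
#' internal support `b`; `p` and the score follow from the word. The record
#' is cached and appended to the run history on first evaluation; later calls
#' return the cached record without touching the backend.
#'
#' @param ctx an [eval_context].
#' @param word integer 0/1 vector (at least one active gene).
#' @return A list (the evaluation record) with elements `word` (bit string),
#'   `bits`, `b`, `p`, `score`, `topology`, `supports`, `tree` (a
#'   `support_tree` or `NULL` on landscapes), `well_supported`, `ordinal`.
#' @export
evaluate_word <- function(ctx, word) {
  stopifnot(inherits(ctx, "eval_context"))
  word <- assert_word(word, ctx$n)
  if (sum(word) == 0L) {
    stop("cannot evaluate a word with no active gene", call. = FALSE)
  }
  key <- word_to_string(word)
  st <- ctx$state
  if (!is.null(st$cache[[key]])) {
    st$cache_hits <- st$cache_hits + 1L
    return(st$cache[[key]])
  }
  if (is.null(ctx$landscape)) {
    active <- which(word == 1L)
    M <- do.call(rbind, ctx$gene_M[active])
    V <- do.call(rbind, ctx$gene_V[active])
    tr <- with_isolated_rng(
      word_seed(ctx$seed, word),
      nj_bootstrap(M, V, ctx$taxa, reps = ctx$reps, outgroup = ctx$outgroup,
                   cap = ctx$cap)
    )
    fit <- list(b = tr$b, supports = tr$supports, tree = tr,
                topology = topology_key(tr))
    fit$p <- percentage_active(word)
    fit$score <- subset_score(fit$b, fit$p)
  } else {
    fit <- landscape_fitness(ctx$landscape, word)
  }
  rec <- list(word = key, bits = word, b = fit$b, p = fit$p,
              score = fit$score, topology = fit$topology,
              supports = fit$supports, tree = fit$tree,
              well_supported = all(fit$supports > ctx$support_threshold),
              ordinal = st$n_evals + 1L)
  st$n_evals <- st$n_evals + 1L
  st$cache[[key]] <- rec
  st$records[[rec$ordinal]] <- rec
  rec
}

#' Run history of an evaluation context
#'
#' @param ctx an [eval_context].
#' @return An object of class `run_history`: the list of evaluation records
#'   in evaluation order (each distinct word appears exactly once).
#' @export
run_history <- function(ctx) {
  stopifnot(inherits(ctx, "eval_context"))
  structure(ctx$state$records, class = "run_history")
}

#' @export
as.data.frame.run_history <- function(x, ...) {
  data.frame(
    ordinal = vapply(x, `[[`, integer(1), "ordinal"),
    word = vapply(x, `[[`, character(1), "word"),
    b = vapply(x, `[[`, numeric(1), "b"),
    p = vapply(x, `[[`, numeric(1), "p"),
    score = vapply(x, `[[`, numeric(1), "score"),
    topology = vapply(x, `[[`, character(1), "topology"),
    well_supported = vapply(x, `[[`, logical(1), "well_supported"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.run_history <- function(x, ...) {
  cat("Run history:", length(x), "evaluated words\n")
  invisible(x)
}

#' Serialize / read a run history as TSV
#'
#' Columns: ordinal, word bit string, b, p, score (percentages rounded to 2
#' decimals for display), topology key, well_supported flag. Per-branch
#' supports and trees live only in the in-memory records.
#'
#' @param history a `run_history` (or an `eval_context`).
#' @param path output file.
#' @return `write_history()` invisibly returns `path`; `read_history()`
#'   returns a data.frame.
#' @export
write_history <- function(history, path) {
  if (inherits(history, "eval_context")) history <- run_history(history)
  df <- as.data.frame(history)
  df$b <- round(df$b, 2)
  df$p <- round(df$p, 2)
  df$score <- round(df$score, 2)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_history
#' @export
read_history <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(ordinal = "integer", word = "character",
                                   b = "numeric", p = "numeric",
                                   score = "numeric", topology = "character",
                                   well_supported = "logical"))
}
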