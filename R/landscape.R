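#' Pseudo-boolean fitness landscape
#'
#' A deterministic stand-in for the phylogenetic evaluation backend, used to
#' exercise and benchmark the metaheuristics against brute-forceable optima.
#' A set of "bad" genes carries a support penalty: the lowest-bootstrap proxy
#' is `b(word) = max(0, base - penalty * #active bad genes)`, the gene
#' percentage and score follow the usual definitions, and the topology label
#' is synthesized from the activation pattern of the bad genes (so that
#' topology binning has something to bin).
#'
#' @param n number of genes (word length).
#' @param bad integer indices (1-based, in catalogue order) of the penalized
#'   genes.
#' @param penalty support penalty per active bad gene (> 0).
#' @param base support of a word with no active bad gene (default 100).
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(n, bad = integer(0), penalty = 20, base = 100) {
  stopifnot(n >= 1, penalty > 0, base > 0, base <= 100)
  bad <- as.integer(bad)
  if (length(bad) && (any(bad < 1L) || any(bad > n) || anyDuplicated(bad))) {
    stop("bad gene indices must be distinct and within 1..n", call. = FALSE)
  }
  structure(list(n = as.integer(n), bad = sort(bad), penalty = penalty,
                 base = base),
            class = "landscape_spec")
}

#' Evaluate a word on a pseudo-boolean landscape
#'
#' @param spec a [landscape_spec].
#' @param word integer 0/1 vector of length `spec$n`.
#' @return A list with `b`, `p`, `score`, `topology` and `supports` (a single
#'   named pseudo-branch whose support equals `b`). No tree is built.
#' @export
landscape_fitness <- function(spec, word) {
  stopifnot(inherits(spec, "landscape_spec"))
  word <- assert_word(word, spec$n)
  n_bad_active <- if (length(spec$bad)) sum(word[spec$bad]) else 0L
  b <- max(0, spec$base - spec$penalty * n_bad_active)
  p <- percentage_active(word)
  key <- if (length(spec$bad)) {
    paste0("L", paste(word[spec$bad], collapse = ""))
  } else "L"
  list(b = b, p = p, score = subset_score(b, p), topology = key,
       supports = c(landscape = b), tree = NULL)
}

#' Brute-force enumeration of a landscape's optimum
#'
#' Enumerates all `2^n - 1` non-empty words (feasible for `n <= 16`) and
#' returns the best by score, ties broken by larger gene percentage then
#' lexicographic word order.
#'
#' @param spec a [landscape_spec] with `n <= 16`.
#' @return list with `word`, `b`, `p`, `score`.
#' @export
landscape_optimum <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"), spec$n <= 16)
  n <- spec$n
  best <- NULL
  for (code in seq_len(2^n - 1L)) {
    word <- as.integer(intToBits(code)[seq_len(n)])
    fit <- landscape_fitness(spec, word)
    fit$word <- word_to_string(word)
    if (is.null(best) ||
        fit$score > best$score ||
        (fit$score == best$score && fit$p > best$p) ||
        (fit$score == best$score && fit$p == best$p && fit$word < best$word)) {
      best <- fit
    }
  }
  best$bits <- word_from_string(best$word)
  best[c("word", "bits", "b", "p", "score")]
}
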