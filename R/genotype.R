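#' Gene catalogue
#'
#' An ordered, deduplicated set of core-gene names. Genes are sorted in a
#' stable byte-wise (locale-independent) alphabetical order; every subset word
#' in a run is aligned to this order.
#'
#' @param names character vector of gene identifiers (must be unique).
#' @return An object of class `gene_catalog`: a list with `names` (sorted)
#'   and `n` (the catalogue size).
#' @export
gene_catalog <- function(names) {
  if (length(names) < 1L || !is.character(names)) {
    stop("gene catalog requires at least one gene name", call. = FALSE)
  }
  if (anyDuplicated(names)) {
    stop("gene names must be unique", call. = FALSE)
  }
  structure(list(names = sort(names, method = "radix"), n = length(names)),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("Gene catalog of", x$n, "genes:",
      paste(utils::head(x$names, 5L), collapse = ", "),
      if (x$n > 5L) "..." else "", "\n")
  invisible(x)
}

## words are plain integer 0/1 vectors aligned to catalog order
assert_word <- function(word, n = NULL) {
  if (!is.numeric(word) || length(word) < 1L || !all(word %in% c(0L, 1L))) {
    stop("a subset word must be a non-empty vector of 0/1 values", call. = FALSE)
  }
  if (!is.null(n) && length(word) != n) {
    stop("word length ", length(word), " does not match catalog size ", n,
         call. = FALSE)
  }
  invisible(as.integer(word))
}

#' Convert between subset words and 0/1 strings
#'
#' @param word integer 0/1 vector.
#' @return `word_to_string()` returns a character scalar like `"10110"`;
#'   `word_from_string()` its inverse.
#' @export
word_to_string <- function(word) {
  paste(assert_word(word), collapse = "")
}

#' @rdname word_to_string
#' @param s character scalar of 0/1 characters.
#' @export
word_from_string <- function(s) {
  bits <- as.integer(strsplit(s, "", fixed = TRUE)[[1L]])
  assert_word(bits)
}

#' Percentage of active genes in a subset word
#'
#' @param word integer 0/1 vector aligned to the gene catalogue.
#' @return `100 * sum(word) / length(word)`, full precision (round for display).
#' @examples
#' percentage_active(c(rep(1, 121), 0))  # 99.18 when rounded
#' @export
percentage_active <- function(word) {
  word <- assert_word(word)
  100 * sum(word) / length(word)
}

#' Subset score: mean of lowest bootstrap and gene percentage
#'
#' The objective value of a gene subset: the arithmetic mean of `b`, the
#' lowest bootstrap support of the subset's tree, and `p`, the percentage of
#' core genes the subset retains. Both on the 0-100 scale.
#'
#' @param b lowest bootstrap support, in \[0, 100\].
#' @param p percentage of active core genes, in \[0, 100\].
#' @return `(b + p) / 2`.
#' @examples
#' subset_score(96, 99.18)   # 97.59
#' subset_score(100, 96.72)  # 98.36
#' @export
subset_score <- function(b, p) {
  if (!is.numeric(b) || !is.numeric(p) ||
      any(b < 0 | b > 100) || any(p < 0 | p > 100)) {
    stop("b and p must lie in [0, 100]", call. = FALSE)
  }
  (b + p) / 2
}

#' Hamming distance between two subset words
#'
#' @param w1,w2 integer 0/1 vectors of equal length.
#' @return Number of differing positions.
#' @export
hamming_distance <- function(w1, w2) {
  w1 <- assert_word(w1)
  w2 <- assert_word(w2)
  if (length(w1) != length(w2)) {
    stop("words must have equal length", call. = FALSE)
  }
  sum(w1 != w2)
}

## Deterministic ordering of evaluation records: score desc, then p desc
## (the objective prefers the largest subset at equal support), then word
## string as a final lexicographic tie-break.
order_records <- function(records) {
  score <- vapply(records, `[[`, numeric(1), "score")
  p <- vapply(records, `[[`, numeric(1), "p")
  w <- vapply(records, `[[`, character(1), "word")
  order(-score, -p, w, method = "radix")
}

best_record <- function(records) {
  records[[order_records(records)[1L]]]
}

#' Export gene membership of a word as a two-column table
#'
#' @param word integer 0/1 vector.
#' @param catalog a [gene_catalog].
#' @return data.frame with columns `gene` and `included` (0/1).
#' @export
word_membership <- function(word, catalog) {
  word <- assert_word(word, catalog$n)
  data.frame(gene = catalog$names, included = word, stringsAsFactors = FALSE)
}
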