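#' Topology-frequency report of a run history
#'
#' Groups evaluated words by topology key and reports, per topology, the
#' occurrence count and frequency and the best record (by score, ties broken
#' by larger gene percentage then word order).
#'
#' @param history a `run_history`, an `eval_context`, or an optimizer
#'   result.
#' @return data.frame with one row per topology, most frequent first:
#'   `topology`, `n_trees`, `frequency` (fractions summing to 1), `b`, `p`,
#'   `score`, `missing_genes` (count of inactive genes in the best word),
#'   `best_word`.
#' @export
topology_report <- function(history) {
  records <- as_records(history)
  keys <- vapply(records, `[[`, character(1), "topology")
  total <- length(records)
  groups <- split(seq_along(records), keys)
  rows <- lapply(groups, function(idx) {
    best <- best_record(records[idx])
    data.frame(topology = best$topology, n_trees = length(idx),
               frequency = length(idx) / total, b = best$b, p = best$p,
               score = best$score,
               missing_genes = sum(best$bits == 0L),
               best_word = best$word, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_trees, out$topology), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a topology report as TSV
#'
#' Percentages are rounded to 2 decimals for display.
#'
#' @param report data.frame from [topology_report()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  report$frequency <- round(100 * report$frequency, 2)
  report$b <- round(report$b, 2)
  report$p <- round(report$p, 2)
  report$score <- round(report$score, 2)
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' JSON summary of an optimizer result
#'
#' @param result a `ga_result`, `bpso_result` or `sa_result`.
#' @param path output file, or `NULL` to return the list.
#' @return Invisibly the summary list (written as JSON when `path` is
#'   given).
#' @export
result_summary <- function(result, path = NULL) {
  best <- result$best
  out <- list(best_word = best$word, b = best$b, p = round(best$p, 2),
              score = round(best$score, 2), topology = best$topology,
              well_supported = best$well_supported,
              evaluations = length(result$history),
              stop_reason = result$stop_reason %||% NA,
              iterations = result$iterations %||% result$chains_run %||% NA)
  if (!is.null(path)) jsonlite::write_json(out, path, auto_unbox = TRUE)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
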