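as_records <- function(history) {
  if (inherits(history, "eval_context")) history <- run_history(history)
  if (inherits(history, "ga_result") || inherits(history, "bpso_result") ||
      inherits(history, "sa_result")) history <- history$history
  stopifnot(is.list(history), length(history) >= 1L)
  history
}

#' Topologies occurring frequently in a run history
#'
#' @param history a `run_history` (or a context / optimizer result).
#' @param min_freq frequency threshold; topologies whose share of evaluated
#'   trees exceeds it are returned (default 0.10).
#' @return character vector of topology keys, most frequent first.
#' @export
frequent_topologies <- function(history, min_freq = 0.10) {
  records <- as_records(history)
  keys <- vapply(records, `[[`, character(1), "topology")
  tab <- sort(table(keys), decreasing = TRUE)
  freq <- tab / length(keys)
  names(freq)[freq > min_freq]
}

#' Assemble the regression data for one topology and branch
#'
#' Rows are all history words whose tree fell in the given topology; the
#' response is that branch's bootstrap support in each word's tree (0 when a
#' member tree lacks the branch). Gene columns that are constant across the
#' rows are flagged in the `zero_variance` attribute.
#'
#' @param history a `run_history` (or a context / optimizer result).
#' @param topology a topology key from [frequent_topologies()].
#' @param branch a clade label (sorted taxa, comma-separated) naming the
#'   branch whose support is modelled.
#' @param scope which words populate the rows: `"topology"` restricts to the
#'   words whose tree fell in `topology`; `"history"` uses every evaluated
#'   word, reading the branch support by its clade label (0 when the tree
#'   lacks the branch, i.e. a topology change erased it).
#' @return list of class `regression_data`: `W` (m x n 0/1 matrix, columns
#'   named by gene), `Y` (supports), `topology`, `branch`.
#' @export
regression_data <- function(history, topology, branch,
                            scope = c("topology", "history")) {
  scope <- match.arg(scope)
  records <- as_records(history)
  members <- if (scope == "topology") {
    Filter(function(r) identical(r$topology, topology), records)
  } else {
    records
  }
  if (length(members) < 2L) {
    stop("need at least 2 history words in scope", call. = FALSE)
  }
  present <- vapply(members, function(r) branch %in% names(r$supports),
                    logical(1))
  if (!any(present)) {
    stop("branch '", branch, "' absent from every tree of this topology",
         call. = FALSE)
  }
  W <- do.call(rbind, lapply(members, `[[`, "bits"))
  Y <- vapply(members, function(r) {
    if (branch %in% names(r$supports)) unname(r$supports[[branch]]) else 0
  }, numeric(1))
  zv <- apply(W, 2L, function(col) length(unique(col)) == 1L)
  structure(list(W = W, Y = Y, topology = topology, branch = branch,
                 zero_variance = which(zv)),
            class = "regression_data")
}

#' Lasso of branch support on gene-inclusion indicators
#'
#' Minimizes `sum_i (Y_i - sum_j beta_j X_ij)^2 + lambda sum_j |beta_j|`.
#' There is no intercept term; the response and the non-constant columns are
#' centered before fitting, which is equivalent to an unpenalized intercept
#' (raw 0/1 columns against an uncentered response would force spurious
#' positive coefficients). The sign of `beta_j` tells whether including gene
#' `j` raises or lowers the branch support.
#'
#' @param data a [regression_data] (or any list with `W` and `Y`).
#' @param lambda penalty weight on the scale of the objective above;
#'   `NULL` selects it by cross-validation over a logarithmic grid (the
#'   consumed sign pattern is insensitive across a wide lambda range).
#' @return list of class `lasso_fit`: `beta` (named by gene when `W` has
#'   column names, else `g1..gn`), `lambda` (the penalty used, objective
#'   scale).
#' @export
lasso_fit <- function(data, lambda = NULL) {
  W <- as.matrix(data$W)
  Y <- as.numeric(data$Y)
  m <- nrow(W)
  stopifnot(m >= 2L, length(Y) == m, is.null(lambda) || lambda >= 0)
  gene_names <- colnames(W)
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(ncol(W)))
  Wc <- scale(W, center = TRUE, scale = FALSE)
  Yc <- Y - mean(Y)
  keep <- apply(Wc, 2L, function(col) any(col != 0))
  if (!any(keep)) stop("all gene columns are constant", call. = FALSE)
  if (all(Yc == 0)) {   # constant response: the penalized optimum is 0
    beta <- stats::setNames(numeric(length(gene_names)), gene_names)
    return(structure(list(beta = beta,
                          lambda = if (is.null(lambda)) 0 else lambda,
                          zero_variance = which(!keep)),
                     class = "lasso_fit"))
  }
  X <- Wc[, keep, drop = FALSE]
  padded <- FALSE
  if (ncol(X) == 1L) {              # glmnet requires >= 2 columns
    X <- cbind(X, 0)
    padded <- TRUE
  }
  ## glmnet objective is (1/(2m)) RSS + lambda_g * L1, so the penalty above
  ## maps to lambda_g = lambda / (2m)
  if (is.null(lambda)) {
    nfolds <- max(3L, min(10L, m))
    cv <- glmnet::cv.glmnet(X, Yc, intercept = FALSE, standardize = FALSE,
                            nfolds = nfolds, thresh = 1e-12)
    lambda_g <- cv$lambda.min
    lambda <- lambda_g * 2 * m
    fit <- cv$glmnet.fit
  } else {
    lambda_g <- lambda / (2 * m)
    lam0 <- max(abs(crossprod(X, Yc))) / m
    path <- unique(sort(c(exp(seq(log(max(lam0, lambda_g * 10, 1e-3)),
                                  log(max(lambda_g, 1e-10)),
                                  length.out = 50)), lambda_g),
                        decreasing = TRUE))
    fit <- glmnet::glmnet(X, Yc, intercept = FALSE, standardize = FALSE,
                          lambda = path, thresh = 1e-12)
  }
  coefs <- as.numeric(fit$beta[, which.min(abs(fit$lambda - lambda_g))])
  if (padded) coefs <- coefs[1L]
  beta <- numeric(length(gene_names))
  beta[keep] <- coefs
  names(beta) <- gene_names
  structure(list(beta = beta, lambda = lambda,
                 zero_variance = which(!keep)),
            class = "lasso_fit")
}

#' Genes whose inclusion lowers the branch support
#'
#' @param fit a [lasso_fit].
#' @return character vector of gene names with a strictly negative
#'   coefficient.
#' @export
problematic_genes <- function(fit) {
  stopifnot(inherits(fit, "lasso_fit"))
  names(fit$beta)[fit$beta < 0]
}

#' Lasso attribution report over a run history
#'
#' For every frequent topology, takes the best word's tree, finds its
#' problematic branches (internal supports below the well-supported
#' threshold), fits the support-on-genes Lasso over that topology's words
#' for each such branch, and collects the negative-coefficient genes.
#'
#' @param history a `run_history` (or a context / optimizer result).
#' @param catalog the [gene_catalog] naming the word positions.
#' @param min_freq topology frequency threshold.
#' @param threshold well-supported threshold on branch supports.
#' @param lambda fixed penalty, or `NULL` for cross-validation.
#' @param scope row population of each regression, see [regression_data()].
#' @return list with `table` (one row per topology x branch: topology,
#'   frequency, branch, flagged genes), `fits` (the `lasso_fit` objects) and
#'   `flagged` (the union of problematic gene names).
#' @export
lasso_report <- function(history, catalog, min_freq = 0.10, threshold = 95,
                         lambda = NULL, scope = c("history", "topology")) {
  scope <- match.arg(scope)
  records <- as_records(history)
  topo <- vapply(records, `[[`, character(1), "topology")
  rows <- list()
  fits <- list()
  flagged <- character(0)
  for (key in frequent_topologies(records, min_freq)) {
    members <- records[topo == key]
    best <- best_record(members)
    bad_branches <- names(best$supports)[best$supports < threshold]
    for (branch in bad_branches) {
      data <- regression_data(records, key, branch, scope = scope)
      colnames(data$W) <- catalog$names
      fit <- lasso_fit(data, lambda = lambda)
      genes <- problematic_genes(fit)
      flagged <- union(flagged, genes)
      fits[[paste(key, branch, sep = "::")]] <- fit
      rows[[length(rows) + 1L]] <- data.frame(
        topology = key, frequency = mean(topo == key), branch = branch,
        flagged = paste(genes, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  list(table = if (length(rows)) do.call(rbind, rows) else
         data.frame(topology = character(0), frequency = numeric(0),
                    branch = character(0), flagged = character(0)),
       fits = fits, flagged = flagged)
}

#' Hybrid refinement: prune Lasso-flagged genes and relaunch the GA
#'
#' Bins the GA history by topology, fits the support-on-genes Lasso for
#' every frequent topology's problematic branches, removes the union of
#' negative-coefficient genes (their bits are frozen at 0), re-evaluates the
#' retained population and relaunches the GA main loop with unchanged stop
#' rules. With no frequent problematic branch the refinement is a plain GA
#' continuation.
#'
#' @param result a `ga_result`.
#' @param cfg a [ga_config] for the relaunched phase.
#' @param seed seed for the relaunch.
#' @param min_freq,threshold,lambda,scope passed to [lasso_report()].
#' @return A `ga_result` whose `refinement` element holds the report and
#'   pruned genes.
#' @export
hybrid_refine <- function(result, cfg = ga_config(), seed = 1L,
                          min_freq = 0.10, threshold = 95, lambda = NULL,
                          scope = c("history", "topology")) {
  stopifnot(inherits(result, "ga_result"))
  ctx <- result$ctx
  report <- lasso_report(result$history, ctx$catalog, min_freq = min_freq,
                         threshold = threshold, lambda = lambda,
                         scope = scope)
  frozen <- match(report$flagged, ctx$catalog$names)
  population <- result$population
  if (length(frozen)) {
    words <- unique(lapply(population, function(r) {
      w <- r$bits
      w[frozen] <- 0L
      w
    }))
    population <- lapply(Filter(function(w) sum(w) > 0L, words),
                         function(w) evaluate_word(ctx, w))
    population <- population[order_records(population)]
  }
  refined <- run_ga(ctx, cfg, seed = seed, population = population,
                    frozen_zero = frozen)
  ## the run's overall best (the shared history spans both phases), so
  ## refinement never loses the pre-refinement optimum
  refined$best <- best_record(refined$history)
  refined$refinement <- list(report = report, pruned = report$flagged)
  refined
}
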