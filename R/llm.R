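#' Binary TF-occupancy matrix from motif hits
#'
#' A TF occupies a promoter when the promoter carries at least one hit of
#' any TFBS that the TF is known to bind.
#'
#' @param hits [motif_hits][as_motif_hits] table.
#' @param binding Binding map (list `tfbs_id` -> TF ids).
#' @param genes Promoter/gene universe for the rows (default: genes in hits).
#' @return Binary integer matrix, promoters x TFs, with dimnames.
#' @export
occupancy_from_hits <- function(hits, binding, genes = NULL) {
  check_binding_coverage(hits, binding)
  if (is.null(genes)) genes <- sort(unique(hits$gene_id))
  pairs <- unique(hits[, c("gene_id", "tfbs_id")])
  tf_per_row <- binding[pairs$tfbs_id]
  gene_rep <- rep(pairs$gene_id, lengths(tf_per_row))
  tf_rep <- unlist(tf_per_row, use.names = FALSE)
  tfs <- sort(unique(unlist(binding, use.names = FALSE)))
  occ <- matrix(0L, length(genes), length(tfs), dimnames = list(genes, tfs))
  keep <- gene_rep %in% genes
  occ[cbind(match(gene_rep[keep], genes), match(tf_rep[keep], tfs))] <- 1L
  occ
}

#' Cross-classify binary TF columns into a 2^k contingency table
#'
#' @param occ Binary matrix (promoters x TFs) with column names.
#' @param tf_subset Character or integer vector of k columns (k <= 12).
#' @return Object of class `contingency_table`: list with `counts` (length
#'   2^k; cell index = 1 + sum over variables v in state 1 of 2^(v-1)),
#'   `vars` (the k column names) and `n`.
#' @export
tabulate_occupancy <- function(occ, tf_subset = colnames(occ)) {
  sub <- occ[, tf_subset, drop = FALSE]
  if (!all(sub %in% c(0L, 1L))) stop("occupancy matrix must be binary")
  k <- ncol(sub)
  if (k < 1L || k > 12L) stop("k must be in 1..12")
  idx <- as.integer(sub %*% 2^(seq_len(k) - 1L)) + 1L
  counts <- tabulate(idx, nbins = 2L^k)
  structure(list(counts = as.numeric(counts),
                 vars = colnames(sub), n = nrow(sub)),
            class = "contingency_table")
}

#' Fit a hierarchical log-linear model by iterative proportional fitting
#'
#' Fits the hierarchical log-linear model over the table's variables defined
#' by an edge set. With `generator = "cliques"` (the default) the generating
#' class is the set of maximal cliques of the graph — a graphical model, so
#' the complete graph is the saturated model. With `generator = "pairwise"`
#' the generating class is the edges themselves plus isolated singletons —
#' the all-two-factor hierarchy used by [backward_select()]. Fitting is by
#' IPF from an independence start until the largest absolute gap between
#' observed and fitted generator margins is below `tol`. The deviance is
#' `G2 = 2 * sum n * log(n / mhat)` with `0 * log 0 := 0`; degrees of
#' freedom are the saturated parameter count minus the model's (one
#' parameter per subset of a generator, variables being binary).
#'
#' @param table A `contingency_table` from [tabulate_occupancy()].
#' @param edges Two-column matrix of edges, as integer indices into
#'   `table$vars` or as variable names. Zero rows give the complete
#'   independence model.
#' @param generator `"cliques"` (graphical model) or `"pairwise"`
#'   (all-two-factor hierarchy).
#' @param tol IPF convergence tolerance on margin gaps (default 1e-3; loose
#'   enough for dense non-decomposable generators on sparse tables, while
#'   decomposable fits converge to machine precision regardless).
#' @param maxit Sweep cap (default 1000); non-convergence is an error
#'   carrying the residual margin gap.
#' @return Object of class `loglinear_fit`: list with `vars`, `edges`
#'   (integer matrix), `fitted`, `G2`, `df`, `n_params`, `iterations`.
#' @export
ipf_fit <- function(table, edges, generator = c("cliques", "pairwise"),
                    tol = 1e-3, maxit = 1000) {
  stopifnot(inherits(table, "contingency_table"))
  generator <- match.arg(generator)
  k <- length(table$vars)
  edges <- .as_edge_matrix(edges, table$vars)
  res <- .cpp_ipf_fit(table$counts, k, edges, tol, as.integer(maxit),
                      generator == "pairwise")
  if (!res$converged)
    stop(sprintf("IPF did not converge in %d sweeps (max margin gap %.3g)",
                 maxit, res$max_gap))
  structure(list(vars = table$vars, edges = edges, fitted = res$fitted,
                 G2 = res$G2, df = res$df, n_params = res$n_params,
                 iterations = res$iterations, generator = generator),
            class = "loglinear_fit")
}

.as_edge_matrix <- function(edges, vars) {
  if (is.null(edges) || length(edges) == 0L)
    return(matrix(integer(0), 0L, 2L))
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (!is.matrix(edges)) edges <- matrix(edges, ncol = 2L, byrow = TRUE)
  if (is.character(edges)) {
    m <- matrix(match(edges, vars), ncol = 2L)
    if (anyNA(m)) stop("edge references unknown variable")
    edges <- m
  }
  storage.mode(edges) <- "integer"
  edges
}

#' All unordered pairs of k variables as an edge matrix
#' @param k Number of variables.
#' @return Integer matrix with choose(k, 2) rows.
#' @export
all_pairs <- function(k) {
  if (k < 2L) return(matrix(integer(0), 0L, 2L))
  t(utils::combn(k, 2L))
}

#' Backward elimination of pairwise interaction terms
#'
#' Starts from the full model FM containing every two-factor interaction
#' (the all-pairwise hierarchy) and repeatedly tests the removal of each
#' remaining edge: `p_RM` is the chi-squared p-value of the deviance
#' increase of the reduced model RM against the current model (a 1-df
#' likelihood-ratio test between smooth models, which stays calibrated on
#' sparse tables), and `p_FM` is the chi-squared p-value of the deviance
#' difference between FM and RM. The removal with the largest `p_RM` among
#' candidates with both p-values above `alpha` is accepted; elimination
#' stops when no candidate qualifies. The retained edge set is the inferred
#' interaction graph.
#'
#' @inheritParams ipf_fit
#' @param alpha Significance level gating removals (default 0.05).
#' @return The final `loglinear_fit` (pairwise generator), with `fm_G2`,
#'   `fm_df` of the full model and the elimination trace (step, removed
#'   edge, p_RM, p_FM) in `$trace`.
#' @export
backward_select <- function(table, alpha = 0.05, tol = 1e-3, maxit = 1000) {
  stopifnot(inherits(table, "contingency_table"))
  k <- length(table$vars)
  res <- .cpp_backward_select(table$counts, k, alpha, tol,
                              as.integer(maxit))
  trace <- data.frame(step = seq_along(res$trace_a),
                      var_a = table$vars[res$trace_a],
                      var_b = table$vars[res$trace_b],
                      p_RM = res$trace_p_rm, p_FM = res$trace_p_fm,
                      stringsAsFactors = FALSE)
  structure(list(vars = table$vars, edges = res$edges, fitted = res$fitted,
                 G2 = res$G2, df = res$df, n_params = res$n_params,
                 fm_G2 = res$fm_G2, fm_df = res$fm_df,
                 generator = "pairwise", trace = trace),
            class = "loglinear_fit")
}

#' Edges of a log-linear fit as variable-name pairs
#' @param fit `loglinear_fit`.
#' @return Character matrix with columns `var_a`, `var_b` (0 rows when the
#'   model has no interactions).
#' @export
fit_edges <- function(fit) {
  stopifnot(inherits(fit, "loglinear_fit"))
  m <- cbind(var_a = fit$vars[fit$edges[, 1]],
             var_b = fit$vars[fit$edges[, 2]])
  if (nrow(fit$edges) == 0L)
    m <- matrix(character(0), 0L, 2L, dimnames = list(NULL, c("var_a", "var_b")))
  m
}
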