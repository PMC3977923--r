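#' Iterative random-sampling estimation of TF-TF interaction probabilities
#'
#' The number of TFs makes a single log-linear model over all of them
#' intractable, so interaction evidence is accumulated by sampling: each
#' iteration draws k TFs without replacement, counts a trial `t` for every
#' pair among them, runs [backward_select()] on their 2^k contingency table,
#' and counts an edge observation `f` for every pair whose interaction
#' survived elimination. The interaction probability of a pair is
#' `Pr = f / t`, the fraction of completed fits in which its edge was
#' retained. Sampling stops when the thresholded edge set
#' `{pairs : Pr >= pr_threshold}` has not changed for `stop_window`
#' consecutive iterations, or at `max_iter`.
#'
#' Failed fits (e.g. IPF non-convergence) do not count as trials: the
#' iteration is skipped, logged in `n_failed`, and the trial increments are
#' rolled back so `Pr` remains an edge frequency over completed fits.
#'
#' @param occ Binary occupancy matrix (promoters x TFs, named columns).
#' @param k Subset size per iteration (default 10).
#' @param alpha Significance level for edge elimination (default 0.05).
#' @param pr_threshold Pr cutoff defining the watched edge set (default 0.5).
#' @param stop_window Consecutive unchanged iterations required to stop
#'   (default 10000).
#' @param max_iter Hard iteration cap (default 2e6).
#' @param min_trials Minimum trials for [threshold_edges()] (default 30).
#' @param seed Integer seed; the whole run is deterministic given it.
#' @param tol,maxit IPF settings, see [ipf_fit()].
#' @return Object of class `interaction_graph`: list with `tfs`, symmetric
#'   matrices `t` and `f`, `Pr` (= f/t, 0 where t = 0), `iterations`,
#'   `converged`, `n_failed` and the settings used.
#' @export
run_sampling <- function(occ, k = 10, alpha = 0.05, pr_threshold = 0.5,
                         stop_window = 10000, max_iter = 2e6,
                         min_trials = 30, seed = 1, tol = 1e-3,
                         maxit = 1000) {
  m <- ncol(occ)
  if (k > m) stop("k (", k, ") exceeds the number of TFs (", m, ")")
  tfs <- colnames(occ)
  if (is.null(tfs)) stop("occupancy matrix needs column names")
  t_mat <- f_mat <- matrix(0, m, m, dimnames = list(tfs, tfs))
  pos_pairs <- utils::combn(k, 2L)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  prev_key <- ""
  unchanged <- 0L
  n_failed <- 0L
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    idx <- sort(sample.int(m, k))
    fit <- tryCatch(
      backward_select(tabulate_occupancy(occ, idx), alpha = alpha,
                      tol = tol, maxit = maxit),
      error = function(e) NULL)
    if (is.null(fit)) {            # trial rolled back: nothing was counted
      n_failed <- n_failed + 1L
      next
    }
    a <- idx[pos_pairs[1L, ]]
    b <- idx[pos_pairs[2L, ]]
    t_mat[cbind(a, b)] <- t_mat[cbind(a, b)] + 1
    if (nrow(fit$edges) > 0L) {
      ea <- idx[fit$edges[, 1L]]
      eb <- idx[fit$edges[, 2L]]
      swap <- ea > eb
      tmp <- ea[swap]; ea[swap] <- eb[swap]; eb[swap] <- tmp
      f_mat[cbind(ea, eb)] <- f_mat[cbind(ea, eb)] + 1
    }
    up <- upper.tri(t_mat)
    pr <- ifelse(t_mat[up] > 0, f_mat[up] / t_mat[up], 0)
    key <- paste(which(pr >= pr_threshold), collapse = ",")
    if (identical(key, prev_key)) {
      unchanged <- unchanged + 1L
      if (unchanged >= stop_window) { converged <- TRUE; break }
    } else {
      unchanged <- 0L
      prev_key <- key
    }
  }
  t_sym <- t_mat + t(t_mat)
  f_sym <- f_mat + t(f_mat)
  pr_sym <- ifelse(t_sym > 0, f_sym / t_sym, 0)
  structure(list(tfs = tfs, t = t_sym, f = f_sym, Pr = pr_sym,
                 iterations = iter, converged = converged,
                 n_failed = n_failed, k = k, alpha = alpha,
                 pr_threshold = pr_threshold, min_trials = min_trials,
                 stop_window = stop_window, seed = seed),
            class = "interaction_graph")
}

#' All-pairs table of an interaction graph
#'
#' @param graph `interaction_graph` from [run_sampling()].
#' @return data.frame `tf_a, tf_b, t, f, Pr` over all unordered TF pairs.
#' @export
interaction_table <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  m <- length(graph$tfs)
  up <- which(upper.tri(graph$t), arr.ind = TRUE)
  data.frame(tf_a = graph$tfs[up[, 1]], tf_b = graph$tfs[up[, 2]],
             t = graph$t[up], f = graph$f[up], Pr = graph$Pr[up],
             stringsAsFactors = FALSE)
}

#' Retrieve the thresholded TF-TF interaction list
#'
#' Pairs with at least `min_trials` completed trials and `Pr >=
#' pr_threshold`, sorted by decreasing Pr (ties by pair name).
#'
#' @param graph `interaction_graph`.
#' @param pr_threshold Pr cutoff (default: the run's setting).
#' @param min_trials Trial floor excluding never/rarely co-sampled pairs
#'   (default: the run's setting).
#' @return data.frame `tf_a, tf_b, t, f, Pr`.
#' @export
threshold_edges <- function(graph, pr_threshold = NULL, min_trials = NULL) {
  if (is.null(pr_threshold)) pr_threshold <- graph$pr_threshold
  if (is.null(min_trials)) min_trials <- graph$min_trials
  tab <- interaction_table(graph)
  tab <- tab[tab$t >= min_trials & tab$Pr >= pr_threshold, , drop = FALSE]
  ord <- order(-tab$Pr, tab$tf_a, tab$tf_b)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
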