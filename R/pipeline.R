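#' Run the full promoter-modeling workflow
#'
#' Chains every stage for the four (DEG class x condition) models: gene
#' classification, per-class location weights, TF expression weights, TF-TF
#' interaction sampling (V-family schemes), TGAS computation, the 100-seed
#' regression ensemble per condition, TFBS activity tests, between-condition
#' activity changes, and TF-gene network assembly.
#'
#' The response is `log2(FPKM + 1)` by default; raw-FPKM regression is
#' available via `transform = "identity"`. All stage seeds are derived from
#' `seed`, so two runs with identical inputs and settings produce
#' byte-identical outputs regardless of `n_threads`.
#'
#' @param expr [expression_table][as_expression_table] with two conditions.
#' @param hits [motif_hits][as_motif_hits] table over the gene universe.
#' @param binding Binding map covering every TFBS in `hits`.
#' @param scheme TGAS scheme (default `"V"`).
#' @param fc_threshold,expr_threshold Classification thresholds (2 and 1).
#' @param alpha Significance level used throughout (default 0.05,
#'   uncorrected; Bonferroni columns are reported alongside).
#' @param half_window,bin_size Promoter window and histogram bin (bp).
#' @param n_rand_draws Randomizations per positional histogram (default 100).
#' @param k,pr_threshold,min_trials,stop_window,sampling_max_iter Interaction
#'   sampling settings (see [run_sampling()]); `sampling_max_iter` defaults
#'   to 500 here to keep pipeline runs desk-scale — raise it (with
#'   `stop_window`) for production-size runs.
#' @param n_runs,n_folds Regression ensemble settings (100 and 5).
#' @param transform Response transform, `"log2p1"` or `"identity"`.
#' @param exclude TFBS exclusion list (scheme V3).
#' @param seed Master seed.
#' @param n_threads Workers for the regression runs.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @param graph Optional precomputed `interaction_graph` per class (named
#'   list `A`/`B`); when supplied, sampling is skipped. Required if a
#'   V-family scheme is requested with `sampling_max_iter = 0`.
#' @return Nested list: `classes`, and per DEG class a list with `tgas`,
#'   `graph`, `ensembles` (per condition), `activity` (per condition),
#'   `changes`, `networks` (per condition), `summary`.
#' @export
run_pipeline <- function(expr, hits, binding, scheme = "V",
                         fc_threshold = 2, expr_threshold = 1, alpha = 0.05,
                         half_window = NULL, bin_size = 500,
                         n_rand_draws = 100, k = 10, pr_threshold = 0.5,
                         min_trials = 30, stop_window = 100,
                         sampling_max_iter = 500, n_runs = 100, n_folds = 5,
                         transform = c("log2p1", "identity"), exclude = NULL,
                         seed = 1, n_threads = 1, out_dir = NULL,
                         graph = NULL) {
  transform <- match.arg(transform)
  cond <- attr(expr, "conditions")
  stopifnot(length(cond) == 2L)
  if (is.null(half_window)) half_window <- attr(hits, "half_window")
  check_binding_coverage(hits, binding)

  classes <- assign_classes(expr, fc_threshold = fc_threshold,
                            expr_threshold = expr_threshold)
  all_tfs <- sort(unique(unlist(binding, use.names = FALSE)))
  weights <- tf_weight(expr, all_tfs, expr_threshold = expr_threshold)
  needs_graph <- scheme %in% c("V", "V1", "V2", "V3")
  mask <- switch(scheme,
    V1 = weights$tf_gene_id[weights$flag == "undetected"],
    V2 = {
      d_genes <- classes$gene_id[classes$class == "D"]
      intersect(all_tfs, d_genes)
    },
    NULL)

  tf_y <- function(f) if (transform == "log2p1") log2(f + 1) else f

  result <- list(classes = classes, scheme = scheme, models = list())
  for (K in c("A", "B")) {
    genes_K <- classes$gene_id[classes$class == K]
    hits_K <- hits[hits$gene_id %in% genes_K, , drop = FALSE]
    attr(hits_K, "half_window") <- half_window
    if (length(genes_K) < 2L * n_folds || nrow(hits_K) == 0L) {
      message("class ", K, " too small to model; skipped")
      next
    }
    hits_K <- location_weights_for_hits(hits_K, half_window = half_window,
                                        bin_size = bin_size,
                                        n_rand_draws = n_rand_draws,
                                        seed = seed + 100L * match(K, c("A", "B")))
    g_K <- NULL
    if (needs_graph) {
      g_K <- if (!is.null(graph)) graph[[K]] else NULL
      if (is.null(g_K)) {
        if (sampling_max_iter <= 0)
          stop("scheme ", scheme, " needs an interaction graph: supply ",
               "`graph` or a positive `sampling_max_iter`")
        occ_K <- occupancy_from_hits(hits_K, binding, genes = genes_K)
        occ_K <- occ_K[, colSums(occ_K) > 0 & colSums(occ_K) < nrow(occ_K),
                       drop = FALSE]
        g_K <- run_sampling(occ_K, k = min(k, ncol(occ_K)), alpha = alpha,
                            pr_threshold = pr_threshold,
                            stop_window = stop_window,
                            max_iter = sampling_max_iter,
                            min_trials = min_trials,
                            seed = seed + 200L + match(K, c("A", "B")))
      }
    }
    X <- compute_tgas(scheme, hits_K, weights = weights, binding = binding,
                      graph = if (needs_graph) interaction_table(g_K),
                      genes = genes_K, mask = mask, exclude = exclude)
    ens <- acts <- nets <- list()
    for (ci in 1:2) {
      y <- tf_y(expr[[cond[ci]]][match(genes_K, expr$gene_id)])
      ens[[cond[ci]]] <- run_ensemble(X, y, n_runs = n_runs,
                                      base_seed = seed + 1000L * ci +
                                        10000L * match(K, c("A", "B")),
                                      n_folds = n_folds,
                                      n_threads = n_threads)
      acts[[cond[ci]]] <- activity_tests(ens[[cond[ci]]], alpha = alpha)
      nets[[cond[ci]]] <- build_network(acts[[cond[ci]]], hits_K, binding,
                                        classes = classes)
    }
    changes <- activity_changes(ens[[cond[1]]], ens[[cond[2]]],
                                alpha = alpha)
    summ <- do.call(rbind, lapply(cond, function(cc)
      cbind(class = K, cell = cc, scheme = scheme,
            ens[[cc]]$summary)))
    result$models[[K]] <- list(tgas = X, graph = g_K, ensembles = ens,
                               activity = acts, changes = changes,
                               networks = nets, summary = summ)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(classes, file.path(out_dir, "classes.tsv"))
    for (K in names(result$models)) {
      mod <- result$models[[K]]
      write_tgas(mod$tgas, file.path(out_dir, sprintf("tgas_%s_%s.tsv",
                                                      scheme, K)))
      if (!is.null(mod$graph))
        write_interaction_graph(mod$graph,
                                file.path(out_dir,
                                          sprintf("interactions_%s.tsv", K)))
      for (cc in cond) {
        write_tsv(mod$activity[[cc]],
                  file.path(out_dir, sprintf("activity_%s_%s.tsv", K, cc)))
        write_tsv(mod$networks[[cc]],
                  file.path(out_dir, sprintf("network_%s_%s.tsv", K, cc)))
        write_sif(mod$networks[[cc]],
                  file.path(out_dir, sprintf("network_%s_%s.sif", K, cc)))
        write_tsv(rc_table(mod$ensembles[[cc]]),
                  file.path(out_dir, sprintf("rc_ensembles_%s_%s.tsv", K, cc)))
      }
      if (!is.null(mod$changes))
        write_tsv(mod$changes, file.path(out_dir,
                                         sprintf("changes_%s.tsv", K)))
      write_tsv(mod$summary, file.path(out_dir,
                                       sprintf("summary_%s.tsv", K)))
    }
    write_manifest(list(
      scheme = scheme, conditions = cond, fc_threshold = fc_threshold,
      expr_threshold = expr_threshold, alpha = alpha,
      half_window = half_window, bin_size = bin_size,
      n_rand_draws = n_rand_draws, k = k, pr_threshold = pr_threshold,
      min_trials = min_trials, stop_window = stop_window,
      sampling_max_iter = sampling_max_iter, n_runs = n_runs,
      n_folds = n_folds, transform = transform, seed = seed),
      file.path(out_dir, "manifest.json"))
  }
  result
}
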