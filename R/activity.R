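#' One-sample t-test of a TFBS's RC ensemble against zero
#'
#' Tests whether the mean regression coefficient of a TFBS across repeated
#' runs differs from zero. Ensembles with fewer than 2 values or zero sample
#' variance are flagged degenerate and never significant.
#'
#' @param rc Numeric vector of regression coefficients for one TFBS.
#' @param alpha Significance level (default 0.05, uncorrected).
#' @return One-row data.frame: `n, mean_rc, t, p, sign, significant,
#'   degenerate`.
#' @export
one_sample_test <- function(rc, alpha = 0.05) {
  n <- length(rc)
  m <- if (n) mean(rc) else NA_real_
  if (n < 2L || stats::sd(rc) == 0) {
    return(data.frame(n = n, mean_rc = m, t = NA_real_, p = NA_real_,
                      sign = if (isTRUE(m < 0)) "negative" else "positive",
                      significant = FALSE, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  tt <- stats::t.test(rc, mu = 0)
  data.frame(n = n, mean_rc = m, t = unname(tt$statistic),
             p = tt$p.value,
             sign = if (m < 0) "negative" else "positive",
             significant = tt$p.value < alpha, degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Test all RC ensembles of a model for significant TFBS activity
#'
#' @param ens `rc_ensemble_set` from [run_ensemble()] (or a named list of
#'   numeric RC vectors). Empty ensembles are excluded.
#' @param alpha Significance level (default 0.05).
#' @return data.frame with one row per tested TFBS: `tfbs_id, n, mean_rc, t,
#'   p, p_bonferroni, sign, significant, degenerate`. `p_bonferroni` caps
#'   `p * m` at 1, with m the number of tests.
#' @export
activity_tests <- function(ens, alpha = 0.05) {
  e <- if (inherits(ens, "rc_ensemble_set")) ens$ensembles else ens
  e <- e[lengths(e) > 0]
  rows <- lapply(names(e), function(j)
    cbind(tfbs_id = j, one_sample_test(e[[j]], alpha = alpha)))
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni(out$p)
  out[, c("tfbs_id", "n", "mean_rc", "t", "p", "p_bonferroni", "sign",
          "significant", "degenerate")]
}

#' Welch two-sample t-test of a TFBS's activity change between conditions
#'
#' Compares the RC ensembles of the same TFBS in two conditions and
#' classifies the change: `unchanged` when not significant; otherwise
#' `sign-flip` when the two means have opposite signs, `gain` when the
#' absolute mean activity increased from condition 1 to 2, `loss` when it
#' decreased. `strength_increased` is `|mean2| > |mean1|`.
#'
#' @param rc1,rc2 RC ensembles in condition 1 and 2 (each n >= 2 with
#'   positive variance, else degenerate).
#' @param alpha Significance level (default 0.05).
#' @return One-row data.frame: `mean1, mean2, t, p, classification,
#'   strength_increased, degenerate`.
#' @export
two_sample_test <- function(rc1, rc2, alpha = 0.05) {
  m1 <- mean(rc1); m2 <- mean(rc2)
  degenerate <- length(rc1) < 2L || length(rc2) < 2L ||
    (stats::sd(rc1) == 0 && stats::sd(rc2) == 0)
  if (degenerate) {
    return(data.frame(mean1 = m1, mean2 = m2, t = NA_real_, p = NA_real_,
                      classification = "unchanged",
                      strength_increased = abs(m2) > abs(m1),
                      degenerate = TRUE, stringsAsFactors = FALSE))
  }
  if (identical(rc1, rc2)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(rc1, rc2, var.equal = FALSE)
  }
  sig <- tt$p.value < alpha
  classification <- if (!sig) "unchanged"
    else if (sign(m1) != sign(m2)) "sign-flip"
    else if (abs(m2) > abs(m1)) "gain"
    else "loss"
  data.frame(mean1 = m1, mean2 = m2, t = unname(tt$statistic),
             p = tt$p.value, classification = classification,
             strength_increased = abs(m2) > abs(m1), degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Activity changes for all TFBSs shared by two models
#'
#' @param ens1,ens2 `rc_ensemble_set`s for the two conditions.
#' @param alpha Significance level (default 0.05).
#' @return data.frame keyed by `tfbs_id` with the [two_sample_test()]
#'   columns plus `p_bonferroni`.
#' @export
activity_changes <- function(ens1, ens2, alpha = 0.05) {
  e1 <- if (inherits(ens1, "rc_ensemble_set")) ens1$ensembles else ens1
  e2 <- if (inherits(ens2, "rc_ensemble_set")) ens2$ensembles else ens2
  shared <- intersect(names(e1)[lengths(e1) > 0], names(e2)[lengths(e2) > 0])
  rows <- lapply(shared, function(j)
    cbind(tfbs_id = j, two_sample_test(e1[[j]], e2[[j]], alpha = alpha)))
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$p_bonferroni <- bonferroni(out$p)
  out
}

#' Bonferroni adjustment
#'
#' `p * m` capped at 1, order preserved; NAs pass through.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param m Number of tests (default `length(p)` counting non-NA entries).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = sum(!is.na(p))) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- p
  out[ok] <- pmin(1, p[ok] * m)
  out
}

#' Assemble a TF-gene network from significant TFBSs
#'
#' For every significant TFBS j, an edge (tf, gene, tfbs) is created for
#' each gene whose promoter carries at least one hit of j and each TF known
#' to bind j. Edges are deduplicated on (tf, gene, tfbs). Gene class labels
#' annotate the targets when provided.
#'
#' @param sig data.frame from [activity_tests()] (rows with
#'   `significant == TRUE` are used), or a character vector of TFBS ids.
#' @param hits [motif_hits][as_motif_hits] table.
#' @param binding Binding map.
#' @param classes Optional [assign_classes()] output for target annotation.
#' @return data.frame `tf_gene_id, target_gene_id, tfbs_id` (+
#'   `target_class` when classes are given), of class `tf_gene_network`.
#' @export
build_network <- function(sig, hits, binding, classes = NULL) {
  sig_ids <- if (is.character(sig)) sig else sig$tfbs_id[sig$significant]
  pairs <- unique(hits[hits$tfbs_id %in% sig_ids, c("gene_id", "tfbs_id")])
  if (nrow(pairs) == 0L) {
    out <- data.frame(tf_gene_id = character(0),
                      target_gene_id = character(0),
                      tfbs_id = character(0), stringsAsFactors = FALSE)
  } else {
    tf_per_row <- binding[pairs$tfbs_id]
    out <- data.frame(
      tf_gene_id = unlist(tf_per_row, use.names = FALSE),
      target_gene_id = rep(pairs$gene_id, lengths(tf_per_row)),
      tfbs_id = rep(pairs$tfbs_id, lengths(tf_per_row)),
      stringsAsFactors = FALSE)
    out <- unique(out)
    out <- out[order(out$tf_gene_id, out$target_gene_id, out$tfbs_id), ]
    rownames(out) <- NULL
  }
  if (!is.null(classes))
    out$target_class <- classes$class[match(out$target_gene_id,
                                            classes$gene_id)]
  class(out) <- c("tf_gene_network", "data.frame")
  out
}

#' Write a network as a SIF-style file
#'
#' One line per edge: `tf<TAB>binds<TAB>target`, with the TFBS appended as a
#' fourth column.
#'
#' @param network `tf_gene_network` from [build_network()].
#' @param path Output file.
#' @export
write_sif <- function(network, path) {
  df <- data.frame(source = network$tf_gene_id, interaction = "binds",
                   target = network$target_gene_id,
                   tfbs_id = network$tfbs_id, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
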