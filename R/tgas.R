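#' Expression-change weight F for transcription factors
#'
#' For each TF gene, F is the fold-change magnitude of its own expression
#' between the two conditions (pseudo-counted). TFs whose coding gene is
#' below `expr_threshold` in both conditions, or absent from the expression
#' table altogether, get the neutral weight F = 1 so they neither boost nor
#' suppress the scores of the sites they bind.
#'
#' @param expr An [expression_table][as_expression_table] with two conditions.
#' @param tf_ids Character vector of TF gene ids to weight.
#' @param expr_threshold FPKM threshold (default 1).
#' @param pseudo Pseudo-count used in the fold change (default 0.1).
#' @return data.frame `tf_gene_id, F, flag` with flag one of `"ok"`,
#'   `"below_threshold"`, `"undetected"`.
#' @export
tf_weight <- function(expr, tf_ids, expr_threshold = 1, pseudo = 0.1) {
  cond <- attr(expr, "conditions")
  stopifnot(length(cond) == 2L)
  i <- match(tf_ids, expr$gene_id)
  f1 <- expr[[cond[1]]][i]
  f2 <- expr[[cond[2]]][i]
  undetected <- is.na(i)
  below <- !undetected & f1 < expr_threshold & f2 < expr_threshold
  F <- rep(1, length(tf_ids))
  ok <- !undetected & !below
  if (any(ok))
    F[ok] <- fold_change(f1[ok], f2[ok], pseudo = pseudo)$magnitude
  flag <- ifelse(undetected, "undetected",
                 ifelse(below, "below_threshold", "ok"))
  data.frame(tf_gene_id = tf_ids, F = F, flag = flag,
             stringsAsFactors = FALSE)
}

#' TF-TF interaction score per TFBS
#'
#' For TFBS j, `I_j` sums `Pr(t, t') * F(t')` over every TF t known to bind
#' j and every interaction partner t' of t. Sites bound by many TFs that
#' interact with strongly fold-changing partners get large scores.
#'
#' @param binding Binding map (list `tfbs_id` -> TF ids).
#' @param weights `tf_weight()` output (or named numeric vector of F values).
#' @param graph data.frame with columns `tf_a, tf_b, Pr` (e.g. from
#'   [interaction_table()] or [threshold_edges()]), or an
#'   `interaction_graph`.
#' @return Named numeric vector `I_j` over `names(binding)`.
#' @export
interaction_scores <- function(binding, weights, graph) {
  FV <- .f_vector(weights)
  edges <- if (is.data.frame(graph)) graph else interaction_table(graph)
  edges <- edges[edges$Pr > 0, , drop = FALSE]
  I <- setNames(numeric(length(binding)), names(binding))
  if (nrow(edges) == 0L) return(I)
  f_of <- function(tf) ifelse(is.na(FV[tf]), 1, FV[tf])
  # partner contributions indexed by TF: sum over partners of Pr * F(partner)
  tfs <- unique(c(edges$tf_a, edges$tf_b))
  contrib <- setNames(numeric(length(tfs)), tfs)
  ca <- tapply(edges$Pr * f_of(edges$tf_b), edges$tf_a, sum)
  cb <- tapply(edges$Pr * f_of(edges$tf_a), edges$tf_b, sum)
  contrib[names(ca)] <- contrib[names(ca)] + ca
  contrib[names(cb)] <- contrib[names(cb)] + cb
  for (j in names(binding)) {
    b <- binding[[j]]
    I[j] <- sum(contrib[intersect(b, tfs)])
  }
  I
}

.f_vector <- function(weights) {
  if (is.data.frame(weights)) setNames(weights$F, weights$tf_gene_id)
  else weights
}

.flag_vector <- function(weights) {
  if (is.data.frame(weights)) setNames(weights$flag, weights$tf_gene_id)
  else setNames(rep("ok", length(weights)), names(weights))
}

#' Compute a TFBS-gene association score (TGAS) matrix
#'
#' Sums per-hit contributions `g` into a genes x TFBS score matrix under one
#' of the scoring schemes:
#' \describe{
#'   \item{I}{`g = s`, the motif match score alone.}
#'   \item{II}{`g = s * L`, weighted by the location weight.}
#'   \item{III}{`g = s * L * F_j`, where `F_j` is the largest expression
#'     fold-change weight among the TFs binding site j.}
#'   \item{IV}{as III, but columns whose every binding TF is below the
#'     expression threshold (or undetected) are deleted.}
#'   \item{V}{`g = s * L * F_j * (1 + I_j)`, adding the TF-TF interaction
#'     score; reduces exactly to III when all interaction probabilities
#'     are 0.}
#'   \item{V1, V2}{as V with the supplied TF mask applied (`F := 0`) before
#'     aggregation; columns are retained even if fully masked.}
#'   \item{V3}{as V with the columns in `exclude` deleted.}
#' }
#'
#' @param scheme One of `"I", "II", "III", "IV", "V", "V1", "V2", "V3"`.
#' @param hits [motif_hits][as_motif_hits] table; schemes II-V require an `L`
#'   column (see [location_weights_for_hits()]).
#' @param weights `tf_weight()` output (required for III-V).
#' @param binding Binding map (required for III-V).
#' @param graph Interaction table/graph with `Pr` values (required for the V
#'   family).
#' @param genes Gene universe for the rows (default: genes present in hits).
#' @param mask Character vector of TF gene ids whose F is set to 0 before
#'   aggregation (schemes V1/V2; accepted for any V-family scheme).
#' @param exclude Character vector of TFBS ids to delete (scheme V3).
#' @return Numeric matrix (genes x TFBS) with `attr(, "scheme")`.
#' @export
compute_tgas <- function(scheme, hits, weights = NULL, binding = NULL,
                         graph = NULL, genes = NULL, mask = NULL,
                         exclude = NULL) {
  scheme <- match.arg(scheme, c("I", "II", "III", "IV", "V", "V1", "V2", "V3"))
  if (is.null(genes)) genes <- sort(unique(hits$gene_id))
  tfbs <- sort(unique(hits$tfbs_id))
  needsL <- scheme != "I"
  needsF <- !scheme %in% c("I", "II")
  needsI <- scheme %in% c("V", "V1", "V2", "V3")
  if (needsL && is.null(hits$L))
    stop("scheme ", scheme, " needs location weights; run location_weights_for_hits() first")
  if (needsF && (is.null(weights) || is.null(binding)))
    stop("scheme ", scheme, " needs tf_weight() output and a binding map")
  if (needsI && is.null(graph))
    stop("scheme ", scheme, " needs an interaction graph (run_sampling output)")
  if (scheme == "V3" && is.null(exclude))
    stop("scheme V3 needs an exclusion list of TFBS ids")

  g <- hits$score
  if (needsL) g <- g * hits$L

  if (needsF) {
    check_binding_coverage(hits, binding)
    FV <- .f_vector(weights)
    flags <- .flag_vector(weights)
    if (!is.null(mask)) FV[names(FV) %in% mask] <- 0
    f_of_tf <- function(tf) ifelse(is.na(FV[tf]), 1, FV[tf])
    Fj <- vapply(binding[tfbs], function(b) max(f_of_tf(b)), numeric(1))
    names(Fj) <- tfbs
    g <- g * Fj[hits$tfbs_id]
  }

  if (needsI) {
    w_masked <- FV
    Ij <- interaction_scores(binding, w_masked, graph)
    Ij_full <- setNames(rep(0, length(tfbs)), tfbs)
    Ij_full[intersect(tfbs, names(Ij))] <- Ij[intersect(tfbs, names(Ij))]
    g <- g * (1 + Ij_full[hits$tfbs_id])
  }

  n <- length(genes)
  p <- length(tfbs)
  ig <- match(hits$gene_id, genes)
  it <- match(hits$tfbs_id, tfbs)
  keep <- !is.na(ig)
  x <- matrix(0, n, p, dimnames = list(genes, tfbs))
  if (any(keep)) {
    lin <- (it[keep] - 1L) * n + ig[keep]
    agg <- rowsum(g[keep], group = lin)
    x[as.integer(rownames(agg))] <- agg
  }

  if (scheme == "IV") {
    # TFs absent from the weight table count as undetected
    dead <- vapply(binding[tfbs], function(b) {
      fl <- flags[b]
      fl[is.na(fl)] <- "undetected"
      all(fl %in% c("below_threshold", "undetected"))
    }, logical(1))
    x <- x[, !dead, drop = FALSE]
  }
  if (scheme == "V3")
    x <- x[, setdiff(colnames(x), exclude), drop = FALSE]

  attr(x, "scheme") <- scheme
  x
}
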