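#' Fold change between two FPKM values
#'
#' Returns the fold-change magnitude `max(r, 1/r)` with
#' `r = (fpkm1 + pseudo) / (fpkm2 + pseudo)` and the direction of change.
#' With `pseudo = 0` a `1e-9` guard prevents division by zero when exactly
#' one value is 0; `(0, 0)` gives magnitude 1 and direction `"none"`.
#'
#' @param fpkm1,fpkm2 Non-negative FPKM values (vectorized).
#' @param pseudo Pseudo-count added to both values (default 0).
#' @return data.frame with columns `magnitude` (>= 1) and `direction`
#'   (`"up_in_cond1"`, `"up_in_cond2"` or `"none"`).
#' @export
fold_change <- function(fpkm1, fpkm2, pseudo = 0) {
  if (any(fpkm1 < 0) || any(fpkm2 < 0)) stop("FPKM values must be >= 0")
  if (pseudo < 0) stop("pseudo must be >= 0")
  p <- pseudo
  guard <- p == 0 & (fpkm1 == 0 | fpkm2 == 0)
  p <- ifelse(guard, 1e-9, p)
  r <- (fpkm1 + p) / (fpkm2 + p)
  magnitude <- pmax(r, 1 / r)
  direction <- ifelse(r > 1, "up_in_cond1",
                      ifelse(r < 1, "up_in_cond2", "none"))
  data.frame(magnitude = magnitude, direction = direction,
             stringsAsFactors = FALSE)
}

#' Assign genes to expression classes A/B/C/D
#'
#' Classifies every gene from its FPKM in two conditions: Class D if both
#' FPKMs are below `expr_threshold`; otherwise Class A if the fold change is
#' at least `fc_threshold` and expression is higher in condition 1, Class B
#' if higher in condition 2, and Class C otherwise. Classes A and B are the
#' differentially expressed genes, C the steady-state expressed genes, and D
#' the low-expression genes. The fold-change boundary is inclusive.
#'
#' @param expr An [expression_table][as_expression_table] with exactly two
#'   condition columns (condition 1 first).
#' @param fc_threshold Fold-change threshold (default 2).
#' @param expr_threshold FPKM threshold below which a gene counts as
#'   unexpressed (default 1).
#' @param pseudo Pseudo-count for the fold change (default 0; see
#'   [fold_change()]).
#' @return data.frame with columns `gene_id, fpkm1, fpkm2, fold_change,
#'   direction, class`.
#' @export
assign_classes <- function(expr, fc_threshold = 2, expr_threshold = 1,
                           pseudo = 0) {
  cond <- attr(expr, "conditions")
  if (length(cond) != 2L)
    stop("classification requires exactly 2 conditions, got ", length(cond))
  f1 <- expr[[cond[1]]]
  f2 <- expr[[cond[2]]]
  fc <- fold_change(f1, f2, pseudo = pseudo)
  klass <- ifelse(f1 < expr_threshold & f2 < expr_threshold, "D",
           ifelse(fc$magnitude >= fc_threshold & fc$direction == "up_in_cond1", "A",
           ifelse(fc$magnitude >= fc_threshold & fc$direction == "up_in_cond2", "B",
                  "C")))
  data.frame(gene_id = expr$gene_id, fpkm1 = f1, fpkm2 = f2,
             fold_change = fc$magnitude, direction = fc$direction,
             class = klass, stringsAsFactors = FALSE)
}
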