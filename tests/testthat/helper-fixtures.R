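# Small fixtures built in code, shared across test files.

write_expr_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

toy_expression <- function() {
  as_expression_table(data.frame(
    gene_id = c("Pparg", "Rorc", "Actb"),
    LT = c(0.3747, 6.4252, 50),
    ST = c(0.2616, 1.0000, 48)))
}

toy_hits <- function(half_window = 5000) {
  as_motif_hits(data.frame(
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    tfbs_id = c("M1", "M2", "M1", "M1", "M2"),
    position = c(-4900, -100, 250, -250, 10),
    strand = c("+", "-", "+", "+", "-"),
    score = c(0.9, 0.8, 0.7, 0.6, 0.5)), half_window = half_window)
}

toy_binding <- function() list(M1 = c("TfA", "TfB"), M2 = "TfC")
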