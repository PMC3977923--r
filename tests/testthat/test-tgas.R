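test_that("TF expression weights follow the fold-change / neutral rules", {
  expr <- as_expression_table(data.frame(
    gene_id = c("TfUp", "TfLow"), LT = c(4, 0.3), ST = c(1, 0.2)))
  w <- tf_weight(expr, c("TfUp", "TfLow", "TfGone"), expr_threshold = 1,
                 pseudo = 0.1)
  expect_equal(w$F[w$tf_gene_id == "TfUp"], 4.1 / 1.1)
  expect_equal(w$F[w$tf_gene_id == "TfLow"], 1)       # below threshold
  expect_equal(w$flag[w$tf_gene_id == "TfLow"], "below_threshold")
  expect_equal(w$F[w$tf_gene_id == "TfGone"], 1)      # undetected
  expect_equal(w$flag[w$tf_gene_id == "TfGone"], "undetected")
})

test_that("interaction scores sum Pr * F over binding TFs and partners", {
  binding <- list(M1 = "t1", M2 = c("t1", "t2"))
  FW <- c(t1 = 1, t2 = 1, t3 = 2)
  g0 <- data.frame(tf_a = "t1", tf_b = "t3", Pr = 0)
  expect_equal(unname(interaction_scores(binding, FW, g0)), c(0, 0))

  g1 <- data.frame(tf_a = "t1", tf_b = "t3", Pr = 0.8)
  I <- interaction_scores(binding, FW, g1)
  expect_equal(unname(I["M1"]), 0.8 * 2)    # t1's partner t3 has F = 2
  # a site bound by two interacting TFs doubles the score of one
  binding2 <- list(Mx = c("t1", "t2"))
  g2 <- rbind(g1, data.frame(tf_a = "t2", tf_b = "t3", Pr = 0.8))
  expect_equal(unname(interaction_scores(binding2, FW, g2)["Mx"]),
               2 * 0.8 * 2)
  # one TF with several partners accumulates over all of them
  g3 <- data.frame(tf_a = c("t1", "t1"), tf_b = c("t2", "t3"),
                   Pr = c(0.5, 0.5))
  expect_equal(unname(interaction_scores(list(M = "t1"), FW, g3)["M"]),
               0.5 * 1 + 0.5 * 2)
})

one_hit <- function(s = 0.9, L = 0.5) {
  h <- as_motif_hits(data.frame(gene_id = "g1", tfbs_id = "M1",
                                position = -100, strand = "+", score = s),
                     half_window = 1000)
  h$L <- L
  h
}

test_that("the five scoring schemes compose as s, sL, sLF, and sLF(1+I)", {
  h <- one_hit()
  w <- data.frame(tf_gene_id = "t1", F = 2, flag = "ok")
  b <- list(M1 = "t1")
  g0 <- data.frame(tf_a = "t1", tf_b = "t2", Pr = 0)
  expect_equal(unname(compute_tgas("I", h)["g1", "M1"]), 0.9)
  expect_equal(unname(compute_tgas("II", h)["g1", "M1"]), 0.45)
  expect_equal(unname(compute_tgas("III", h, w, b)["g1", "M1"]), 0.9)
  expect_equal(unname(compute_tgas("V", h, w, b, graph = g0)["g1", "M1"]), 0.9)
})

test_that("scheme V equals scheme III when all Pr are zero", {
  set.seed(21)
  genes <- sprintf("g%02d", 1:30)
  hb <- gen_hits(genes, n_tfbs = 8, tf_ids = paste0("t", 1:6),
                 n_biased = 0, seed = 3)
  hits <- location_weights_for_hits(hb$hits, n_rand_draws = 10, seed = 4)
  expr <- as_expression_table(data.frame(gene_id = paste0("t", 1:6),
                                         LT = runif(6, 1, 8),
                                         ST = runif(6, 1, 8)))
  w <- tf_weight(expr, paste0("t", 1:6))
  g0 <- data.frame(tf_a = "t1", tf_b = "t2", Pr = 0)
  xIII <- compute_tgas("III", hits, w, hb$binding, genes = genes)
  xV <- compute_tgas("V", hits, w, hb$binding, graph = g0, genes = genes)
  expect_equal(unclass(xV)[, ], unclass(xIII)[, ])
})

test_that("scheme IV deletes columns whose every TF is unexpressed", {
  h <- rbind(one_hit(), one_hit())
  h$tfbs_id <- c("M1", "M2")
  h <- as_motif_hits(h[, 1:5], half_window = 1000)
  h$L <- 0.5
  expr <- as_expression_table(data.frame(gene_id = c("tOn", "tOff"),
                                         LT = c(5, 0.2), ST = c(2, 0.4)))
  w <- tf_weight(expr, c("tOn", "tOff"))
  b <- list(M1 = "tOn", M2 = "tOff")
  xIII <- compute_tgas("III", h, w, b)
  xIV <- compute_tgas("IV", h, w, b)
  expect_setequal(colnames(xIII), c("M1", "M2"))
  expect_equal(colnames(xIV), "M1")
  expect_true(ncol(xIV) <= ncol(xIII))
})

test_that("ablation masks only reduce scores and V3 deletes listed columns", {
  set.seed(31)
  genes <- sprintf("g%02d", 1:25)
  tfs <- paste0("t", 1:8)
  hb <- gen_hits(genes, n_tfbs = 10, tf_ids = tfs, n_biased = 0, seed = 5)
  hits <- location_weights_for_hits(hb$hits, n_rand_draws = 10, seed = 6)
  expr <- as_expression_table(data.frame(gene_id = tfs,
                                         LT = runif(8, 1, 8),
                                         ST = runif(8, 1, 8)))
  w <- tf_weight(expr, tfs)
  g <- data.frame(tf_a = tfs[1], tf_b = tfs[2], Pr = 0.7)
  xV <- compute_tgas("V", hits, w, hb$binding, graph = g, genes = genes)
  xV1 <- compute_tgas("V1", hits, w, hb$binding, graph = g, genes = genes,
                      mask = tfs[1:3])
  expect_equal(dim(xV1), dim(xV))
  expect_true(all(xV1 <= xV + 1e-12))

  excl <- colnames(xV)[1:2]
  xV3 <- compute_tgas("V3", hits, w, hb$binding, graph = g, genes = genes,
                      exclude = excl)
  expect_equal(ncol(xV3), ncol(xV) - 2L)
  expect_false(any(excl %in% colnames(xV3)))
})

test_that("scores are nonnegative sums over hits: adding a hit never decreases", {
  h2 <- rbind(one_hit(s = 0.9), one_hit(s = 0.6))
  h2 <- as_motif_hits(h2[, 1:5], half_window = 1000)
  h2$L <- c(0.5, 0.5)
  x2 <- compute_tgas("II", h2)
  expect_equal(unname(x2["g1", "M1"]), 0.9 * 0.5 + 0.6 * 0.5)
  x1 <- compute_tgas("II", one_hit(s = 0.9))
  expect_true(x2["g1", "M1"] >= x1["g1", "M1"])
  expect_true(all(x2 >= 0))
})
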