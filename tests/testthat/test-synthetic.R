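test_that("generated expression reproduces its planted class labels exactly", {
  ge <- gen_expression(1000, c(A = .1, B = .1, C = .5, D = .3), seed = 17)
  cl <- assign_classes(ge$expr)
  expect_identical(cl$class, ge$classes$class)
  expect_equal(as.vector(table(ge$classes$class)[c("A","B","C","D")]),
               c(100, 100, 500, 300))

  allD <- gen_expression(200, c(A = 0, B = 0, C = 0, D = 1), seed = 18)
  expect_true(all(allD$expr$LT < 1 & allD$expr$ST < 1))

  ge2 <- gen_expression(1000, c(A = .1, B = .1, C = .5, D = .3), seed = 17)
  expect_identical(ge$expr, ge2$expr)
})

test_that("generated hits respect the window, score range and planted bias", {
  genes <- sprintf("g%03d", 1:150)
  hb <- gen_hits(genes, n_tfbs = 12, half_window = 2000, bin_size = 500,
                 n_biased = 1, bias_frac = 0.9, seed = 19)
  expect_true(all(abs(hb$hits$position) <= 2000))
  expect_true(all(hb$hits$score >= 0 & hb$hits$score <= 1))
  expect_true(all(lengths(hb$binding) >= 1 & lengths(hb$binding) <= 8))

  hw <- location_weights_for_hits(hb$hits, half_window = 2000,
                                  bin_size = 500, n_rand_draws = 50,
                                  seed = 20)
  bi <- hb$bias$tfbs_id[1]
  bin <- hb$bias$bin[1]
  lo <- -2000 + (bin - 1) * 500
  in_bin <- hw$tfbs_id == bi & hw$position >= lo & hw$position < lo + 500
  expect_gt(mean(hw$L[in_bin]), 0.8)

  hb2 <- gen_hits(genes, n_tfbs = 12, half_window = 2000, bin_size = 500,
                  n_biased = 1, bias_frac = 0.9, seed = 19)
  expect_identical(hb$hits, hb2$hits)
})

emp_or <- function(x, y) {
  n11 <- sum(x & y); n00 <- sum(!x & !y)
  n10 <- sum(x & !y); n01 <- sum(!x & y)
  n11 * n00 / (n10 * n01)
}

test_that("occupancy matrices carry the planted odds ratios", {
  occ <- gen_occupancy(5000, 6, dependency_edges = cbind(1, 2),
                       odds_ratio = 3, seed = 21)
  expect_true(all(occ %in% 0:1))
  or12 <- emp_or(occ[, 1], occ[, 2])
  expect_gt(or12, 2.5)
  expect_lt(or12, 3.6)
  # untouched pairs stay near independence
  ors <- c(emp_or(occ[, 3], occ[, 4]), emp_or(occ[, 5], occ[, 6]),
           emp_or(occ[, 3], occ[, 6]))
  expect_true(all(abs(log(ors)) < log(1.35)))

  occ_ind <- gen_occupancy(5000, 4, seed = 22)
  ors2 <- apply(all_pairs(4), 1, function(e) emp_or(occ_ind[, e[1]],
                                                    occ_ind[, e[2]]))
  expect_true(all(abs(log(ors2)) < log(1.35)))

  expect_error(gen_occupancy(100, 4, dependency_edges = rbind(c(1, 2),
                                                              c(2, 3))),
               "at most one")
  expect_identical(gen_occupancy(500, 5, seed = 23),
                   gen_occupancy(500, 5, seed = 23))
})

test_that("noiseless planted responses are exactly recoverable by OLS", {
  fx <- gen_regression_fixture(n_genes = 120, n_tfbs = 12, n_main = 3,
                               n_pair = 1, noise_frac = 0, seed = 24)
  Xs <- standardize_columns(fx$X)
  z <- Xs[, fx$truth$pair_terms$a] * Xs[, fx$truth$pair_terms$b]
  z <- (z - mean(z)) / sd(z)
  D <- cbind(Xs[, names(fx$truth$main_terms)], pair = z)
  f <- fit_ols(D, fx$y)
  expect_equal(unname(f$coefficients),
               unname(c(fx$truth$main_terms, fx$truth$pair_terms$beta)),
               tolerance = 1e-8)
})

test_that("the full bundle is seed-reproducible and internally consistent", {
  d1 <- simulate_dataset(n_genes = 200, n_tfbs = 10, n_tfs = 10,
                         n_promoters = 150, n_dependency_edges = 2,
                         seed = 25)
  d2 <- simulate_dataset(n_genes = 200, n_tfbs = 10, n_tfs = 10,
                         n_promoters = 150, n_dependency_edges = 2,
                         seed = 25)
  expect_identical(d1$hits, d2$hits)
  expect_identical(d1$occupancy, d2$occupancy)
  expect_identical(d1$truth$dependency_edges, d2$truth$dependency_edges)
  # hits cover only DEG promoters; binding covers every TFBS in hits
  deg <- d1$classes$gene_id[d1$classes$class %in% c("A", "B")]
  expect_true(all(d1$hits$gene_id %in% deg))
  expect_true(all(d1$hits$tfbs_id %in% names(d1$binding)))

  out <- file.path(tempdir(), "bundle-test")
  simulate_dataset(n_genes = 200, n_tfbs = 10, n_tfs = 10,
                   n_promoters = 150, n_dependency_edges = 2, seed = 25,
                   out_dir = out)
  expect_true(all(file.exists(file.path(out,
    c("expression.tsv", "hits.tsv", "binding_map.tsv", "occupancy.tsv",
      "truth.json", "true_classes.tsv")))))
  unlink(out, recursive = TRUE)
})
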