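rand_occ <- function(n, k, seed = 1, p = 0.5) {
  set.seed(seed)
  matrix(rbinom(n * k, 1L, p), n, k,
         dimnames = list(NULL, LETTERS[seq_len(k)]))
}

test_that("tabulation cross-classifies binary rows exactly", {
  occ <- matrix(c(0,0, 0,1, 1,0, 1,1), 4, 2, byrow = TRUE,
                dimnames = list(NULL, c("A", "B")))
  tab <- tabulate_occupancy(occ)
  expect_equal(tab$counts, rep(1, 4))
  expect_equal(tab$n, 4)

  occ2 <- cbind(A = c(0L, 0L, 0L), B = c(1L, 0L, 1L))
  tab2 <- tabulate_occupancy(occ2)
  expect_equal(sum(tab2$counts[c(2, 4)]), 0)  # A=1 slice empty

  # brute-force oracle on a random 200 x 3 matrix
  occ3 <- rand_occ(200, 3, seed = 7)
  tab3 <- tabulate_occupancy(occ3)
  brute <- table(factor(apply(occ3, 1, paste, collapse = ""),
                        levels = c("000","100","010","110",
                                   "001","101","011","111")))
  expect_equal(tab3$counts, as.numeric(brute))
  expect_error(tabulate_occupancy(matrix(2, 2, 2,
                                         dimnames = list(NULL, c("A","B")))),
               "binary")
})

test_that("the saturated model reproduces the table with zero deviance", {
  tab <- tabulate_occupancy(rand_occ(150, 3, seed = 2))
  f <- ipf_fit(tab, all_pairs(3), tol = 1e-8)
  expect_equal(f$fitted, tab$counts, tolerance = 1e-10)
  expect_equal(f$G2, 0, tolerance = 1e-8)
  expect_equal(f$df, 0)
})

test_that("IPF matches the closed form for conditional independence", {
  tab <- tabulate_occupancy(rand_occ(400, 3, seed = 3))
  f <- ipf_fit(tab, rbind(c(1, 3), c(2, 3)), tol = 1e-8)  # A _|_ B | C
  cnt <- array(tab$counts, c(2, 2, 2))
  closed <- array(0, c(2, 2, 2))
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    closed[i, j, k] <- sum(cnt[i, , k]) * sum(cnt[, j, k]) / sum(cnt[, , k])
  expect_equal(array(f$fitted, c(2, 2, 2)), closed, tolerance = 1e-8)
  expect_equal(f$df, 2)
})

test_that("IPF matches the closed form for chain and star graphs", {
  # chain A-B-C-D: m = n_ab n_bc n_cd / (n_b n_c)
  tab <- tabulate_occupancy(rand_occ(500, 4, seed = 4))
  cnt <- array(tab$counts, c(2, 2, 2, 2))
  f <- ipf_fit(tab, rbind(c(1, 2), c(2, 3), c(3, 4)), tol = 1e-8)
  closed <- array(0, c(2, 2, 2, 2))
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) for (d in 1:2)
    closed[a, b, cc, d] <- sum(cnt[a, b, , ]) * sum(cnt[, b, cc, ]) *
      sum(cnt[, , cc, d]) / (sum(cnt[, b, , ]) * sum(cnt[, , cc, ]))
  expect_equal(array(f$fitted, c(2, 2, 2, 2)), closed, tolerance = 1e-8)

  # star centred on A: m = n_ab n_ac n_ad / n_a^2
  f2 <- ipf_fit(tab, rbind(c(1, 2), c(1, 3), c(1, 4)), tol = 1e-8)
  closed2 <- array(0, c(2, 2, 2, 2))
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) for (d in 1:2)
    closed2[a, b, cc, d] <- sum(cnt[a, b, , ]) * sum(cnt[a, , cc, ]) *
      sum(cnt[a, , , d]) / sum(cnt[a, , , ])^2
  expect_equal(array(f2$fitted, c(2, 2, 2, 2)), closed2, tolerance = 1e-8)
})

test_that("IPF agrees with stats::loglin on a non-decomposable generator", {
  tab <- tabulate_occupancy(rand_occ(600, 4, seed = 5))
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4))  # 4-cycle
  f <- ipf_fit(tab, edges, tol = 1e-10, maxit = 10000)
  ll <- stats::loglin(array(tab$counts, c(2, 2, 2, 2)),
                      margin = list(c(1, 2), c(2, 3), c(3, 4), c(1, 4)),
                      fit = TRUE, eps = 1e-10, iter = 10000, print = FALSE)
  expect_equal(f$fitted, as.vector(ll$fit), tolerance = 1e-6)
  expect_equal(f$G2, ll$lrt, tolerance = 1e-6)
  expect_equal(f$df, ll$df)
})

test_that("a table of equal counts fits complete independence exactly", {
  tab <- structure(list(counts = rep(5, 8), vars = c("A", "B", "C"), n = 40),
                   class = "contingency_table")
  f <- ipf_fit(tab, NULL, tol = 1e-8)
  expect_equal(f$G2, 0, tolerance = 1e-8)
})

test_that("deviance grows monotonically as edges are removed", {
  tab <- tabulate_occupancy(rand_occ(300, 4, seed = 6))
  edges <- all_pairs(4)
  g2s <- vapply(rev(seq_len(nrow(edges) + 1L)) - 1L, function(ne)
    ipf_fit(tab, edges[seq_len(ne), , drop = FALSE],
            generator = "pairwise", tol = 1e-6, maxit = 5000)$G2,
    numeric(1))
  expect_true(all(diff(g2s) >= -1e-6))
})

test_that("backward elimination keeps real edges and drops null ones", {
  # two independent variables, large n -> empty edge set
  set.seed(8)
  occ <- cbind(A = rbinom(4000, 1, .5), B = rbinom(4000, 1, .4))
  bs <- backward_select(tabulate_occupancy(occ))
  expect_equal(nrow(bs$edges), 0L)

  # duplicated column -> its edge survives
  occ2 <- cbind(A = occ[, 1], B = occ[, 1], C = rbinom(4000, 1, .5))
  bs2 <- backward_select(tabulate_occupancy(occ2))
  e <- fit_edges(bs2)
  expect_true(any(e[, 1] == "A" & e[, 2] == "B"))
})

test_that("the single-edge removal p-value is approximately uniform under the null", {
  set.seed(9)
  n_sim <- 400
  p <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    occ <- matrix(rbinom(600, 1, .5), 200, 3,
                  dimnames = list(NULL, c("A", "B", "C")))
    tab <- tabulate_occupancy(occ)
    fm <- ipf_fit(tab, all_pairs(3), generator = "pairwise", tol = 1e-6,
                  maxit = 5000)
    rm <- ipf_fit(tab, rbind(c(1, 3), c(2, 3)), generator = "pairwise",
                  tol = 1e-6, maxit = 5000)
    p[s] <- pchisq(max(0, rm$G2 - fm$G2), rm$df - fm$df, lower.tail = FALSE)
  }
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
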