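std <- function(x) (x - mean(x)) / sd(x)

test_that("OLS recovers exact coefficients and handles degenerate designs", {
  set.seed(41)
  X <- cbind(x1 = rnorm(50), x2 = rnorm(50))
  y <- 3 * X[, "x1"] - 2 * X[, "x2"]
  f <- fit_ols(X, y)
  expect_equal(unname(f$coefficients), c(3, -2), tolerance = 1e-8)
  expect_lt(f$rss, 1e-16)

  yc <- rep(4, 50)
  fc <- fit_ols(X, yc)
  expect_equal(unname(fc$coefficients), c(0, 0), tolerance = 1e-10)
  expect_equal(fc$intercept, 4, tolerance = 1e-10)

  Xd <- cbind(X, x3 = X[, "x1"])
  expect_warning(fd <- fit_ols(Xd, y), "aliased")
  expect_equal(fd$fitted, f$fitted, tolerance = 1e-10)
})

test_that("AIC backward elimination matches stats::step on a small case", {
  set.seed(42)
  X <- matrix(rnorm(80 * 6), 80, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- 1.5 * X[, 1] - X[, 4] + rnorm(80, 0, 1)
  ab <- aic_backward(X, y)
  df <- data.frame(y = y, X)
  st <- stats::step(stats::lm(y ~ ., data = df), direction = "backward",
                    trace = 0)
  expect_setequal(ab$retained, setdiff(names(stats::coef(st)), "(Intercept)"))
})

test_that("AIC backward keeps informative columns and prunes noise", {
  keep_all <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    X <- matrix(rnorm(300 * 25), 300, 25,
                dimnames = list(NULL, paste0("x", 1:25)))
    beta <- c(rep(1, 5), rep(0, 20))
    sig <- drop(X %*% beta)
    y <- sig + rnorm(300, 0, 0.2 * sd(sig))
    all(paste0("x", 1:5) %in% aic_backward(X, y)$retained)
  }, logical(1))
  expect_gte(mean(keep_all), 0.95)

  near_empty <- vapply(1:40, function(s) {
    set.seed(2000 + s)
    X <- matrix(rnorm(800 * 5), 800, 5,
                dimnames = list(NULL, paste0("x", 1:5)))
    length(aic_backward(X, rnorm(800))$retained) <= 2
  }, logical(1))
  expect_gte(mean(near_empty), 0.9)

  set.seed(3)
  X1 <- matrix(rnorm(200), 200, 1, dimnames = list(NULL, "x1"))
  y1 <- 2 * X1[, 1] + rnorm(200, 0, 0.3)
  expect_equal(aic_backward(X1, y1)$retained, "x1")
})

test_that("the CV-gated search finds a planted pairwise term exactly", {
  set.seed(43)
  n <- 200
  X <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("x", 1:12)))
  Xs <- standardize_columns(X)
  z <- std(Xs[, "x3"] * Xs[, "x4"])
  y <- 3 * Xs[, "x1"] + 1.5 * z        # noiseless
  run <- pairwise_search(Xs, y, retained = "x1",
                         removed = paste0("x", 2:12), seed = 7)
  expect_true(any(run$pair_terms[, 1] == "x3" & run$pair_terms[, 2] == "x4" |
                  run$pair_terms[, 1] == "x4" & run$pair_terms[, 2] == "x3"))
  expect_equal(unname(run$coefficients["x3:x4"]), 1.5, tolerance = 1e-6)
  expect_equal(unname(run$coefficients["x1"]), 3, tolerance = 1e-6)
  expect_equal(run$R, 1, tolerance = 1e-8)
  # pairwise terms never combine retained main effects
  expect_false(any(run$pair_terms == "x1"))
})

test_that("incremental CV updates agree with naive refits", {
  set.seed(46)
  X <- standardize_columns(matrix(rnorm(100 * 8), 100, 8,
                                  dimnames = list(NULL, paste0("x", 1:8))))
  y <- drop(X[, 1] - X[, 2] + rnorm(100, 0, .7))
  run <- pairwise_search(X, y, retained = c("x1", "x2"),
                         removed = paste0("x", 3:8), seed = 9)
  # rebuild the final design and recompute the mean test r the slow way
  set.seed(9)
  fold <- sample(rep(1:5, length.out = 100))
  D <- X[, c("x1", "x2")]
  if (nrow(run$pair_terms)) {
    for (e in seq_len(nrow(run$pair_terms))) {
      z <- X[, run$pair_terms[e, 1]] * X[, run$pair_terms[e, 2]]
      D <- cbind(D, (z - mean(z)) / sd(z))
    }
  }
  expect_equal(run$cv_r, promod:::.cv_mean_r(D, y, fold), tolerance = 1e-10)
})

test_that("the CV gate bounds junk pairwise uptake on pure noise", {
  # Whole-sample chance correlations pass any same-data CV screen, so the
  # gate cannot reject all junk; it must, however, stay well below free
  # uptake and leave most candidates out.
  fracs <- vapply(1:5, function(s) {
    set.seed(4000 + s)
    X <- standardize_columns(matrix(rnorm(300 * 30), 300, 30,
                                    dimnames = list(NULL, paste0("x", 1:30))))
    y <- rnorm(300)
    ab <- aic_backward(X, y)
    if (length(ab$removed) < 2) return(0)
    run <- pairwise_search(X, y, ab$retained, ab$removed, seed = s)
    run$n_accepted / run$n_candidates
  }, numeric(1))
  expect_lte(mean(fracs), 0.25)
})

test_that("a run is bit-identical under the same seed and improves monotonically", {
  set.seed(44)
  X <- standardize_columns(matrix(rnorm(120 * 10), 120, 10,
                                  dimnames = list(NULL, paste0("x", 1:10))))
  y <- drop(X[, 1] + rnorm(120, 0, .5))
  ab <- aic_backward(X, y)
  r1 <- pairwise_search(X, y, ab$retained, ab$removed, seed = 11)
  r2 <- pairwise_search(X, y, ab$retained, ab$removed, seed = 11)
  expect_identical(r1, r2)
  expect_true(r1$R >= -1 && r1$R <= 1)
})

test_that("CV folds partition the genes into near-equal blocks", {
  set.seed(45)
  fold <- sample(rep(seq_len(5), length.out = 123))
  expect_equal(length(fold), 123)
  expect_true(all(table(fold) %in% c(24, 25)))
})

test_that("ensembles on a noiseless planted model reach R ~ 1 and attribute RCs", {
  fx <- gen_regression_fixture(n_genes = 150, n_tfbs = 15, n_main = 4,
                               n_pair = 0, noise_frac = 0, seed = 5)
  ens <- run_ensemble(fx$X, fx$y, n_runs = 10, base_seed = 100)
  expect_gte(ens$summary$R_mean, 0.999)
  # planted main effects must be retained with sign-correct RCs
  for (j in names(fx$truth$main_terms)) {
    expect_true(j %in% ens$retained)
    expect_equal(sign(mean(ens$ensembles[[j]])),
                 sign(fx$truth$main_terms[[j]]))
  }
})

test_that("planted signs are recovered by the ensemble means", {
  main_ok <- pair_ok <- logical(0)
  for (s in 1:3) {
    fx <- gen_regression_fixture(n_genes = 300, n_tfbs = 24, n_main = 6,
                                 n_pair = 2, noise_frac = 0.2, seed = s)
    ens <- run_ensemble(fx$X, fx$y, n_runs = 15, base_seed = 300 + 50 * s)
    for (j in names(fx$truth$main_terms)) {
      e <- ens$ensembles[[j]]
      main_ok <- c(main_ok, length(e) > 0 &&
                     sign(mean(e)) == sign(fx$truth$main_terms[[j]]))
    }
    # whenever a planted pair term was accepted, its coefficient carries
    # the planted sign
    for (run in ens$runs) {
      if (nrow(run$pair_terms) == 0) next
      for (e in seq_len(nrow(fx$truth$pair_terms))) {
        a <- fx$truth$pair_terms$a[e]; b <- fx$truth$pair_terms$b[e]
        hit <- (run$pair_terms[, 1] == a & run$pair_terms[, 2] == b) |
               (run$pair_terms[, 1] == b & run$pair_terms[, 2] == a)
        if (any(hit)) {
          nm <- paste0(run$pair_terms[hit, 1], ":", run$pair_terms[hit, 2])
          pair_ok <- c(pair_ok, sign(run$coefficients[[nm]]) ==
                         sign(fx$truth$pair_terms$beta[e]))
        }
      }
    }
  }
  expect_gte(mean(main_ok), 0.9)
  expect_true(length(pair_ok) > 0)
  expect_gte(mean(pair_ok), 0.9)
})

test_that("ensemble runs are independent of the number of threads", {
  fx <- gen_regression_fixture(n_genes = 100, n_tfbs = 10, n_main = 2,
                               n_pair = 1, noise_frac = 0.1, seed = 7)
  e1 <- run_ensemble(fx$X, fx$y, n_runs = 6, base_seed = 50, n_threads = 1)
  e2 <- run_ensemble(fx$X, fx$y, n_runs = 6, base_seed = 50, n_threads = 2)
  expect_equal(e1$ensembles, e2$ensembles)
  expect_equal(e1$summary, e2$summary)
})
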