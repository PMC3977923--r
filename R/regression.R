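#' Ordinary least squares with Gaussian AIC
#'
#' Least-squares fit with intercept. Aliased (rank-deficient) columns are
#' dropped with a warning, their coefficients reported as 0. The AIC follows
#' the Gaussian-likelihood convention `n * log(RSS / n) + 2 * (rank + 1)`
#' (the +1 counts the error variance), so only differences between nested
#' fits on the same response are meaningful.
#'
#' @param X Numeric predictor matrix (no intercept column), named columns.
#' @param y Numeric response, `length(y) == nrow(X)`.
#' @return List with `coefficients` (named, excluding intercept),
#'   `intercept`, `fitted`, `rss`, `rank`, `aic`, `dropped` (aliased column
#'   names).
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, n > 1L)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  cf <- fit$coefficients
  dropped <- names(cf)[is.na(cf)]
  if (length(dropped)) {
    warning("aliased column(s) dropped: ", paste(dropped, collapse = ", "))
    cf[is.na(cf)] <- 0
  }
  rss <- sum(fit$residuals^2)
  aic <- n * log(max(rss, 1e-300) / n) + 2 * (fit$rank + 1)
  list(coefficients = cf[-1L], intercept = cf[[1L]],
       fitted = fit$fitted.values, rss = rss, rank = fit$rank,
       aic = aic, dropped = dropped)
}

# RSS/rank of y ~ 1 + X, fast path used in the selection loops.
.ols_rss <- function(X, y) {
  fit <- stats::lm.fit(cbind(1, X), y)
  list(rss = sum(fit$residuals^2), rank = fit$rank)
}

.gauss_aic <- function(rss, rank, n) n * log(max(rss, 1e-300) / n) + 2 * (rank + 1)

#' Backward elimination of main-effect terms by AIC
#'
#' Classic backward elimination: starting from the full model, repeatedly
#' drops the single column whose removal most decreases the Gaussian AIC,
#' until no removal decreases it.
#'
#' @inheritParams fit_ols
#' @return List with `retained` and `removed` column names (removal order)
#'   and the final `aic`.
#' @export
aic_backward <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  cur <- colnames(X)
  if (is.null(cur)) stop("X needs column names")
  f <- .ols_rss(X, y)
  cur_aic <- .gauss_aic(f$rss, f$rank, n)
  removed <- character(0)
  while (length(cur) > 0L) {
    aics <- vapply(seq_along(cur), function(i) {
      g <- .ols_rss(X[, cur[-i], drop = FALSE], y)
      .gauss_aic(g$rss, g$rank, n)
    }, numeric(1))
    best <- which.min(aics)
    if (aics[best] >= cur_aic) break
    removed <- c(removed, cur[best])
    cur <- cur[-best]
    cur_aic <- aics[best]
  }
  list(retained = cur, removed = removed, aic = cur_aic)
}

# Mean test-fold Pearson r of y ~ 1 + D under a fixed fold assignment.
# Degenerate folds (zero-variance predictions or response) contribute 0.
.cv_mean_r <- function(D, y, fold) {
  nf <- max(fold)
  r <- numeric(nf)
  for (i in seq_len(nf)) {
    test <- fold == i
    if (is.null(D)) {
      pred <- rep(mean(y[!test]), sum(test))
    } else {
      fit <- stats::lm.fit(cbind(1, D[!test, , drop = FALSE]), y[!test])
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      pred <- drop(cbind(1, D[test, , drop = FALSE]) %*% cf)
    }
    r[i] <- if (stats::sd(pred) > 0 && stats::sd(y[test]) > 0)
      stats::cor(pred, y[test]) else 0
  }
  mean(r)
}

#' Randomized pairwise-term search gated by cross-validation
#'
#' Extends an AIC-reduced main-effect model with pairwise TFBS terms:
#' candidates are the elementwise products of all distinct pairs of columns
#' that AIC removed (pairwise terms never combine retained main effects).
#' Candidates are visited in a seed-determined random order; each is added
#' to the current model and kept iff the mean test-fold Pearson r of a
#' 5-fold cross-validation strictly improves. The fold partition is drawn
#' once per run from the same seed. After the candidate sweep the final
#' model is refit on all genes and the model quality R (Pearson correlation
#' between observed and fitted response) is recorded.
#'
#' @param X Standardized predictor matrix (see [run_ensemble()]).
#' @param y Response vector on the model's transform scale.
#' @param retained,removed Column-name sets from [aic_backward()].
#' @param n_folds CV folds (default 5).
#' @param seed Integer seed; the run is deterministic given it.
#' @return Object of class `regression_run`: list with `seed`, `main_terms`,
#'   `pair_terms` (2-column character matrix), `coefficients` (named; pair
#'   terms named `"a:b"`), `intercept`, `cv_r` (final mean test r), `R`,
#'   `n_candidates`, `n_accepted`.
#' @export
pairwise_search <- function(X, y, retained, removed, n_folds = 5, seed = 1) {
  n <- length(y)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- sample(rep(seq_len(n_folds), length.out = n))

  pairs <- if (length(removed) >= 2L) utils::combn(removed, 2L) else
    matrix(character(0), 2L, 0L)
  ord <- if (ncol(pairs)) sample.int(ncol(pairs)) else integer(0)

  fold_r <- function(pred, yte)
    if (stats::sd(pred) > 0 && stats::sd(yte) > 0) stats::cor(pred, yte)
    else 0

  # Per-fold state: an orthonormal train-side basis Q of the growing model,
  # the test design mapped through the same transform (Qte), and test
  # predictions. Appending a candidate column is then O(n p) instead of a
  # full O(n p^2) refit, with identical least-squares predictions.
  base <- cbind(`(Intercept)` = rep(1, n),
                if (length(retained)) X[, retained, drop = FALSE])
  st <- lapply(seq_len(n_folds), function(i) {
    tr <- fold != i
    qrD <- qr(base[tr, , drop = FALSE])
    r <- qrD$rank
    piv <- qrD$pivot[seq_len(r)]
    Q <- qr.Q(qrD)[, seq_len(r), drop = FALSE]
    Rm <- qr.R(qrD)[seq_len(r), seq_len(r), drop = FALSE]
    Qte <- t(backsolve(Rm, t(base[!tr, piv, drop = FALSE]),
                       transpose = TRUE))
    cvec <- drop(crossprod(Q, y[tr]))
    list(tr = tr, ytr = y[tr], yte = y[!tr], Q = Q, Qte = Qte,
         pred = drop(Qte %*% cvec))
  })
  best_r <- mean(vapply(st, function(s) fold_r(s$pred, s$yte), numeric(1)))

  D <- if (length(retained)) X[, retained, drop = FALSE] else NULL
  accepted <- matrix(character(0), 0L, 2L)
  for (ci in ord) {
    a <- pairs[1L, ci]; b <- pairs[2L, ci]
    z <- X[, a] * X[, b]
    sz <- stats::sd(z)
    if (!is.finite(sz) || sz == 0) next
    z <- (z - mean(z)) / sz
    rs <- numeric(n_folds)
    upd <- vector("list", n_folds)
    for (i in seq_len(n_folds)) {
      s <- st[[i]]
      ztr <- z[s$tr]
      g <- drop(crossprod(s$Q, ztr))
      u <- ztr - drop(s$Q %*% g)
      nu <- sqrt(sum(u^2))
      if (nu < 1e-8 * sqrt(length(ztr))) {   # aliased within this fold
        rs[i] <- fold_r(s$pred, s$yte)
      } else {
        q <- u / nu
        qte <- (z[!s$tr] - drop(s$Qte %*% g)) / nu
        cc <- sum(q * s$ytr)
        prednew <- s$pred + cc * qte
        rs[i] <- fold_r(prednew, s$yte)
        upd[[i]] <- list(q = q, qte = qte, pred = prednew)
      }
    }
    r_try <- mean(rs)
    if (r_try > best_r) {
      best_r <- r_try
      for (i in seq_len(n_folds)) {
        if (is.null(upd[[i]])) next
        st[[i]]$Q <- cbind(st[[i]]$Q, upd[[i]]$q)
        st[[i]]$Qte <- cbind(st[[i]]$Qte, upd[[i]]$qte)
        st[[i]]$pred <- upd[[i]]$pred
      }
      D <- cbind(D, z)
      colnames(D)[ncol(D)] <- paste0(a, ":", b)
      accepted <- rbind(accepted, c(a, b))
    }
  }

  if (is.null(D)) {
    cf <- numeric(0)
    intercept <- mean(y)
    fitted <- rep(intercept, n)
  } else {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, D), y)
    cfa <- fit$coefficients
    cfa[is.na(cfa)] <- 0
    intercept <- cfa[[1L]]
    cf <- cfa[-1L]
    fitted <- fit$fitted.values
  }
  R <- if (stats::sd(fitted) > 0) stats::cor(y, fitted) else 0
  structure(list(seed = seed, main_terms = retained, pair_terms = accepted,
                 coefficients = cf, intercept = intercept, cv_r = best_r,
                 R = R, n_candidates = ncol(pairs),
                 n_accepted = nrow(accepted)),
            class = "regression_run")
}

#' Repeated-seed regression ensemble and per-TFBS coefficient collections
#'
#' Standardizes the predictor columns (z-scores; zero-variance columns become
#' all-zero), reduces the main effects once by [aic_backward()] (the
#' reduction is deterministic), then repeats [pairwise_search()] `n_runs`
#' times with seeds `base_seed + 1, ..., base_seed + n_runs`. Each run
#' attributes one regression coefficient (RC) to every TFBS it involves: its
#' main-effect coefficient if retained, otherwise the sum of the
#' coefficients of the accepted pairwise terms containing it. TFBSs that a
#' run does not involve contribute nothing to that run's ensemble entry.
#'
#' @inheritParams pairwise_search
#' @param n_runs Number of repeated runs (default 100).
#' @param base_seed Base seed; run i uses `base_seed + i`.
#' @param standardize Standardize columns first (default TRUE; the matrix is
#'   assumed already standardized when FALSE).
#' @param n_threads Parallel workers over runs via `parallel::mclapply`;
#'   results are independent of this value because every run has a fixed
#'   seed (default 1).
#' @return Object of class `rc_ensemble_set`: list with `ensembles` (named
#'   list, TFBS -> numeric vector of RCs), `runs` (list of
#'   `regression_run`), `retained`, `removed`, `summary` (data.frame with
#'   mean/sd of R and of single/pairwise/total term counts), `base_seed`.
#' @export
run_ensemble <- function(X, y, n_runs = 100, base_seed = 1, n_folds = 5,
                         standardize = TRUE, n_threads = 1) {
  X <- as.matrix(X)
  if (standardize) X <- standardize_columns(X)
  ab <- aic_backward(X, y)
  run_one <- function(i)
    pairwise_search(X, y, ab$retained, ab$removed,
                    n_folds = n_folds, seed = base_seed + i)
  runs <- if (n_threads > 1L)
    parallel::mclapply(seq_len(n_runs), run_one, mc.cores = n_threads)
  else lapply(seq_len(n_runs), run_one)

  ens <- lapply(setNames(nm = colnames(X)), function(j) numeric(0))
  for (run in runs) {
    cf <- run$coefficients
    for (j in run$main_terms)
      ens[[j]] <- c(ens[[j]], unname(cf[j]))
    if (nrow(run$pair_terms)) {
      pair_names <- paste0(run$pair_terms[, 1], ":", run$pair_terms[, 2])
      involved <- unique(c(run$pair_terms))
      for (j in involved) {
        sel <- run$pair_terms[, 1] == j | run$pair_terms[, 2] == j
        ens[[j]] <- c(ens[[j]], sum(cf[pair_names[sel]]))
      }
    }
  }

  Rv <- vapply(runs, `[[`, numeric(1), "R")
  n_pair <- vapply(runs, `[[`, numeric(1), "n_accepted")
  n_tfbs <- vapply(runs, function(r)
    length(unique(c(r$main_terms, c(r$pair_terms)))), numeric(1))
  summ <- data.frame(
    n_runs = n_runs,
    tfbs_mean = mean(n_tfbs), tfbs_sd = stats::sd(n_tfbs),
    R_mean = mean(Rv), R_sd = stats::sd(Rv),
    single_mean = length(ab$retained), single_sd = 0,
    pairwise_mean = mean(n_pair), pairwise_sd = stats::sd(n_pair))
  structure(list(ensembles = ens, runs = runs, retained = ab$retained,
                 removed = ab$removed, summary = summ,
                 base_seed = base_seed),
            class = "rc_ensemble_set")
}

#' Z-score standardize matrix columns
#'
#' Zero-variance columns become all-zero rather than NaN so they stay inert
#' in downstream fits.
#'
#' @param X Numeric matrix.
#' @return Standardized matrix with the same dimnames.
#' @export
standardize_columns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  Xs <- sweep(X, 2, mu, "-")
  sdv[sdv == 0 | !is.finite(sdv)] <- Inf
  sweep(Xs, 2, sdv, "/")
}

#' Long-format table of RC ensembles
#' @param ens `rc_ensemble_set`.
#' @return data.frame `tfbs_id, run_index, rc` (only TFBSs with >= 1 RC).
#' @export
rc_table <- function(ens) {
  stopifnot(inherits(ens, "rc_ensemble_set"))
  keep <- lengths(ens$ensembles) > 0
  e <- ens$ensembles[keep]
  data.frame(tfbs_id = rep(names(e), lengths(e)),
             run_index = unlist(lapply(e, seq_along), use.names = FALSE),
             rc = unlist(e, use.names = FALSE),
             stringsAsFactors = FALSE)
}
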