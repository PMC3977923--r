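#' Generate a two-condition expression table with known class labels
#'
#' FPKM pairs are constructed per class so that [assign_classes()] under the
#' default thresholds recovers the planted labels exactly: Class D genes get
#' both FPKMs below the expression threshold; Class C genes get a high
#' baseline with fold changes safely inside the threshold; Class A/B genes
#' get fold changes safely above it, up in condition 1 or 2 respectively.
#'
#' @param n_genes Number of genes.
#' @param class_fractions Named or positional fractions for classes A, B, C,
#'   D (must sum to 1).
#' @param fc_threshold,expr_threshold Classification thresholds the labels
#'   are planted against (defaults 2 and 1).
#' @param conditions Two condition labels (default `c("LT", "ST")`).
#' @param seed Integer seed.
#' @return List with `expr` (an [expression_table][as_expression_table]) and
#'   `classes` (data.frame `gene_id, class`).
#' @export
gen_expression <- function(n_genes, class_fractions = c(A = 0.1, B = 0.1,
                                                        C = 0.5, D = 0.3),
                           fc_threshold = 2, expr_threshold = 1,
                           conditions = c("LT", "ST"), seed = 1) {
  stopifnot(length(class_fractions) == 4L,
            abs(sum(class_fractions) - 1) < 1e-8)
  counts <- floor(n_genes * class_fractions)
  counts[1] <- counts[1] + (n_genes - sum(counts))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  klass <- rep(c("A", "B", "C", "D"), counts)
  n <- length(klass)
  f1 <- f2 <- numeric(n)
  thr <- expr_threshold

  iD <- klass == "D"
  f1[iD] <- stats::runif(sum(iD), 0, 0.9 * thr)
  f2[iD] <- stats::runif(sum(iD), 0, 0.9 * thr)

  iC <- klass == "C"
  base <- thr * (2 + stats::rlnorm(sum(iC), meanlog = 1, sdlog = 0.8))
  ratio <- stats::runif(sum(iC), 1 / (0.9 * fc_threshold), 0.9 * fc_threshold)
  f2[iC] <- base
  f1[iC] <- base * ratio

  iA <- klass == "A"
  f2[iA] <- thr * stats::runif(sum(iA), 0.6, 5)
  f1[iA] <- f2[iA] * stats::runif(sum(iA), 1.1 * fc_threshold,
                                  4 * fc_threshold)

  iB <- klass == "B"
  f1[iB] <- thr * stats::runif(sum(iB), 0.6, 5)
  f2[iB] <- f1[iB] * stats::runif(sum(iB), 1.1 * fc_threshold,
                                  4 * fc_threshold)

  gene_id <- sprintf("g%05d", seq_len(n))
  df <- data.frame(gene_id = gene_id, f1, f2, stringsAsFactors = FALSE)
  names(df)[2:3] <- conditions
  list(expr = as_expression_table(df),
       classes = data.frame(gene_id = gene_id, class = klass,
                            stringsAsFactors = FALSE))
}

#' Generate a motif-hit table and binding map
#'
#' Hit counts per (gene, TFBS) are Poisson with a per-TFBS rate; positions
#' are uniform over the promoter window except for planted positionally
#' biased TFBSs, whose hits concentrate in one bin with probability
#' `bias_frac`; match scores are Beta-distributed in `[0, 1]`; each TFBS is
#' bound by 1-8 TFs drawn from the TF universe.
#'
#' @param genes Character vector of gene/promoter ids.
#' @param n_tfbs Number of TFBS (motif) identifiers.
#' @param tf_ids TF gene ids the binding map draws from (default
#'   `sprintf("TF%03d", 1:40)`).
#' @param half_window Promoter half-window in bp (default 5000).
#' @param bin_size Bin width the bias is planted against (default 500).
#' @param rate_range Range of per-TFBS Poisson hit rates per gene
#'   (default `c(0.3, 0.9)`).
#' @param n_biased Number of positionally biased TFBSs (default 2).
#' @param bias_frac Fraction of a biased TFBS's hits placed in its planted
#'   bin (default 0.85).
#' @param seed Integer seed.
#' @return List with `hits` ([motif_hits][as_motif_hits]), `binding` (list),
#'   and `bias` (data.frame `tfbs_id, bin` of planted biases).
#' @export
gen_hits <- function(genes, n_tfbs = 60, tf_ids = sprintf("TF%03d", 1:40),
                     half_window = 5000, bin_size = 500,
                     rate_range = c(0.3, 0.9), n_biased = 2,
                     bias_frac = 0.85, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  tfbs_ids <- sprintf("M%03d", seq_len(n_tfbs))
  nbins <- as.integer(ceiling(2 * half_window / bin_size))
  biased <- if (n_biased > 0)
    data.frame(tfbs_id = tfbs_ids[seq_len(n_biased)],
               bin = sample.int(nbins, n_biased, replace = TRUE),
               stringsAsFactors = FALSE)
  else data.frame(tfbs_id = character(0), bin = integer(0))

  rates <- stats::runif(n_tfbs, rate_range[1], rate_range[2])
  counts <- matrix(stats::rpois(length(genes) * n_tfbs,
                                rep(rates, each = length(genes))),
                   length(genes), n_tfbs)
  total <- sum(counts)
  gene_rep <- rep(rep(genes, n_tfbs), as.vector(counts))
  tfbs_rep <- rep(rep(tfbs_ids, each = length(genes)), as.vector(counts))
  pos <- stats::runif(total, -half_window, half_window)
  for (i in seq_len(nrow(biased))) {
    sel <- tfbs_rep == biased$tfbs_id[i]
    inbin <- sel & stats::runif(total) < bias_frac
    lo <- -half_window + (biased$bin[i] - 1L) * bin_size
    pos[inbin] <- stats::runif(sum(inbin), lo, min(lo + bin_size, half_window))
  }
  hits <- data.frame(gene_id = gene_rep, tfbs_id = tfbs_rep,
                     position = round(pos),
                     strand = sample(c("+", "-"), total, replace = TRUE),
                     score = stats::rbeta(total, 5, 1.5),
                     stringsAsFactors = FALSE)
  binding <- lapply(setNames(nm = tfbs_ids), function(j)
    sample(tf_ids, sample.int(min(8L, length(tf_ids)), 1L)))
  list(hits = as_motif_hits(hits, half_window = half_window),
       binding = binding, bias = biased)
}

#' Generate a binary TF-occupancy matrix with planted dependencies
#'
#' Columns are independent Bernoulli draws except the planted pairs, which
#' are sampled jointly with the requested within-stratum odds ratio at the
#' specified marginals (Plackett bivariate-Bernoulli construction); each TF
#' may appear in at most one planted pair.
#'
#' @param n_promoters Rows.
#' @param n_tfs Columns (named `TF001`, ... unless `tf_ids` given).
#' @param dependency_edges Two-column matrix/data.frame of TF indices or
#'   names to couple (default none).
#' @param odds_ratio Within-pair odds ratio (default 3; scalar or one per
#'   edge).
#' @param marginal Bernoulli marginal for every column (default 0.4).
#' @param tf_ids Optional column names.
#' @param seed Integer seed.
#' @return Binary integer matrix with `attr(, "dependency_edges")`.
#' @export
gen_occupancy <- function(n_promoters, n_tfs, dependency_edges = NULL,
                          odds_ratio = 3, marginal = 0.4, tf_ids = NULL,
                          seed = 1) {
  if (is.null(tf_ids)) tf_ids <- sprintf("TF%03d", seq_len(n_tfs))
  stopifnot(length(tf_ids) == n_tfs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  occ <- matrix(stats::rbinom(n_promoters * n_tfs, 1L, marginal),
                n_promoters, n_tfs, dimnames = list(NULL, tf_ids))
  edges <- NULL
  if (!is.null(dependency_edges) && NROW(dependency_edges) > 0) {
    edges <- as.matrix(dependency_edges)
    if (is.character(edges)) edges <- matrix(match(edges, tf_ids),
                                             ncol = 2L)
    storage.mode(edges) <- "integer"
    if (anyNA(edges)) stop("dependency edge references unknown TF")
    if (anyDuplicated(as.vector(edges)))
      stop("each TF may appear in at most one planted dependency pair")
    or <- rep_len(odds_ratio, nrow(edges))
    for (e in seq_len(nrow(edges))) {
      p11 <- .plackett_p11(marginal, marginal, or[e])
      p10 <- marginal - p11
      p01 <- marginal - p11
      p00 <- 1 - p11 - p10 - p01
      if (min(p11, p10, p01, p00) < 0)
        stop("infeasible odds ratio / marginal combination")
      cell <- sample.int(4L, n_promoters, replace = TRUE,
                         prob = c(p11, p10, p01, p00))
      occ[, edges[e, 1]] <- as.integer(cell %in% c(1L, 2L))
      occ[, edges[e, 2]] <- as.integer(cell %in% c(1L, 3L))
    }
    edges <- cbind(tf_ids[edges[, 1]], tf_ids[edges[, 2]])
  }
  attr(occ, "dependency_edges") <- edges
  occ
}

# Joint P(X=1, Y=1) for marginals pa, pb and odds ratio psi (Plackett).
.plackett_p11 <- function(pa, pb, psi) {
  if (abs(psi - 1) < 1e-12) return(pa * pb)
  s <- 1 + (psi - 1) * (pa + pb)
  (s - sqrt(s^2 - 4 * psi * (psi - 1) * pa * pb)) / (2 * (psi - 1))
}

#' Generate a response from planted main and pairwise effects
#'
#' `y = Xs beta_main + (standardized pairwise products) beta_pair + noise`,
#' where `Xs` is the column-standardized score matrix and the noise is
#' Gaussian with standard deviation `noise_frac * sd(signal)` — the same
#' transform scale and standardization the regression module fits on.
#'
#' @param tgas Genes x TFBS score matrix (e.g. from [compute_tgas()]).
#' @param main_terms Named numeric vector: planted main-effect coefficients
#'   keyed by TFBS column name.
#' @param pair_terms data.frame/matrix with columns `a, b, beta` (TFBS
#'   column names and the planted pairwise coefficient); may be empty.
#' @param noise_frac Noise sd as a fraction of the signal sd (default 0.2;
#'   0 gives a noiseless response).
#' @param seed Integer seed.
#' @return List with `y`, `signal`, `sigma` and the echoed truth.
#' @export
gen_response <- function(tgas, main_terms, pair_terms = NULL,
                         noise_frac = 0.2, seed = 1) {
  Xs <- standardize_columns(as.matrix(tgas))
  stopifnot(all(names(main_terms) %in% colnames(Xs)))
  signal <- drop(Xs[, names(main_terms), drop = FALSE] %*% main_terms)
  if (!is.null(pair_terms) && NROW(pair_terms) > 0) {
    pair_terms <- as.data.frame(pair_terms, stringsAsFactors = FALSE)
    names(pair_terms) <- c("a", "b", "beta")
    pair_terms$beta <- as.numeric(pair_terms$beta)
    for (e in seq_len(nrow(pair_terms))) {
      z <- Xs[, pair_terms$a[e]] * Xs[, pair_terms$b[e]]
      z <- (z - mean(z)) / stats::sd(z)
      signal <- signal + pair_terms$beta[e] * z
    }
  }
  sigma <- noise_frac * stats::sd(signal)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  y <- signal + stats::rnorm(length(signal), 0, sigma)
  list(y = y, signal = signal, sigma = sigma,
       main_terms = main_terms, pair_terms = pair_terms,
       noise_frac = noise_frac, seed = seed)
}

#' Desk-scale regression fixture with planted truth
#'
#' Generates hits for `n_genes` promoters, scores them (TGAS scheme I), and
#' plants `n_main` main effects (half positive, half negative) plus `n_pair`
#' pairwise effects among columns carrying no main effect, with Gaussian
#' noise at `noise_frac` of the signal sd.
#'
#' @param n_genes,n_tfbs Fixture size (defaults 400 x 60).
#' @param n_main,n_pair Planted effect counts (defaults 8 and 4).
#' @param beta Absolute planted coefficient (default 1).
#' @param noise_frac Noise fraction (default 0.2).
#' @param seed Integer seed controlling hits, truth placement and noise.
#' @return List with `X` (score matrix), `y`, `truth` (list: `main_terms`,
#'   `pair_terms`, `planted_tfbs`, `null_tfbs`, `sigma`), plus the
#'   underlying `hits` and `binding`.
#' @export
gen_regression_fixture <- function(n_genes = 400, n_tfbs = 60, n_main = 8,
                                   n_pair = 4, beta = 1, noise_frac = 0.2,
                                   seed = 1) {
  genes <- sprintf("g%05d", seq_len(n_genes))
  hb <- gen_hits(genes, n_tfbs = n_tfbs, n_biased = 0, seed = seed)
  X <- compute_tgas("I", hb$hits, genes = genes)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + 1L)
  cols <- sample(colnames(X))
  main_cols <- cols[seq_len(n_main)]
  pair_cols <- cols[n_main + seq_len(2 * n_pair)]
  main_terms <- setNames(beta * rep(c(1, -1), length.out = n_main),
                         main_cols)
  pair_terms <- data.frame(a = pair_cols[seq_len(n_pair)],
                           b = pair_cols[n_pair + seq_len(n_pair)],
                           beta = beta * rep(c(1, -1), length.out = n_pair),
                           stringsAsFactors = FALSE)
  resp <- gen_response(X, main_terms, pair_terms,
                       noise_frac = noise_frac, seed = seed + 2L)
  planted <- unique(c(main_cols, pair_cols))
  list(X = X, y = resp$y,
       truth = list(main_terms = main_terms, pair_terms = pair_terms,
                    planted_tfbs = planted,
                    null_tfbs = setdiff(colnames(X), planted),
                    sigma = resp$sigma, signal = resp$signal),
       hits = hb$hits, binding = hb$binding)
}

#' Generate a complete seeded input bundle with ground truth
#'
#' One call produces every input the pipeline consumes — expression table
#' with planted classes, motif hits and binding map for the DEG promoters,
#' and a TF-occupancy matrix with planted dependency edges — together with a
#' truth list sufficient to score recovery at every stage. Regenerating with
#' the same seed reproduces everything bit-identically.
#'
#' @param n_genes Genes in the expression table (default 2000).
#' @param class_fractions Class fractions (default `c(.2, .2, .35, .25)`,
#'   giving 400 genes in each DEG class).
#' @param n_tfbs,n_tfs TFBS and TF universe sizes (defaults 60 and 40).
#' @param n_promoters Occupancy matrix rows (default 2000).
#' @param n_dependency_edges Planted TF-TF dependencies (default 5).
#' @param odds_ratio Planted within-stratum odds ratio (default 3).
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, all tables are written as
#'   TSV plus a `truth.json` manifest.
#' @return List with `expr`, `classes`, `hits`, `binding`, `occupancy`,
#'   `truth`.
#' @export
simulate_dataset <- function(n_genes = 2000,
                             class_fractions = c(A = 0.2, B = 0.2,
                                                 C = 0.35, D = 0.25),
                             n_tfbs = 60, n_tfs = 40, n_promoters = 2000,
                             n_dependency_edges = 5, odds_ratio = 3,
                             seed = 1, out_dir = NULL) {
  ge <- gen_expression(n_genes, class_fractions, seed = seed)
  # TFs are named by gene ids so their expression weights are defined;
  # a few extra ids stay absent from the table (undetected TFs).
  old <- .Random.seed_save()
  set.seed(seed + 10L)
  n_undet <- max(1L, round(0.1 * n_tfs))
  tf_ids <- c(sample(ge$expr$gene_id, n_tfs - n_undet),
              sprintf("TFX%02d", seq_len(n_undet)))
  .Random.seed_restore(old)

  deg_genes <- ge$classes$gene_id[ge$classes$class %in% c("A", "B")]
  hb <- gen_hits(deg_genes, n_tfbs = n_tfbs, tf_ids = tf_ids,
                 seed = seed + 20L)
  dep <- if (n_dependency_edges > 0)
    cbind(seq_len(n_dependency_edges) * 2L - 1L,
          seq_len(n_dependency_edges) * 2L)
  else NULL
  occ <- gen_occupancy(n_promoters, n_tfs, dependency_edges = dep,
                       odds_ratio = odds_ratio, tf_ids = tf_ids,
                       seed = seed + 30L)
  truth <- list(seed = seed, n_genes = n_genes,
                class_fractions = as.list(class_fractions),
                classes = ge$classes,
                positional_bias = hb$bias,
                dependency_edges = attr(occ, "dependency_edges"),
                odds_ratio = odds_ratio,
                undetected_tfs = sprintf("TFX%02d", seq_len(n_undet)))
  out <- list(expr = ge$expr, classes = ge$classes, hits = hb$hits,
              binding = hb$binding, occupancy = occ, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_expression(ge$expr, file.path(out_dir, "expression.tsv"))
    write_hits(hb$hits, file.path(out_dir, "hits.tsv"))
    write_tsv(data.frame(
      tfbs_id = rep(names(hb$binding), lengths(hb$binding)),
      tf_gene_id = unlist(hb$binding, use.names = FALSE)),
      file.path(out_dir, "binding_map.tsv"))
    write_tsv(data.frame(promoter = seq_len(nrow(occ)), occ,
                         check.names = FALSE),
              file.path(out_dir, "occupancy.tsv"))
    tr <- truth
    tr$classes <- NULL  # regenerable; keep the JSON small
    jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_tsv(ge$classes, file.path(out_dir, "true_classes.tsv"))
  }
  out
}
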