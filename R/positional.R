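#' Observed vs randomized position histograms for one TFBS
#'
#' Bins the TSS-relative positions of one TFBS's hits over the promoter
#' window `[-half_window, half_window]`, and builds a reference histogram by
#' re-placing the same number of positions uniformly in the window. The
#' randomized histogram is the mean over `n_rand_draws` draws, which reduces
#' its Monte-Carlo variance; it has the same total mass as the observed one.
#'
#' @param hits A [motif_hits][as_motif_hits] table.
#' @param tfbs_id TFBS identifier to histogram (must have >= 1 hit).
#' @param half_window Promoter half-window in bp (defaults to the window the
#'   hits were read with).
#' @param bin_size Bin width in bp (default 500).
#' @param n_rand_draws Number of uniform randomizations averaged (default 100).
#' @param seed Integer seed making the randomized histogram reproducible.
#' @return Object of class `position_histograms`: list with `tfbs_id`,
#'   `bin_size`, `half_window`, `breaks`, `h_obs`, `h_rand`, `n_rand_draws`.
#' @export
build_histograms <- function(hits, tfbs_id, half_window = NULL,
                             bin_size = 500, n_rand_draws = 100, seed = 1) {
  if (is.null(half_window)) half_window <- attr(hits, "half_window")
  stopifnot(is.numeric(half_window), half_window > 0, bin_size > 0)
  pos <- hits$position[hits$tfbs_id == tfbs_id]
  if (length(pos) == 0L)
    stop("no hits for TFBS '", tfbs_id, "'")
  nbins <- as.integer(ceiling(2 * half_window / bin_size))
  bin_of <- function(p) pmin(nbins, floor((p + half_window) / bin_size) + 1L)
  h_obs <- tabulate(bin_of(pos), nbins = nbins)
  n <- length(pos)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  h_rand <- rep(0, nbins)
  for (d in seq_len(n_rand_draws)) {
    rp <- stats::runif(n, -half_window, half_window)
    h_rand <- h_rand + tabulate(bin_of(rp), nbins = nbins)
  }
  h_rand <- h_rand / n_rand_draws
  structure(list(tfbs_id = tfbs_id, bin_size = bin_size,
                 half_window = half_window,
                 breaks = seq(-half_window, by = bin_size,
                              length.out = nbins + 1L),
                 h_obs = h_obs, h_rand = h_rand,
                 n_rand_draws = n_rand_draws),
            class = "position_histograms")
}

#' Location-dependent weight of a hit position
#'
#' For the bin `m` containing `position`, returns
#' `L = h_obs(m) / (h_obs(m) + h_rand(m))`, a value in `[0, 1]`: 0.5 when the
#' observed density matches the uniform expectation, near 1 when hits
#' concentrate non-randomly in the bin, near 0 when the bin is depleted.
#' When both terms are zero (empty bin never sampled) L is 0.5.
#'
#' @param hist A `position_histograms` object from [build_histograms()].
#' @param position Position(s) in bp relative to the TSS; must lie inside the
#'   window.
#' @return Numeric vector of weights in `[0, 1]`.
#' @export
location_weight <- function(hist, position) {
  stopifnot(inherits(hist, "position_histograms"))
  hw <- hist$half_window
  if (any(abs(position) > hw))
    stop("position outside the ±", hw, " bp window")
  nbins <- length(hist$h_obs)
  m <- pmin(nbins, floor((position + hw) / hist$bin_size) + 1L)
  o <- hist$h_obs[m]
  r <- hist$h_rand[m]
  L <- ifelse(o + r == 0, 0.5, o / (o + r))
  as.numeric(L)
}

#' Location weights for every hit in a table
#'
#' Builds one histogram per TFBS (each with its own seed derived from
#' `seed`) and annotates every hit with its location weight L.
#'
#' @inheritParams build_histograms
#' @return The hits table with an added numeric column `L`; the per-TFBS
#'   histogram list is attached as `attr(, "histograms")`.
#' @export
location_weights_for_hits <- function(hits, half_window = NULL,
                                      bin_size = 500, n_rand_draws = 100,
                                      seed = 1) {
  if (is.null(half_window)) half_window <- attr(hits, "half_window")
  ids <- sort(unique(hits$tfbs_id))
  hists <- vector("list", length(ids))
  names(hists) <- ids
  L <- numeric(nrow(hits))
  for (i in seq_along(ids)) {
    h <- build_histograms(hits, ids[i], half_window = half_window,
                          bin_size = bin_size, n_rand_draws = n_rand_draws,
                          seed = seed + i)
    hists[[i]] <- h
    sel <- hits$tfbs_id == ids[i]
    L[sel] <- location_weight(h, hits$position[sel])
  }
  out <- hits
  out$L <- L
  attr(out, "histograms") <- hists
  out
}

#' Export a histogram table
#' @param hists List of `position_histograms` (e.g.
#'   `attr(location_weights_for_hits(...), "histograms")`).
#' @return data.frame `tfbs_id, bin_index, h_obs, h_rand, L`.
#' @export
histogram_table <- function(hists) {
  do.call(rbind, lapply(hists, function(h) {
    data.frame(tfbs_id = h$tfbs_id, bin_index = seq_along(h$h_obs),
               h_obs = h$h_obs, h_rand = h$h_rand,
               L = ifelse(h$h_obs + h$h_rand == 0, 0.5,
                          h$h_obs / (h$h_obs + h$h_rand)),
               stringsAsFactors = FALSE)
  }))
}

# Save/restore .Random.seed so seeded helpers don't disturb the caller's RNG.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
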