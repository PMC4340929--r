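## Spatial null model: how far is the nearest nest of a species that forages
## but does not nest on a tree, and is that nearer than expected when nests
## are reshuffled over trees with all row and column sums held fixed?

## Map F-N records to integer indices of a layer matrix.
.fn_index <- function(fn, layer) {
  list(t = match(fn$tree_id, rownames(layer)),
       s = match(fn$species_code, colnames(layer)))
}

## Distance from each F-N record's focal tree to the nearest *other* tree
## holding a nest of the record's species. NA when no other tree does (only
## possible for randomized layers: the F-N definition guarantees >= 1 nest
## off the focal tree in the observed layer).
.nearest_dist_core <- function(t_idx, s_idx, nest, dmat) {
  out <- rep(NA_real_, length(t_idx))
  for (s in unique(s_idx)) {
    rows <- which(s_idx == s)
    cand <- which(nest[, s] == 1)
    if (!length(cand)) next
    sub <- dmat[t_idx[rows], cand, drop = FALSE]
    self <- match(t_idx[rows], cand)           # focal tree never a candidate
    hit <- which(!is.na(self))
    if (length(hit)) sub[cbind(hit, self[hit])] <- Inf
    mins <- apply(sub, 1, min)
    mins[!is.finite(mins)] <- NA_real_
    out[rows] <- mins
  }
  out
}

## Per-radius mean nesting probability over F-N records:
## p(t, s, d) = (# other trees within d holding a nest of s) /
##              (# other trees within d), averaged over records with a
## nonzero denominator. Accounts for local tree density by construction.
## Split into a setup step (radius neighbourhoods, independent of the nest
## layer) and an evaluation step, so permutations only pay for the latter.
.profile_setup <- function(t_idx, s_idx, dmat, radii) {
  focal <- sort(unique(t_idx))
  within <- lapply(radii, function(r) {
    w <- (dmat[focal, , drop = FALSE] <= r) + 0
    w[cbind(seq_along(focal), focal)] <- 0   # exclude the focal tree
    w
  })
  list(radii = radii, focal = focal,
       frow = match(t_idx, focal),
       sp = sort(unique(s_idx)),
       scol = match(s_idx, sort(unique(s_idx))),
       within = within,
       denom = lapply(within, rowSums))
}

.profile_eval <- function(setup, nest) {
  nest_sub <- unname(nest[, setup$sp, drop = FALSE])
  k_n <- length(setup$radii)
  means <- numeric(k_n)
  nrec <- integer(k_n)
  ij <- cbind(setup$frow, setup$scol)
  for (k in seq_len(k_n)) {
    num <- setup$within[[k]] %*% nest_sub
    denom <- setup$denom[[k]][setup$frow]
    ok <- denom > 0
    means[k] <- if (any(ok)) mean(num[ij][ok] / denom[ok]) else NA_real_
    nrec[k] <- sum(ok)
  }
  list(mean = means, n_records = nrec)
}

.profile_core <- function(t_idx, s_idx, nest, dmat, radii) {
  .profile_eval(.profile_setup(t_idx, s_idx, dmat, radii), nest)
}

#' Nearest-nest distances for F-N records
#'
#' For each (tree, species) pair where the species forages but does not nest
#' on the tree, the Euclidean distance from the focal trunk to the nearest
#' other tree holding a nest of that species.
#'
#' @param x an `ant_community`
#' @param plot plot label
#' @param apply_exclusions drop `exclude_from_spatial` species (default TRUE)
#' @return data frame: `tree_id`, `species_code`, `plot`, `distance` (m);
#'   distances are strictly positive (coincident trunks aside) because the
#'   focal tree holds no nest of the species by definition
#' @export
nearest_nest_distances <- function(x, plot, apply_exclusions = TRUE) {
  fn <- derive_fn_records(x, plot, apply_exclusions)
  nest <- incidence_layer(x, plot, "nest")
  dmat <- pairwise_distances(x, plot)
  idx <- .fn_index(fn, nest)
  fn$distance <- .nearest_dist_core(idx$t, idx$s, nest, dmat)
  fn
}

#' Empirical cumulative distance curve
#'
#' Proportion of F-N records whose nearest conspecific nest lies within each
#' grid distance.
#'
#' @param distances data frame from [nearest_nest_distances()] (or any data
#'   frame with a `distance` column), no NA distances
#' @param grid evaluation distances in metres (default 0-30 m in 1 m steps)
#' @return data frame: `grid_m`, `cum` (in `[0, 1]`, nondecreasing)
#' @export
cumulative_curve <- function(distances, grid = seq(0, 30, by = 1)) {
  d <- if (is.data.frame(distances)) distances$distance else distances
  d <- d[!is.na(d)]
  if (!length(d)) .stopf("no F-N records to build a cumulative curve from")
  data.frame(grid_m = grid,
             cum = vapply(grid, function(g) mean(d <= g), numeric(1)))
}

#' Mean nesting probability of F-N species within increasing radii
#'
#' For each F-N record and radius d, the proportion of trees within d of the
#' focal tree (excluding the focal tree itself) that hold a nest of the
#' record's species; the per-radius value is the mean over records with at
#' least one candidate tree within d. Because the denominator is the local
#' tree count, the statistic is density-adjusted.
#'
#' @param x an `ant_community`
#' @param plot plot label
#' @param radii radii in metres, all positive (default `c(5, 10, ..., 30)`)
#' @param apply_exclusions drop `exclude_from_spatial` species (default TRUE)
#' @return data frame: `radius_m`, `mean_p`, `n_records`
#' @export
nesting_probability_profile <- function(x, plot, radii = seq(5, 30, by = 5),
                                        apply_exclusions = TRUE) {
  if (any(radii <= 0)) .stopf("radii must be positive")
  fn <- derive_fn_records(x, plot, apply_exclusions)
  if (!nrow(fn)) .stopf("no F-N records in plot '%s'", plot)
  nest <- incidence_layer(x, plot, "nest")
  dmat <- pairwise_distances(x, plot)
  idx <- .fn_index(fn, nest)
  pr <- .profile_core(idx$t, idx$s, nest, dmat, radii)
  data.frame(radius_m = radii, mean_p = pr$mean, n_records = pr$n_records)
}

#' Fixed-marginal (quasiswap-style) randomization of a binary incidence layer
#'
#' Draws randomized matrices with exactly the row and column sums of the
#' input. Mixing uses curveball trades (Strona et al. 2014): two random rows
#' exchange a random reshuffle of the columns held by exactly one of them,
#' which preserves both margins and has the uniform distribution over the
#' margin-preserving matrix class as its stationary distribution. Every
#' requested matrix is produced by an independent run of `n_trades` trades
#' restarted from the input, so draws are independent of each other — the
#' defining property of the quasiswap-style null used for co-occurrence
#' analysis (as opposed to a sequential swap chain).
#'
#' @param layer binary matrix (trees in rows, species in columns)
#' @param seed integer seed; the draw is a pure function of
#'   `(layer, seed, nsim, n_trades)` and the caller's RNG state is left
#'   untouched
#' @param nsim number of independent matrices
#' @param n_trades attempted trades per draw; the default,
#'   `max(100, 10 * sum(layer))`, scales the burn-in with matrix fill
#' @return for `nsim = 1` a single matrix with the input's dimnames;
#'   otherwise a 3-d array (trees x species x nsim)
#' @export
quasiswap_randomize <- function(layer, seed, nsim = 1, n_trades = NULL) {
  .assert_binary(layer, "incidence layer")
  stopifnot(is.numeric(seed), length(seed) == 1, nsim >= 1)
  if (is.null(n_trades)) n_trades <- max(100L, 10L * sum(layer))
  storage.mode(layer) <- "integer"
  sims <- .with_seed(seed,
    curveball_draws_cpp(layer, as.integer(nsim), as.integer(n_trades)))
  sims <- array(as.numeric(sims), dim = c(nrow(layer), ncol(layer), nsim),
                dimnames = c(dimnames(layer), list(NULL)))
  if (nsim == 1) sims[, , 1] else sims
}

#' Permutation null-model test of F-N spatial dependence
#'
#' Holds the observed F-N record list fixed and randomizes the plot's nest
#' incidence matrix `n_perm` times with fixed row and column sums
#' ([quasiswap_randomize()]). The chosen statistic is recomputed against each
#' randomized layer:
#' \describe{
#'   \item{`nearest_distance`}{per-record nearest-nest distances, summarised
#'     by the mean and the cumulative distance curve on `grid`;}
#'   \item{`probability_profile`}{per-radius mean nesting probability
#'     ([nesting_probability_profile()]).}
#' }
#' Envelopes are nearest-rank 2.5\%/97.5\% order statistics of the permuted
#' values (with `n_perm = 100`: the 3rd and 98th); the min-max band is also
#' reported. The observed mean is compared to the null means by a two-sided
#' empirical rank p-value (`(2 * min(rank, reverse rank)) / (n_perm + 1)`)
#' and by a Wilcoxon rank-sum test of the observed mean against the null
#' means.
#'
#' If a randomized layer leaves a record's species with nests only on the
#' record's focal tree, that record contributes no distance for that
#' permutation (the focal tree is never a candidate); such permuted means
#' average over the remaining records.
#'
#' @param x an `ant_community`
#' @param plot plot label
#' @param statistic `"nearest_distance"` or `"probability_profile"`
#' @param n_perm number of independent permutations, >= 2 (default 100)
#' @param seed integer seed (required; drives all randomization)
#' @param radii radii for the probability profile
#' @param grid distance grid for the cumulative curve
#' @param apply_exclusions drop `exclude_from_spatial` species (default TRUE)
#' @return object of class `ant_null_test`; see Details for components
#'
#' @details The returned list carries `statistic`, `plot`, `n_perm`, `seed`,
#' `n_records`, `fn` (the fixed record list) and, depending on the statistic:
#' for `nearest_distance`: `observed_mean`, `null_means`, `null_mean`,
#' `rank_p`, `ranksum` (list `W`, `p`), `below_envelope` /`above_envelope`
#' flags for the mean, and `curve` (grid-wise observed and null bands);
#' for `probability_profile`: `profile`, a data frame with per-radius
#' observed mean, null mean, envelope bounds, min-max band, outside flag and
#' rank p.
#' @export
null_test <- function(x, plot,
                      statistic = c("nearest_distance", "probability_profile"),
                      n_perm = 100, seed, radii = seq(5, 30, by = 5),
                      grid = seq(0, 30, by = 1), apply_exclusions = TRUE) {
  statistic <- match.arg(statistic)
  if (n_perm < 2) .stopf("n_perm must be >= 2")
  if (missing(seed)) .stopf("an explicit integer seed is required")
  fn <- derive_fn_records(x, plot, apply_exclusions)
  if (!nrow(fn)) .stopf("no F-N records in plot '%s'", plot)
  nest <- incidence_layer(x, plot, "nest")
  dmat <- pairwise_distances(x, plot)
  idx <- .fn_index(fn, nest)
  sims <- quasiswap_randomize(nest, seed = seed, nsim = n_perm)

  out <- list(statistic = statistic, plot = plot, n_perm = n_perm,
              seed = seed, n_records = nrow(fn), fn = fn)

  if (statistic == "nearest_distance") {
    d_obs <- .nearest_dist_core(idx$t, idx$s, nest, dmat)
    obs_curve <- cumulative_curve(d_obs, grid)
    null_means <- numeric(n_perm)
    null_curves <- matrix(NA_real_, n_perm, length(grid))
    for (j in seq_len(n_perm)) {
      dj <- .nearest_dist_core(idx$t, idx$s, sims[, , j], dmat)
      null_means[j] <- mean(dj, na.rm = TRUE)
      null_curves[j, ] <- cumulative_curve(dj, grid)$cum
    }
    env <- .envelope(null_curves)
    out$distances <- cbind(fn, distance = d_obs)
    out$observed_mean <- mean(d_obs)
    out$null_means <- null_means
    out$null_mean <- mean(null_means)
    out$rank_p <- .rank_p(out$observed_mean, null_means)
    wt <- suppressWarnings(stats::wilcox.test(out$observed_mean, null_means))
    out$ranksum <- list(W = unname(wt$statistic), p = wt$p.value)
    mean_env <- .nearest_rank(null_means, c(0.025, 0.975))
    out$below_envelope <- out$observed_mean < mean_env[1]
    out$above_envelope <- out$observed_mean > mean_env[2]
    out$mean_envelope <- mean_env
    out$curve <- data.frame(grid_m = grid, observed_cum = obs_curve$cum,
                            null_mean = colMeans(null_curves),
                            env_lo = env$lo, env_hi = env$hi,
                            null_min = env$min, null_max = env$max)
  } else {
    if (any(radii <= 0)) .stopf("radii must be positive")
    setup <- .profile_setup(idx$t, idx$s, dmat, radii)
    obs <- .profile_eval(setup, nest)
    null_profiles <- matrix(NA_real_, n_perm, length(radii))
    for (j in seq_len(n_perm))
      null_profiles[j, ] <- .profile_eval(setup, sims[, , j])$mean
    env <- .envelope(null_profiles)
    rank_p <- vapply(seq_along(radii), function(k)
      .rank_p(obs$mean[k], null_profiles[, k]), numeric(1))
    out$profile <- data.frame(
      radius_m = radii, observed_mean = obs$mean,
      n_records = obs$n_records,
      null_mean = colMeans(null_profiles, na.rm = TRUE),
      env_lo = env$lo, env_hi = env$hi,
      null_min = env$min, null_max = env$max,
      outside_envelope = obs$mean < env$lo | obs$mean > env$hi,
      rank_p = rank_p)
    out$null_profiles <- null_profiles
  }
  class(out) <- "ant_null_test"
  out
}

#' @export
print.ant_null_test <- function(x, ...) {
  cat(sprintf("Fixed-marginal null-model test (quasiswap, %d permutations, seed %s)\n",
              x$n_perm, format(x$seed)))
  cat(sprintf("  plot '%s': %d F-N records\n", x$plot, x$n_records))
  if (x$statistic == "nearest_distance") {
    cat(sprintf("  observed mean nearest-nest distance: %.2f m (null mean %.2f m)\n",
                x$observed_mean, x$null_mean))
    cat(sprintf("  envelope for the mean: [%.2f, %.2f] m -> %s\n",
                x$mean_envelope[1], x$mean_envelope[2],
                if (x$below_envelope) "below envelope (nests nearer than expected)"
                else if (x$above_envelope) "above envelope"
                else "inside envelope"))
    cat(sprintf("  rank p = %.4f; rank-sum W = %s, p = %.4f\n",
                x$rank_p, format(x$ranksum$W), x$ranksum$p))
  } else {
    cat("  per-radius mean nesting probability of F-N species:\n")
    pr <- x$profile
    for (k in seq_len(nrow(pr)))
      cat(sprintf("    d <= %2g m: observed %.3f, null %.3f [%.3f, %.3f]%s\n",
                  pr$radius_m[k], pr$observed_mean[k], pr$null_mean[k],
                  pr$env_lo[k], pr$env_hi[k],
                  if (isTRUE(pr$outside_envelope[k])) "  *outside*" else ""))
  }
  invisible(x)
}
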