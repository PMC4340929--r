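## Incidence-based diversity: richness per tree, rarefaction, Chao2,
## shared species and occupancy summaries. Trees are the sampling units.

#' Incidence frequency summary of a binary layer
#'
#' Collapses a trees-by-species binary matrix to the quantities the
#' incidence-based estimators need: number of samples H, observed richness,
#' per-species incidence frequencies Y, and the counts of uniques (q1,
#' species in exactly one tree) and duplicates (q2, exactly two trees).
#'
#' @param m binary matrix (trees in rows, species in columns), e.g. from
#'   [incidence_layer()]
#' @return object of class `incidence_summary`: list with `H`, `S_obs`,
#'   `Y` (named incidence frequencies, zero-frequency species dropped),
#'   `q1`, `q2`
#' @export
incidence_summary <- function(m) {
  .assert_binary(m, "incidence layer")
  Y <- colSums(m)
  Y <- Y[Y > 0]
  structure(list(H = nrow(m), S_obs = length(Y), Y = Y,
                 q1 = sum(Y == 1), q2 = sum(Y == 2)),
            class = "incidence_summary")
}

#' @export
print.incidence_summary <- function(x, ...) {
  cat(sprintf("incidence summary: H = %d trees, S_obs = %d, q1 = %d, q2 = %d\n",
              x$H, x$S_obs, x$q1, x$q2))
  invisible(x)
}

#' Mao Tau expected richness for h pooled samples
#'
#' Analytic sample-based rarefaction: the expected number of species found in
#' a random subset of `h` of the `H` samples,
#' \deqn{\tau(h) = \sum_i \left[1 - \binom{H - Y_i}{h} / \binom{H}{h}\right],}
#' with binomial coefficients evaluated in log space and \eqn{\binom{n}{k} = 0}
#' for \eqn{k > n}. At `h = H` this equals the observed richness; at `h = 1`
#' it is the mean per-sample richness.
#'
#' @param summary an [incidence_summary()]
#' @param h number of samples, vectorised, each in `1..H`
#' @return numeric vector of expected richness values
#' @export
mao_tau <- function(summary, h) {
  stopifnot(inherits(summary, "incidence_summary"))
  if (any(h < 1 | h > summary$H | h != round(h)))
    .stopf("h must be integer(s) in 1..H = %d", summary$H)
  H <- summary$H
  Y <- summary$Y
  vapply(h, function(hh) {
    lr <- lchoose(H - Y, hh) - lchoose(H, hh)   # -Inf when h > H - Y_i
    sum(1 - exp(lr))
  }, numeric(1))
}

#' Sample-based rarefaction curve of one layer
#'
#' @param x an `ant_community`
#' @param plot plot label
#' @param layer `"all"`, `"nest"` or `"forage"`
#' @param h grid of sample counts (default `1:H`)
#' @return data frame with columns `plot`, `layer`, `h`, `tau`
#' @export
rarefaction_curve <- function(x, plot, layer = c("all", "nest", "forage"),
                              h = NULL) {
  layer <- match.arg(layer)
  s <- incidence_summary(incidence_layer(x, plot, layer))
  if (is.null(h)) h <- seq_len(s$H)
  data.frame(plot = plot, layer = layer, h = h, tau = mao_tau(s, h))
}

#' Chao2 incidence-based richness estimate
#'
#' Nonparametric lower-bound estimate of total species richness from
#' incidence frequencies, with the (H-1)/H small-sample correction:
#' classic variant \eqn{S_{obs} + \frac{H-1}{H}\, q_1^2 / (2 q_2)} (requires
#' `q2 > 0`; otherwise falls back to the bias-corrected variant with a
#' warning), bias-corrected variant
#' \eqn{S_{obs} + \frac{H-1}{H}\, q_1 (q_1 - 1) / (2 (q_2 + 1))}.
#' The SD comes from the incidence variance formulas of Chao (1987) matching
#' the variant. With `q1 = 0` there is no undetected-species signal and the
#' estimate equals `S_obs` with SD 0.
#'
#' @param summary an [incidence_summary()]
#' @param variant `"classic"` or `"bias_corrected"`
#' @return list with `estimate`, `sd`, `variant` (the variant actually used),
#'   `S_obs`, `H`, `q1`, `q2`
#' @export
chao2 <- function(summary, variant = c("classic", "bias_corrected")) {
  stopifnot(inherits(summary, "incidence_summary"))
  variant <- match.arg(variant)
  H <- summary$H
  if (H < 1) .stopf("need at least one sample")
  S <- summary$S_obs
  q1 <- summary$q1
  q2 <- summary$q2
  A <- (H - 1) / H

  if (variant == "classic" && q2 == 0) {
    .warnf("classic Chao2 undefined with q2 = 0; using bias_corrected variant")
    variant <- "bias_corrected"
  }

  if (q1 == 0) {
    est <- S
    v <- 0
  } else if (variant == "classic") {
    r <- q1 / q2
    est <- S + A * q1^2 / (2 * q2)
    v <- q2 * (A * r^2 / 2 + A^2 * r^3 + A^2 * r^4 / 4)
  } else {
    est <- S + A * q1 * (q1 - 1) / (2 * (q2 + 1))
    v <- A   * q1 * (q1 - 1)     / (2 * (q2 + 1)) +
         A^2 * q1 * (2 * q1 - 1)^2 / (4 * (q2 + 1)^2) +
         A^2 * q1^2 * q2 * (q1 - 1)^2 / (4 * (q2 + 1)^4)
  }
  list(estimate = est, sd = sqrt(v), variant = variant,
       S_obs = S, H = H, q1 = q1, q2 = q2)
}

#' Per-tree species richness by layer
#'
#' Counts species per tree for the requested layers: `all` (union of nesting
#' and foraging; a species doing both on one tree counts once), `nest`,
#' `forage`, and `fn` (species foraging but not nesting on the tree that nest
#' on >= 1 tree of the plot — the F-N definition). Trees with no ants are
#' included with count 0.
#'
#' @param x an `ant_community`
#' @param plot plot label
#' @param layers subset of `c("all", "nest", "forage", "fn")`
#' @param apply_exclusions drop `exclude_from_spatial` species from the `fn`
#'   layer (default `FALSE`: the per-tree summaries keep all species; the
#'   exclusion list is a spatial-analysis concern)
#' @return data frame: `tree_id`, `plot`, one integer column per layer
#' @export
per_tree_richness <- function(x, plot,
                              layers = c("all", "nest", "forage", "fn"),
                              apply_exclusions = FALSE) {
  layers <- match.arg(layers, several.ok = TRUE)
  i <- .check_plot(x, plot)
  nest <- x$nest[i, , drop = FALSE]
  forage <- x$forage[i, , drop = FALSE]
  out <- data.frame(tree_id = rownames(nest), plot = plot,
                    stringsAsFactors = FALSE)
  for (ly in layers) {
    out[[ly]] <- switch(ly,
      all = as.integer(rowSums(pmax(nest, forage))),
      nest = as.integer(rowSums(nest)),
      forage = as.integer(rowSums(forage)),
      fn = {
        keep <- colSums(nest) >= 1
        if (apply_exclusions) keep <- keep & !x$species$exclude_from_spatial
        fnm <- (forage == 1 & nest == 0)
        fnm[, !keep] <- FALSE
        as.integer(rowSums(fnm))
      })
  }
  out
}

#' Plot-level mean, SE and max of per-tree richness
#'
#' @param richness output of [per_tree_richness()]
#' @return data frame: `plot`, `layer`, `mean`, `se`, `max`
#' @export
richness_summary <- function(richness) {
  layers <- setdiff(names(richness), c("tree_id", "plot"))
  do.call(rbind, lapply(layers, function(ly) {
    v <- richness[[ly]]
    data.frame(plot = richness$plot[1], layer = ly,
               mean = mean(v), se = .se(v), max = max(v))
  }))
}

#' Species shared between two plots
#'
#' A species is counted as present in a plot when it has >= 1 occurrence in
#' the union of the requested layers there.
#'
#' @param x an `ant_community`
#' @param plot_a,plot_b plot labels
#' @param layers layers whose union defines presence (default both)
#' @return list with `count` and the sorted `species` codes
#' @export
shared_species <- function(x, plot_a, plot_b,
                           layers = c("nest", "forage")) {
  pres <- function(plot) {
    m <- Reduce(pmax, lapply(layers, function(ly) incidence_layer(x, plot, ly)))
    colnames(m)[colSums(m) > 0]
  }
  sp <- sort(intersect(pres(plot_a), pres(plot_b)))
  list(count = length(sp), species = sp)
}

#' Per-species occupancy and abundance summary for one plot
#'
#' Occupancy is the number of trees occupied (column sums) per layer.
#' When count layers are present their per-species totals (numbers of nests,
#' forager individuals) and grand totals are reported; otherwise totals are
#' `NA`. Invasive fractions are the share of occurrences (and individuals,
#' when counted) belonging to species flagged invasive.
#'
#' @param x an `ant_community`
#' @param plot plot label
#' @return list with `species` (per-species data frame, occupancy-ranked),
#'   `totals` (named vector: nests, foragers) and `invasive_fraction`
#'   (named vector: share of occurrences and of individuals)
#' @export
occupancy_summary <- function(x, plot) {
  i <- .check_plot(x, plot)
  nest <- x$nest[i, , drop = FALSE]
  forage <- x$forage[i, , drop = FALSE]
  df <- data.frame(species_code = colnames(nest),
                   occupancy_nest = as.integer(colSums(nest)),
                   occupancy_forage = as.integer(colSums(forage)),
                   occupancy_all = as.integer(colSums(pmax(nest, forage))),
                   invasive = x$species$invasive,
                   stringsAsFactors = FALSE)
  nests_total <- foragers_total <- NA_real_
  df$nests <- df$foragers <- NA_real_
  if (!is.null(x$counts$nest)) {
    cm <- x$counts$nest[i, , drop = FALSE]
    df$nests <- colSums(cm)
    nests_total <- sum(cm)
  }
  if (!is.null(x$counts$forage)) {
    cm <- x$counts$forage[i, , drop = FALSE]
    df$foragers <- colSums(cm)
    foragers_total <- sum(cm)
  }
  occ_share <- if (sum(df$occupancy_all) > 0)
    sum(df$occupancy_all[df$invasive]) / sum(df$occupancy_all) else NA_real_
  ind_share <- if (!is.na(foragers_total) && foragers_total > 0)
    sum(df$foragers[df$invasive]) / foragers_total else NA_real_
  df <- df[order(-df$occupancy_all, df$species_code), , drop = FALSE]
  rownames(df) <- NULL
  list(species = df,
       totals = c(nests = nests_total, foragers = foragers_total),
       invasive_fraction = c(occurrences = occ_share, individuals = ind_share))
}
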