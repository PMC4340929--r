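## Stem-map and incidence-layer simulator. Foraging is generated
## mechanistically from nests through a distance-decay kernel, so recovering
## the spatial signal with the null model is a genuine inference problem.

## Evaluate expr under a fixed seed, leaving the caller's RNG state intact.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Configuration for the synthetic forest generator
#'
#' All spatial units are metres. Defaults emulate a 0.32 ha rainforest
#' census plot: a 40 x 80 m rectangle with a few hundred mapped stems,
#' a strongly skewed (log-series) species occupancy distribution, and
#' foraging spreading from nests under an exponential distance-decay kernel.
#'
#' @param plot_width,plot_height plot dimensions (m)
#' @param n_trees number of stems
#' @param position stem placement: `"uniform"` (binomial process) or
#'   `"thomas"` (Thomas cluster process: Poisson parents, Gaussian offspring)
#' @param parent_intensity Thomas parents per square metre
#' @param offspring_sd Thomas offspring dispersal SD (m)
#' @param n_species species-pool size
#' @param logseries_x log-series parameter in (0, 1) for per-species tree
#'   occupancy (larger = longer common-species tail); draws are truncated at
#'   `n_trees`
#' @param nest_aggregation within-species nest clustering range (m): 0 places
#'   each species' occupied trees as a uniform random subset; > 0 samples
#'   trees with probability decaying as `exp(-d/nest_aggregation)` from a
#'   random seed tree
#' @param forage_lambda foraging kernel range lambda (m, > 0): a nest on tree
#'   u marks foraging on tree t with probability
#'   `forage_emission * exp(-d(u, t) / forage_lambda)`, combined
#'   independently over the species' nests
#' @param forage_emission kernel amplitude in `[0, 1]`; 0 switches the kernel
#'   off
#' @param tourist_rate per-(tree, nesting species) probability of a uniform
#'   "tourist" foraging record independent of distance (out-of-plot or
#'   ground-based foragers)
#' @param ground_forager add one ground-nesting super-colony species
#'   (flagged `exclude_from_spatial` and invasive) with 4 satellite nests and
#'   widespread trunk foraging
#' @param species_offset offset into the shared species-code namespace
#'   (`SIMU###`); plots simulated with overlapping code ranges share those
#'   species, which is how the two-plot presets control their shared-species
#'   count
#' @param plot_label plot label written into the tree table
#' @param seed integer master seed; generation is a pure function of
#'   `(config, seed)`
#' @return validated list of class `sim_config`
#' @export
simulation_config <- function(plot_width = 40, plot_height = 80,
                              n_trees = 350,
                              position = c("uniform", "thomas"),
                              parent_intensity = 0.005, offspring_sd = 4,
                              n_species = 60, logseries_x = 0.95,
                              nest_aggregation = 0,
                              forage_lambda = 5, forage_emission = 0.08,
                              tourist_rate = 0.005,
                              ground_forager = FALSE, species_offset = 0,
                              plot_label = "plot1", seed = NULL) {
  position <- match.arg(position)
  cfg <- list(plot_width = plot_width, plot_height = plot_height,
              n_trees = as.integer(n_trees), position = position,
              parent_intensity = parent_intensity,
              offspring_sd = offspring_sd,
              n_species = as.integer(n_species),
              logseries_x = logseries_x,
              nest_aggregation = nest_aggregation,
              forage_lambda = forage_lambda,
              forage_emission = forage_emission,
              tourist_rate = tourist_rate,
              ground_forager = isTRUE(ground_forager),
              species_offset = as.integer(species_offset),
              plot_label = plot_label, seed = seed)
  if (cfg$plot_width <= 0 || cfg$plot_height <= 0)
    .stopf("plot dimensions must be positive")
  if (cfg$n_trees < 1 || cfg$n_species < 1)
    .stopf("n_trees and n_species must be >= 1")
  if (cfg$logseries_x <= 0 || cfg$logseries_x >= 1)
    .stopf("logseries_x must be in (0, 1)")
  if (cfg$forage_lambda <= 0) .stopf("forage_lambda must be > 0")
  if (cfg$forage_emission < 0 || cfg$forage_emission > 1 ||
      cfg$tourist_rate < 0 || cfg$tourist_rate > 1)
    .stopf("forage_emission and tourist_rate must be in [0, 1]")
  if (cfg$nest_aggregation < 0 || cfg$parent_intensity <= 0 ||
      cfg$offspring_sd <= 0 || cfg$species_offset < 0)
    .stopf("rates and ranges must be nonnegative (cluster parameters positive)")
  class(cfg) <- "sim_config"
  cfg
}

#' Scenario presets rehearsing a two-plot rainforest census
#'
#' `"primary_like"` emulates an old-growth 0.32 ha plot (389 stems, species
#' pool of 102, strong 5 m foraging kernel); `"secondary_like"` a young
#' secondary plot (295 stems, 50 species incl. one ground-nesting
#' super-colony species flagged for exclusion from spatial analyses, weaker
#' 10 m kernel, more tourist foraging). The secondary pool overlaps the
#' primary one in 26 species codes, so the combined census has 126 species
#' of which 26 are shared.
#'
#' @param preset `"primary_like"` or `"secondary_like"`
#' @param seed integer master seed
#' @return a [simulation_config()]
#' @export
preset_config <- function(preset = c("primary_like", "secondary_like"), seed) {
  preset <- match.arg(preset)
  switch(preset,
    primary_like = simulation_config(
      n_trees = 389, n_species = 102, logseries_x = 0.95,
      nest_aggregation = 0, forage_lambda = 5, forage_emission = 0.08,
      tourist_rate = 0.005, plot_label = "primary", seed = seed),
    secondary_like = simulation_config(
      n_trees = 295, n_species = 49, logseries_x = 0.96,
      nest_aggregation = 0, forage_lambda = 10, forage_emission = 0.03,
      tourist_rate = 0.01, ground_forager = TRUE, species_offset = 76,
      plot_label = "secondary", seed = seed))
}

#' Generate a mapped stem table
#'
#' Positions are uniform or Thomas-clustered inside the plot rectangle; DBH
#' is right-skewed (5 cm census floor plus a lognormal), so that typically
#' over half of stems have DBH <= 10 cm; a noisy allometric tree height is
#' added.
#'
#' @param config a [simulation_config()]
#' @param seed overrides `config$seed`
#' @return data frame: `tree_id`, `plot`, `x`, `y`, `dbh`, `height_m`
#' @export
generate_forest <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) .stopf("a seed is required for generation")
  .with_seed(seed, {
    n <- config$n_trees
    w <- config$plot_width; h <- config$plot_height
    if (config$position == "uniform") {
      x <- runif(n, 0, w); y <- runif(n, 0, h)
    } else {
      n_par <- max(1L, rpois(1, config$parent_intensity * w * h))
      px <- runif(n_par, 0, w); py <- runif(n_par, 0, h)
      x <- y <- numeric(n)
      for (i in seq_len(n)) {
        repeat {
          p <- sample.int(n_par, 1)
          xi <- rnorm(1, px[p], config$offspring_sd)
          yi <- rnorm(1, py[p], config$offspring_sd)
          if (xi >= 0 && xi <= w && yi >= 0 && yi <= h) break
        }
        x[i] <- xi; y[i] <- yi
      }
    }
    dbh <- 5 + rlnorm(n, meanlog = log(4), sdlog = 0.9)
    height <- exp(0.6 + 0.75 * log(dbh) + rnorm(n, 0, 0.25))
    data.frame(tree_id = sprintf("%s-T%04d", config$plot_label, seq_len(n)),
               plot = config$plot_label, x = x, y = y,
               dbh = dbh, height_m = height, stringsAsFactors = FALSE)
  })
}

#' Generate a nest incidence layer over a stem table
#'
#' Per-species tree occupancy is drawn from a log-series distribution
#' truncated at the number of trees (a few common species, a long tail of
#' singletons). With `nest_aggregation > 0` a species' occupied trees cluster
#' around a random seed tree; with 0 they are a uniform random subset, which
#' makes the generated matrix (conditionally on its margins) a uniform draw
#' from the fixed-margin class — the regime used for null-model calibration.
#'
#' @param trees stem table from [generate_forest()]
#' @param config a [simulation_config()]
#' @param seed overrides `config$seed + 1`
#' @return binary matrix, trees x species
#' @export
generate_nest_layer <- function(trees, config,
                                seed = if (!is.null(config$seed))
                                  config$seed + 1L else NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) .stopf("a seed is required for generation")
  n <- nrow(trees)
  n_sp <- config$n_species
  if (n_sp > n) {
    .warnf("n_species (%d) exceeds n_trees (%d); truncating species pool",
           n_sp, n)
    n_sp <- n
  }
  .with_seed(seed, {
    occ <- .rlogseries(n_sp, config$logseries_x, kmax = n)
    m <- matrix(0, n, n_sp,
                dimnames = list(trees$tree_id,
                                sprintf("SIMU%03d",
                                        config$species_offset + seq_len(n_sp))))
    agg <- config$nest_aggregation
    dmat <- if (agg > 0) as.matrix(stats::dist(cbind(trees$x, trees$y)))
            else NULL
    for (s in seq_len(n_sp)) {
      k <- occ[s]
      if (agg > 0 && k > 1) {
        first <- sample.int(n, 1)
        wgt <- exp(-dmat[first, ] / agg)
        wgt[first] <- 0
        rest <- sample.int(n, k - 1, prob = wgt)
        m[c(first, rest), s] <- 1
      } else {
        m[sample.int(n, k), s] <- 1
      }
    }
    m
  })
}

#' Generate a foraging incidence layer from nests
#'
#' Every nest marks foraging on its own tree; other trees receive foraging
#' of the species with probability
#' `1 - prod(1 - forage_emission * exp(-d / forage_lambda))` over the
#' species' nest trees, plus a uniform tourist probability independent of
#' distance. The result is binary.
#'
#' @param trees stem table
#' @param nest binary nest layer from [generate_nest_layer()]
#' @param config a [simulation_config()]
#' @param seed overrides `config$seed + 2`
#' @return binary matrix, trees x species, `>= nest` cell-wise
#' @export
generate_forage_layer <- function(trees, nest, config,
                                  seed = if (!is.null(config$seed))
                                    config$seed + 2L else NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) .stopf("a seed is required for generation")
  .assert_binary(nest, "nest layer")
  .with_seed(seed, {
    n <- nrow(nest)
    dmat <- as.matrix(stats::dist(cbind(trees$x, trees$y)))
    p_forage <- matrix(0, n, ncol(nest), dimnames = dimnames(nest))
    if (config$forage_emission > 0) {
      ker <- config$forage_emission * exp(-dmat / config$forage_lambda)
      L <- log1p(-pmin(ker, 1 - 1e-12))
      p_forage <- 1 - exp(unname(L) %*% nest)
      rownames(p_forage) <- rownames(nest)
    }
    draw <- (p_forage > matrix(runif(length(p_forage)), n)) + 0
    if (config$tourist_rate > 0) {
      nesting_sp <- colSums(nest) > 0
      tour <- matrix(runif(length(p_forage)), n) < config$tourist_rate
      tour[, !nesting_sp] <- FALSE
      draw <- pmax(draw, tour + 0)
    }
    pmax(draw, nest)
  })
}

#' Simulate a complete synthetic community
#'
#' Runs [generate_forest()], [generate_nest_layer()] and
#' [generate_forage_layer()] under sub-seeds derived from the master seed and
#' assembles an [ant_community()]. With `ground_forager = TRUE` one extra
#' species (code `GRND001`) is appended: 4 satellite nests and uniform trunk
#' foraging on ~40\% of stems, flagged invasive and `exclude_from_spatial`.
#'
#' @param config a [simulation_config()] (or a preset name via
#'   [preset_config()])
#' @param seed overrides `config$seed`
#' @return list with `community` (an `ant_community`) and `truth` (the
#'   config plus the realized per-species nest occupancy)
#' @export
simulate_community <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) .stopf("a seed is required for generation")
  config$seed <- seed
  trees <- generate_forest(config, seed)
  nest <- generate_nest_layer(trees, config, seed + 1L)
  forage <- generate_forage_layer(trees, nest, config, seed + 2L)
  species <- data.frame(species_code = colnames(nest),
                        full_name = paste("Simulated species",
                                          seq_len(ncol(nest))),
                        invasive = FALSE, exclude_from_spatial = FALSE,
                        stringsAsFactors = FALSE)
  if (config$ground_forager) {
    gr <- .with_seed(seed + 3L, {
      nest_col <- numeric(nrow(trees))
      nest_col[sample.int(nrow(trees), min(4L, nrow(trees)))] <- 1
      forage_col <- pmax((runif(nrow(trees)) < 0.4) + 0, nest_col)
      cbind(nest = nest_col, forage = forage_col)
    })
    nest <- cbind(nest, GRND001 = gr[, "nest"])
    forage <- cbind(forage, GRND001 = gr[, "forage"])
    species <- rbind(species, data.frame(
      species_code = "GRND001",
      full_name = "Simulated ground-nesting super-colony species",
      invasive = TRUE, exclude_from_spatial = TRUE))
  }
  community <- ant_community(trees, nest, forage, species)
  truth <- list(config = config,
                nest_occupancy = colSums(nest),
                kernel = c(lambda = config$forage_lambda,
                           emission = config$forage_emission,
                           tourist_rate = config$tourist_rate))
  list(community = community, truth = truth)
}

#' Combine per-plot communities into one dataset
#'
#' Stacks tree tables and block-aligns the incidence layers on the union of
#' the species registers (absent species become all-zero columns).
#'
#' @param ... two or more `ant_community` objects with disjoint tree ids and
#'   distinct plot labels
#' @return an `ant_community`
#' @export
combine_communities <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 2, all(vapply(xs, inherits, TRUE, "ant_community")))
  trees <- do.call(rbind, lapply(xs, `[[`, "trees"))
  sp <- Reduce(union, lapply(xs, function(x) colnames(x$nest)))
  nest <- do.call(rbind, lapply(xs, function(x) .expand_species(x$nest, sp)))
  forage <- do.call(rbind, lapply(xs, function(x) .expand_species(x$forage, sp)))
  meta <- do.call(rbind, lapply(xs, `[[`, "species"))
  meta <- meta[!duplicated(meta$species_code), , drop = FALSE]
  ant_community(trees, nest, forage, meta)
}
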