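## Orchestration: a flat YAML run configuration drives simulation, diversity
## summaries and the spatial null model, writing long-format CSVs plus a
## provenance sidecar (config copy, config hash, seed, package version).

#' Read and validate a run configuration
#'
#' The YAML file names either an input dataset (`input:` with `trees`,
#' `nest`, `forage` and optional `species` CSV paths) or a simulation
#' (`simulate: presets: [primary_like, secondary_like]`), plus analysis
#' settings: `seed` (required), `n_perm`, `radii`, `grid_max`, `grid_step`,
#' `plots`, `apply_exclusions`, `outdir`.
#'
#' @param path YAML file path, or a named list with the same structure
#' @return validated list of class `run_config`
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) .stopf("config file not found: %s", path)
    yaml::read_yaml(path)
  } else as.list(path)
  if (is.null(cfg$seed))
    .stopf("config must set an integer random seed ('seed:')")
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_perm <- as.integer(cfg$n_perm %||% 100L)
  if (cfg$n_perm < 2) .stopf("n_perm must be >= 2")
  cfg$radii <- as.numeric(cfg$radii %||% seq(5, 30, by = 5))
  if (any(cfg$radii <= 0)) .stopf("radii must be positive")
  cfg$grid_max <- as.numeric(cfg$grid_max %||% 30)
  cfg$grid_step <- as.numeric(cfg$grid_step %||% 1)
  cfg$apply_exclusions <- isTRUE(cfg$apply_exclusions %||% TRUE)
  cfg$outdir <- cfg$outdir %||% "arborant-out"
  if (is.null(cfg$input) && is.null(cfg$simulate))
    .stopf("config needs an 'input:' or a 'simulate:' section")
  if (!is.null(cfg$input)) {
    need <- c("trees", "nest", "forage")
    miss <- setdiff(need, names(cfg$input))
    if (length(miss))
      .stopf("input section missing path(s): %s", paste(miss, collapse = ", "))
  }
  if (!is.null(cfg$simulate) && is.null(cfg$simulate$presets))
    cfg$simulate$presets <- c("primary_like", "secondary_like")
  class(cfg) <- "run_config"
  cfg
}

.grid_of <- function(cfg) seq(0, cfg$grid_max, by = cfg$grid_step)

.write_sidecar <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  info <- list(package = "arborant",
               version = as.character(utils::packageVersion("arborant")),
               seed = cfg$seed,
               config_md5 = unname(tools::md5sum(cfg_path)))
  yaml::write_yaml(info, file.path(outdir, "run_info.yaml"))
  invisible(info)
}

#' Simulate the configured synthetic dataset and write it to disk
#'
#' Each preset in `config$simulate$presets` is simulated under a sub-seed
#' (`seed`, `seed + 100`, ...), the per-plot communities are combined, and
#' the dataset is written as the CSV suite of [write_community()] together
#' with the generator truth (`truth.yaml`).
#'
#' @param config a `run_config` (or path to one)
#' @param outdir output directory (default `config$outdir`)
#' @return the combined `ant_community`, invisibly
#' @export
run_simulate <- function(config, outdir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  if (is.null(cfg$simulate)) .stopf("config has no 'simulate:' section")
  outdir <- outdir %||% cfg$outdir
  presets <- cfg$simulate$presets
  sims <- lapply(seq_along(presets), function(i)
    simulate_community(preset_config(presets[i],
                                     seed = cfg$seed + 100L * (i - 1L))))
  community <- if (length(sims) == 1) sims[[1]]$community
               else do.call(combine_communities, lapply(sims, `[[`, "community"))
  dir.create(file.path(outdir, "dataset"), showWarnings = FALSE,
             recursive = TRUE)
  write_community(community, file.path(outdir, "dataset"))
  yaml::write_yaml(lapply(sims, function(s)
    c(unclass(s$truth$config),
      list(nest_occupancy = as.integer(s$truth$nest_occupancy)))),
    file.path(outdir, "dataset", "truth.yaml"))
  .write_sidecar(cfg, outdir)
  message(sprintf("simulated %d plot(s): %d trees, %d species",
                  length(presets), nrow(community$trees),
                  ncol(community$nest)))
  invisible(community)
}

.load_dataset <- function(cfg) {
  if (!is.null(cfg$input)) {
    read_community(cfg$input$trees, cfg$input$nest, cfg$input$forage,
                   cfg$input$species)
  } else {
    read_community(file.path(cfg$outdir, "dataset", "trees.csv"),
                   file.path(cfg$outdir, "dataset", "nest.csv"),
                   file.path(cfg$outdir, "dataset", "forage.csv"),
                   file.path(cfg$outdir, "dataset", "species.csv"))
  }
}

#' Compute and write the diversity summaries
#'
#' Writes long-format CSVs to `outdir`: `rarefaction.csv` (plot, layer, h,
#' tau), `richness.csv` (per tree, per layer), `richness_summary.csv` (plot,
#' layer, mean, se, max), `estimators.csv` (Chao2 by plot and layer, both
#' variants), `occupancy.csv`, and `shared_species.csv` when the dataset has
#' two or more plots.
#'
#' @param config a `run_config` (or path)
#' @param community optionally a ready `ant_community` (skips file loading)
#' @param outdir output directory (default `config$outdir`)
#' @return list of the written tables, invisibly
#' @export
run_diversity <- function(config, community = NULL, outdir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  outdir <- outdir %||% cfg$outdir
  x <- community %||% .load_dataset(cfg)
  plots <- cfg$plots %||% plot_labels(x)
  layers <- c("all", "nest", "forage")

  rarefaction <- do.call(rbind, lapply(plots, function(p)
    do.call(rbind, lapply(layers, function(ly) rarefaction_curve(x, p, ly)))))
  estimators <- do.call(rbind, lapply(plots, function(p)
    do.call(rbind, lapply(layers, function(ly) {
      s <- incidence_summary(incidence_layer(x, p, ly))
      do.call(rbind, lapply(c("classic", "bias_corrected"), function(v) {
        est <- suppressWarnings(chao2(s, v))
        data.frame(plot = p, layer = ly, variant = est$variant,
                   requested_variant = v, S_obs = est$S_obs,
                   chao2 = est$estimate, sd = est$sd)
      }))
    }))))
  richness <- do.call(rbind, lapply(plots, function(p) per_tree_richness(x, p)))
  summary <- do.call(rbind, lapply(plots, function(p)
    richness_summary(per_tree_richness(x, p))))
  occupancy <- do.call(rbind, lapply(plots, function(p) {
    o <- occupancy_summary(x, p)$species
    cbind(plot = p, o)
  }))

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.csv(rarefaction, file.path(outdir, "rarefaction.csv"), row.names = FALSE)
  write.csv(richness, file.path(outdir, "richness.csv"), row.names = FALSE)
  write.csv(summary, file.path(outdir, "richness_summary.csv"), row.names = FALSE)
  write.csv(estimators, file.path(outdir, "estimators.csv"), row.names = FALSE)
  write.csv(occupancy, file.path(outdir, "occupancy.csv"), row.names = FALSE)

  shared <- NULL
  if (length(plots) >= 2) {
    shared <- shared_species(x, plots[1], plots[2])
    write.csv(data.frame(plot_a = plots[1], plot_b = plots[2],
                         shared = shared$count,
                         species = paste(shared$species, collapse = ";")),
              file.path(outdir, "shared_species.csv"), row.names = FALSE)
  }
  .write_sidecar(cfg, outdir)
  for (p in plots) {
    s <- summary[summary$plot == p & summary$layer == "all", ]
    message(sprintf("plot %s: S_obs(all) = %d, mean richness/tree = %.2f",
                    p, sum(colSums(incidence_layer(x, p, "all")) > 0), s$mean))
  }
  invisible(list(rarefaction = rarefaction, richness = richness,
                 summary = summary, estimators = estimators,
                 occupancy = occupancy, shared = shared))
}

#' Run the spatial null model and write its outputs
#'
#' Per plot: F-N nearest-nest distances (`fn_distances.csv`), the cumulative
#' distance curve with permutation bands (`curve.csv`), the nesting
#' probability profile with envelopes (`profile.csv`) and a test report
#' (`test_report.csv`) carrying observed and null means, the empirical rank
#' p, the rank-sum statistic, `n_perm` and the seed.
#'
#' @param config a `run_config` (or path)
#' @param community optionally a ready `ant_community`
#' @param outdir output directory (default `config$outdir`)
#' @return list of `ant_null_test` objects by plot, invisibly
#' @export
run_nullmodel <- function(config, community = NULL, outdir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  outdir <- outdir %||% cfg$outdir
  x <- community %||% .load_dataset(cfg)
  plots <- cfg$plots %||% plot_labels(x)
  grid <- .grid_of(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  fn_all <- list(); curve_all <- list(); profile_all <- list()
  report <- list(); tests <- list()
  for (i in seq_along(plots)) {
    p <- plots[i]
    seed_p <- cfg$seed + 1000L * i
    t0 <- proc.time()[["elapsed"]]
    nd <- null_test(x, p, "nearest_distance", n_perm = cfg$n_perm,
                    seed = seed_p, grid = grid,
                    apply_exclusions = cfg$apply_exclusions)
    pp <- null_test(x, p, "probability_profile", n_perm = cfg$n_perm,
                    seed = seed_p, radii = cfg$radii,
                    apply_exclusions = cfg$apply_exclusions)
    elapsed <- proc.time()[["elapsed"]] - t0
    tests[[p]] <- list(nearest_distance = nd, probability_profile = pp)
    fn_all[[p]] <- nd$distances
    curve_all[[p]] <- cbind(plot = p, nd$curve)
    profile_all[[p]] <- cbind(plot = p, pp$profile)
    report[[p]] <- data.frame(
      plot = p, statistic = "nearest_distance",
      n_records = nd$n_records, observed_mean = nd$observed_mean,
      null_mean = nd$null_mean, env_lo = nd$mean_envelope[1],
      env_hi = nd$mean_envelope[2],
      below_envelope = nd$below_envelope, rank_p = nd$rank_p,
      ranksum_W = nd$ranksum$W, ranksum_p = nd$ranksum$p,
      n_perm = cfg$n_perm, seed = seed_p)
    message(sprintf(
      "plot %s: %d F-N records; mean nearest nest %.2f m (null %.2f m, rank p = %.3f) [%.1fs]",
      p, nd$n_records, nd$observed_mean, nd$null_mean, nd$rank_p, elapsed))
  }
  write.csv(do.call(rbind, fn_all), file.path(outdir, "fn_distances.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, curve_all), file.path(outdir, "curve.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, profile_all), file.path(outdir, "profile.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, report), file.path(outdir, "test_report.csv"),
            row.names = FALSE)
  .write_sidecar(cfg, outdir)
  invisible(tests)
}

#' Run the full pipeline: simulate (optional), diversity, null model
#'
#' @param config a `run_config` or path to the YAML file
#' @param outdir output directory (default `config$outdir`)
#' @return list with `community`, `diversity`, `nullmodel`, invisibly
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  outdir <- outdir %||% cfg$outdir
  community <- if (!is.null(cfg$simulate)) run_simulate(cfg, outdir)
               else .load_dataset(cfg)
  div <- run_diversity(cfg, community, outdir)
  nm <- run_nullmodel(cfg, community, outdir)
  invisible(list(community = community, diversity = div, nullmodel = nm))
}
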