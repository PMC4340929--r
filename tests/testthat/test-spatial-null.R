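## A compact community with a strong built-in spatial signal for smoke-level
## checks; heavier calibration/power simulations live in test-acceptance.R.
signal_community <- function(seed = 1, n_trees = 90, n_species = 20,
                             lambda = 4, emission = 0.25, tourists = 0) {
  cfg <- simulation_config(n_trees = n_trees, n_species = n_species,
                           forage_lambda = lambda, forage_emission = emission,
                           tourist_rate = tourists, plot_label = "sim",
                           seed = seed)
  simulate_community(cfg)$community
}

test_that("nearest-nest distances handle single and multiple candidates", {
  trees <- data.frame(tree_id = c("T1", "T2", "T3"), plot = "p",
                      x = c(0, 3, 0), y = c(0, 4, 2), dbh = 10)
  nest <- matrix(0, 3, 2, dimnames = list(trees$tree_id, c("AAAA001", "BBBB001")))
  forage <- nest
  nest["T1", "AAAA001"] <- 1
  forage["T2", "AAAA001"] <- 1                    # single candidate at 5 m
  nest[c("T2", "T3"), "BBBB001"] <- 1
  forage["T1", "BBBB001"] <- 1                    # candidates at 5 m and 2 m
  x <- ant_community(trees, nest, forage)
  nd <- nearest_nest_distances(x, "p")
  expect_equal(nd$distance[nd$species_code == "AAAA001"], 5)
  expect_equal(nd$distance[nd$species_code == "BBBB001"], 2)
  expect_true(all(nd$distance > 0))
})

test_that("nearest-nest distances equal the brute-force oracle", {
  for (seed in 1:10) {
    x <- random_community(25, 8, seed = 300 + seed)
    nd <- nearest_nest_distances(x, "p1")
    nest <- incidence_layer(x, "p1", "nest")
    dmat <- pairwise_distances(x, "p1")
    expect_equal(nd$distance, oracle_nearest(nd, nest, dmat), tolerance = 1e-9)
  }
})

test_that("cumulative curves are counting-correct, monotone and bounded", {
  cc <- cumulative_curve(data.frame(distance = c(1, 3, 9, 20)),
                         grid = c(0, 5, 10, 25))
  expect_equal(cc$cum, c(0, 0.5, 0.75, 1))
  step <- cumulative_curve(data.frame(distance = rep(4, 7)),
                           grid = c(3.9, 4, 30))
  expect_equal(step$cum, c(0, 1, 1))
  expect_error(cumulative_curve(data.frame(distance = numeric(0))),
               "no F-N records")
  x <- signal_community(2)
  cc <- cumulative_curve(nearest_nest_distances(x, "sim"), grid = 0:60)
  expect_true(all(diff(cc$cum) >= 0))
  expect_true(all(cc$cum >= 0 & cc$cum <= 1))
})

test_that("nesting probability is nests over trees within the radius", {
  # focal T0 at origin; 4 trees within 5 m, exactly one with a nest of A
  trees <- data.frame(tree_id = paste0("T", 0:5), plot = "p",
                      x = c(0, 1, 2, 3, 4, 30), y = 0, dbh = 10)
  nest <- matrix(0, 6, 1, dimnames = list(trees$tree_id, "AAAA001"))
  forage <- nest
  nest["T2", ] <- 1
  forage["T0", ] <- 1
  x <- ant_community(trees, nest, forage)
  pr <- nesting_probability_profile(x, "p", radii = c(5, 40))
  expect_equal(pr$mean_p[pr$radius_m == 5], 0.25)
  expect_equal(pr$mean_p[pr$radius_m == 40], 0.2)
  expect_error(nesting_probability_profile(x, "p", radii = c(-1, 5)),
               "positive")
})

test_that("records with no tree inside the radius are skipped there", {
  trees <- data.frame(tree_id = c("A", "B", "C"), plot = "p",
                      x = c(0, 50, 50.5), y = 0, dbh = 10)
  nest <- matrix(0, 3, 1, dimnames = list(trees$tree_id, "AAAA001"))
  forage <- nest
  nest["B", ] <- 1
  forage[c("A", "C"), ] <- 1
  x <- ant_community(trees, nest, forage)
  pr <- nesting_probability_profile(x, "p", radii = c(2, 60))
  # at 2 m only record C has a neighbour (B): p = 1; A contributes nothing
  expect_identical(pr$n_records[pr$radius_m == 2], 1L)
  expect_equal(pr$mean_p[pr$radius_m == 2], 1)
  expect_identical(pr$n_records[pr$radius_m == 60], 2L)
})

test_that("probability profile is invariant to relabeling and rigid motion", {
  x <- signal_community(3)
  pr0 <- nesting_probability_profile(x, "sim")
  # rotate 37 degrees and translate
  th <- 37 * pi / 180
  y <- x
  y$trees$x <- cos(th) * x$trees$x - sin(th) * x$trees$y + 100
  y$trees$y <- sin(th) * x$trees$x + cos(th) * x$trees$y - 50
  pr1 <- nesting_probability_profile(y, "sim")
  expect_equal(pr1$mean_p, pr0$mean_p, tolerance = 1e-9)
  # permute tree labels (rows of every component consistently)
  set.seed(1)
  ord <- sample(nrow(x$trees))
  z <- ant_community(x$trees[ord, ], x$nest[ord, ], x$forage[ord, ],
                     x$species)
  pr2 <- nesting_probability_profile(z, "sim")
  expect_equal(pr2$mean_p, pr0$mean_p, tolerance = 1e-9)
})

test_that("quasiswap preserves margins exactly and is seed-deterministic", {
  for (seed in 1:10) {
    set.seed(400 + seed)
    m <- matrix(rbinom(150, 1, 0.3), 15, 10,
                dimnames = list(paste0("t", 1:15), paste0("s", 1:10)))
    sims <- quasiswap_randomize(m, seed = seed, nsim = 20)
    for (j in 1:20) {
      expect_identical(rowSums(sims[, , j]), rowSums(m))
      expect_identical(colSums(sims[, , j]), colSums(m))
    }
  }
  m <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_identical(quasiswap_randomize(m, seed = 5),
                   quasiswap_randomize(m, seed = 5))
  expect_error(quasiswap_randomize(m * 2, seed = 1), "binary")
})

test_that("matrices without a checkerboard cannot change", {
  # nested (triangular) occupancy admits no 2x2 checkerboard submatrix
  m <- matrix(0, 4, 4, dimnames = list(paste0("t", 1:4), paste0("s", 1:4)))
  for (i in 1:4) m[i, seq_len(i)] <- 1
  expect_identical(length(oracle_margin_class(m)), 1L)
  for (seed in 1:5)
    expect_identical(quasiswap_randomize(m, seed = seed), m)
})

test_that("the 2x2 checkerboard flips roughly half the time", {
  m <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  sims <- quasiswap_randomize(m, seed = 42, nsim = 1000)
  frac_id <- mean(sims[1, 1, ] == 1)
  expect_gt(frac_id, 0.4)
  expect_lt(frac_id, 0.6)
})

test_that("empty rows and columns are forced to stay empty", {
  set.seed(6)
  m <- matrix(rbinom(80, 1, 0.4), 10, 8,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:8)))
  m[3, ] <- 0; m[, 5] <- 0
  sims <- quasiswap_randomize(m, seed = 9, nsim = 25)
  expect_true(all(sims[3, , ] == 0))
  expect_true(all(sims[, 5, ] == 0))
})

test_that("null_test validates inputs and keeps the F-N set fixed", {
  x <- signal_community(4)
  expect_error(null_test(x, "sim", n_perm = 1, seed = 1), "n_perm")
  expect_error(null_test(x, "sim", n_perm = 10), "seed")
  nt <- null_test(x, "sim", "nearest_distance", n_perm = 19, seed = 3)
  expect_identical(nt$n_records, nrow(derive_fn_records(x, "sim")))
  expect_identical(nt$fn[c("tree_id", "species_code")],
                   derive_fn_records(x, "sim")[c("tree_id", "species_code")])
  # same seed, same result
  nt2 <- null_test(x, "sim", "nearest_distance", n_perm = 19, seed = 3)
  expect_identical(nt$null_means, nt2$null_means)
})

test_that("empirical rank p follows the two-sided rank arithmetic", {
  expect_equal(arborant:::.rank_p(0, 1:100), 2 / 101)
  expect_equal(arborant:::.rank_p(101, 1:100), 2 / 101)
  expect_equal(arborant:::.rank_p(50.5, 1:100), 1)
  # nearest-rank envelope: with 100 values the bounds are the 3rd and 98th
  v <- sort(rnorm(100))
  expect_identical(arborant:::.nearest_rank(v, c(0.025, 0.975)),
                   c(v[3], v[98]))
})

test_that("degenerate margins collapse the envelope onto the observation", {
  # nested nest layer: its margin class has a single member, so every
  # permutation equals the observed matrix and all null statistics coincide
  trees <- data.frame(tree_id = paste0("T", 1:4), plot = "p",
                      x = c(0, 2, 5, 9), y = 0, dbh = 10)
  nest <- matrix(0, 4, 4,
                 dimnames = list(trees$tree_id, sprintf("SPEC%03d", 1:4)))
  for (i in 1:4) nest[i, seq_len(i)] <- 1
  forage <- nest
  forage["T1", "SPEC003"] <- 1    # one F-N record
  x <- ant_community(trees, nest, forage)
  nt <- null_test(x, "p", "nearest_distance", n_perm = 25, seed = 2)
  expect_equal(nt$mean_envelope[1], nt$observed_mean)
  expect_equal(nt$mean_envelope[2], nt$observed_mean)
  expect_false(nt$below_envelope || nt$above_envelope)
})

test_that("a strong foraging kernel is detected as spatial aggregation", {
  x <- signal_community(7, n_trees = 120, n_species = 25,
                        lambda = 3, emission = 0.35)
  nt <- null_test(x, "sim", "nearest_distance", n_perm = 99, seed = 11)
  expect_true(nt$below_envelope)
  expect_lt(nt$observed_mean, nt$null_mean)
  expect_lt(nt$rank_p, 0.05)
  pp <- null_test(x, "sim", "probability_profile", n_perm = 99, seed = 11)
  expect_true(pp$profile$outside_envelope[pp$profile$radius_m == 5])
  expect_gt(pp$profile$observed_mean[1], pp$profile$env_hi[1])
})

test_that("null statistics are recomputed per permutation, margins intact", {
  x <- signal_community(8, n_trees = 60, n_species = 12)
  nest <- incidence_layer(x, "sim", "nest")
  sims <- quasiswap_randomize(nest, seed = 13, nsim = 30)
  for (j in c(1, 15, 30)) {
    expect_identical(rowSums(sims[, , j]), rowSums(nest))
    expect_identical(colSums(sims[, , j]), colSums(nest))
  }
  # the permuted statistic matches a from-scratch computation on that layer
  fn <- derive_fn_records(x, "sim")
  dmat <- pairwise_distances(x, "sim")
  idx <- arborant:::.fn_index(fn, nest)
  d15 <- arborant:::.nearest_dist_core(idx$t, idx$s, sims[, , 15], dmat)
  expect_equal(d15, oracle_nearest(fn, sims[, , 15], dmat), tolerance = 1e-9)
})
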