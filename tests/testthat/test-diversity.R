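test_that("mao_tau endpoints and closed forms hold", {
  x <- random_community(12, 8, seed = 2)
  m <- incidence_layer(x, "p1", "all")
  s <- incidence_summary(m)
  expect_equal(mao_tau(s, s$H), s$S_obs)                   # all samples
  expect_equal(mao_tau(s, 1), sum(s$Y) / s$H)              # mean per tree
  expect_error(mao_tau(s, 0), "1..H")
  expect_error(mao_tau(s, s$H + 1), "1..H")
})

test_that("mao_tau equals the exhaustive subset-enumeration oracle", {
  # the spec case: H = 4, incidence frequencies (4, 2, 1), h = 2
  m <- matrix(0, 4, 3, dimnames = list(paste0("T", 1:4), paste0("S", 1:3)))
  m[, 1] <- 1; m[1:2, 2] <- 1; m[3, 3] <- 1
  s <- incidence_summary(m)
  expect_equal(mao_tau(s, 2), oracle_accumulation(m, 2), tolerance = 1e-12)

  for (seed in 1:6) {
    set.seed(seed)
    H <- sample(3:8, 1)
    mm <- matrix(rbinom(H * 6, 1, 0.4), H, 6,
                 dimnames = list(paste0("T", 1:H), paste0("S", 1:6)))
    ss <- incidence_summary(mm)
    for (h in seq_len(H))
      expect_equal(mao_tau(ss, h), oracle_accumulation(mm, h),
                   tolerance = 1e-9)
  }
})

test_that("rarefaction curves are nondecreasing and end at S_obs", {
  for (seed in 1:10) {
    x <- random_community(15, 10, seed = seed)
    cur <- rarefaction_curve(x, "p1", "all")
    expect_true(all(diff(cur$tau) >= -1e-12))
    s <- incidence_summary(incidence_layer(x, "p1", "all"))
    expect_equal(cur$tau[nrow(cur)], s$S_obs)
  }
})

test_that("mao_tau agrees with vegan's analytic accumulation curve", {
  x <- random_community(30, 12, seed = 4)
  m <- incidence_layer(x, "p1", "all")
  m <- m[, colSums(m) > 0, drop = FALSE]
  s <- incidence_summary(m)
  sa <- vegan::specaccum(m, method = "exact")
  expect_equal(mao_tau(s, seq_len(s$H)), sa$richness, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("chao2 reproduces the direct formula and its edge cases", {
  mk <- function(S, q1, q2, H) {
    # synthetic incidence frequencies: q1 singletons, q2 doubletons, rest 3
    Y <- c(rep(1, q1), rep(2, q2), rep(3, S - q1 - q2))
    structure(list(H = H, S_obs = S, Y = Y, q1 = q1, q2 = q2),
              class = "incidence_summary")
  }
  est <- chao2(mk(10, 4, 2, 100), "classic")
  expect_equal(est$estimate, 10 + 0.99 * 16 / 4)           # 13.96
  # q1 = 0: no undetected-species signal
  est0 <- chao2(mk(10, 0, 3, 50))
  expect_equal(est0$estimate, 10)
  expect_lt(est0$sd, 1e-12)
  # q2 = 0 falls back to bias_corrected with a warning
  expect_warning(estf <- chao2(mk(10, 4, 0, 50), "classic"), "bias_corrected")
  expect_identical(estf$variant, "bias_corrected")
  expect_equal(estf$estimate, 10 + (49 / 50) * 4 * 3 / 2)
})

test_that("chao2 is never below S_obs; bias-corrected never above classic", {
  for (seed in 1:20) {
    x <- random_community(25, 15, seed = 100 + seed, p_nest = 0.08,
                          p_forage = 0.05)
    s <- incidence_summary(incidence_layer(x, "p1", "all"))
    if (s$S_obs == 0) next
    bc <- chao2(s, "bias_corrected")
    expect_gte(bc$estimate, s$S_obs)
    if (s$q2 >= 1) {
      cl <- chao2(s, "classic")
      expect_gte(cl$estimate, s$S_obs)
      if (s$q1 >= 1) expect_lte(bc$estimate, cl$estimate)
    }
  }
})

test_that("classic chao2 matches vegan::specpool estimate and SE", {
  set.seed(9)
  m <- matrix(rbinom(50 * 40, 1, 0.06), 50, 40)
  m <- m[, colSums(m) > 0, drop = FALSE]
  dimnames(m) <- list(paste0("T", seq_len(nrow(m))),
                      paste0("S", seq_len(ncol(m))))
  s <- incidence_summary(m)
  stopifnot(s$q2 > 0)
  est <- chao2(s, "classic")
  sp <- vegan::specpool(m)
  expect_equal(est$estimate, sp$chao, tolerance = 1e-10)
  expect_equal(est$sd, sp$chao.se, tolerance = 1e-10)
})

test_that("per-tree richness counts match row-sum oracles and inequalities", {
  x <- toy_community()
  r <- per_tree_richness(x, "a")
  expect_identical(r$all, c(1L, 1L, 1L))
  expect_identical(r$fn, c(0L, 1L, 0L))    # T3's forager B has no nest

  for (seed in 1:8) {
    y <- random_community(20, 10, seed = 200 + seed)
    r <- per_tree_richness(y, "p1")
    nest <- incidence_layer(y, "p1", "nest")
    forage <- incidence_layer(y, "p1", "forage")
    expect_identical(r$nest, as.integer(rowSums(nest)))
    expect_identical(r$forage, as.integer(rowSums(forage)))
    expect_identical(r$all, as.integer(rowSums(pmax(nest, forage))))
    expect_true(all(r$all >= pmax(r$nest, r$forage)))
    expect_true(all(r$fn <= r$forage))
    # fn = forage - (both layers) restricted to species nesting in the plot
    nesting <- colSums(nest) >= 1
    fn_oracle <- vapply(seq_len(nrow(nest)), function(t)
      sum(forage[t, nesting] == 1 & nest[t, nesting] == 0), numeric(1))
    expect_identical(r$fn, as.integer(fn_oracle))
  }
})

test_that("trees with no ants keep zero counts in every layer", {
  x <- toy_community()
  empty <- per_tree_richness(x, "a")
  # T3 has only the nest-less forager B: fn/nest must be 0, forage 1
  row <- empty[empty$tree_id == "T3", ]
  expect_identical(row$nest, 0L)
  expect_identical(row$fn, 0L)
  y <- x
  y$forage["T3", ] <- 0
  r <- per_tree_richness(y, "a")
  expect_identical(unlist(r[r$tree_id == "T3", c("all", "nest", "forage", "fn")],
                          use.names = FALSE), rep(0L, 4))
})

test_that("richness summaries report mean, SE and max per layer", {
  x <- random_community(30, 10, seed = 5)
  r <- per_tree_richness(x, "p1")
  s <- richness_summary(r)
  expect_setequal(s$layer, c("all", "nest", "forage", "fn"))
  a <- s[s$layer == "all", ]
  expect_equal(a$mean, mean(r$all))
  expect_equal(a$se, sd(r$all) / sqrt(length(r$all)))
  expect_identical(a$max, max(r$all))
})

test_that("shared species across plots behave at the extremes", {
  x <- toy_community()
  # plot a uses species A and B, plot b only C -> no overlap
  expect_identical(shared_species(x, "a", "b")$count, 0L)
  y <- x
  y$forage["U2", "AAAA001"] <- 1
  expect_identical(shared_species(y, "a", "b")$species, "AAAA001")
  # identical communities share everything observed
  z <- random_community(10, 6, seed = 7)
  z2 <- z
  z2$trees$tree_id <- paste0("q", z2$trees$tree_id)
  z2$trees$plot <- "p2"
  rownames(z2$nest) <- rownames(z2$forage) <- z2$trees$tree_id
  both <- combine_communities(z, z2)
  occ <- colnames(z$nest)[colSums(pmax(z$nest, z$forage)) > 0]
  expect_identical(shared_species(both, "p1", "p2")$count, length(occ))
})

test_that("occupancy summary tallies occurrences, counts and invasives", {
  x <- toy_community()
  x$species$invasive[x$species$species_code == "AAAA001"] <- TRUE
  o <- occupancy_summary(x, "a")
  a <- o$species[o$species$species_code == "AAAA001", ]
  expect_identical(a$occupancy_nest, 1L)
  expect_identical(a$occupancy_forage, 2L)
  expect_true(is.na(o$totals[["foragers"]]))   # no count layers supplied
  expect_equal(o$invasive_fraction[["occurrences"]], 2 / 3)

  # with a forager count layer, totals are grand sums and top shares tally
  y <- random_community(12, 5, seed = 8)
  cnt <- y$forage * matrix(rpois(60, 20), 12, 5)
  y$counts <- list(forage = cnt)
  oy <- occupancy_summary(y, "p1")
  expect_equal(oy$totals[["foragers"]], sum(cnt))
  expect_equal(sum(oy$species$foragers), sum(cnt))
  ranked <- sort(colSums(cnt), decreasing = TRUE)
  top5 <- sum(head(ranked, 5)) / sum(cnt)
  got <- sort(oy$species$foragers, decreasing = TRUE)
  expect_equal(sum(head(got, 5)) / sum(oy$species$foragers), top5)
})
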