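## Fixture builders and independent brute-force oracles used across the
## suite. Oracles are deliberately naive (loops, exhaustive enumeration) and
## share no code with the package internals they check.

## A small hand-built two-plot community.
toy_community <- function() {
  trees <- data.frame(
    tree_id = c("T1", "T2", "T3", "U1", "U2"),
    plot = c("a", "a", "a", "b", "b"),
    x = c(0, 3, 0, 0, 10),
    y = c(0, 4, 10, 0, 0),
    dbh = c(10, 20, 15, 8, 30))
  sp <- c("AAAA001", "BBBB001", "CCCC001")
  nest <- matrix(0, 5, 3, dimnames = list(trees$tree_id, sp))
  forage <- nest
  nest["T1", "AAAA001"] <- 1
  forage[c("T1", "T2"), "AAAA001"] <- 1      # A: F-N on T2
  forage["T3", "BBBB001"] <- 1               # B forages, never nests
  nest["U1", "CCCC001"] <- 1
  forage[c("U1", "U2"), "CCCC001"] <- 1      # C: F-N on U2
  ant_community(trees, nest, forage)
}

## Random community on a uniform stem map; layers are unstructured noise.
random_community <- function(n_trees = 20, n_species = 10, seed = 1,
                             p_nest = 0.15, p_forage = 0.2,
                             plot = "p1", width = 40, height = 80) {
  set.seed(seed)
  trees <- data.frame(
    tree_id = sprintf("%s-T%03d", plot, seq_len(n_trees)),
    plot = plot,
    x = runif(n_trees, 0, width), y = runif(n_trees, 0, height),
    dbh = 5 + rlnorm(n_trees, log(4), 0.9))
  sp <- sprintf("RAND%03d", seq_len(n_species))
  nest <- matrix(rbinom(n_trees * n_species, 1, p_nest), n_trees,
                 dimnames = list(trees$tree_id, sp))
  forage <- matrix(rbinom(n_trees * n_species, 1, p_forage), n_trees,
                   dimnames = list(trees$tree_id, sp))
  ant_community(trees, nest, forage)
}

## Triple-loop F-N derivation.
oracle_fn <- function(x, plot, apply_exclusions = TRUE) {
  keep <- x$trees$plot == plot
  nest <- x$nest[keep, , drop = FALSE]
  forage <- x$forage[keep, , drop = FALSE]
  out <- NULL
  for (t in rownames(nest)) {
    for (s in colnames(nest)) {
      excluded <- apply_exclusions &&
        x$species$exclude_from_spatial[x$species$species_code == s]
      if (forage[t, s] == 1 && nest[t, s] == 0 &&
          sum(nest[, s]) >= 1 && !excluded)
        out <- rbind(out, data.frame(tree_id = t, species_code = s))
    }
  }
  out
}

## Double-loop Euclidean distances.
oracle_distances <- function(trees) {
  n <- nrow(trees)
  d <- matrix(0, n, n, dimnames = list(trees$tree_id, trees$tree_id))
  for (i in seq_len(n))
    for (j in seq_len(n))
      d[i, j] <- sqrt((trees$x[i] - trees$x[j])^2 +
                      (trees$y[i] - trees$y[j])^2)
  d
}

## Per-record nearest-nest scan.
oracle_nearest <- function(fn, nest, dmat) {
  vapply(seq_len(nrow(fn)), function(k) {
    t <- fn$tree_id[k]; s <- fn$species_code[k]
    cand <- setdiff(rownames(nest)[nest[, s] == 1], t)
    if (!length(cand)) return(NA_real_)
    min(dmat[t, cand])
  }, numeric(1))
}

## Exhaustive subset-enumeration expected richness (Mao Tau oracle, H <= 8).
oracle_accumulation <- function(m, h) {
  H <- nrow(m)
  subs <- utils::combn(H, h, simplify = FALSE)
  mean(vapply(subs, function(ss)
    sum(colSums(m[ss, , drop = FALSE]) > 0), numeric(1)))
}

## Enumerate every binary matrix with the margins of m (small matrices only).
## Recursion over rows: choose each row as a subset with the right row sum,
## pruning on remaining column capacity.
oracle_margin_class <- function(m) {
  rs <- rowSums(m); cs <- colSums(m)
  n <- nrow(m); k <- ncol(m)
  out <- list()
  rows_with_sum <- function(s) {
    if (s == 0) return(list(rep(0, k)))
    cols <- utils::combn(k, s, simplify = FALSE)
    lapply(cols, function(cc) { r <- rep(0, k); r[cc] <- 1; r })
  }
  recurse <- function(i, acc, cap) {
    if (i > n) {
      if (all(cap == 0)) out[[length(out) + 1]] <<- do.call(rbind, acc)
      return(invisible())
    }
    if (sum(cap) < sum(rs[i:n])) return(invisible())
    for (r in rows_with_sum(rs[i])) {
      if (all(cap - r >= 0)) recurse(i + 1, c(acc, list(r)), cap - r)
    }
  }
  recurse(1, list(), cs)
  out
}

matrix_key <- function(m) paste(as.vector(m), collapse = "")
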