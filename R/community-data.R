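## Data model: mapped stems plus aligned binary incidence layers.

#' Assemble an arboreal ant community dataset
#'
#' Bundles a tree table (mapped stems) with aligned binary trees-by-species
#' incidence matrices for the nesting and foraging layers, plus species
#' metadata. All downstream statistics operate on this container.
#'
#' @param trees data frame with columns `tree_id`, `plot`, `x`, `y` (trunk
#'   coordinates in metres within the plot) and `dbh` (cm); further size-trait
#'   columns (e.g. `height_m`, `crown_width_m`) are carried along unused.
#' @param nest,forage binary matrices (trees in rows, species in columns) with
#'   dimnames; row names must match `trees$tree_id` as a set, column names the
#'   species register. Rows are reordered to the tree-table order.
#' @param species optional data frame with columns `species_code`,
#'   `full_name`, `invasive`, `exclude_from_spatial`. When `NULL`, a register
#'   is built from the matrix columns with all flags `FALSE`.
#' @param counts optional named list with elements `nest` and/or `forage`
#'   holding count matrices of the same shape (nest counts, forager
#'   individuals) used only by abundance summaries; all spatial statistics use
#'   the binary layers.
#'
#' @return An object of class `ant_community`: a list with elements `trees`,
#'   `nest`, `forage`, `species`, `counts`.
#'
#' @details The census rule for stem inclusion is DBH >= 5 cm; smaller values
#'   raise a warning, not an error, so sub-census stems can still be carried.
#'   Coordinates must be finite. A species may be absent (all-zero column)
#'   from one layer while present in the other.
#'
#' @examples
#' trees <- data.frame(tree_id = c("T1", "T2"), plot = "p", x = c(0, 3),
#'                     y = c(0, 4), dbh = c(10, 20))
#' m <- matrix(c(1, 0, 1, 1), 2, 2,
#'             dimnames = list(c("T1", "T2"), c("AAAA001", "BBBB001")))
#' com <- ant_community(trees, nest = m, forage = m)
#' com
#' @export
ant_community <- function(trees, nest, forage, species = NULL, counts = NULL) {
  trees <- as.data.frame(trees)
  req <- c("tree_id", "plot", "x", "y", "dbh")
  miss <- setdiff(req, names(trees))
  if (length(miss))
    .stopf("tree table is missing column(s): %s", paste(miss, collapse = ", "))
  trees$tree_id <- as.character(trees$tree_id)
  trees$plot <- as.character(trees$plot)
  if (anyDuplicated(trees$tree_id))
    .stopf("duplicated tree_id: %s",
           paste(unique(trees$tree_id[duplicated(trees$tree_id)]), collapse = ", "))
  for (cc in c("x", "y")) {
    bad <- !is.finite(trees[[cc]])
    if (any(bad))
      .stopf("non-finite %s coordinate for tree(s): %s", cc,
             paste(trees$tree_id[bad], collapse = ", "))
  }
  if (any(!is.finite(trees$dbh) | trees$dbh <= 0))
    .stopf("dbh must be positive and finite")
  if (any(trees$dbh < 5))
    .warnf("%d tree(s) have DBH < 5 cm, below the census rule (DBH >= 5 cm)",
           sum(trees$dbh < 5))

  nest <- .align_layer(nest, trees$tree_id, "nest")
  forage <- .align_layer(forage, trees$tree_id, "forage")
  if (!identical(colnames(nest), colnames(forage))) {
    sp <- union(colnames(nest), colnames(forage))
    nest <- .expand_species(nest, sp)
    forage <- .expand_species(forage, sp)
  }

  if (is.null(species)) {
    species <- data.frame(species_code = colnames(nest),
                          full_name = colnames(nest),
                          invasive = FALSE,
                          exclude_from_spatial = FALSE,
                          stringsAsFactors = FALSE)
  } else {
    species <- as.data.frame(species)
    if (!"species_code" %in% names(species))
      .stopf("species metadata needs a species_code column")
    species$species_code <- as.character(species$species_code)
    if (anyDuplicated(species$species_code))
      .stopf("duplicated species_code in metadata")
    species$full_name <- as.character(species$full_name %||% species$species_code)
    species$invasive <- as.logical(species$invasive %||% FALSE)
    species$exclude_from_spatial <-
      as.logical(species$exclude_from_spatial %||% FALSE)
    extra <- setdiff(colnames(nest), species$species_code)
    if (length(extra))
      .stopf("species in matrices but not in metadata: %s",
             paste(extra, collapse = ", "))
    species <- species[match(colnames(nest), species$species_code), , drop = FALSE]
    rownames(species) <- NULL
  }

  if (!is.null(counts)) {
    counts <- counts[intersect(names(counts), c("nest", "forage"))]
    for (nm in names(counts)) {
      cm <- counts[[nm]]
      cm <- .align_layer(cm, trees$tree_id, paste0(nm, " counts"),
                         binary = FALSE)
      cm <- .expand_species(cm, colnames(nest))
      if (any(cm < 0)) .stopf("%s counts must be nonnegative", nm)
      counts[[nm]] <- cm
    }
  }

  structure(list(trees = trees, nest = nest, forage = forage,
                 species = species, counts = counts),
            class = "ant_community")
}

## Reorder a layer matrix to the tree register, checking label sets.
.align_layer <- function(m, tree_ids, what, binary = TRUE) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    .stopf("%s matrix must carry tree row names and species column names", what)
  missing_rows <- setdiff(tree_ids, rownames(m))
  orphan_rows <- setdiff(rownames(m), tree_ids)
  if (length(missing_rows) || length(orphan_rows))
    .stopf("%s matrix misaligned with tree table%s%s", what,
           if (length(missing_rows))
             paste0("; trees without matrix rows: ",
                    paste(missing_rows, collapse = ", ")) else "",
           if (length(orphan_rows))
             paste0("; matrix rows without trees: ",
                    paste(orphan_rows, collapse = ", ")) else "")
  storage.mode(m) <- "double"
  if (anyNA(m)) .stopf("%s matrix contains NA", what)
  if (binary) .assert_binary(m, paste(what, "matrix"))
  m[tree_ids, , drop = FALSE]
}

.expand_species <- function(m, species) {
  add <- setdiff(species, colnames(m))
  if (length(add)) {
    zero <- matrix(0, nrow(m), length(add),
                   dimnames = list(rownames(m), add))
    m <- cbind(m, zero)
  }
  m[, species, drop = FALSE]
}

#' @export
print.ant_community <- function(x, ...) {
  cat("ant_community:", nrow(x$trees), "trees,",
      ncol(x$nest), "species,",
      length(unique(x$trees$plot)), "plot(s)\n")
  for (p in unique(x$trees$plot)) {
    i <- x$trees$plot == p
    cat(sprintf("  %s: %d trees, %d nesting / %d foraging species\n", p,
                sum(i),
                sum(colSums(x$nest[i, , drop = FALSE]) > 0),
                sum(colSums(x$forage[i, , drop = FALSE]) > 0)))
  }
  invisible(x)
}

#' List plot labels of a community dataset
#' @param x an `ant_community`
#' @return character vector of plot labels in tree-table order
#' @export
plot_labels <- function(x) unique(x$trees$plot)

.check_plot <- function(x, plot) {
  if (!plot %in% x$trees$plot)
    .stopf("unknown plot label '%s' (have: %s)", plot,
           paste(unique(x$trees$plot), collapse = ", "))
  which(x$trees$plot == plot)
}

#' Extract one incidence layer of one plot
#'
#' @param x an `ant_community`
#' @param plot plot label
#' @param layer `"nest"`, `"forage"`, or `"all"` (cell-wise union of the two:
#'   a species nesting and foraging on a tree counts once)
#' @return binary matrix, plot trees in rows, all species in columns
#' @export
incidence_layer <- function(x, plot, layer = c("all", "nest", "forage")) {
  layer <- match.arg(layer)
  i <- .check_plot(x, plot)
  switch(layer,
         nest = x$nest[i, , drop = FALSE],
         forage = x$forage[i, , drop = FALSE],
         all = pmax(x$nest[i, , drop = FALSE], x$forage[i, , drop = FALSE]))
}

#' Read a community dataset from delimited text files
#'
#' Expects CSV files with a header row and identifiers in the first column:
#' a tree table (`tree_id, plot, x, y, dbh, ...`), two trees-by-species
#' incidence matrices, and optionally a species metadata table
#' (`species_code, full_name, invasive, exclude_from_spatial`).
#'
#' Matrix cells larger than 1 are taken to be counts: they are binarized with
#' a warning and the raw values retained as a count layer for abundance
#' summaries.
#'
#' @param tree_table_path,nest_matrix_path,forage_matrix_path,species_meta_path
#'   file paths; `species_meta_path` may be `NULL`.
#' @param transpose set `TRUE` when the matrix files store species as rows and
#'   trees as columns.
#' @return an [ant_community()]
#' @export
read_community <- function(tree_table_path, nest_matrix_path,
                           forage_matrix_path, species_meta_path = NULL,
                           transpose = FALSE) {
  for (p in c(tree_table_path, nest_matrix_path, forage_matrix_path,
              species_meta_path))
    if (!file.exists(p)) .stopf("file not found: %s", p)

  trees <- read.csv(tree_table_path, stringsAsFactors = FALSE)
  for (cc in intersect(c("x", "y", "dbh"), names(trees))) {
    v <- suppressWarnings(as.numeric(trees[[cc]]))
    bad <- which(is.na(v) & !is.na(trees[[cc]]) & trees[[cc]] != "")
    if (length(bad))
      .stopf("non-numeric %s in %s at data row(s) %s", cc,
             basename(tree_table_path), paste(bad, collapse = ", "))
    trees[[cc]] <- v
  }

  read_layer <- function(path, what) {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "double"
    if (anyNA(m)) .stopf("NA cell in %s", basename(path))
    if (transpose) m <- t(m)
    counts <- NULL
    if (any(m > 1)) {
      .warnf("%s layer in %s contains counts > 1; binarized (counts kept as a count layer)",
             what, basename(path))
      counts <- m
      m <- (m > 0) + 0
    }
    list(binary = m, counts = counts)
  }

  nest <- read_layer(nest_matrix_path, "nest")
  forage <- read_layer(forage_matrix_path, "forage")

  species <- NULL
  if (!is.null(species_meta_path))
    species <- read.csv(species_meta_path, stringsAsFactors = FALSE)

  counts <- list()
  if (!is.null(nest$counts)) counts$nest <- nest$counts
  if (!is.null(forage$counts)) counts$forage <- forage$counts
  if (!length(counts)) counts <- NULL

  ant_community(trees, nest$binary, forage$binary, species, counts)
}

#' Write a community dataset as CSV files
#'
#' Inverse of [read_community()]: writes `trees.csv`, `nest.csv`,
#' `forage.csv`, `species.csv` (and count layers when present) into `dir`.
#'
#' @param x an `ant_community`
#' @param dir output directory, created if needed
#' @return invisibly, the named character vector of files written
#' @export
write_community <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(trees = file.path(dir, "trees.csv"),
             nest = file.path(dir, "nest.csv"),
             forage = file.path(dir, "forage.csv"),
             species = file.path(dir, "species.csv"))
  write.csv(x$trees, files["trees"], row.names = FALSE)
  write_layer <- function(m, path) {
    df <- data.frame(tree_id = rownames(m), m, check.names = FALSE)
    write.csv(df, path, row.names = FALSE)
  }
  write_layer(x$nest, files["nest"])
  write_layer(x$forage, files["forage"])
  write.csv(x$species, files["species"], row.names = FALSE)
  for (nm in names(x$counts)) {
    f <- file.path(dir, paste0(nm, "_counts.csv"))
    write_layer(x$counts[[nm]], f)
    files[paste0(nm, "_counts")] <- f
  }
  invisible(files)
}

#' Derive F-N records: species foraging but not nesting on a tree
#'
#' An F-N record is a (tree, species) pair where the species forages on the
#' tree, does not nest on it, and nests on at least one other tree of the
#' same plot. Species flagged `exclude_from_spatial` (ground-level nesters
#' whose trunk foragers do not reflect arboreal nest placement) are dropped
#' when `apply_exclusions` is `TRUE`, the default used by the spatial stages.
#'
#' @param x an `ant_community`
#' @param plot plot label
#' @param apply_exclusions drop species flagged `exclude_from_spatial`
#' @return data frame with columns `tree_id`, `species_code`, `plot`
#' @export
derive_fn_records <- function(x, plot, apply_exclusions = TRUE) {
  i <- .check_plot(x, plot)
  nest <- x$nest[i, , drop = FALSE]
  forage <- x$forage[i, , drop = FALSE]
  keep_sp <- colSums(nest) >= 1
  if (apply_exclusions) keep_sp <- keep_sp & !x$species$exclude_from_spatial
  fn <- forage == 1 & nest == 0
  fn[, !keep_sp] <- FALSE
  idx <- which(fn, arr.ind = TRUE)
  out <- data.frame(tree_id = rownames(nest)[idx[, 1]],
                    species_code = colnames(nest)[idx[, 2]],
                    plot = rep(plot, nrow(idx)), stringsAsFactors = FALSE)
  out <- out[order(out$tree_id, out$species_code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Euclidean trunk-to-trunk distance matrix of one plot
#'
#' Trunk positions are used as a surrogate for nest positions; distances are
#' planar within-plot metres. The mean and SD of the upper triangle (all
#' unordered tree pairs) are attached as attributes `mean_dist` / `sd_dist`.
#'
#' @param x an `ant_community`
#' @param plot plot label
#' @return square symmetric numeric matrix with zero diagonal, tree ids as
#'   dimnames
#' @export
pairwise_distances <- function(x, plot) {
  i <- .check_plot(x, plot)
  tr <- x$trees[i, , drop = FALSE]
  if (any(!is.finite(tr$x) | !is.finite(tr$y)))
    .stopf("missing coordinate for tree(s): %s",
           paste(tr$tree_id[!is.finite(tr$x) | !is.finite(tr$y)],
                 collapse = ", "))
  d <- as.matrix(stats::dist(cbind(tr$x, tr$y)))
  dimnames(d) <- list(tr$tree_id, tr$tree_id)
  if (nrow(d) > 1) {
    up <- d[upper.tri(d)]
    attr(d, "mean_dist") <- mean(up)
    attr(d, "sd_dist") <- stats::sd(up)
  } else {
    attr(d, "mean_dist") <- NA_real_
    attr(d, "sd_dist") <- NA_real_
  }
  d
}
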