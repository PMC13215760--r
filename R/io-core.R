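#' Read a rooted phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] with the conventions used throughout this
#' package: branch lengths missing from the Newick string are set to 1
#' (the usual convention for topology-only supertrees), tip labels must be
#' unique, and the tree must be rooted.
#'
#' @param path Path to a Newick file containing a single tree.
#' @return An object of class `phylo`.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree)) stop("Newick parse error in '", path, "'", call. = FALSE)
  validate_tree(tree)
}

#' Write a phylogeny to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Shared validation: rooted, unique tips, lengths defaulting to 1.
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  # trees with a basal polytomy are treated as rooted at the basal node
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    tree$edge.length[is.na(tree$edge.length)] <- 1
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  tree
}

# Root-to-node path lengths for every node (tips first, ape numbering).
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Force a tree to be ultrametric by terminal-branch extension
#'
#' Each terminal branch is lengthened so that every root-to-tip path equals
#' the maximum original root-to-tip depth. Internal branches are untouched
#' and no branch ever shrinks, so the procedure is deterministic and
#' order-independent.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @return An ultrametric `phylo` object.
#' @export
force_ultrametric <- function(tree) {
  tree <- validate_tree(tree)
  depths <- node_depths(tree)
  ntip <- length(tree$tip.label)
  target <- max(depths[seq_len(ntip)])
  term <- match(seq_len(ntip), tree$edge[, 2])
  tree$edge.length[term] <- tree$edge.length[term] +
    (target - depths[seq_len(ntip)])
  tree
}

#' Resolve polytomies into a binary tree
#'
#' Multifurcations are broken into bifurcations joined by zero-length
#' branches, so all pairwise patristic distances are preserved exactly.
#' The arbitrary choice among resolutions is seed-deterministic.
#'
#' @param tree A rooted `phylo` object.
#' @param seed Integer seed controlling the resolution chosen.
#' @return A binary `phylo` object with the same tips.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  tree <- validate_tree(tree)
  if (ape::is.binary(tree) && ape::is.rooted(tree)) return(tree)
  # a zero root edge makes ape treat a basal polytomy as rooted, so the
  # basal node is resolved too
  had_root_edge <- !is.null(tree$root.edge)
  if (!had_root_edge) tree$root.edge <- 0
  out <- with_seed(seed, ape::multi2di(tree, random = TRUE))
  if (!had_root_edge) out$root.edge <- NULL
  out
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips,
#' ordered as `tree$tip.label`.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
patristic_distances <- function(tree) {
  tree <- validate_tree(tree)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Branch incidence of a rooted tree
#'
#' Decomposes the tree into branch units: for every branch (edge) the set
#' of tips descending from it, together with its length. The root-to-tip
#' path of a species is exactly the set of branches incident to it, so the
#' row sums of `incidence` weighted by `lengths` equal root-to-tip depths.
#' This decomposition underlies both the branch-based Simpson phylogenetic
#' beta diversity and the phylogenetic correspondence analysis.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @return A list of class `branch_incidence` with elements `incidence`
#'   (tips x branches 0/1 matrix, rows in tip-label order), `lengths`
#'   (branch lengths), and `edge` (the tree's edge matrix).
#' @export
branch_incidence <- function(tree) {
  tree <- validate_tree(tree)
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  tips_below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tips_below[[i]] <- i
  inc <- matrix(0L, ntip, nedge,
                dimnames = list(tree$tip.label,
                                paste0("b", seq_len(nedge))))
  for (e in ape::postorder(tree)) {
    child <- tree$edge[e, 2]
    parent <- tree$edge[e, 1]
    inc[tips_below[[child]], e] <- 1L
    tips_below[[parent]] <- c(tips_below[[parent]], tips_below[[child]])
  }
  structure(list(incidence = inc,
                 lengths = tree$edge.length,
                 edge = tree$edge),
            class = "branch_incidence")
}

#' Construct an occurrence grid
#'
#' Container for a grid-cell x species presence/absence matrix plus the
#' (row, col) centroid of every cell. Cell ids are the matrix row names.
#'
#' @param x Binary matrix, cells x species, with unique row names (cell
#'   ids) and column names (species).
#' @param coords Data frame with columns `cell_id`, `row`, `col`, one row
#'   per matrix row.
#' @return An object of class `occurrence_grid`.
#' @export
occurrence_grid <- function(x, coords) {
  x <- as.matrix(x)
  stopifnot(!is.null(rownames(x)), !is.null(colnames(x)),
            all(c("cell_id", "row", "col") %in% names(coords)))
  if (anyDuplicated(rownames(x))) stop("duplicate cell ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate species names", call. = FALSE)
  if (!all(x %in% c(0, 1))) stop("occurrence matrix must be 0/1", call. = FALSE)
  coords <- as.data.frame(coords)[, c("cell_id", "row", "col")]
  if (!setequal(coords$cell_id, rownames(x)) ||
      anyDuplicated(coords$cell_id)) {
    stop("coords$cell_id must match matrix row names", call. = FALSE)
  }
  coords <- coords[match(rownames(x), coords$cell_id), ]
  rownames(coords) <- NULL
  structure(list(x = x, coords = coords), class = "occurrence_grid")
}

#' @export
print.occurrence_grid <- function(x, ...) {
  cat("Occurrence grid:", nrow(x$x), "cells x", ncol(x$x), "species\n")
  cat("  presences:", sum(x$x), sprintf("(fill %.3f)\n", mean(x$x)))
  invisible(x)
}

#' Read / write an occurrence grid as CSV
#'
#' The canonical dialect is UTF-8, comma-separated with a header row and
#' columns `cell_id, row, col`, then one 0/1 column per species.
#'
#' @param path CSV file path.
#' @return `read_occurrence_csv()` returns an `occurrence_grid`.
#' @export
read_occurrence_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "row", "col") %in% names(df)))
  sp <- setdiff(names(df), c("cell_id", "row", "col"))
  m <- as.matrix(df[, sp, drop = FALSE])
  rownames(m) <- df$cell_id
  occurrence_grid(m, df[, c("cell_id", "row", "col")])
}

#' @rdname read_occurrence_csv
#' @param occ An `occurrence_grid`.
#' @export
write_occurrence_csv <- function(occ, path) {
  df <- cbind(occ$coords, as.data.frame(occ$x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a region map as CSV (columns `cell_id`, `label`)
#'
#' @param path CSV file path.
#' @return `read_region_map()` returns a named character vector
#'   (cell id -> region label).
#' @export
read_region_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "label") %in% names(df)))
  stats::setNames(as.character(df$label), as.character(df$cell_id))
}

#' @rdname read_region_map
#' @param map Named character vector or `regionalization` object.
#' @export
write_region_map <- function(map, path) {
  a <- as_assignment(map)
  utils::write.csv(data.frame(cell_id = names(a), label = unname(a)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a regionalization
#'
#' A cell -> region-label map with method metadata. Region labels are
#' arbitrary strings; delineation functions in this package assign letters
#' A, B, ... in decreasing region size.
#'
#' @param assignment Named character vector, names are cell ids.
#' @param method One of `"evoregion"`, `"phyloregion"`, `"external"`,
#'   `"planted"`, `"random"`.
#' @param explained_variance Optional explained variance of the chosen k.
#' @param coords Optional cell-centroid data frame (`cell_id`, `row`,
#'   `col`); needed for spatial null models and perturbation.
#' @return An object of class `regionalization`.
#' @export
regionalization <- function(assignment, method = "external",
                            explained_variance = NA_real_, coords = NULL) {
  stopifnot(!is.null(names(assignment)), !anyNA(assignment))
  if (anyDuplicated(names(assignment))) stop("duplicate cell ids", call. = FALSE)
  assignment <- stats::setNames(as.character(assignment), names(assignment))
  if (!is.null(coords)) {
    coords <- as.data.frame(coords)[, c("cell_id", "row", "col")]
    coords <- coords[match(names(assignment), coords$cell_id), ]
    if (anyNA(coords$cell_id)) stop("coords must cover all cells", call. = FALSE)
    rownames(coords) <- NULL
  }
  structure(list(assignment = assignment,
                 k = length(unique(assignment)),
                 method = method,
                 explained_variance = explained_variance,
                 coords = coords),
            class = "regionalization")
}

#' @export
print.regionalization <- function(x, ...) {
  cat("Regionalization (", x$method, "): ", length(x$assignment),
      " cells in k = ", x$k, " regions\n", sep = "")
  print(sort(table(x$assignment), decreasing = TRUE))
  if (is.finite(x$explained_variance)) {
    cat(sprintf("  explained variance: %.3f\n", x$explained_variance))
  }
  invisible(x)
}

#' @export
plot.regionalization <- function(x, ...) {
  if (is.null(x$coords)) stop("no coordinates stored", call. = FALSE)
  labs <- sort(unique(x$assignment))
  z <- matrix(NA_integer_, max(x$coords$row), max(x$coords$col))
  z[cbind(x$coords$row, x$coords$col)] <- match(x$assignment, labs)
  graphics::image(t(z)[, nrow(z):1, drop = FALSE], axes = FALSE,
                  col = grDevices::hcl.colors(length(labs), "Dark 3"), ...)
  graphics::legend("topright", legend = labs, bty = "n",
                   fill = grDevices::hcl.colors(length(labs), "Dark 3"))
  invisible(x)
}

# Coerce a regionalization or named vector to a named character vector.
as_assignment <- function(map) {
  if (inherits(map, "regionalization")) return(map$assignment)
  if (!is.null(names(map))) return(stats::setNames(as.character(map), names(map)))
  stop("expected a regionalization or a named cell -> label vector",
       call. = FALSE)
}

# Coordinates carried by a map, if any.
map_coords <- function(map) {
  if (inherits(map, "regionalization")) map$coords else NULL
}

#' Match a phylogeny to an occurrence table
#'
#' Keeps species present in both the tree and the table, reorders table
#' columns to tip order, prunes unmatched tips and drops unmatched columns
#' (each with a warning), and removes grid cells left without any species
#' (empty assemblages have undefined composition and undefined beta
#' diversity).
#'
#' @param tree A `phylo` object.
#' @param occ An `occurrence_grid`.
#' @return List with elements `tree` and `occ`, aligned.
#' @export
align_tree_and_table <- function(tree, occ) {
  tree <- validate_tree(tree)
  stopifnot(inherits(occ, "occurrence_grid"))
  shared <- intersect(tree$tip.label, colnames(occ$x))
  if (length(shared) == 0L) {
    stop("tree and occurrence table share no species", call. = FALSE)
  }
  drop_sp <- setdiff(colnames(occ$x), shared)
  if (length(drop_sp)) {
    warning("dropping ", length(drop_sp),
            " species absent from the tree: ",
            paste(utils::head(drop_sp, 5), collapse = ", "),
            if (length(drop_sp) > 5) ", ..." else "")
  }
  drop_tip <- setdiff(tree$tip.label, shared)
  if (length(drop_tip)) {
    warning("pruning ", length(drop_tip),
            " tips absent from the table: ",
            paste(utils::head(drop_tip, 5), collapse = ", "),
            if (length(drop_tip) > 5) ", ..." else "")
    tree <- ape::drop.tip(tree, drop_tip)
  }
  m <- occ$x[, tree$tip.label, drop = FALSE]
  empty <- rowSums(m) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty grid cells")
    m <- m[!empty, , drop = FALSE]
  }
  zero_sp <- colSums(m) == 0
  if (any(zero_sp)) {
    warning("pruning ", sum(zero_sp), " species with no occurrences")
    tree <- ape::drop.tip(tree, colnames(m)[zero_sp])
    m <- m[, tree$tip.label, drop = FALSE]
  }
  coords <- occ$coords[match(rownames(m), occ$coords$cell_id), ]
  list(tree = tree, occ = occurrence_grid(m, coords))
}
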