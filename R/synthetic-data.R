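#' Simulate an ultrametric Yule tree
#'
#' Pure-birth simulation conditioned on the number of extant tips, used to
#' emulate the regional species pools the pipeline is designed for. Tips
#' are labelled `sp001`, `sp002`, ...
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate (events per unit time).
#' @param seed Integer seed; the same seed reproduces the same tree.
#' @return A rooted, binary, ultrametric `phylo` object.
#' @export
generate_yule_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  stopifnot(birth_rate > 0)
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  tree
}

#' Plant a contiguous random landscape on a rectangular grid
#'
#' Partitions an `n_rows` x `n_cols` grid into `k_regions` rook-contiguous
#' regions by seeded balanced region growing: k random seed cells expand
#' one frontier cell at a time, always growing the currently smallest
#' region, which keeps region sizes within a factor of ~3 of each other.
#' Attempts whose size ratio exceeds 3 (a region got enclosed early) are
#' discarded and regrown from a derived seed.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param k_regions Number of regions (1 <= k <= number of cells).
#' @param seed Integer seed.
#' @return A `regionalization` (method `"planted"`) with coordinates.
#' @export
generate_planted_landscape <- function(n_rows, n_cols, k_regions, seed = 1L) {
  n <- n_rows * n_cols
  if (k_regions < 1 || k_regions > n) {
    stop("k_regions must be between 1 and n_rows * n_cols", call. = FALSE)
  }
  coords <- data.frame(cell_id = sprintf("cell_%04d", seq_len(n)),
                       row = rep(seq_len(n_rows), each = n_cols),
                       col = rep(seq_len(n_cols), times = n_rows))
  adj <- grid_adjacency(coords)
  seeds <- derive_seeds(seed, 50L)
  for (s in seeds) {
    lab <- with_seed(s, grow_regions(adj, n, k_regions, targets = NULL))
    sizes <- tabulate(lab, k_regions)
    if (max(sizes) <= 3L * min(sizes)) {
      assignment <- stats::setNames(as.character(lab), coords$cell_id)
      assignment <- canonical_labels(assignment)
      return(regionalization(assignment, method = "planted", coords = coords))
    }
  }
  stop("could not plant ", k_regions,
       " regions with balanced sizes on this grid", call. = FALSE)
}

# Balanced (targets = NULL) or size-targeted seeded region growing.
# Returns an integer label per cell. Caller controls the RNG state.
grow_regions <- function(adj, n, k, targets = NULL) {
  lab <- integer(n)
  seed_cells <- sample.int(n, k)
  lab[seed_cells] <- seq_len(k)
  cand <- lapply(seed_cells, function(c) adj[[c]])
  blocked <- logical(k)
  assigned <- k
  sizes <- rep(1L, k)
  while (assigned < n && !all(blocked)) {
    open <- which(!blocked)
    r <- if (is.null(targets)) {
      open[which.min(sizes[open])]
    } else {
      deficit <- (targets[open] - sizes[open]) / pmax(targets[open], 1L)
      if (all(deficit <= 0)) open[which.min(sizes[open] / pmax(targets[open], 1L))]
      else open[which.max(deficit)]
    }
    cand[[r]] <- cand[[r]][lab[cand[[r]]] == 0L]
    if (length(cand[[r]]) == 0L) {
      blocked[r] <- TRUE
      next
    }
    cell <- if (length(cand[[r]]) == 1L) cand[[r]] else sample(cand[[r]], 1L)
    lab[cell] <- r
    sizes[r] <- sizes[r] + 1L
    assigned <- assigned + 1L
    cand[[r]] <- c(cand[[r]], adj[[cell]])
  }
  lab
}

#' Simulate clade-structured occurrences on a planted landscape
#'
#' Creates the clade-in-region signal both regionalization methods assume:
#' the tree is split greedily into as many maximal disjoint clades as there
#' are regions (always splitting the largest clade, so clade sizes are
#' near-equal), clades are paired with regions by decreasing size, and
#' each member species then occupies cells of its home region with
#' probability `p_in` and other cells with probability `p_out`. A fraction
#' of tips is set aside as widespread species with uniform occupancy
#' probability `(p_in + p_out) / 2` everywhere. A species left with zero
#' occupied cells is resampled once, then reported as an error.
#'
#' @param tree Ultrametric `phylo`; tips define the species pool.
#' @param region_map A `regionalization` (e.g. from
#'   [generate_planted_landscape()]).
#' @param p_in,p_out Per-cell occupancy probabilities inside/outside the
#'   home region (`0 <= p_out < p_in <= 1`).
#' @param widespread_fraction Proportion of tips with no home region.
#' @param seed Integer seed.
#' @return An `occurrence_grid` with attributes `clade_assignment` (tip ->
#'   home region label or `"widespread"`) and `region_map`.
#' @export
generate_occurrences <- function(tree, region_map, p_in = 0.9, p_out = 0.05,
                                 widespread_fraction = 0, seed = 1L) {
  stopifnot(p_out >= 0, p_in <= 1, p_out < p_in,
            widespread_fraction >= 0, widespread_fraction < 1)
  tree <- validate_tree(tree)
  map <- as_assignment(region_map)
  coords <- map_coords(region_map)
  if (is.null(coords)) stop("region_map must carry coordinates", call. = FALSE)
  labels <- names(sort(table(map), decreasing = TRUE))
  k <- length(labels)
  ntip <- length(tree$tip.label)
  if (ntip < k) stop("need at least one tip per region", call. = FALSE)

  clades <- split_into_clades(tree, k)
  sizes <- vapply(clades, length, integer(1))
  clade_assign <- character(ntip)
  names(clade_assign) <- tree$tip.label
  for (i in seq_len(k)) {
    clade_assign[clades[[order(-sizes)[i]]]] <- labels[i]
  }

  with_seed(seed, {
    nw <- round(widespread_fraction * ntip)
    if (nw > 0) {
      clade_assign[sample(tree$tip.label, nw)] <- "widespread"
    }
    cells <- names(map)
    n <- length(cells)
    m <- matrix(0L, n, ntip, dimnames = list(cells, tree$tip.label))
    p_wide <- (p_in + p_out) / 2
    for (sp in tree$tip.label) {
      home <- clade_assign[[sp]]
      p <- if (home == "widespread") rep(p_wide, n) else
        ifelse(map == home, p_in, p_out)
      draw <- as.integer(stats::runif(n) < p)
      if (sum(draw) == 0L) draw <- as.integer(stats::runif(n) < p)
      if (sum(draw) == 0L) {
        stop("species ", sp, " occupies no cells after resampling; ",
             "increase p_in/p_out", call. = FALSE)
      }
      m[, sp] <- draw
    }
    occ <- occurrence_grid(m, coords)
    attr(occ, "clade_assignment") <- clade_assign
    attr(occ, "region_map") <- region_map
    occ
  })
}

# Split the tips of a rooted binary-ish tree into k maximal disjoint
# clades of near-equal size by repeatedly splitting the largest clade.
split_into_clades <- function(tree, k) {
  ntip <- length(tree$tip.label)
  stopifnot(k >= 1, k <= ntip)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  tips_of <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(children[[as.character(node)]], tips_of), use.names = FALSE)
  }
  root <- ntip + 1L
  groups <- list(root)
  repeat {
    sizes <- vapply(groups, function(nd) length(tips_of(nd)), integer(1))
    if (length(groups) >= k) break
    splittable <- which(sizes > 1L)
    if (!length(splittable)) break
    g <- splittable[which.max(sizes[splittable])]
    node <- groups[[g]]
    groups <- c(groups[-g], as.list(children[[as.character(node)]]))
  }
  lapply(groups, tips_of)
}

#' Perturb a region map by boundary swaps
#'
#' Reassigns `round(swap_fraction * n_cells)` cells, one at a time, to the
#' label of a randomly chosen neighbouring region, producing maps whose
#' congruence with the original degrades gradually with `swap_fraction`.
#' The label set can only shrink, never grow.
#'
#' @param region_map A `regionalization` with coordinates.
#' @param swap_fraction Fraction of cells to reassign, in \[0, 1\].
#' @param seed Integer seed.
#' @return A perturbed `regionalization`.
#' @export
perturb_map <- function(region_map, swap_fraction, seed = 1L) {
  stopifnot(swap_fraction >= 0, swap_fraction <= 1)
  map <- as_assignment(region_map)
  coords <- map_coords(region_map)
  if (is.null(coords)) stop("region_map must carry coordinates", call. = FALSE)
  n_swaps <- round(swap_fraction * length(map))
  if (n_swaps == 0) {
    return(regionalization(map, method = "external", coords = coords))
  }
  adj <- grid_adjacency(coords)
  lab <- unname(map[coords$cell_id])
  with_seed(seed, {
    for (i in seq_len(n_swaps)) {
      boundary <- which(vapply(seq_along(lab), function(j) {
        any(lab[adj[[j]]] != lab[j])
      }, logical(1)))
      if (!length(boundary)) break
      cell <- if (length(boundary) == 1L) boundary else sample(boundary, 1L)
      other <- unique(lab[adj[[cell]]])
      other <- other[other != lab[cell]]
      lab[cell] <- if (length(other) == 1L) other else sample(other, 1L)
    }
  })
  regionalization(stats::setNames(lab, coords$cell_id),
                  method = "external", coords = coords)
}

#' Hand-sized worked fixture
#'
#' A fixed 4-tip tree `((A:1,B:1):1,(C:1,D:1):1)` and a 2 x 3 grid of six
#' cells with hand-written presences (`cell_1 = {A,B}`, `cell_2 = {A,C}`,
#' `cell_3 = {C,D}`, `cell_4 = {D}`, `cell_5 = {A,B,C,D}`,
#' `cell_6 = {B,D}`), small enough that every downstream quantity can be
#' checked by hand.
#'
#' @return List with elements `tree` (`phylo`) and `occ`
#'   (`occurrence_grid`).
#' @export
micro_fixture <- function() {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m <- rbind(
    cell_1 = c(A = 1, B = 1, C = 0, D = 0),
    cell_2 = c(A = 1, B = 0, C = 1, D = 0),
    cell_3 = c(A = 0, B = 0, C = 1, D = 1),
    cell_4 = c(A = 0, B = 0, C = 0, D = 1),
    cell_5 = c(A = 1, B = 1, C = 1, D = 1),
    cell_6 = c(A = 0, B = 1, C = 0, D = 1))
  coords <- data.frame(cell_id = rownames(m),
                       row = rep(1:2, each = 3),
                       col = rep(1:3, times = 2))
  list(tree = tree, occ = occurrence_grid(m, coords))
}
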