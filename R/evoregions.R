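#' Phylogenetic fuzzy weights Q
#'
#' Pairwise phylogenetic similarity between species derived from patristic
#' distances, `s_ij = 1 - d_ij / max(d)` (so `s_ii = 1` and the most
#' distant pair scores 0), then column-standardized so each column is a
#' probability vector: `q_ij = s_ij / sum_k s_kj`. Column j of Q is the
#' fuzzy degree to which each species "belongs to" species j's lineage.
#'
#' @param tree Ultrametric `phylo` with at least 2 tips.
#' @return Species x species matrix `Q` with unit column sums.
#' @export
phylo_similarity_Q <- function(tree) {
  tree <- validate_tree(tree)
  if (length(tree$tip.label) < 2) {
    stop("need at least 2 species", call. = FALSE)
  }
  d <- patristic_distances(tree)
  dmax <- max(d)
  if (dmax <= 0) stop("all patristic distances are zero", call. = FALSE)
  s <- 1 - d / dmax
  sweep(s, 2, colSums(s), "/")
}

#' Fuzzy phylogenetic composition P
#'
#' Row-standardizes the presence/absence matrix (each cell's presences sum
#' to 1), multiplies by the fuzzy weights `Q`, and re-standardizes rows,
#' yielding for every cell the phylogenetically weighted degree to which
#' each species belongs to that cell's assemblage.
#'
#' @param occ Aligned `occurrence_grid` (no empty cells).
#' @param Q Matrix from [phylo_similarity_Q()]; column order must match
#'   the species order of `occ`.
#' @return Cells x species matrix with unit row sums.
#' @export
fuzzy_composition_P <- function(occ, Q) {
  stopifnot(inherits(occ, "occurrence_grid"))
  if (!identical(colnames(occ$x), colnames(Q))) {
    stop("species order of occ and Q differ; run align_tree_and_table first",
         call. = FALSE)
  }
  rs <- rowSums(occ$x)
  if (any(rs == 0)) stop("empty cells present; align first", call. = FALSE)
  W <- occ$x / rs
  P <- W %*% Q
  P / rowSums(P)
}

#' Principal coordinates of phylogenetic structure (PCPS)
#'
#' Principal coordinate analysis of the fuzzy composition matrix `P`,
#' using square-rooted Bray-Curtis dissimilarities between cells (the
#' square root makes the dissimilarity close to Euclidean-embeddable and
#' avoids meaningful negative eigenvalues). Axes with positive eigenvalues
#' are kept internally; axes explaining more than `retain_threshold` of
#' the positive-eigenvalue variance are flagged as retained for
#' clustering.
#'
#' @param P Matrix from [fuzzy_composition_P()].
#' @param retain_threshold Variance fraction above which an axis is
#'   retained (default 0.05).
#' @return Object of class `pcps`: `scores` (cells x positive axes),
#'   `eigenvalues`, `variance_fractions`, `retained` (logical).
#' @export
pcps <- function(P, retain_threshold = 0.05) {
  if (nrow(P) < 2) stop("need at least 2 cells", call. = FALSE)
  D <- sqrt(as.matrix(vegan::vegdist(P, method = "bray")))
  # cmdscale warns when trailing eigenvalues are not positive; we keep
  # only the positive part anyway
  pc <- suppressWarnings(
    stats::cmdscale(stats::as.dist(D), k = nrow(P) - 1, eig = TRUE))
  eig <- pc$eig
  if (any(eig < -1e-8 * max(abs(eig)))) {
    warning("negative PCoA eigenvalues beyond tolerance; clamping")
  }
  eig[eig < 0] <- 0
  # drop numerically-null axes (their scores are pure round-off noise)
  eig[eig < 1e-10 * max(eig)] <- 0
  npos <- sum(eig > 0)
  scores <- pc$points[, seq_len(min(npos, ncol(pc$points))), drop = FALSE]
  vf <- eig[seq_len(ncol(scores))] / sum(eig)
  retained <- vf > retain_threshold
  if (!any(retained)) retained[1] <- TRUE
  colnames(scores) <- paste0("pcps", seq_len(ncol(scores)))
  rownames(scores) <- rownames(P)
  structure(list(scores = scores,
                 eigenvalues = eig[seq_len(ncol(scores))],
                 variance_fractions = vf,
                 retained = retained,
                 retain_threshold = retain_threshold),
            class = "pcps")
}

#' @export
print.pcps <- function(x, ...) {
  cat("PCPS:", ncol(x$scores), "positive axes,",
      sum(x$retained), "retained (>",
      sprintf("%.0f%% variance)\n", 100 * x$retain_threshold))
  cat("  leading variance fractions:",
      paste(sprintf("%.3f", utils::head(x$variance_fractions, 5)),
            collapse = " "), "\n")
  invisible(x)
}

# Elbow of a curve y(k): the point with maximum perpendicular distance to
# the chord joining the first and last point. Returns an index into k.
elbow_index <- function(k, y) {
  if (length(k) < 3) return(which.max(y))
  x1 <- k[1]; y1 <- y[1]; x2 <- k[length(k)]; y2 <- y[length(k)]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  d <- abs((y2 - y1) * k - (x2 - x1) * y + x2 * y1 - y2 * x1) / len
  which.max(d)
}

#' DAPC-style clustering of PCPS scores into evoregions
#'
#' For every candidate k, k-means (25 restarts) is run on the retained
#' PCPS axes and the explained variance (between-cluster over total sum of
#' squares) recorded. The number of regions is the elbow of that curve:
#' the k with maximum perpendicular distance to the chord joining its end
#' points, i.e. the smallest k achieving most of the attainable explained
#' variance. The chosen k-means partition is then refined by posterior
#' assignment from a linear discriminant analysis fit to it (the "DA" step
#' of DAPC); if the discriminant fit is singular or degenerate the k-means
#' labels stand. Regions are lettered A, B, ... by decreasing size.
#'
#' @param pc A `pcps` object.
#' @param k_range Candidate cluster numbers (default `2:10`).
#' @param seed Integer seed (k-means restarts).
#' @param n_restarts Random k-means restarts per k.
#' @return A `regionalization` (method `"evoregion"`) whose
#'   `explained_variance` is that of the chosen k; the candidate curve is
#'   attached as attribute `diagnostics` (data frame `k`,
#'   `explained_variance`).
#' @export
evoregion_clustering <- function(pc, k_range = 2:10, seed = 1L,
                                 n_restarts = 25L) {
  stopifnot(inherits(pc, "pcps"))
  S <- pc$scores[, pc$retained, drop = FALSE]
  n <- nrow(S)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n - 1)) {
    stop("k_range must lie in [2, n_cells - 1]", call. = FALSE)
  }
  tot <- sum(scale(S, scale = FALSE)^2)
  if (tot <= 0) stop("degenerate input: all cells identical", call. = FALSE)

  fits <- with_seed(seed, lapply(k_range, function(k) {
    stats::kmeans(S, centers = k, nstart = n_restarts, iter.max = 100)
  }))
  ev <- vapply(fits, function(f) f$betweenss / f$totss, numeric(1))
  best <- elbow_index(k_range, ev)
  km <- fits[[best]]
  cl <- km$cluster

  refined <- tryCatch({
    fit <- MASS::lda(S, grouping = factor(cl))
    as.integer(stats::predict(fit, S)$class)
  }, error = function(e) cl)
  if (length(unique(refined)) == length(unique(cl))) cl <- refined

  assignment <- canonical_labels(stats::setNames(as.character(cl),
                                                 rownames(S)))
  out <- regionalization(assignment, method = "evoregion",
                         explained_variance = ev[best])
  attr(out, "diagnostics") <- data.frame(k = k_range,
                                         explained_variance = ev)
  out
}

#' Delineate evoregions end to end
#'
#' Convenience wrapper: aligns tree and table, builds the fuzzy weights Q
#' and composition P, extracts PCPS axes, and clusters cells into
#' evoregions.
#'
#' @inheritParams align_tree_and_table
#' @inheritParams evoregion_clustering
#' @param retain_threshold Passed to [pcps()].
#' @return Object of class `evoregion`: `regionalization`, `pcps`, `Q`,
#'   `P`, `diagnostics`.
#' @export
evoregion <- function(tree, occ, k_range = 2:10, seed = 1L,
                      retain_threshold = 0.05) {
  al <- align_tree_and_table(tree, occ)
  Q <- phylo_similarity_Q(al$tree)
  P <- fuzzy_composition_P(al$occ, Q)
  pc <- pcps(P, retain_threshold = retain_threshold)
  reg <- evoregion_clustering(pc, k_range = k_range, seed = seed)
  reg$coords <- al$occ$coords
  structure(list(regionalization = reg,
                 pcps = pc, Q = Q, P = P,
                 diagnostics = attr(reg, "diagnostics"),
                 tree = al$tree, occ = al$occ),
            class = "evoregion")
}

#' @export
print.evoregion <- function(x, ...) {
  cat("Evoregion delineation\n")
  cat("  PCPS axes retained:", sum(x$pcps$retained), "\n")
  print(x$regionalization)
  invisible(x)
}
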