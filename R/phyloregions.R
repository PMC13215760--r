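#' Branch-based Simpson phylogenetic beta diversity (pbsim)
#'
#' For every pair of grid cells the branches of the tree are partitioned
#' by the cells' assemblages: `a` = total length of branches on the
#' root-to-tip path of at least one species in *both* cells, `b` and `c` =
#' lengths unique to either cell. The Simpson (turnover-only) index is
#' `min(b, c) / (a + min(b, c))`, which is 0 for nested branch sets (pure
#' richness difference) and 1 for assemblages sharing no branches, making
#' it insensitive to richness differences between cells.
#'
#' @param occ Aligned `occurrence_grid` with no empty cells.
#' @param tree Rooted `phylo` aligned to `occ` (same species).
#' @return Symmetric cells x cells matrix in \[0, 1\] with zero diagonal,
#'   of class `betadiv`.
#' @export
phylo_betadiv_sim <- function(occ, tree) {
  stopifnot(inherits(occ, "occurrence_grid"))
  tree <- validate_tree(tree)
  if (!identical(colnames(occ$x), tree$tip.label)) {
    stop("occ and tree are not aligned; run align_tree_and_table first",
         call. = FALSE)
  }
  if (any(rowSums(occ$x) == 0)) {
    stop("empty cells present; drop them before computing beta diversity",
         call. = FALSE)
  }
  bi <- branch_incidence(tree)
  C <- (occ$x %*% bi$incidence) > 0          # cells x branches
  CL <- C * rep(bi$lengths, each = nrow(C))  # length-weighted
  A <- CL %*% t(C)                           # shared branch length
  tot <- rowSums(CL)
  b <- outer(tot, rep(1, length(tot))) - A
  cc <- t(b)
  m <- pmin(b, cc)
  beta <- ifelse(m == 0, 0, m / (A + m))
  diag(beta) <- 0
  dimnames(beta) <- list(rownames(occ$x), rownames(occ$x))
  class(beta) <- c("betadiv", class(beta))
  beta
}

#' UPGMA dendrogram of a beta-diversity matrix
#'
#' Average-linkage agglomerative clustering (`stats::hclust`,
#' `method = "average"`), whose merge heights are guaranteed
#' non-decreasing, so the implied cophenetic distances are ultrametric.
#'
#' @param beta Symmetric dissimilarity matrix (e.g. from
#'   [phylo_betadiv_sim()]).
#' @return An `hclust` object.
#' @export
upgma <- function(beta) {
  beta <- unclass(beta)
  if (!isSymmetric(unname(beta), tol = 1e-12)) {
    stop("beta matrix must be symmetric", call. = FALSE)
  }
  # canonical cell order so exact ties (e.g. identical assemblages) are
  # broken the same way whatever the input row order
  if (!is.null(rownames(beta))) {
    ord <- order(rownames(beta))
    beta <- beta[ord, ord]
  }
  stats::hclust(stats::as.dist(beta), method = "average")
}

# Explained variation of a partition of a dissimilarity matrix:
# 1 - (sum of squared within-group dissimilarities) / (sum of all squared
# dissimilarities). Splitting a group can only remove pairs from the
# within set, so the curve is non-decreasing along nested dendrogram
# cuts; it is 0 at k = 1 and 1 when all clusters are internally
# homogeneous (all within-group dissimilarities zero).
explained_variation <- function(beta, groups) {
  beta2 <- unclass(beta)^2
  ut <- upper.tri(beta2)
  tot <- sum(beta2[ut])
  if (tot <= 0) return(1)
  same <- outer(groups, groups, "==")
  1 - sum(beta2[ut & same]) / tot
}

#' Optimal number of phyloregions
#'
#' Cuts the UPGMA dendrogram at every k up to `k_max` and computes the
#' explained variation of each cut: one minus the ratio of the summed
#' squared within-group dissimilarities to the summed squared
#' dissimilarities overall (so a cut into internally homogeneous
#' clusters explains ~1). The chosen k is the elbow of
#' the curve (maximum perpendicular distance to its chord) provided its
#' explained variation reaches `min_explained`; otherwise the smallest k
#' reaching the floor; if the floor is unreachable at `k_max`, `k_max`
#' with a warning.
#'
#' @param dendrogram `hclust` object from [upgma()].
#' @param beta The dissimilarity matrix the dendrogram was built from.
#' @param k_max Largest candidate k (default 20).
#' @param min_explained Explained-variation floor (default 0.90).
#' @return List with `k` (chosen), `curve` (data frame `k`, `explained`).
#' @export
optimal_k <- function(dendrogram, beta, k_max = 20, min_explained = 0.90) {
  n <- nrow(unclass(beta))
  if (k_max >= n) stop("k_max must be < number of cells", call. = FALSE)
  ks <- seq_len(k_max)
  cuts <- stats::cutree(dendrogram, k = ks)
  expl <- vapply(ks, function(k) {
    explained_variation(beta, cuts[, k])
  }, numeric(1))
  el <- elbow_index(ks, expl)
  if (expl[el] >= min_explained) {
    k <- ks[el]
  } else if (any(expl >= min_explained)) {
    k <- ks[which(expl >= min_explained)[1]]
  } else {
    warning("explained variation never reaches ", min_explained,
            " up to k_max = ", k_max, "; returning k_max")
    k <- k_max
  }
  list(k = k, curve = data.frame(k = ks, explained = expl))
}

#' Cut a dendrogram into k phyloregions
#'
#' @param dendrogram `hclust` object from [upgma()].
#' @param k Number of regions (2 <= k <= n cells).
#' @param coords Optional cell coordinates to attach.
#' @param explained_variance Optional explained variation of this cut.
#' @return A `regionalization` (method `"phyloregion"`), lettered A, B,
#'   ... by decreasing region size.
#' @export
phyloregion_assign <- function(dendrogram, k, coords = NULL,
                               explained_variance = NA_real_) {
  ct <- stats::cutree(dendrogram, k = k)
  assignment <- canonical_labels(stats::setNames(as.character(ct),
                                                 names(ct)))
  regionalization(assignment, method = "phyloregion",
                  explained_variance = explained_variance, coords = coords)
}

#' Delineate phyloregions end to end
#'
#' Aligns tree and table, computes the pbsim matrix, clusters it with
#' UPGMA, selects k by the elbow rule under the explained-variation floor,
#' and returns the lettered regionalization.
#'
#' @inheritParams align_tree_and_table
#' @inheritParams optimal_k
#' @return Object of class `phyloregion`: `regionalization`, `beta`,
#'   `dendrogram`, `k`, `curve`.
#' @export
phyloregion_delineate <- function(tree, occ, k_max = 20,
                                  min_explained = 0.90) {
  al <- align_tree_and_table(tree, occ)
  beta <- phylo_betadiv_sim(al$occ, al$tree)
  dend <- upgma(beta)
  sel <- optimal_k(dend, beta, k_max = min(k_max, nrow(beta) - 1),
                   min_explained = min_explained)
  reg <- phyloregion_assign(dend, sel$k, coords = al$occ$coords,
                            explained_variance =
                              sel$curve$explained[sel$k])
  structure(list(regionalization = reg, beta = beta, dendrogram = dend,
                 k = sel$k, curve = sel$curve,
                 tree = al$tree, occ = al$occ),
            class = "phyloregion")
}

#' @export
print.phyloregion <- function(x, ...) {
  cat("Phyloregion delineation (UPGMA on pbsim)\n")
  print(x$regionalization)
  invisible(x)
}
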