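#' Cross-tabulate two region maps
#'
#' Counts, for every pair of labels, the grid cells carrying that label
#' combination. Cells present in only one map are dropped with a warning.
#'
#' @param mapA,mapB `regionalization` objects or named cell -> label
#'   vectors.
#' @return Integer matrix, regions of A x regions of B.
#' @export
cross_tabulate <- function(mapA, mapB) {
  a <- as_assignment(mapA)
  b <- as_assignment(mapB)
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0L) stop("maps share no cells", call. = FALSE)
  if (length(shared) < length(a) || length(shared) < length(b)) {
    warning("dropping ", length(a) + length(b) - 2L * length(shared),
            " cells missing from one of the maps")
  }
  tab <- table(A = a[shared], B = b[shared])
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}

#' V-measure of two categorical maps
#'
#' Entropy-based spatial agreement between two regionalizations of the
#' same grid, each cell counting once. Homogeneity
#' `h = 1 - H(A|B)/H(A)` measures how well regions of map B are composed
#' of single regions of map A; completeness `c = 1 - H(B|A)/H(B)` the
#' converse; `V = 2hc/(h+c)` is their harmonic mean, ranging from 0 (no
#' congruence) to 1 (identical partitions). Entropies are natural-log.
#' Degenerate cases: `h = 1` when `H(A) = 0`, `c = 1` when `H(B) = 0`,
#' `V = 0` when `h + c = 0`.
#'
#' @param tab Contingency table from [cross_tabulate()].
#' @return Named numeric vector `V`, `homogeneity`, `completeness`.
#' @export
v_measure <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), sum(tab) > 0)
  n <- sum(tab)
  p <- tab / n
  pr <- rowSums(p)
  pc <- colSums(p)
  HA <- shannon_entropy(pr)
  HB <- shannon_entropy(pc)
  nz <- p > 0
  HAgB <- -sum(p[nz] * log(p[nz] / rep(pc, each = nrow(p))[nz]))
  HBgA <- -sum(p[nz] * log(p[nz] / rep(pr, times = ncol(p))[nz]))
  h <- if (HA == 0) 1 else 1 - HAgB / HA
  cm <- if (HB == 0) 1 else 1 - HBgA / HB
  V <- if (h + cm == 0) 0 else 2 * h * cm / (h + cm)
  c(V = V, homogeneity = h, completeness = cm)
}

#' Contiguous random regionalization preserving a template's structure
#'
#' Draws a rook-contiguous random partition of the template's cells into
#' the same number of regions with sizes matching the template's within
#' `size_tol` (default 10%), by seeded region growing toward size
#' targets. Growth deadlocks or out-of-tolerance sizes trigger a restart
#' from a derived seed (up to `max_attempts`); if all attempts fail the
#' size tolerance is relaxed with a warning.
#'
#' @param template_map A `regionalization` with coordinates, or a named
#'   label vector plus `coords`.
#' @param coords Optional cell-centroid data frame if the template does
#'   not carry one.
#' @param seed Integer seed.
#' @param size_tol Relative size tolerance per region.
#' @param max_attempts Restart budget.
#' @return A `regionalization` (method `"random"`).
#' @export
random_regionalization <- function(template_map, coords = NULL, seed = 1L,
                                   size_tol = 0.10, max_attempts = 100L) {
  map <- as_assignment(template_map)
  if (is.null(coords)) coords <- map_coords(template_map)
  if (is.null(coords)) stop("need cell coordinates", call. = FALSE)
  coords <- coords[match(names(map), coords$cell_id), ]
  n <- length(map)
  targets <- as.integer(sort(table(map), decreasing = TRUE))
  k <- length(targets)
  if (k == 1L) {
    return(regionalization(map, method = "random", coords = coords))
  }
  adj <- grid_adjacency(coords)
  seeds <- derive_seeds(seed, max_attempts)
  best <- NULL
  best_dev <- Inf
  for (s in seeds) {
    lab <- with_seed(s, grow_regions(adj, n, k, targets = targets))
    if (any(lab == 0L)) next
    sizes <- tabulate(lab, k)
    dev <- max(abs(sort(sizes, decreasing = TRUE) - targets) /
                 targets)
    if (dev < best_dev) {
      best <- lab
      best_dev <- dev
    }
    if (dev <= size_tol) break
  }
  if (is.null(best)) stop("random regionalization failed", call. = FALSE)
  if (best_dev > size_tol) {
    warning("region sizes deviate from template by up to ",
            sprintf("%.0f%%", 100 * best_dev),
            " (tolerance relaxed)")
  }
  assignment <- canonical_labels(stats::setNames(as.character(best),
                                                 coords$cell_id))
  regionalization(assignment, method = "random", coords = coords)
}

#' Congruence test between two regionalizations
#'
#' Computes the observed V-measure, homogeneity and completeness, then
#' assesses significance with a two-directional randomization: the
#' observed map A is compared against `n_rand` contiguous random
#' regionalizations of map B (preserving B's region count and approximate
#' sizes), and vice versa. Upper-tail p-values use the add-one
#' correction, `p = (1 + #{V_null >= V_obs}) / (1 + n_rand)`; lower-tail
#' analogously. The standardized effect size per direction is
#' `(V_obs - mean(V_null)) / sd(V_null)`; the pooled SES is the mean of
#' the two. Congruence is flagged significant iff *both* upper-tail
#' p-values are below 0.05.
#'
#' @param mapA,mapB `regionalization` objects carrying coordinates.
#' @param n_rand Number of randomizations per direction (default 999).
#' @param seed Integer seed.
#' @param alpha Significance level for the conjunction rule.
#' @return Object of class `congruence`.
#' @export
congruence_test <- function(mapA, mapB, n_rand = 999, seed = 1L,
                            alpha = 0.05) {
  if (n_rand < 1) stop("n_rand must be >= 1", call. = FALSE)
  obs <- v_measure(cross_tabulate(mapA, mapB))
  seeds <- derive_seeds(seed, 2L * n_rand)
  null_randB <- vapply(seq_len(n_rand), function(i) {
    rb <- random_regionalization(mapB, seed = seeds[i])
    v_measure(cross_tabulate(mapA, rb))[["V"]]
  }, numeric(1))
  null_randA <- vapply(seq_len(n_rand), function(i) {
    ra <- random_regionalization(mapA, seed = seeds[n_rand + i])
    v_measure(cross_tabulate(ra, mapB))[["V"]]
  }, numeric(1))
  ptail <- function(null, v) {
    c(upper = (1 + sum(null >= v)) / (1 + length(null)),
      lower = (1 + sum(null <= v)) / (1 + length(null)))
  }
  pA <- ptail(null_randB, obs[["V"]])
  pB <- ptail(null_randA, obs[["V"]])
  ses <- function(null, v) (v - mean(null)) / stats::sd(null)
  ses_A <- ses(null_randB, obs[["V"]])
  ses_B <- ses(null_randA, obs[["V"]])
  structure(list(
    V = obs[["V"]], homogeneity = obs[["homogeneity"]],
    completeness = obs[["completeness"]],
    p_A_vs_randB = pA[["upper"]], p_B_vs_randA = pB[["upper"]],
    p_lower_A_vs_randB = pA[["lower"]], p_lower_B_vs_randA = pB[["lower"]],
    SES_A_vs_randB = ses_A, SES_B_vs_randA = ses_B,
    SES = mean(c(ses_A, ses_B)),
    null_mean = c(A_vs_randB = mean(null_randB),
                  B_vs_randA = mean(null_randA)),
    null_sd = c(A_vs_randB = stats::sd(null_randB),
                B_vs_randA = stats::sd(null_randA)),
    n_randomizations = n_rand,
    significant = pA[["upper"]] < alpha && pB[["upper"]] < alpha,
    alpha = alpha),
    class = "congruence")
}

#' @export
print.congruence <- function(x, ...) {
  cat(sprintf("V-measure congruence: V = %.3f (h = %.3f, c = %.3f)\n",
              x$V, x$homogeneity, x$completeness))
  cat(sprintf("  null (%d reps): p = %.4f / %.4f, SES = %.2f / %.2f (pooled %.2f)\n",
              x$n_randomizations, x$p_A_vs_randB, x$p_B_vs_randA,
              x$SES_A_vs_randB, x$SES_B_vs_randA, x$SES))
  cat("  significant (both p <", x$alpha, "):", x$significant, "\n")
  invisible(x)
}
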