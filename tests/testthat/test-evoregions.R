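test_that("fuzzy weights Q match hand computations", {
  two <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(phylo_similarity_Q(two), diag(2),
               ignore_attr = TRUE)

  fx <- micro_fixture()
  Q <- phylo_similarity_Q(fx$tree)
  expect_equal(unname(Q[, "A"]), c(1, 0.5, 0, 0) / 1.5)
  expect_equal(colSums(Q), setNames(rep(1, 4), LETTERS[1:4]))

  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  s_off <- 1 - patristic_distances(star) / max(patristic_distances(star))
  diag(s_off) <- NA
  expect_equal(stats::sd(s_off, na.rm = TRUE), 0)
})

test_that("Q columns and P rows are probability vectors on random data", {
  for (s in 1:4) {
    d <- small_dataset(n_tips = 15, n_rows = 5, n_cols = 6, k = 2,
                       seed = 100 * s)
    al <- suppressWarnings(align_tree_and_table(d$tree, d$occ))
    Q <- phylo_similarity_Q(al$tree)
    expect_equal(colSums(Q), setNames(rep(1, ncol(Q)), colnames(Q)),
                 tolerance = 1e-9)
    P <- fuzzy_composition_P(al$occ, Q)
    expect_true(all(P >= 0))
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-9)
  }
})

test_that("identity weights leave relative composition unchanged", {
  fx <- micro_fixture()
  Q <- diag(4)
  dimnames(Q) <- list(LETTERS[1:4], LETTERS[1:4])
  P <- fuzzy_composition_P(fx$occ, Q)
  expect_equal(P, fx$occ$x / rowSums(fx$occ$x), ignore_attr = TRUE)
})

test_that("a single-species cell takes that species' fuzzy profile", {
  fx <- micro_fixture()
  m <- rbind(fx$occ$x, cell_7 = c(A = 1, B = 0, C = 0, D = 0))
  coords <- rbind(fx$occ$coords,
                  data.frame(cell_id = "cell_7", row = 3, col = 1))
  occ <- occurrence_grid(m, coords)
  Q <- phylo_similarity_Q(fx$tree)
  P <- fuzzy_composition_P(occ, Q)
  expect_equal(P["cell_7", ], Q["A", ] / sum(Q["A", ]))
})

test_that("PCPS reconstructs the sqrt-Bray-Curtis geometry", {
  d <- small_dataset(n_tips = 12, n_rows = 4, n_cols = 5, k = 2, seed = 77)
  al <- align_tree_and_table(d$tree, d$occ)
  P <- fuzzy_composition_P(al$occ, phylo_similarity_Q(al$tree))
  pc <- pcps(P)
  expect_true(all(pc$eigenvalues >= 0))
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  expect_true(any(pc$retained))
  expect_lte(sum(pc$variance_fractions), 1 + 1e-9)

  D <- sqrt(as.matrix(vegan::vegdist(P, method = "bray")))
  D2hat <- as.matrix(stats::dist(pc$scores))^2
  # valid when essentially no negative eigenvalues were clamped
  expect_equal(D2hat, D^2, ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("identical cells share identical PCPS scores", {
  fx <- micro_fixture()
  m <- rbind(fx$occ$x, cell_7 = fx$occ$x["cell_1", ])
  coords <- rbind(fx$occ$coords,
                  data.frame(cell_id = "cell_7", row = 3, col = 1))
  P <- fuzzy_composition_P(occurrence_grid(m, coords),
                           phylo_similarity_Q(fx$tree))
  pc <- pcps(P)
  expect_equal(pc$scores["cell_7", ], pc$scores["cell_1", ],
               tolerance = 1e-9)
})

test_that("clustering recovers well-separated point clouds", {
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  pts <- do.call(rbind, lapply(1:4, function(i) {
    sweep(matrix(stats::rnorm(40, sd = 0.3), 20, 2), 2, centers[i, ], "+")
  }))
  rownames(pts) <- sprintf("cell_%03d", 1:80)
  pc <- structure(list(scores = pts, eigenvalues = c(2, 1),
                       variance_fractions = c(0.6, 0.4),
                       retained = c(TRUE, TRUE), retain_threshold = 0.05),
                  class = "pcps")
  reg <- evoregion_clustering(pc, k_range = 2:8, seed = 1)
  expect_equal(reg$k, 4)
  truth <- rep(1:4, each = 20)
  expect_equal(mclust::adjustedRandIndex(reg$assignment, truth), 1)
})

test_that("explained variance matches brute-force k-means on 8 points", {
  set.seed(10)
  pts <- matrix(stats::rnorm(16), 8, 2)
  rownames(pts) <- paste0("c", 1:8)
  pc <- structure(list(scores = pts, eigenvalues = c(1, 1),
                       variance_fractions = c(0.5, 0.5),
                       retained = c(TRUE, TRUE), retain_threshold = 0.05),
                  class = "pcps")
  tot <- sum(scale(pts, scale = FALSE)^2)
  best_ev <- function(k) {
    labelings <- as.matrix(expand.grid(rep(list(seq_len(k)), 7)))
    best <- 0
    for (r in seq_len(nrow(labelings))) {
      g <- c(1L, labelings[r, ])
      if (length(unique(g)) != k) next
      w <- sum(vapply(split(seq_len(8), g), function(idx) {
        sum(scale(pts[idx, , drop = FALSE], scale = FALSE)^2)
      }, numeric(1)))
      best <- max(best, 1 - w / tot)
    }
    best
  }
  oracle <- vapply(2:4, best_ev, numeric(1))
  reg <- evoregion_clustering(pc, k_range = 2:4, seed = 3,
                              n_restarts = 50)
  diag <- attr(reg, "diagnostics")
  expect_equal(diag$explained_variance, oracle, tolerance = 1e-8)
  expect_true(all(diff(diag$explained_variance) >= -1e-8))
})

test_that("evoregion delineation is label-permutation stable across seeds", {
  d <- small_dataset(n_tips = 24, n_rows = 10, n_cols = 10, k = 3,
                     seed = 5)
  e1 <- evoregion(d$tree, d$occ, k_range = 2:6, seed = 1)
  e2 <- evoregion(d$tree, d$occ, k_range = 2:6, seed = 999)
  expect_gte(mclust::adjustedRandIndex(e1$regionalization$assignment,
                                       e2$regionalization$assignment),
             0.99)
  # letters are assigned by decreasing size
  sizes <- table(e1$regionalization$assignment)
  expect_true(all(diff(as.integer(sizes[order(names(sizes))])) <= 0))
})

test_that("degenerate inputs are rejected", {
  flat <- ape::read.tree(text = "(A:0,B:0);")
  expect_error(phylo_similarity_Q(flat), "zero")
  fx <- micro_fixture()
  Qbad <- phylo_similarity_Q(fx$tree)[, c(2, 1, 3, 4)]
  expect_error(fuzzy_composition_P(fx$occ, Qbad), "order")
  expect_error(pcps(matrix(1, 1, 3)), "2 cells")
})
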