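test_that("species affiliation applies the 55% rule", {
  coords <- data.frame(cell_id = paste0("c", 1:10), row = 1, col = 1:10)
  map <- regionalization(setNames(rep(c("A", "B"), c(6, 4)),
                                  coords$cell_id),
                         coords = coords)
  m <- cbind(sp1 = rep(1, 10),            # 6/10 in A -> A
             sp2 = rep(c(1, 0), c(6, 4)), # all in A
             sp3 = c(0, 0, 1, 1, 0, 0, 1, 1, 0, 0)) # 50/50 -> widespread
  rownames(m) <- coords$cell_id
  aff <- species_affiliation(occurrence_grid(m, coords), map)
  expect_equal(unname(aff$state[c("sp1", "sp2", "sp3")]),
               c("A", "A", "widespread"))
  expect_equal(aff$fractions["sp1", "A"], 0.6)
  expect_equal(aff$fractions["sp2", "A"], 1)
  expect_equal(unname(rowSums(aff$fractions)), rep(1, 3))

  # threshold comparison is >= : exactly 55% affiliates
  coords2 <- data.frame(cell_id = paste0("c", 1:20), row = 1, col = 1:20)
  map2 <- regionalization(setNames(rep(c("A", "B"), c(11, 9)),
                                   coords2$cell_id), coords = coords2)
  m2 <- matrix(1, 20, 1, dimnames = list(coords2$cell_id, "sp"))
  aff2 <- species_affiliation(occurrence_grid(m2, coords2), map2)
  expect_equal(aff2$fractions["sp", "A"], 0.55)
  expect_equal(unname(aff2$state["sp"]), "A")
})

test_that("pruning likelihood equals exhaustive enumeration", {
  for (s in 1:4) {
    tree <- generate_yule_tree(4, 1, seed = 300 + s)
    tip_states <- with_seed_test(400 + s,
      setNames(sample(c("A", "B", "C"), 4, replace = TRUE),
               tree$tip.label))
    if (length(unique(tip_states)) < 2) tip_states[1] <- "C"
    states <- sort(unique(tip_states))
    for (rate in c(0.1, 0.7, 2)) {
      expect_equal(mk_loglik(tree, tip_states, states, rate),
                   log(mk_lik_enum(tree, tip_states, states, rate)),
                   tolerance = 1e-12)
    }
  }
  # exhaustive over all 5-tip two-state patterns
  tree5 <- generate_yule_tree(5, 1, seed = 77)
  pats <- expand.grid(rep(list(c("A", "B")), 5))
  for (r in seq_len(nrow(pats))) {
    tip_states <- setNames(as.character(unlist(pats[r, ])),
                           tree5$tip.label)
    if (length(unique(tip_states)) < 2) next
    expect_equal(mk_loglik(tree5, tip_states, c("A", "B"), 0.5),
                 log(mk_lik_enum(tree5, tip_states, c("A", "B"), 0.5)),
                 tolerance = 1e-12)
  }
})

test_that("the ML rate matches a dense grid search", {
  fx <- mk_fixture()
  fit <- fit_mk(fx$tree, fx$states)
  h <- max(ape::node.depth.edgelength(fx$tree))
  grid <- exp(seq(log(1e-8), log(500 / h), length.out = 501))
  ll <- vapply(grid, function(r) {
    mk_loglik(fx$tree, fx$states, fit$states, r)
  }, numeric(1))
  best <- grid[which.max(ll)]
  step <- log(grid[2]) - log(grid[1])
  expect_lt(abs(log(fit$rate) - log(best)), step)
  expect_gte(fit$log_likelihood + 1e-9, max(ll))
})

test_that("Mk fit agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  fx <- mk_fixture()
  fit <- fit_mk(fx$tree, fx$states)
  Q <- matrix(fit$rate, 2, 2,
              dimnames = list(fit$states, fit$states))
  diag(Q) <- -fit$rate
  ref <- phytools::fitMk(fx$tree, fx$states, fixedQ = Q, pi = "equal")
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(ref)),
               tolerance = 1e-6)
})

test_that("an invariant character degenerates cleanly", {
  fx <- mk_fixture()
  const <- setNames(rep("A", 6), fx$tree$tip.label)
  expect_warning(fit <- fit_mk(fx$tree, const), "single")
  sm <- stochastic_maps(fit, n_maps = 20, seed = 1)
  expect_equal(sm$mean_transitions, 0)
  expect_true(all(sm$node_freq[, "A"] == 1))
})

test_that("stochastic maps honour tips, sum to one and are seeded", {
  fx <- mk_fixture()
  fit <- fit_mk(fx$tree, fx$states)
  sm <- stochastic_maps(fit, n_maps = 50, seed = 3)
  expect_equal(unname(rowSums(sm$node_freq)), rep(1, 11))
  for (tp in names(fx$states)) {
    expect_equal(unname(sm$node_freq[tp, fx$states[[tp]]]), 1)
  }
  sm2 <- stochastic_maps(fit, n_maps = 50, seed = 3)
  expect_identical(sm$node_freq, sm2$node_freq)
  expect_identical(sm$mean_transitions, sm2$mean_transitions)
})

test_that("endpoint-conditioned fallback matches rejection sampling", {
  # force the uniformization path and compare transition-count
  # distributions against the rejection sampler
  rate <- 0.6; t <- 1.5; m <- 3
  rej <- with_seed_test(5, replicate(4000,
    evoregio:::sample_branch_transitions(1L, 2L, t, rate, m)))
  uni <- with_seed_test(6, replicate(4000,
    evoregio:::sample_branch_transitions(1L, 2L, t, rate, m,
                                         max_reject = 0L)))
  expect_equal(mean(uni), mean(rej), tolerance = 0.1)
  expect_gte(min(uni), 1)  # endpoints differ: at least one transition
})

test_that("evoCA matches its chi-square and SVD identities", {
  # two regions, two private branches: N = [[4,0],[0,4]]
  two <- ape::read.tree(text = "(A:1,B:1);")
  coords <- data.frame(cell_id = paste0("c", 1:8), row = 1, col = 1:8)
  m <- matrix(0L, 8, 2, dimnames = list(coords$cell_id, c("A", "B")))
  m[1:4, "A"] <- 1L
  m[5:8, "B"] <- 1L
  occ <- occurrence_grid(m, coords)
  map <- regionalization(setNames(rep(c("R1", "R2"), each = 4),
                                  coords$cell_id), coords = coords)
  res <- evoca(occ, two, map)
  expect_equal(length(res$eigenvalues), 1)
  expect_equal(res$total_inertia, 1)
  expect_equal(sum(res$site_scores), 0, tolerance = 1e-9)
  expect_equal(abs(res$site_scores[1, 1]), abs(res$site_scores[2, 1]))

  # random data: inertia = chi-square / grand total; centering; SVD
  d <- small_dataset(n_tips = 12, n_rows = 5, n_cols = 5, k = 3, seed = 15)
  al <- align_tree_and_table(d$tree, d$occ)
  res2 <- evoca(al$occ, al$tree, d$land)
  chi <- suppressWarnings(stats::chisq.test(res2$M)$statistic)
  expect_equal(res2$total_inertia, unname(chi) / sum(res2$M),
               tolerance = 1e-10)
  r <- rowSums(res2$M) / sum(res2$M)
  expect_equal(unname(as.vector(r %*% res2$site_scores)),
               rep(0, ncol(res2$site_scores)), tolerance = 1e-9)
  # scores reconstruct the standardized residual matrix
  cc <- colSums(res2$M) / sum(res2$M)
  dvals <- sqrt(res2$eigenvalues)
  S_hat <- (sqrt(r) * res2$site_scores) %*% diag(1 / dvals) %*%
    t(sqrt(cc) * res2$branch_scores)
  P <- res2$M / sum(res2$M)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  expect_equal(S_hat, S, ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("proportional region profiles carry zero inertia", {
  two <- ape::read.tree(text = "(A:1,B:1);")
  coords <- data.frame(cell_id = paste0("c", 1:6), row = 1, col = 1:6)
  m <- matrix(1L, 6, 2, dimnames = list(coords$cell_id, c("A", "B")))
  occ <- occurrence_grid(m, coords)
  map <- regionalization(setNames(rep(c("R1", "R2"), c(2, 4)),
                                  coords$cell_id), coords = coords)
  res <- evoca(occ, two, map)
  expect_equal(res$total_inertia, 0, tolerance = 1e-12)
  expect_equal(sum(abs(res$contributions)), 0)
  expect_false(any(species_contributions(res)$flagged))
})

test_that("species contributions sum to one and are permutation-stable", {
  d <- small_dataset(n_tips = 14, n_rows = 5, n_cols = 5, k = 3, seed = 19)
  al <- align_tree_and_table(d$tree, d$occ)
  res <- evoca(al$occ, al$tree, d$land)
  expect_equal(sum(res$contributions), 1, tolerance = 1e-9)
  expect_true(all(res$contributions >= 0 & res$contributions <= 1))

  perm <- with_seed_test(3, sample(ncol(al$occ$x)))
  occ_p <- occurrence_grid(al$occ$x[, perm, drop = FALSE], al$occ$coords)
  al_p <- suppressWarnings(align_tree_and_table(al$tree, occ_p))
  res_p <- evoca(al_p$occ, al_p$tree, d$land)
  expect_equal(res_p$contributions[names(res$contributions)],
               res$contributions, tolerance = 1e-10)

  sc <- species_contributions(res, threshold = 0.05)
  expect_true(all(diff(sc$contribution) <= 0))
  expect_equal(sc$flagged, sc$contribution >= 0.05)
})
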