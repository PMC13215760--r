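# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation.

# V-measure via the mutual-information identity: h = I/H(A), c = I/H(B).
vmeasure_oracle <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  p <- tab / n
  pr <- rowSums(p)
  pc <- colSums(p)
  H <- function(q) {
    q <- q[q > 0]
    -sum(q * log(q))
  }
  HA <- H(pr); HB <- H(pc); HAB <- H(as.vector(p))
  I <- HA + HB - HAB
  h <- if (HA == 0) 1 else I / HA
  cm <- if (HB == 0) 1 else I / HB
  V <- if (h + cm == 0) 0 else 2 * h * cm / (h + cm)
  c(V = V, homogeneity = h, completeness = cm)
}

# pbsim by explicit enumeration of the branch set of each assemblage:
# walk every present tip's root path with ape::nodepath and union edges.
pbsim_oracle <- function(occ_mat, tree) {
  root <- length(tree$tip.label) + 1L
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  lens <- stats::setNames(tree$edge.length, edge_key)
  branch_set <- function(species) {
    keys <- character(0)
    for (sp in species) {
      np <- ape::nodepath(tree, from = root,
                          to = match(sp, tree$tip.label))
      keys <- union(keys, paste(np[-length(np)], np[-1]))
    }
    keys
  }
  cells <- rownames(occ_mat)
  sets <- lapply(cells, function(cl) {
    branch_set(colnames(occ_mat)[occ_mat[cl, ] > 0])
  })
  out <- matrix(0, length(cells), length(cells),
                dimnames = list(cells, cells))
  for (i in seq_along(cells)) {
    for (j in seq_along(cells)) {
      if (i == j) next
      a <- sum(lens[intersect(sets[[i]], sets[[j]])])
      b <- sum(lens[setdiff(sets[[i]], sets[[j]])])
      cc <- sum(lens[setdiff(sets[[j]], sets[[i]])])
      m <- min(b, cc)
      out[i, j] <- if (m == 0) 0 else m / (a + m)
    }
  }
  out
}

# Generic matrix exponential of the ER rate matrix via eigendecomposition
# (the package uses the closed form instead).
er_ptrans_oracle <- function(rate, t, m) {
  Q <- matrix(rate, m, m)
  diag(Q) <- -(m - 1) * rate
  ev <- eigen(Q, symmetric = TRUE)
  ev$vectors %*% diag(exp(ev$values * t)) %*% t(ev$vectors)
}

# Mk likelihood by exhaustive summation over every internal-node state
# combination.
mk_lik_enum <- function(tree, tip_states, states, rate,
                        root_prior = rep(1 / length(states),
                                         length(states))) {
  m <- length(states)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  tipidx <- match(tip_states[tree$tip.label], states)
  total <- 0
  combos <- as.matrix(expand.grid(rep(list(seq_len(m)), nint)))
  for (r in seq_len(nrow(combos))) {
    st <- c(tipidx, combos[r, ])
    pr <- root_prior[st[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      P <- er_ptrans_oracle(rate, tree$edge.length[e], m)
      pr <- pr * P[st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    }
    total <- total + pr
  }
  total
}

# Marginal ancestral posteriors by the same exhaustive enumeration.
mk_marginals_enum <- function(tree, tip_states, states, rate) {
  m <- length(states)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  tipidx <- match(tip_states[tree$tip.label], states)
  combos <- as.matrix(expand.grid(rep(list(seq_len(m)), nint)))
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e) {
    er_ptrans_oracle(rate, tree$edge.length[e], m)
  })
  post <- matrix(0, nint, m)
  for (r in seq_len(nrow(combos))) {
    st <- c(tipidx, combos[r, ])
    pr <- (1 / m)
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * Ps[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    }
    for (v in seq_len(nint)) post[v, combos[r, v]] <-
        post[v, combos[r, v]] + pr
  }
  post / rowSums(post)
}

# All ways of writing `total` as an ordered sum of `ncell` non-negative
# integers (compositions), as a matrix with one composition per row.
compositions <- function(total, ncell) {
  if (ncell == 1L) return(matrix(total, 1, 1))
  do.call(rbind, lapply(0:total, function(first) {
    rest <- compositions(total - first, ncell - 1L)
    cbind(first, rest, deparse.level = 0)
  }))
}

# Contiguity oracle: igraph connected components on the grid graph.
contiguous_igraph <- function(assignment, coords) {
  adj <- evoregio:::grid_adjacency(coords)
  idx <- stats::setNames(seq_len(nrow(coords)), coords$cell_id)
  edges <- do.call(rbind, lapply(seq_along(adj), function(i) {
    nb <- adj[[i]][adj[[i]] > i]
    if (!length(nb)) return(NULL)
    cbind(i, nb)
  }))
  all(vapply(split(idx[names(assignment)], as.character(assignment)),
             function(members) {
    sub <- edges[edges[, 1] %in% members & edges[, 2] %in% members, ,
                 drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(sub[, 1]),
                 to = as.character(sub[, 2])),
      directed = FALSE,
      vertices = data.frame(name = as.character(members)))
    igraph::components(g)$no == 1
  }, logical(1)))
}

# Tiny aligned dataset used by several module tests.
small_dataset <- function(n_tips = 24, n_rows = 10, n_cols = 10, k = 3,
                          p_in = 0.9, p_out = 0.05, widespread = 0,
                          seed = 42) {
  land <- generate_planted_landscape(n_rows, n_cols, k, seed = seed)
  tree <- generate_yule_tree(n_tips, 1, seed = seed + 1)
  occ <- generate_occurrences(tree, land, p_in, p_out, widespread,
                              seed = seed + 2)
  list(land = land, tree = tree, occ = occ)
}

# Seeded evaluation for test-local randomness.
with_seed_test <- function(seed, code) {
  set.seed(seed)
  code
}

# Fixed 6-tip two-state fixture for the Mk and stochastic-mapping tests.
mk_fixture <- function() {
  tree <- ape::read.tree(
    text = "(((t1:1,t2:1):1,t3:2):1,((t4:1,t5:1):1,t6:2):1);")
  states <- c(t1 = "A", t2 = "A", t3 = "B", t4 = "B", t5 = "B", t6 = "A")
  list(tree = tree, states = states)
}
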