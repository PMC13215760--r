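#' Affiliate species with regions (55% rule)
#'
#' For every species the fraction of its occupied cells falling in each
#' region is computed; the species is affiliated with the region holding
#' at least `threshold` (default 55%) of its cells, and is classed
#' `"widespread"` when no region reaches the threshold.
#'
#' @param occ Aligned `occurrence_grid`.
#' @param reg A `regionalization` covering every occupied cell.
#' @param threshold Affiliation threshold (comparison is `>=`).
#' @return Object of class `affiliation`: `fractions` (species x regions),
#'   `state` (named character: region label or `"widespread"`),
#'   `threshold`.
#' @export
species_affiliation <- function(occ, reg, threshold = 0.55) {
  stopifnot(inherits(occ, "occurrence_grid"), threshold > 0, threshold <= 1)
  map <- as_assignment(reg)
  if (!all(rownames(occ$x) %in% names(map))) {
    stop("regionalization does not cover all occupied cells", call. = FALSE)
  }
  if (any(colSums(occ$x) == 0)) {
    stop("species with zero occupied cells", call. = FALSE)
  }
  labels <- sort(unique(map))
  cell_lab <- factor(map[rownames(occ$x)], levels = labels)
  counts <- t(rowsum(occ$x, cell_lab))          # species x regions
  fractions <- counts / rowSums(counts)
  best <- max.col(fractions, ties.method = "first")
  state <- ifelse(fractions[cbind(seq_len(nrow(fractions)), best)] >=
                    threshold,
                  labels[best], "widespread")
  names(state) <- rownames(fractions)
  structure(list(fractions = fractions, state = state,
                 threshold = threshold),
            class = "affiliation")
}

#' @export
print.affiliation <- function(x, ...) {
  cat("Species affiliation (threshold ", x$threshold, "):\n", sep = "")
  print(table(x$state))
  invisible(x)
}

# Equal-rates Mk transition probability matrix over m states at time t:
# P[same] = 1/m + (m-1)/m e^{-m r t}, P[diff] = (1 - e^{-m r t}) / m.
mk_ptrans <- function(rate, t, m) {
  if (m == 1) return(matrix(1, 1, 1))
  e <- exp(-m * rate * t)
  p <- matrix((1 - e) / m, m, m)
  diag(p) <- 1 / m + (m - 1) * e / m
  p
}

#' Log-likelihood of an equal-rates Mk model
#'
#' Felsenstein pruning: post-order accumulation of conditional likelihoods
#' with per-node rescaling, using the closed-form equal-rates transition
#' probabilities. The root state is integrated over `root_prior`.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param tip_states Named character vector of states, one per tip.
#' @param states Ordered state labels.
#' @param rate Transition rate (per branch-length unit).
#' @param root_prior Probability vector over `states` (default uniform).
#' @return Log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, tip_states, states, rate,
                      root_prior = rep(1 / length(states), length(states))) {
  cl <- mk_conditionals(tree, tip_states, states, rate)
  root <- length(tree$tip.label) + 1L
  # scaling factors propagate to the root during the post-order pass
  log(sum(root_prior * cl$L[root, ])) + cl$logscale[root]
}

# Conditional likelihoods per node (rows rescaled to max 1), with the log
# of the scaling factor accumulated per node; internal marks non-tips.
mk_conditionals <- function(tree, tip_states, states, rate) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  m <- length(states)
  st <- match(tip_states[tree$tip.label], states)
  if (anyNA(st)) stop("tip state missing or not in state set", call. = FALSE)
  L <- matrix(1, nn, m)
  L[seq_len(ntip), ] <- 0
  L[cbind(seq_len(ntip), st)] <- 1
  logscale <- numeric(nn)
  for (e in ape::postorder(tree)) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    p <- mk_ptrans(rate, tree$edge.length[e], m)
    v <- as.vector(p %*% L[child, ])
    L[parent, ] <- L[parent, ] * v
    s <- max(L[parent, ])
    if (s > 0 && s < 1e-10) {
      L[parent, ] <- L[parent, ] / s
      logscale[parent] <- logscale[parent] + log(s)
    }
    logscale[parent] <- logscale[parent] + logscale[child]
  }
  list(L = L, logscale = logscale)
}

#' Fit an equal-rates Mk model to tip states
#'
#' Maximizes the pruning-algorithm likelihood over the single transition
#' rate by bounded one-dimensional optimization on the log-rate scale,
#' with a uniform root prior. When only one state is observed the
#' maximum-likelihood rate degenerates to zero; the rate is then fixed at
#' the lower bound with a warning.
#'
#' @inheritParams mk_loglik
#' @param lower,upper Rate bounds; `upper` defaults to `500 / tree
#'   height`.
#' @return Object of class `mk_fit`: `states`, `rate`, `log_likelihood`,
#'   `root_prior`, `tree`, `tip_states`.
#' @export
fit_mk <- function(tree, tip_states, lower = 1e-8, upper = NULL) {
  tree <- validate_tree(tree)
  tip_states <- stats::setNames(as.character(tip_states), names(tip_states))
  if (!all(tree$tip.label %in% names(tip_states))) {
    stop("every tip needs a state", call. = FALSE)
  }
  tip_states <- tip_states[tree$tip.label]
  states <- sort(unique(tip_states))
  m <- length(states)
  h <- max(node_depths(tree)[seq_len(length(tree$tip.label))])
  if (is.null(upper)) upper <- 500 / max(h, 1e-9)
  prior <- rep(1 / m, m)
  if (m < 2) {
    warning("single observed state; rate fixed at lower bound")
    return(structure(list(states = states, rate = lower,
                          log_likelihood = 0, root_prior = prior,
                          tree = tree, tip_states = tip_states),
                     class = "mk_fit"))
  }
  opt <- stats::optimize(function(lr) {
    mk_loglik(tree, tip_states, states, exp(lr), prior)
  }, interval = log(c(lower, upper)), maximum = TRUE)
  structure(list(states = states, rate = exp(opt$maximum),
                 log_likelihood = opt$objective, root_prior = prior,
                 tree = tree, tip_states = tip_states),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Equal-rates Mk fit:", length(x$states), "states, rate =",
      signif(x$rate, 4), ", logLik =", round(x$log_likelihood, 3), "\n")
  invisible(x)
}

# One endpoint-conditioned transition-count sample on a branch under the
# ER model: forward rejection, then uniformization fallback (with the
# uniformization rate equal to the true leaving rate the self-jump
# probability is zero, so every virtual jump is a real transition and the
# conditioned number of jumps can be sampled from closed-form powers of
# the complete-graph walk matrix).
sample_branch_transitions <- function(i, j, t, rate, m,
                                      max_reject = 200L) {
  if (m == 1) return(0L)
  leave <- (m - 1) * rate
  for (try in seq_len(max_reject)) {
    s <- i
    tt <- stats::rexp(1, leave)
    ntr <- 0L
    while (tt <= t) {
      nxt <- sample.int(m - 1L, 1L)
      s <- if (nxt >= s) nxt + 1L else nxt
      ntr <- ntr + 1L
      tt <- tt + stats::rexp(1, leave)
    }
    if (s == j) return(ntr)
  }
  # uniformization fallback
  mu <- leave * t
  nmax <- max(10L, stats::qpois(1 - 1e-12, mu) + 10L)
  ns <- 0:nmax
  # R^n[i,j] for the complete-graph jump chain
  rn <- if (i == j) {
    ((m - 1)^ns + (m - 1) * (-1)^ns) / (m * (m - 1)^ns)
  } else {
    ((m - 1)^ns - (-1)^ns) / (m * (m - 1)^ns)
  }
  w <- stats::dpois(ns, mu) * rn
  if (sum(w) <= 0) stop("endpoint-conditioned sampling failed", call. = FALSE)
  sample(ns, 1L, prob = w)
}

#' Stochastic character maps of regional affiliation
#'
#' Simulates `n_maps` character histories conditional on the observed tip
#' states under the fitted equal-rates Mk model: node states are drawn
#' jointly (root from prior x conditional likelihood, then pre-order
#' sampling of each child given its parent), and each branch's transition
#' history is drawn from the endpoint-conditioned process by forward
#' rejection with a uniformization fallback. Node state frequencies over
#' maps approximate the marginal ancestral posteriors.
#'
#' @param fit An `mk_fit` (carries tree and tip states).
#' @param n_maps Number of maps (default 1000).
#' @param seed Integer seed.
#' @return Object of class `ancestral_summary`: `node_freq` (all nodes x
#'   states; tip rows are point masses on the observed states), `n_maps`,
#'   `mean_transitions`, `states`, `tree`.
#' @export
stochastic_maps <- function(fit, n_maps = 1000, seed = 1L) {
  stopifnot(inherits(fit, "mk_fit"), n_maps >= 1)
  tree <- fit$tree
  states <- fit$states
  m <- length(states)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  cl <- mk_conditionals(tree, fit$tip_states, states, fit$rate)
  po <- ape::postorder(tree)
  pre <- rev(po)
  ptr <- lapply(seq_len(nrow(tree$edge)), function(e) {
    mk_ptrans(fit$rate, tree$edge.length[e], m)
  })
  counts <- matrix(0L, nn, m, dimnames = list(NULL, states))
  total_transitions <- 0
  with_seed(seed, {
    for (rep in seq_len(n_maps)) {
      node_state <- integer(nn)
      w <- fit$root_prior * cl$L[root, ]
      node_state[root] <- sample.int(m, 1L, prob = w)
      for (e in pre) {
        parent <- tree$edge[e, 1]
        child <- tree$edge[e, 2]
        w <- ptr[[e]][node_state[parent], ] * cl$L[child, ]
        node_state[child] <- sample.int(m, 1L, prob = w)
        total_transitions <- total_transitions +
          sample_branch_transitions(node_state[parent], node_state[child],
                                    tree$edge.length[e], fit$rate, m)
      }
      counts[cbind(seq_len(nn), node_state)] <-
        counts[cbind(seq_len(nn), node_state)] + 1L
    }
  })
  node_ids <- c(tree$tip.label, paste0("node", (ntip + 1L):nn))
  freq <- counts / n_maps
  rownames(freq) <- node_ids
  structure(list(node_freq = freq, n_maps = n_maps,
                 mean_transitions = total_transitions / n_maps,
                 states = states, tree = tree),
            class = "ancestral_summary")
}

#' @export
print.ancestral_summary <- function(x, ...) {
  cat("Ancestral-state summary over", x$n_maps, "stochastic maps;",
      "mean transitions per map:", round(x$mean_transitions, 2), "\n")
  ntip <- length(x$tree$tip.label)
  cat("Root state frequencies:\n")
  print(round(x$node_freq[ntip + 1L, ], 3))
  invisible(x)
}

#' Phylogenetic correspondence analysis (evoCA)
#'
#' Correspondence analysis in which the columns are the branch units of
#' the phylogeny rather than species: the regions x species table of
#' occupied-cell counts is projected onto branches (each branch column is
#' its length times the summed counts of the species descending from it)
#' and the chi-square standardized residuals of that table are decomposed
#' by SVD. Region (site) and branch scores are reported in principal
#' coordinates; the inertia carried by each branch is apportioned to the
#' species on whose root-to-tip path it lies, shared branches being
#' divided equally among their present descendant species, which yields a
#' per-species fraction of total inertia summing to one.
#'
#' @param occ Aligned `occurrence_grid`.
#' @param tree Rooted `phylo` aligned to `occ`.
#' @param reg A `regionalization` with at least 2 regions.
#' @return Object of class `evoca`: `eigenvalues`, `site_scores`,
#'   `branch_scores`, `contributions` (named, per species),
#'   `total_inertia`, `N` (regions x species counts), `M` (regions x
#'   branches).
#' @export
evoca <- function(occ, tree, reg) {
  stopifnot(inherits(occ, "occurrence_grid"))
  tree <- validate_tree(tree)
  if (!identical(colnames(occ$x), tree$tip.label)) {
    stop("occ and tree are not aligned", call. = FALSE)
  }
  map <- as_assignment(reg)
  labels <- sort(unique(map[rownames(occ$x)]))
  if (length(labels) < 2) stop("need at least 2 regions", call. = FALSE)
  cell_lab <- factor(map[rownames(occ$x)], levels = labels)
  N <- rowsum(occ$x, cell_lab)                      # regions x species
  empty <- rowSums(N) == 0
  if (any(empty)) {
    warning("dropping region(s) with no occupied cells: ",
            paste(labels[empty], collapse = ", "))
    N <- N[!empty, , drop = FALSE]
  }
  bi <- branch_incidence(tree)
  M <- (N %*% bi$incidence) * rep(bi$lengths, each = nrow(N))
  keep <- colSums(M) > 0
  M <- M[, keep, drop = FALSE]
  inc <- bi$incidence[, keep, drop = FALSE]

  grand <- sum(M)
  Pm <- M / grand
  r <- rowSums(Pm)
  cc <- colSums(Pm)
  E <- outer(r, cc)
  S <- (Pm - E) / sqrt(E)
  sv <- svd(S)
  pos <- sv$d^2 > 1e-12
  if (!any(pos)) pos[1] <- TRUE   # degenerate table: keep one null axis
  d <- sv$d[pos]
  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  site_scores <- sweep(U, 1, sqrt(r), "/") %*% diag(d, length(d))
  branch_scores <- sweep(V, 1, sqrt(cc), "/") %*% diag(d, length(d))
  dimnames(site_scores) <- list(rownames(M),
                                paste0("axis", seq_len(ncol(site_scores))))
  dimnames(branch_scores) <- list(colnames(M),
                                  colnames(site_scores))
  total_inertia <- sum(d^2)

  inertia_b <- colSums(S^2)
  npres <- colSums(inc)                 # present descendants per branch
  share <- inertia_b / pmax(npres, 1L)
  contributions <- as.vector(inc %*% share)
  names(contributions) <- rownames(inc)
  contributions <- if (total_inertia > 0) {
    contributions / total_inertia
  } else {
    contributions * 0
  }

  structure(list(eigenvalues = d^2, site_scores = site_scores,
                 branch_scores = branch_scores,
                 contributions = contributions,
                 total_inertia = total_inertia, N = N, M = M),
            class = "evoca")
}

#' @export
print.evoca <- function(x, ...) {
  cat("Phylogenetic correspondence analysis:",
      length(x$eigenvalues), "axes, total inertia",
      signif(x$total_inertia, 5), "\n")
  cat("Top species contributions:\n")
  print(round(utils::head(sort(x$contributions, decreasing = TRUE), 5), 3))
  invisible(x)
}

#' Species contributing most to between-region phylogenetic differences
#'
#' Flags species whose apportioned share of the evoCA inertia reaches
#' `threshold` (default 5% of the explained variation), sorted by
#' contribution in decreasing order.
#'
#' @param evoca_result An `evoca` object.
#' @param threshold Contribution threshold (comparison is `>=`).
#' @return Data frame `species`, `contribution`, `flagged`, sorted by
#'   decreasing contribution.
#' @export
species_contributions <- function(evoca_result, threshold = 0.05) {
  stopifnot(inherits(evoca_result, "evoca"))
  contr <- sort(evoca_result$contributions, decreasing = TRUE)
  data.frame(species = names(contr),
             contribution = unname(contr),
             flagged = unname(contr) >= threshold &
               evoca_result$total_inertia > 0,
             row.names = NULL)
}
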