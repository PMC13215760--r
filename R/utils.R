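# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one parent seed, all < 2^31.
derive_seeds <- function(seed, n) {
  (as.integer(seed) %% 1000003L) * 1009L + seq_len(n)
}

# Shannon entropy (nats) of a count or probability vector.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

# Region labels A, B, ... (falls back to R01, R02, ... past 26).
region_letters <- function(k) {
  if (k <= 26L) LETTERS[seq_len(k)] else sprintf("R%02d", seq_len(k))
}

# Relabel a partition so labels are A, B, ... in decreasing region size,
# ties broken by the lexicographically smallest member cell id.
canonical_labels <- function(assignment) {
  stopifnot(!is.null(names(assignment)))
  groups <- split(names(assignment), as.character(assignment))
  sizes <- vapply(groups, length, integer(1))
  firsts <- vapply(groups, function(g) min(g), character(1))
  ord <- order(-sizes, firsts)
  map <- stats::setNames(region_letters(length(groups)), names(groups)[ord])
  out <- unname(map[as.character(assignment)])
  names(out) <- names(assignment)
  out
}

# Rook-adjacency of grid cells; returns a list of integer neighbour indices
# aligned with the rows of `coords` (columns cell_id, row, col).
grid_adjacency <- function(coords) {
  stopifnot(all(c("cell_id", "row", "col") %in% names(coords)))
  key <- paste(coords$row, coords$col, sep = "_")
  idx <- stats::setNames(seq_len(nrow(coords)), key)
  lapply(seq_len(nrow(coords)), function(i) {
    r <- coords$row[i]; c <- coords$col[i]
    nb <- c(paste(r - 1L, c, sep = "_"), paste(r + 1L, c, sep = "_"),
            paste(r, c - 1L, sep = "_"), paste(r, c + 1L, sep = "_"))
    unname(idx[nb[nb %in% names(idx)]])
  })
}

# BFS flood fill: is the cell set `members` (integer indices) connected
# under the adjacency list `adj`?
is_connected_set <- function(members, adj) {
  if (length(members) <= 1L) return(TRUE)
  inset <- logical(length(adj))
  inset[members] <- TRUE
  seen <- logical(length(adj))
  queue <- members[1L]
  seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    nb <- adj[[v]]
    nb <- nb[inset[nb] & !seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  sum(seen) == length(members)
}

# All regions of an assignment contiguous on the grid?
all_regions_contiguous <- function(assignment, coords) {
  adj <- grid_adjacency(coords)
  idx <- stats::setNames(seq_len(nrow(coords)), coords$cell_id)
  groups <- split(idx[names(assignment)], as.character(assignment))
  all(vapply(groups, is_connected_set, logical(1), adj = adj))
}
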