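# Shared fixtures and independent oracles for the test suite.

# -- cached end-to-end fixture (built once per test run) ---------------------

.fx <- new.env(parent = emptyenv())

fixture_complex <- function() {
  if (is.null(.fx$sc)) {
    path <- file.path(tempdir(), "pm13_fixture.pdb")
    make_complex_pdb(path)
    raw <- parse_structure(path)
    .fx$raw <- raw
    .fx$sc <- standardize_complex(raw, identify_complexes(raw)[[1]])
  }
  .fx$sc
}

fixture_pockets <- function() {
  if (is.null(.fx$pockets)) {
    .fx$pockets <- extract_pockets(fixture_complex())
  }
  .fx$pockets
}

# a pocket built directly from typed coordinates
manual_pocket <- function(xyz, types, kind = "synthetic") {
  atoms <- data.frame(chain = "A", resno = seq_len(nrow(xyz)),
                      resname = "UNK", elety = "X", type = types,
                      radius = group_radius(types),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  structure(list(kind = kind, atoms = atoms, source = "test"),
            class = "pm13_pocket")
}

# 4 C4H3 atoms at the corners of a 2 A square, and its 3-corner sub-pocket
square_pocket <- function() {
  manual_pocket(2 * cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0), rep("C4H3", 4))
}
corner_pocket <- function() {
  manual_pocket(2 * cbind(c(0, 1, 1), c(0, 0, 1), 0), rep("C4H3", 3))
}

# -- independent oracles ------------------------------------------------------

# maximum bipartite matching size on the |a_i - b_j| <= t compatibility graph
oracle_max_matching <- function(a, b, threshold) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(0L)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, na + nb, type = c(rep(FALSE, na),
                                                 rep(TRUE, nb)))
  edges <- c()
  for (i in seq_len(na)) {
    hit <- which(abs(a[i] - b) <= threshold)
    if (length(hit)) edges <- c(edges, rbind(i, na + hit))
  }
  if (is.null(edges)) return(0L)
  g <- igraph::add_edges(g, as.vector(edges))
  igraph::max_bipartite_match(g)$matching_size
}

# Needleman-Wunsch oracle (match +1, mismatch 0, gap -1): optimal score only
oracle_global_alignment_score <- function(q, r, match = 1, mismatch = 0,
                                          gap = -1) {
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  n <- length(qs); m <- length(rs)
  F <- matrix(0, n + 1, m + 1)
  F[, 1] <- gap * (0:n); F[1, ] <- gap * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    F[i + 1, j + 1] <- max(F[i, j] + ifelse(qs[i] == rs[j], match, mismatch),
                           F[i, j + 1] + gap,
                           F[i + 1, j] + gap)
  }
  F[n + 1, m + 1]
}

# score of an alignment mapping under the same scheme (to compare optima)
mapping_alignment_score <- function(mapping, q, r, match = 1, mismatch = 0,
                                    gap = -1) {
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  aligned <- which(!is.na(mapping))
  s <- sum(ifelse(qs[aligned] == rs[mapping[aligned]], match, mismatch))
  # gaps: unaligned query residues plus unaligned reference positions
  n_gap <- sum(is.na(mapping)) + (length(rs) - length(aligned))
  s + gap * n_gap
}

# brute-force rigid superposition RMSD: multistart quasi-Newton over Euler
# angles, translation solved by centroid matching
oracle_superpose_rmsd <- function(mobile, target) {
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Rz %*% Ry %*% Rx
  }
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(target, 2, colMeans(target))
  f <- function(ang) sqrt(mean(rowSums((A %*% rot(ang) - B)^2)))
  best <- Inf
  grid <- seq(0, 2 * pi, length.out = 5)[-5]
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    o <- stats::optim(c(a1, a2, a3), f, method = "BFGS")
    if (o$value < best) best <- o$value
  }
  best
}

# naive per-point occlusion recomputation (independent loops, no pruning)
oracle_sasa <- function(atoms, probe = 1.4, n_points = 960) {
  sp <- sphere_points(n_points)
  n <- nrow(atoms)
  vapply(seq_len(n), function(i) {
    R <- atoms$radius[i] + probe
    pts <- sp * R
    pts[, 1] <- pts[, 1] + atoms$x[i]
    pts[, 2] <- pts[, 2] + atoms$y[i]
    pts[, 3] <- pts[, 3] + atoms$z[i]
    acc <- 0L
    for (k in seq_len(n_points)) {
      inside <- FALSE
      for (j in seq_len(n)) {
        if (j == i) next
        Rj <- atoms$radius[j] + probe
        if ((pts[k, 1] - atoms$x[j])^2 + (pts[k, 2] - atoms$y[j])^2 +
            (pts[k, 3] - atoms$z[j])^2 < Rj^2) { inside <- TRUE; break }
      }
      if (!inside) acc <- acc + 1L
    }
    4 * pi * R^2 * acc / n_points
  }, 1)
}

random_sorted_list <- function(n, span = 20) sort(stats::runif(n, 0, span))
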