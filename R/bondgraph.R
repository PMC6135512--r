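# Bond-graph derived pair classes (1-2, 1-3, 1-4), cached per topology.

bond_graph <- function(top) {
  cache <- top$cache
  if (!is.null(cache$graph)) return(cache$graph)
  n <- n_atoms(top)
  adj <- vector("list", n)
  b <- top$bonds
  if (nrow(b)) {
    for (r in seq_len(nrow(b))) {
      adj[[b[r, 1]]] <- c(adj[[b[r, 1]]], b[r, 2])
      adj[[b[r, 2]]] <- c(adj[[b[r, 2]]], b[r, 1])
    }
  }
  pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  p12 <- if (nrow(b)) pair_key(b[, 1], b[, 2]) else character(0)
  p13 <- character(0); p14 <- character(0)
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      p13 <- c(p13, pair_key(cmb[1, ], cmb[2, ]))
    }
  }
  p13 <- setdiff(unique(p13), p12)
  if (nrow(b)) {
    for (r in seq_len(nrow(b))) {   # central bond j-k of each 1-4 path
      j <- b[r, 1]; k <- b[r, 2]
      ni <- setdiff(adj[[j]], k); nl <- setdiff(adj[[k]], j)
      if (length(ni) && length(nl)) {
        grid <- expand.grid(i = ni, l = nl)
        grid <- grid[grid$i != grid$l, , drop = FALSE]
        if (nrow(grid)) p14 <- c(p14, pair_key(grid$i, grid$l))
      }
    }
  }
  p14 <- setdiff(unique(p14), c(p12, p13))
  g <- list(adj = adj, p12 = p12, p13 = p13, p14 = p14)
  cache$graph <- g
  g
}

pair_class_matrix <- function(top) {
  # 0 = ordinary nonbonded, 1 = excluded (1-2/1-3), 2 = scaled (1-4)
  cache <- top$cache
  if (!is.null(cache$pcm)) return(cache$pcm)
  n <- n_atoms(top)
  g <- bond_graph(top)
  M <- matrix(0L, n, n)
  set_pairs <- function(keys, val) {
    if (!length(keys)) return()
    ij <- do.call(rbind, strsplit(keys, " "))
    i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
    M[cbind(i, j)] <<- val; M[cbind(j, i)] <<- val
  }
  set_pairs(c(g$p12, g$p13), 1L)
  set_pairs(g$p14, 2L)
  cache$pcm <- M
  M
}
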