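# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the package's own code paths: graph distances by a plain
# BFS, E-state sums by the literal double sum, hat matrices and LOO by
# explicit matrix algebra / refits.

# build a mol_graph directly (elements + bond list + optional coordinates)
make_mol <- function(elements, bonds, coords = NULL, id = "toy") {
  atoms <- tibble::tibble(
    element = elements,
    x = if (is.null(coords)) 0 else coords[, 1],
    y = if (is.null(coords)) 0 else coords[, 2],
    z = if (is.null(coords)) 0 else coords[, 3]
  )
  b <- tibble::tibble(i = bonds[, 1], j = bonds[, 2],
                      order = if (ncol(bonds) > 2) bonds[, 3] else 1L)
  tzdqsar:::new_mol_graph(id, atoms, b, smiles = NULL)
}

# point cloud of identical "atoms" for MoRSE / WHIM geometry tests: a chain
# of bonds keeps the graph connected, geometry carries the information
make_cloud <- function(coords, elements = NULL) {
  n <- nrow(coords)
  elements <- elements %||% rep("C", n)
  bonds <- cbind(seq_len(n - 1), 2:n)
  make_mol(elements, bonds, coords = coords)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# plain BFS shortest-path distances over an adjacency list
bfs_distances <- function(n, edges) {
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

# literal Kier-Hall double sum on the heavy-atom graph of a mol_graph
brute_estate <- function(mol, delta_v = "screened") {
  el_all <- mol$atoms$element
  heavy <- which(el_all != "H")
  hmap <- match(seq_along(el_all), heavy)
  eb <- as.matrix(mol$bonds[, c("i", "j")])
  # H counts
  nh <- sapply(heavy, function(i) {
    nb <- c(eb[eb[, 1] == i, 2], eb[eb[, 2] == i, 1])
    sum(el_all[nb] == "H")
  })
  he <- eb[el_all[eb[, 1]] != "H" & el_all[eb[, 2]] != "H", , drop = FALSE]
  he <- cbind(hmap[he[, 1]], hmap[he[, 2]])
  n <- length(heavy)
  d <- bfs_distances(n, he)
  tab <- list(C = c(6, 4, 2), N = c(7, 5, 2), O = c(8, 6, 2),
              F = c(9, 7, 2), S = c(16, 6, 3), Cl = c(17, 7, 3),
              Br = c(35, 7, 4))
  I <- numeric(n)
  for (k in seq_len(n)) {
    pr <- tab[[el_all[heavy[k]]]]
    z <- pr[1]; zv <- pr[2]; L <- pr[3]
    delta <- sum(he[, 1] == k) + sum(he[, 2] == k)
    dv <- if (delta_v == "classic") zv - nh[k] else (zv - nh[k]) / (z - zv - 1)
    I[k] <- ((2 / L)^2 * dv + 1) / delta
  }
  dI <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) dI[i] <- dI[i] + (I[i] - I[j]) / (d[i, j] + 1)^2
    }
  }
  list(I = I, dI = dI, maxdp = max(c(dI, 0)))
}

# hat matrix by explicit algebra
brute_hat <- function(X) {
  Xa <- cbind(1, as.matrix(X))
  Xa %*% solve(t(Xa) %*% Xa) %*% t(Xa)
}

# PRESS by n explicit lm() refits
brute_press <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  e <- numeric(n)
  for (i in seq_len(n)) {
    fit <- lm(y[-i] ~ X[-i, , drop = FALSE])
    pred <- sum(c(1, X[i, ]) * coef(fit))
    e[i] <- y[i] - pred
  }
  sum(e^2)
}

# Q2_LOO via brute_press (oracle for subset fitness)
brute_q2 <- function(X, y) 1 - brute_press(X, y) / sum((y - mean(y))^2)

random_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# permute atom order of a mol_graph, remapping bonds
permute_mol <- function(mol, perm) {
  inv <- order(perm)
  atoms <- mol$atoms[perm, ]
  bonds <- tibble::tibble(i = inv[mol$bonds$i], j = inv[mol$bonds$j],
                          order = mol$bonds$order)
  tzdqsar:::new_mol_graph(mol$id, atoms, bonds, smiles = NULL)
}
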