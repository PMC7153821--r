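# Independent oracles used across the suite: naive reimplementations kept
# deliberately simple (and slow) so they cannot share defects with the
# package's optimized paths.

# O(n^3) unweighted average-linkage agglomeration with a distance cutoff.
naive_average_linkage <- function(D, cutoff) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    m <- length(clusters)
    if (m == 1) break
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best[1]) best <- c(d, i, j)
    }
    if (best[1] > cutoff) break
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  labels <- integer(n)
  for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
  labels
}

# partition equality up to relabeling
same_partition <- function(a, b) {
  length(a) == length(b) &&
    identical(match(a, unique(a)), match(b, unique(b)))
}

# textbook Kosaraju strongly connected components on an adjacency matrix
kosaraju_scc <- function(adj) {
  n <- nrow(adj)
  visited <- rep(FALSE, n)
  order <- integer(0)
  dfs1 <- function(v) {
    visited[v] <<- TRUE
    for (u in which(adj[v, ] > 0)) if (!visited[u]) dfs1(u)
    order <<- c(order, v)
  }
  for (v in seq_len(n)) if (!visited[v]) dfs1(v)
  comp <- rep(0L, n)
  cur <- 0L
  tadj <- t(adj)
  for (v in rev(order)) {
    if (comp[v] == 0L) {
      cur <- cur + 1L
      st <- v
      comp[v] <- cur
      while (length(st) > 0) {
        u <- st[length(st)]
        st <- st[-length(st)]
        nbrs <- which(tadj[u, ] > 0 & comp == 0L)
        comp[nbrs] <- cur
        st <- c(st, nbrs)
      }
    }
  }
  comp
}

# term-by-term dihedral metric
naive_dihedral_distance <- function(a, b) {
  s <- 0
  for (k in seq_along(a)) s <- s + 2 * (1 - cos((a[k] - b[k]) * pi / 180))
  sqrt(s / length(a))
}

# simulate a discrete Markov chain (1-based states)
simulate_chain <- function(T, n, start = 1L) {
  cum <- t(apply(T, 1, cumsum))
  s <- integer(n)
  s[1] <- start
  u <- stats::runif(n)
  for (t in 2:n) s[t] <- sum(u[t] > cum[s[t - 1], ]) + 1L
  s
}

# Monte-Carlo mean first passage time (steps) from `source` to set `target`
mc_mfpt_steps <- function(T, source, target, n_walks) {
  cum <- t(apply(T, 1, cumsum))
  cur <- rep(source, n_walks)
  steps <- rep(0L, n_walks)
  alive <- seq_len(n_walks)
  t <- 0L
  while (length(alive) > 0) {
    t <- t + 1L
    u <- stats::runif(length(alive))
    nxt <- rowSums(u > cum[cur[alive], , drop = FALSE]) + 1L
    cur[alive] <- nxt
    done <- nxt %in% target
    steps[alive[done]] <- t
    alive <- alive[!done]
    if (t > 1e6) stop("MC walk did not absorb")
  }
  steps
}

# --- ideal backbone builder (NeRF) for PDB round-trip tests ---------------

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# place atom D bonded to C with length L, bond angle theta (B-C-D) and
# torsion chi (A-B-C-D), all degrees
nerf_place <- function(A, B, C, L, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- c(-L * cos(th), L * sin(th) * cos(ch), L * sin(th) * sin(ch))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# backbone N/CA/C coordinates for n_res residues with given phi/psi
# (omega fixed trans); returns a data.frame atom/resno/xyz
build_backbone <- function(n_res, phi, psi) {
  phi <- rep(phi, length.out = n_res)
  psi <- rep(psi, length.out = n_res)
  bl <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329)
  ba <- c(N_CA_C = 111.2, CA_C_N = 116.2, C_N_CA = 121.7)
  coords <- list()
  # seed first residue
  N1 <- c(0, 0, 0)
  CA1 <- c(bl["N_CA"], 0, 0)
  th <- ba["N_CA_C"] * pi / 180
  C1 <- CA1 + bl["CA_C"] * c(-cos(th), sin(th), 0)
  coords[[1]] <- rbind(N = N1, CA = CA1, C = C1)
  for (r in 2:n_res) {
    prev <- coords[[r - 1]]
    N <- nerf_place(prev["N", ], prev["CA", ], prev["C", ], bl["C_N"],
                    ba["CA_C_N"], psi[r - 1])
    CA <- nerf_place(prev["CA", ], prev["C", ], N, bl["N_CA"],
                     ba["C_N_CA"], 180)          # omega trans
    C <- nerf_place(prev["C", ], N, CA, bl["CA_C"], ba["N_CA_C"], phi[r])
    coords[[r]] <- rbind(N = N, CA = CA, C = C)
  }
  do.call(rbind, lapply(seq_len(n_res), function(r) {
    data.frame(elety = c("N", "CA", "C"), resno = r,
               x = coords[[r]][, 1], y = coords[[r]][, 2], z = coords[[r]][, 3])
  }))
}

# minimal PDB text (optionally multi-model) from a build_backbone table
write_backbone_pdb <- function(tab, path, chain = "A", n_models = 1) {
  lines <- character(0)
  atom_lines <- vapply(seq_len(nrow(tab)), function(i) {
    sprintf("ATOM  %5d  %-3s ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            i, tab$elety[i], chain, tab$resno[i], tab$x[i], tab$y[i], tab$z[i],
            substr(tab$elety[i], 1, 1))
  }, character(1))
  if (n_models == 1) {
    lines <- c(atom_lines, "END")
  } else {
    for (m in seq_len(n_models)) {
      lines <- c(lines, sprintf("MODEL     %4d", m), atom_lines, "ENDMDL")
    }
    lines <- c(lines, "END")
  }
  writeLines(lines, path)
  path
}

# small synthetic spec used by several files (fast, well separated)
small_spec <- function(seed = 11, n_traj = 40, traj_len = 300) {
  default_synthetic_spec(seed = seed, n_traj = n_traj, traj_len = traj_len)
}
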