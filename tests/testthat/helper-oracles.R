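# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# Flood-fill connected components by breadth-first search over an explicit
# queue; returns an integer label matrix (labels in raster order of first
# pixel, to allow partition comparison by pixel sets).
oracle_flood_fill <- function(bin, connectivity) {
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(-1:1, each = 3), rep(-1:1, 3))[-5, ]
  }
  cur <- 0L
  qr <- integer(nr * nc); qc <- integer(nr * nc)  # flat FIFO queue
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    # note: column-major visit order on purpose (differs from implementation)
    if (!bin[rr, cc] || lab[rr, cc] != 0L) next
    cur <- cur + 1L
    head <- 1L; tail <- 1L
    qr[1] <- rr; qc[1] <- cc
    lab[rr, cc] <- cur
    while (head <= tail) {
      pr <- qr[head]; pc <- qc[head]; head <- head + 1L
      for (k in seq_len(nrow(nb))) {
        r2 <- pr + nb[k, 1]; c2 <- pc + nb[k, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            bin[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          tail <- tail + 1L
          qr[tail] <- r2; qc[tail] <- c2
        }
      }
    }
  }
  lab
}

# Canonical partition of a label matrix: list of sorted pixel-index vectors,
# ordered by their smallest member. Two labelings are equivalent iff their
# partitions are identical.
label_partition <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0) return(list())
  comps <- unname(split(idx, lab[idx]))
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, min, 0))]
}

# Winding-number point-in-polygon (different algorithm from the even-odd
# crossing test used in the package). Points on the boundary are inside.
oracle_point_in_polygon <- function(px, py, vx, vy, tol = 1e-9) {
  n <- length(vx)
  vapply(seq_along(px), function(q) {
    x <- px[q]; y <- py[q]
    wn <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      # boundary check
      cross <- (vx[j] - vx[i]) * (y - vy[i]) - (vy[j] - vy[i]) * (x - vx[i])
      dot <- (x - vx[i]) * (vx[j] - vx[i]) + (y - vy[i]) * (vy[j] - vy[i])
      len2 <- (vx[j] - vx[i])^2 + (vy[j] - vy[i])^2
      if (abs(cross) <= tol * max(1, sqrt(len2)) && dot >= -tol &&
          dot <= len2 + tol) return(TRUE)
      if (vy[i] <= y) {
        if (vy[j] > y && cross > 0) wn <- wn + 1
      } else {
        if (vy[j] <= y && cross < 0) wn <- wn - 1
      }
    }
    wn != 0
  }, logical(1))
}

# Exhaustive maximum any-overlap bipartite matching over an overlap incidence
# matrix (rows = reference objects, cols = automated objects), for small
# object counts.
oracle_max_matching <- function(inc) {
  nr <- nrow(inc); nc <- ncol(inc)
  if (nr == 0 || nc == 0) return(0L)
  best <- 0L
  recurse <- function(r, used_cols, count) {
    if (count + (nr - r + 1) <= best) return()
    if (r > nr) { best <<- max(best, count); return() }
    recurse(r + 1, used_cols, count)  # leave row r unmatched
    for (c in seq_len(nc)) {
      if (!used_cols[c] && inc[r, c]) {
        used_cols[c] <- TRUE
        recurse(r + 1, used_cols, count + 1L)
        used_cols[c] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nc), 0L)
  best
}

# Independent Kruskal-Wallis H from the textbook rank-sum form
# H = 12/(N(N+1)) * sum(R_i^2 / n_i) - 3(N+1), tie-corrected.
oracle_kw_H <- function(groups) {
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  n <- lengths(groups)
  idx <- rep(seq_along(groups), n)
  Rsum <- tapply(r, idx, sum)
  H <- 12 / (N * (N + 1)) * sum(Rsum^2 / n) - 3 * (N + 1)
  tie <- table(pooled)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# Exhaustive permutation distribution of H for small pooled samples.
oracle_kw_perm_p <- function(groups) {
  pooled <- unlist(groups)
  n <- lengths(groups)
  H_obs <- oracle_kw_H(groups)
  # enumerate all assignments of pooled indices to groups of sizes n
  combos_first <- utils::combn(length(pooled), n[1])
  count <- 0L; total <- 0L
  for (i in seq_len(ncol(combos_first))) {
    rest <- setdiff(seq_along(pooled), combos_first[, i])
    combos_second <- if (length(n) == 3) utils::combn(rest, n[2]) else
      matrix(rest, ncol = 1)
    for (j in seq_len(ncol(combos_second))) {
      g1 <- pooled[combos_first[, i]]
      g2 <- pooled[combos_second[, j]]
      g3idx <- setdiff(rest, combos_second[, j])
      gs <- if (length(n) == 3) list(g1, g2, pooled[g3idx]) else list(g1, g2)
      total <- total + 1L
      if (oracle_kw_H(gs) >= H_obs - 1e-12) count <- count + 1L
    }
  }
  count / total
}

# Small deterministic binary fixture grids.
random_binary_matrix <- function(nr, nc, p = 0.4) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}
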