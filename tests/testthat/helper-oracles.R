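# Brute-force O(N^2) neighbour oracle with per-axis minimum image
brute_pairs <- function(pos, cutoff, box) {
  n <- nrow(pos)
  len <- box$hi - box$lo
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pos[i, ] - pos[j, ]
      for (k in 1:3) {
        if (box$periodic[k]) d[k] <- d[k] - len[k] * round(d[k] / len[k])
      }
      if (sum(d^2) < cutoff^2) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

pair_key <- function(p) {
  if (nrow(p) == 0) return(character(0))
  sort(paste(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2])))
}

# Brute-force DPD force evaluation (no noise) matching the engine's
# conventions, for force-equivalence checks
brute_dpd_forces <- function(sys, inter, box) {
  n <- nrow(sys$pos)
  f <- matrix(0, n, 3)
  len <- box$hi - box$lo
  rc <- inter$rc
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ti <- sys$type[i] + 1L
      tj <- sys$type[j] + 1L
      if (ti == 2 && tj == 2) next
      if (sys$cell[i] > 0 && sys$cell[i] == sys$cell[j]) next
      d <- sys$pos[i, ] - sys$pos[j, ]
      for (k in 1:3) {
        if (box$periodic[k]) d[k] <- d[k] - len[k] * round(d[k] / len[k])
      }
      r <- sqrt(sum(d^2))
      if (r >= rc || r < 1e-10) next
      rh <- d / r
      wc <- 1 - r / rc
      wr <- wc^inter$s
      dv <- sys$vel[i, ] - sys$vel[j, ]
      fm <- inter$a[ti, tj] * wc -
        inter$gamma[ti, tj] * wr^2 * sum(rh * dv)
      f[i, ] <- f[i, ] + fm * rh
      f[j, ] <- f[j, ] - fm * rh
    }
  }
  f
}

# small random particle system in a box
random_system <- function(n, box, seed, vel_sd = 0) {
  set.seed(seed)
  pos <- sapply(1:3, function(k) runif(n, box$lo[k], box$hi[k]))
  vel <- matrix(rnorm(3 * n, 0, vel_sd), n, 3)
  particle_system(pos, vel)
}

# central finite-difference force check for a membrane energy term
fd_force_error <- function(vertices, topo, keep, n_probe = 6, h = 1e-5,
                           seed = 1) {
  r <- mavessel:::membrane_eval(vertices, topo, keep)
  en <- function(V) {
    x <- mavessel:::membrane_eval(V, topo, keep, want_forces = FALSE)
    x$vs + x$vb + x$va + x$vv
  }
  fmax <- max(abs(r$forces))
  set.seed(seed)
  err <- 0
  for (i in sample(nrow(vertices), n_probe)) {
    for (k in 1:3) {
      Vp <- vertices; Vp[i, k] <- Vp[i, k] + h
      Vm <- vertices; Vm[i, k] <- Vm[i, k] - h
      g <- -(en(Vp) - en(Vm)) / (2 * h)
      err <- max(err, abs(g - r$forces[i, k]))
    }
  }
  err / fmax
}

# perturbed copy of a mesh for gradient checks
perturbed_vertices <- function(mesh, scale = 1.02, sd = 0.01, seed = 1) {
  set.seed(seed)
  mesh$vertices * scale +
    matrix(rnorm(length(mesh$vertices), 0, sd), nrow(mesh$vertices), 3)
}
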