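# Shared fixtures and independent oracles, built in code at test time.

# small design used by most synthetic-data tests
tiny_config <- function(seed = 7, ...) {
  synthetic_config(n_lots = 1, passages = 2:4, n_wells = 1, n_fields = 2,
                   image_shape = c(256, 256), cells_per_field = 6,
                   seed = seed, ...)
}

make_square_mask <- function(side = 20, pad = 4) {
  m <- matrix(FALSE, side + 2 * pad, side + 2 * pad)
  m[(pad + 1):(pad + side), (pad + 1):(pad + side)] <- TRUE
  m
}

make_disk_mask <- function(r = 50, pad = 5) {
  s <- -(r + pad):(r + pad)
  outer(s^2, s^2, `+`) <= r^2
}

# Independent connected-component count by breadth-first search in plain R
# (used as the flood-fill oracle against the compiled labeller).
bfs_label_count <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  count <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1L
    queue <- matrix(c(i, j), 1)
    seen[i, j] <- TRUE
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        r2 <- cur[1] + offs[k, 1]; c2 <- cur[2] + offs[k, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          queue <- rbind(queue, c(r2, c2))
        }
      }
    }
  }
  count
}

# independent per-object sizes via the BFS labeller
bfs_component_sizes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  offs <- cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  sizes <- integer(0)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || seen[i, j]) next
    sz <- 0L
    queue <- matrix(c(i, j), 1)
    seen[i, j] <- TRUE
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      sz <- sz + 1L
      for (k in seq_len(nrow(offs))) {
        r2 <- cur[1] + offs[k, 1]; c2 <- cur[2] + offs[k, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          queue <- rbind(queue, c(r2, c2))
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  sizes
}

random_rgb <- function(nr = 32, nc = 32) {
  array(sample(0:255, nr * nc * 3, replace = TRUE), c(nr, nc, 3))
}

# one random per-hour summary block (stats data frame + count)
random_stats_block <- function() {
  stats <- as.data.frame(do.call(rbind, lapply(MORPH_FEATURES, function(f) {
    v <- sort(runif(5, 1, 10))
    int <- v[4] - v[2]
    c(AVE = mean(v), Q10 = v[1], Q25 = v[2], Q50 = v[3], Q75 = v[4],
      Q90 = v[5], MED = v[3], INT = int,
      SKEW = (v[4] + v[2] - 2 * v[3]) / int,
      KURT = (v[5] - v[1]) / int)
  })))
  rownames(stats) <- MORPH_FEATURES
  list(stats = stats, count = runif(1, 10, 50))
}

# per-hour distribution summaries with arbitrary values, for M-pattern tests
random_summaries <- function(hours = c(24, 48, 72, 96),
                             constant_over_time = FALSE) {
  blocks <- if (constant_over_time) {
    b <- random_stats_block()
    rep(list(b), length(hours))
  } else replicate(length(hours), random_stats_block(), simplify = FALSE)
  names(blocks) <- as.character(hours)
  blocks
}

# mean-zero exactly-orthonormal design (X'X / n = I, columns mean 0)
orthonormal_design <- function(n = 12, p = 6) {
  H <- stats::contr.helmert(n)[, seq_len(p), drop = FALSE]
  sweep(H, 2, sqrt(colMeans(H^2)), "/")
}

MORPH_FEATURES <- mscmorph:::MORPH_FEATURES
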