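# Independent brute-force oracles, deliberately written in the most naive
# style possible and sharing no code with the package internals.

# nearest-centroid assignment by a double loop; ties -> lowest index
oracle_assign <- function(x, mu) {
  labels <- integer(nrow(x))
  dist2 <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    best <- Inf
    best_j <- NA_integer_
    for (j in seq_len(nrow(mu))) {
      d <- sum((x[i, ] - mu[j, ])^2)
      if (d < best) {
        best <- d
        best_j <- j
      }
    }
    labels[i] <- best_j
    dist2[i] <- best
  }
  list(labels = labels, dist2 = dist2)
}

# textbook Lloyd iteration: assign every observation, replace each
# non-empty cluster's centroid by its member mean, repeat. Records the
# centroid matrix after every update so trajectories can be compared.
oracle_lloyd <- function(x, init, max_iter = 100) {
  mu <- init
  history <- list()
  labels <- NULL
  for (t in seq_len(max_iter)) {
    a <- oracle_assign(x, mu)
    labels <- a$labels
    for (j in seq_len(nrow(mu))) {
      members <- which(labels == j)
      if (length(members) > 0) {
        mu[j, ] <- colMeans(x[members, , drop = FALSE])
      }
    }
    history[[t]] <- mu
    # converged when a further assignment pass no longer moves anything
    if (t > 1 && identical(history[[t]], history[[t - 1]])) break
  }
  list(centroids = mu, labels = oracle_assign(x, mu)$labels,
       history = history)
}

oracle_wcss <- function(x, labels, mu) {
  total <- 0
  per <- numeric(nrow(mu))
  for (i in seq_len(nrow(x))) {
    d <- sum((x[i, ] - mu[labels[i], ])^2)
    per[labels[i]] <- per[labels[i]] + d
    total <- total + d
  }
  list(per_cluster = per, total = total)
}

# densify MatrixMarket coordinate triplets read as plain text
oracle_dense_from_mtx <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "%")]
  hdr <- scan(text = lines[1], quiet = TRUE)
  out <- matrix(0, hdr[1], hdr[2])
  for (ln in lines[-1]) {
    v <- scan(text = ln, quiet = TRUE)
    out[v[1], v[2]] <- v[3]
  }
  out
}

# exact distribution of the ordered (first, second) k-means++ pick on a
# tiny point set with k = 2: first uniform, second proportional to squared
# distance to the first
oracle_kmeanspp_pair_probs <- function(pts) {
  n <- length(pts)
  probs <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d2 <- (pts - pts[i])^2
    probs[i, ] <- (1 / n) * d2 / sum(d2)
  }
  probs
}

# constraint checker for the default chunk rectangle: (i) area under the
# bound (unless the whole matrix is smaller), (ii) fits in the matrix,
# (iii) aspect-matched - each dimension within one integer step of the
# exact scaled value
check_chunk_constraints <- function(geom, n_rows, n_cols, max_area = 1e6) {
  r <- geom$chunk_rows
  cc <- geom$chunk_cols
  fits <- r >= 1 && cc >= 1 && r <= n_rows && cc <= n_cols
  whole <- as.numeric(n_rows) * n_cols < max_area
  area_ok <- if (whole) {
    r == n_rows && cc == n_cols
  } else {
    as.numeric(r) * cc < max_area
  }
  aspect_ok <- if (whole) TRUE else {
    scale <- sqrt((max_area - 1) / (as.numeric(n_rows) * n_cols))
    r_t <- scale * n_rows
    c_t <- scale * n_cols
    if (c_t < 1) {
      # extreme aspect: the thin dimension clamps to 1 and the other takes
      # the largest extent the area bound allows
      cc == 1 && r == min(n_rows, max_area - 1)
    } else if (r_t < 1) {
      r == 1 && cc == min(n_cols, max_area - 1)
    } else {
      abs(r - r_t) <= 1 + 1e-9 && abs(cc - c_t) <= 1 + 1e-9
    }
  }
  fits && area_ok && aspect_ok
}
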