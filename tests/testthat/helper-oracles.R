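# Independent brute-force oracles used to check each pipeline stage. These
# deliberately share no code with the package implementation: loops and
# first-principles definitions only.

# Count voxels of a discrete ball by exhaustive voxel-centre distance.
oracle_ball_count <- function(radius) {
  n <- 0L
  for (x in -ceiling(radius):ceiling(radius))
    for (y in -ceiling(radius):ceiling(radius))
      for (z in -ceiling(radius):ceiling(radius))
        if (x^2 + y^2 + z^2 <= radius^2 + 1e-12) n <- n + 1L
  n
}

# Fraction of a discrete ball still covered after an integer shift:
# |shifted ball intersect ball| / |ball|, all within the grid.
oracle_shifted_ball_overlap <- function(center, radius, shift, dims) {
  inside <- function(p, c) sum((p - c)^2) <= radius^2 + 1e-12
  both <- 0L; total <- 0L
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    p <- c(x, y, z)
    if (inside(p, center)) total <- total + 1L
    if (inside(p, center) && inside(p, center + shift)) both <- both + 1L
  }
  both / total
}

# Full-sort top-k selection with lexicographic tie-breaking.
oracle_topk <- function(values, mask, k) {
  idx <- which(mask)
  v <- values[idx]
  ord <- order(v, -idx, decreasing = TRUE)   # by value desc, then index asc
  sort(idx[ord][seq_len(k)])
}

# Steepest-ascent basin labelling: from every supra-floor voxel, repeatedly
# step to the strictly greater 6-neighbour with the highest value (ties ->
# lowest linear index) until a local maximum; terminal maxima that touch
# within a 26-neighbourhood belong to one basin.
oracle_watershed <- function(map, floor = 0) {
  dims <- dim(map)
  lin <- function(p) p[1] + (p[2] - 1) * dims[1] + (p[3] - 1) * dims[1] * dims[2]
  offs6 <- rbind(c(0, 0, -1), c(0, -1, 0), c(-1, 0, 0),
                 c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  climb <- function(p) {
    repeat {
      cur <- map[p[1], p[2], p[3]]
      best <- NULL; bestv <- -Inf; besti <- Inf
      for (m in seq_len(nrow(offs6))) {
        q <- p + offs6[m, ]
        if (any(q < 1) || any(q > dims)) next
        vq <- map[q[1], q[2], q[3]]
        if (vq <= floor || vq <= cur) next
        if (vq > bestv || (vq == bestv && lin(q) < besti)) {
          best <- q; bestv <- vq; besti <- lin(q)
        }
      }
      if (is.null(best)) return(p)
      p <- best
    }
  }
  roots <- array(0L, dims)
  sup <- which(map > floor)
  for (v in sup) {
    p <- arrayInd(v, dims)[1, ]
    roots[v] <- lin(climb(p))
  }
  # merge roots that are 26-adjacent
  root_ids <- sort(unique(roots[roots > 0L]))
  parent <- seq_along(root_ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  coords <- arrayInd(root_ids, dims)
  for (a in seq_along(root_ids)) for (b in seq_along(root_ids)) {
    if (a < b && all(abs(coords[a, ] - coords[b, ]) <= 1)) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  group <- vapply(seq_along(root_ids), find, integer(1))
  labels <- array(0L, dims)
  for (v in sup) labels[v] <- group[match(roots[v], root_ids)]
  labels
}

# Do two labelled partitions agree up to a relabelling?
same_partition <- function(l1, l2) {
  if (!all((l1 > 0) == (l2 > 0))) return(FALSE)
  idx <- which(l1 > 0)
  key <- paste(l1[idx], l2[idx])
  length(unique(key)) == length(unique(l1[idx])) &&
    length(unique(l1[idx])) == length(unique(l2[idx]))
}

# Largest cluster of TRUE voxels under 6-connectivity, by repeated set growth.
oracle_max_cluster <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(0L)
  coords <- arrayInd(idx, dims)
  seen <- rep(FALSE, length(idx))
  best <- 0L
  for (s in seq_along(idx)) {
    if (seen[s]) next
    comp <- s; frontier <- s; seen[s] <- TRUE
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        d <- abs(coords[, 1] - coords[f, 1]) + abs(coords[, 2] - coords[f, 2]) +
          abs(coords[, 3] - coords[f, 3])
        nb <- which(d == 1 & !seen)
        seen[nb] <- TRUE
        nxt <- c(nxt, nb)
      }
      comp <- c(comp, nxt); frontier <- nxt
    }
    best <- max(best, length(comp))
  }
  best
}

# Closed-form inverse-variance weighted mean.
oracle_ivw <- function(effects, variances) {
  w <- 1 / variances
  list(effect = sum(w * effects) / sum(w), variance = 1 / sum(w))
}

# Normalized sampled 3-D Gaussian (product of axis kernels) centred at `center`.
oracle_gaussian_response <- function(dims, center, sigma_vox) {
  k1 <- function(n, c, s) {
    r <- ceiling(4 * s)
    w <- exp(-((-r):r)^2 / (2 * s^2)); w <- w / sum(w)
    out <- numeric(n)
    for (t in (-r):r) {
      j <- c + t
      if (j >= 1 && j <= n) out[j] <- out[j] + w[t + r + 1]
    }
    out
  }
  kx <- k1(dims[1], center[1], sigma_vox[1])
  ky <- k1(dims[2], center[2], sigma_vox[2])
  kz <- k1(dims[3], center[3], sigma_vox[3])
  outer(outer(kx, ky), kz)
}

# Small fixture: a map of Gaussian bumps on a grid.
make_bump_map <- function(dims, centers, height = 1, width = 6) {
  m <- array(0, dims)
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
    for (b in seq_len(nrow(centers))) {
      m[i, j, k] <- m[i, j, k] +
        height * exp(-sum((c(i, j, k) - centers[b, ])^2) / width)
    }
  }
  m
}

# Quick random z-map with some spatial structure (smoothed white noise).
random_smooth_map <- function(dims, seed, fwhm = 6) {
  z <- withr::with_seed(seed, array(rnorm(prod(dims)), dims))
  smooth_probability_map(abs(z), fwhm, c(2, 2, 2))
}
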