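# Brute-force oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (loops, all-pairs) and independent of the
# package's implementation paths.

# All-pairs Euclidean distance (px) from every pixel to the nearest TRUE
# pixel of `mask`. Only usable on small grids.
brute_distance_px <- function(mask) {
  ij <- which(mask, arr.ind = TRUE)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(Inf, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    out[r, c] <- sqrt(min((ij[, 1] - r)^2 + (ij[, 2] - c)^2))
  }
  out
}

# Pixels 8-adjacent to `mask` (excluding mask itself), by direct enumeration.
brute_adjacent8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  ij <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(ij))) {
    for (dr in -1:1) for (dc in -1:1) {
      r <- ij[k, 1] + dr; c <- ij[k, 2] + dc
      if (r >= 1 && r <= h && c >= 1 && c <= w) out[r, c] <- TRUE
    }
  }
  out & !mask
}

# Random connected blob mask: a random walk dilated once, kept off borders.
random_blob <- function(h, w, n_seed = 30) {
  m <- matrix(FALSE, h, w)
  r <- sample(3:(h - 2), 1); c <- sample(3:(w - 2), 1)
  for (i in seq_len(n_seed)) {
    m[r, c] <- TRUE
    r <- min(max(r + sample(-1:1, 1), 3), h - 2)
    c <- min(max(c + sample(-1:1, 1), 3), w - 2)
  }
  m
}

# Random axis-aligned rectangle mask, off the image border.
random_rect <- function(h, w, min_side = 2) {
  r0 <- sample(2:(h - min_side - 1), 1)
  c0 <- sample(2:(w - min_side - 1), 1)
  r1 <- min(h - 1, r0 + sample(min_side:(min_side + 10), 1))
  c1 <- min(w - 1, c0 + sample(min_side:(min_side + 10), 1))
  m <- matrix(FALSE, h, w)
  m[r0:r1, c0:c1] <- TRUE
  m
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Small, fast section spec used throughout the unit tests.
test_spec <- function(...) {
  args <- list(...)
  defaults <- list(scale = 12, growth_steps = 40, seed = 11)
  do.call(section_spec, utils::modifyList(defaults, args))
}
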