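# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All generator entry points route their randomness through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# 8-connected binary dilation of a logical matrix by one pixel.
dilate8 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  out[-h, ] <- out[-h, ] | m[-1, ]
  out[-1, ] <- out[-1, ] | m[-h, ]
  out[, -w] <- out[, -w] | m[, -1]
  out[, -1] <- out[, -1] | m[, -w]
  out[-h, -w] <- out[-h, -w] | m[-1, -1]
  out[-1, -1] <- out[-1, -1] | m[-h, -w]
  out[-h, -1] <- out[-h, -1] | m[-1, -w]
  out[-1, -w] <- out[-1, -w] | m[-h, -1]
  out
}

# Neighbour linear indices (8-connectivity) for cells of an h x w grid.
# Assumes no index lies on the image border (masks are kept off the border).
neighbor_idx8 <- function(idx, h) {
  offs <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
  rep(idx, each = 8L) + offs
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  invisible(x)
}

mm_to_px <- function(mm, pixel_edge_um) mm * 1000 / pixel_edge_um
um_to_px <- function(um, pixel_edge_um) um / pixel_edge_um

# Vectorised HSV -> RGB (all components in [0,1]); returns list(r, g, b).
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

clamp01 <- function(x) pmax(pmin(x, 1), 0)  # x first: keeps dim attributes
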