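# Independent oracles and fixture builders used across the suite.

# Boundary pixels of a component: pixels missing at least one 4-neighbor.
boundary_pixels <- function(rows, cols) {
  key <- paste(rows, cols)
  has <- function(r, c) paste(r, c) %in% key
  keep <- !(has(rows - 1, cols) & has(rows + 1, cols) &
              has(rows, cols - 1) & has(rows, cols + 1))
  list(rows = rows[keep], cols = cols[keep])
}

# Brute-force Feret oracle over all boundary-pixel pairs, same pixel-center
# + one-pixel-extent convention as the package. Max Feret: largest pairwise
# center distance. Min Feret: smallest caliper width over every pair-defined
# direction (every convex-hull edge is such a pair, and no direction can
# give a width below the minimal one, so the minimum over pairs is exact).
brute_feret <- function(rows, cols) {
  b <- boundary_pixels(rows, cols)
  pts <- cbind(b$cols, b$rows)
  n <- nrow(pts)
  if (n == 1L) return(c(max = 1, min = 1))
  dmax <- max(dist(pts))
  cb <- utils::combn(n, 2L)
  dx <- pts[cb[2L, ], 1L] - pts[cb[1L, ], 1L]
  dy <- pts[cb[2L, ], 2L] - pts[cb[1L, ], 2L]
  len <- sqrt(dx^2 + dy^2)
  keep <- len > 0
  nx <- -dy[keep] / len[keep]
  ny <- dx[keep] / len[keep]
  proj <- pts[, 1L] %o% nx + pts[, 2L] %o% ny
  widths <- apply(proj, 2L, function(p) max(p) - min(p))
  c(max = dmax + 1, min = min(widths) + 1)
}

# Independent rasterizer: pixel centers (r - 0.5, c - 0.5) inside a rotated
# rectangle or ellipse centred at (x0, y0) in pixel units.
rasterize_shape <- function(nr, nc, shape, x0, y0, L, W, theta) {
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rr <- matrix(rep(seq_len(nr), nc), nr, nc)
  X <- (cc - 0.5) - x0
  Y <- (rr - 0.5) - y0
  U <- X * cos(theta) + Y * sin(theta)
  V <- -X * sin(theta) + Y * cos(theta)
  if (shape == "rect") abs(U) <= L / 2 & abs(V) <= W / 2
  else (U / (L / 2))^2 + (V / (W / 2))^2 <= 1
}

# Match detected particle centroids (0-based pixel coords) to ground-truth
# centers (physical um); returns the truth row index nearest to each.
match_truth <- function(particles, truth, pixel_size) {
  px <- (particles$centroid_col + 0.5) * pixel_size
  py <- (particles$centroid_row + 0.5) * pixel_size
  vapply(seq_len(nrow(particles)), function(j)
    which.min((truth$x_um - px[j])^2 + (truth$y_um - py[j])^2), integer(1))
}

# Evaluate code under a fixed seed without disturbing the session RNG.
with_fixed_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Default PE-standard sampling parameters (25 fields at 2000X on a 385 mm^2
# filter, 2 L/min for 1 min).
pe_sampling <- function(n_fov = 25)
  sampling_params(385, 0.0031, n_fov, 2000, 1)
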