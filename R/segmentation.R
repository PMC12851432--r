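#' Label 8-connected foreground components
#'
#' Run-based two-pass labeling with union-find. 8-connectivity is used so
#' that thin diagonal fibers remain single components.
#'
#' @param mask Logical matrix (`TRUE` = foreground).
#' @return Integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in first-encounter order.
#' @export
label_components <- function(mask) {
  if (!is.matrix(mask)) stop("'mask' must be a matrix")
  mode(mask) <- "logical"
  nr <- nrow(mask)
  labels <- matrix(0L, nr, ncol(mask))
  parent <- integer(0)
  nlab <- 0L
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  prev <- NULL # runs of the previous row: start col, end col, raw label
  for (i in seq_len(nr)) {
    rowv <- mask[i, ]
    if (!any(rowv)) { prev <- NULL; next }
    idx <- which(rowv)
    brk <- which(diff(idx) > 1L)
    s <- idx[c(1L, brk + 1L)]
    e <- idx[c(brk, length(idx))]
    labs <- integer(length(s))
    for (j in seq_along(s)) {
      lab <- 0L
      if (!is.null(prev)) {
        # 8-connected overlap: previous-row run within one column
        ov <- which(prev[, 1L] <= e[j] + 1L & prev[, 2L] >= s[j] - 1L)
        for (q in ov) {
          r2 <- find(prev[q, 3L])
          if (lab == 0L) lab <- r2
          else if (r2 != lab) { parent[r2] <- find(lab); lab <- find(lab) }
        }
      }
      if (lab == 0L) {
        nlab <- nlab + 1L
        parent[nlab] <- nlab
        lab <- nlab
      }
      labs[j] <- lab
      labels[i, s[j]:e[j]] <- lab
    }
    prev <- cbind(s, e, labs)
  }
  if (nlab > 0L) {
    root <- vapply(seq_len(nlab), find, integer(1))
    dense <- match(root, unique(root))
    nz <- labels != 0L
    labels[nz] <- dense[labels[nz]]
  }
  labels
}

# Feret diameters (max and min caliper) of a pixel component, in pixel
# units. Convention: calipers are taken over the convex hull of the pixel
# centres and one pixel is added for the pixel extent, so a single pixel
# measures 1 x 1 and a 1 x n run measures n x 1.
feret_diameters <- function(rows, cols) {
  n <- length(rows)
  if (n == 0L) stop("empty component")
  if (n == 1L) return(c(max = 1, min = 1))
  pts <- cbind(as.numeric(cols), as.numeric(rows))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  dmax <- max(stats::dist(hp))
  m <- nrow(hp)
  if (m <= 2L) {
    wmin <- 0
  } else {
    nxt <- c(seq_len(m)[-1L], 1L)
    ex <- hp[nxt, 1L] - hp[, 1L]
    ey <- hp[nxt, 2L] - hp[, 2L]
    len <- sqrt(ex^2 + ey^2)
    ks <- which(len > 0)
    # minimal caliper width is attained perpendicular to a hull edge
    widths <- vapply(ks, function(k) {
      pr <- hp[, 1L] * (-ey[k] / len[k]) + hp[, 2L] * (ex[k] / len[k])
      max(pr) - min(pr)
    }, numeric(1))
    wmin <- min(widths)
  }
  c(max = dmax + 1, min = wmin + 1)
}

#' Measure one connected component
#'
#' Length and width are the maximum and minimum Feret (caliper) diameters of
#' the component's pixel footprint, in micrometres; area is
#' `pixel_count * pixel_size^2`. Calipers are computed over the convex hull
#' of the pixel centres plus one pixel of extent, which makes a single pixel
#' measure `pixel_size` in both directions and an axis-aligned `m x n` block
#' measure its diagonal by `n` pixels.
#'
#' @param rows,cols Integer pixel coordinates of the component (1-based,
#'   equal length).
#' @param pixel_size Micrometres per pixel.
#' @return A list with `length_um`, `width_um`, `aspect_ratio`, `area_um2`,
#'   `pixel_count`.
#' @export
measure_component <- function(rows, cols, pixel_size) {
  if (length(rows) != length(cols) || length(rows) == 0L)
    stop("'rows' and 'cols' must be non-empty and of equal length")
  if (pixel_size <= 0) stop("'pixel_size' must be positive")
  f <- feret_diameters(rows, cols)
  list(length_um = unname(f["max"]) * pixel_size,
       width_um = unname(f["min"]) * pixel_size,
       aspect_ratio = unname(f["max"] / f["min"]),
       area_um2 = length(rows) * pixel_size^2,
       pixel_count = length(rows))
}

#' Extract measured particles from a binary mask
#'
#' Labels 8-connected foreground components, discards components below the
#' minimum pixel count (the sub-pixel detection floor), measures each
#' survivor with [measure_component()], and flags components touching the
#' image border. The pixel total of discarded sub-floor components is
#' attached as attribute `"discarded_pixels"` so that foreground area is
#' fully accounted for.
#'
#' @param mask Logical matrix from [binarize()].
#' @param pixel_size Micrometres per pixel.
#' @param min_pixels Minimum component size in pixels (default 4); smaller
#'   components cannot be measured meaningfully and are discarded.
#' @param fov_id Field-of-view identifier used to build particle ids.
#' @return A data frame with one row per particle: `particle_id`, `fov_id`,
#'   `length_um`, `width_um`, `aspect_ratio`, `area_um2`, `pixel_count`,
#'   `centroid_row`, `centroid_col` (0-based pixel coordinates),
#'   `touches_border`.
#' @export
extract_particles <- function(mask, pixel_size, min_pixels = 4L,
                              fov_id = "fov1") {
  if (!is.matrix(mask)) stop("'mask' must be a matrix")
  if (pixel_size <= 0) stop("'pixel_size' must be positive")
  empty <- data.frame(particle_id = character(), fov_id = character(),
                      length_um = numeric(), width_um = numeric(),
                      aspect_ratio = numeric(), area_um2 = numeric(),
                      pixel_count = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), touches_border = logical(),
                      stringsAsFactors = FALSE)
  labels <- label_components(mask)
  idx <- which(labels > 0L)
  if (length(idx) == 0L) {
    attr(empty, "discarded_pixels") <- 0L
    return(empty)
  }
  nr <- nrow(mask)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  lab <- labels[idx]
  comps_r <- split(rows, lab)
  comps_c <- split(cols, lab)
  counts <- lengths(comps_r)
  keep <- counts >= min_pixels
  discarded <- sum(counts[!keep])
  comps_r <- comps_r[keep]
  comps_c <- comps_c[keep]
  if (length(comps_r) == 0L) {
    attr(empty, "discarded_pixels") <- as.integer(discarded)
    return(empty)
  }
  ncm <- ncol(mask)
  out <- lapply(seq_along(comps_r), function(k) {
    r <- comps_r[[k]]; cc <- comps_c[[k]]
    m <- measure_component(r, cc, pixel_size)
    data.frame(particle_id = sprintf("%s_p%04d", fov_id, k),
               fov_id = fov_id,
               length_um = m$length_um, width_um = m$width_um,
               aspect_ratio = m$aspect_ratio, area_um2 = m$area_um2,
               pixel_count = m$pixel_count,
               centroid_row = mean(r) - 1, centroid_col = mean(cc) - 1,
               touches_border = any(r == 1L | r == nr | cc == 1L | cc == ncm),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "discarded_pixels") <- as.integer(discarded)
  res
}

#' Apply the fiber-counting morphology criteria
#'
#' A particle is a fiber when its aspect ratio is at least
#' `aspect_ratio_min` and its width is below `width_max_um`. There is
#' deliberately no minimum-length rule: short erionite fibers (under 5 um)
#' occur in air samples and are counted. Border-touching particles keep
#' their `is_fiber` verdict but are excluded from counting unless
#' `include_border = TRUE` (no edge-correction rule is applied).
#'
#' @param particles Data frame from [extract_particles()].
#' @param aspect_ratio_min Minimum length/width ratio (default 3).
#' @param width_max_um Maximum width in micrometres (default 3).
#' @param include_border Count border-touching fibers too? Default `FALSE`.
#' @return `particles` with logical columns `is_fiber` (morphology verdict)
#'   and `counted` (verdict combined with the border policy).
#' @export
apply_fiber_criteria <- function(particles, aspect_ratio_min = 3,
                                 width_max_um = 3, include_border = FALSE) {
  stopifnot(is.data.frame(particles))
  particles$is_fiber <- particles$aspect_ratio >= aspect_ratio_min &
    particles$width_um < width_max_um
  particles$counted <- particles$is_fiber &
    (include_border | !particles$touches_border)
  particles
}
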