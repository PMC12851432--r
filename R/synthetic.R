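# Atomic masses for converting mineral formulas to mass percentages.
.ATOMIC_MASS <- c(Si = 28.0855, Al = 26.9815, Mg = 24.3050, Na = 22.9898,
                  K = 39.0983, Ca = 40.0780, Fe = 55.8450, Cl = 35.4530)

# Mass% over the eight-element set from atoms per formula unit.
.formula_mass_pct <- function(atoms) {
  v <- setNames(numeric(length(EDS_ELEMENTS)), EDS_ELEMENTS)
  keep <- intersect(names(atoms), EDS_ELEMENTS)
  v[keep] <- atoms[keep] * .ATOMIC_MASS[keep]
  v / sum(v) * 100
}

#' Reference composition templates
#'
#' Noiseless eight-element mass-percent templates used by the EDS
#' simulator. The erionite template is derived from the electron-microprobe
#' formula of the Timber Bay reference erionite
#' (Na4.62 K1.70 Ca1.27 Mg0.51 Si26.78 Al9.21 per formula unit; Ba and the
#' framework O/H2O fall outside the eight-element analysis set), giving a
#' mass-basis Tsi of ~0.752. The other-zeolite template is a mordenite-like
#' Na8 Al8 Si40 framework (Tsi ~0.84, outside the erionite window); silica
#' and halite templates are constructed fixtures.
#'
#' @param count_rate Reference EDS count rate, counts per second, shared by
#'   all templates (default 2500 cps, a typical 15 kV benchtop SEM-EDS
#'   throughput).
#' @return Named list of `"composition_template"` objects with fields
#'   `name`, `mass_pct` (sums to 100), `count_rate`, and `label` (the class
#'   the template should be screened into).
#' @export
composition_templates <- function(count_rate = 2500) {
  tmpl <- function(name, mass_pct, label) {
    structure(list(name = name, mass_pct = mass_pct,
                   count_rate = count_rate, label = label),
              class = "composition_template")
  }
  erionite_atoms <- c(Na = 4.62, K = 1.70, Ca = 1.27, Mg = 0.51,
                      Si = 26.78, Al = 9.21)
  mordenite_atoms <- c(Na = 8, Al = 8, Si = 40)
  silica <- setNames(numeric(8), EDS_ELEMENTS)
  silica[c("Si", "Al", "Fe")] <- c(99.5, 0.3, 0.2)
  halite <- setNames(numeric(8), EDS_ELEMENTS)
  halite[c("Na", "Cl")] <- .formula_mass_pct(c(Na = 1, Cl = 1))[c("Na", "Cl")]
  list(
    erionite = tmpl("erionite", .formula_mass_pct(erionite_atoms),
                    "erionite_like_zeolite"),
    other_zeolite = tmpl("other_zeolite", .formula_mass_pct(mordenite_atoms),
                         "other_zeolite"),
    silica = tmpl("silica", silica, "silica"),
    salt_halide = tmpl("salt_halide", halite, "salt_halide")
  )
}

#' Simulate one noisy EDS composition from a template
#'
#' Counting statistics only: the total X-ray count is `count_rate *
#' acquisition_time` and per-element counts are drawn multinomially with
#' the template mass fractions as probabilities; the returned composition
#' is the renormalized count fractions as mass%. Shorter acquisition times
#' give fewer counts and noisier compositions, but leave the expected Tsi
#' ratio unchanged.
#'
#' @param template A `"composition_template"` from [composition_templates()].
#' @param acquisition_time Acquisition time in seconds (> 0; default 10,
#'   the high-throughput setting).
#' @param seed Optional integer seed for a reproducible draw.
#' @return An `"eds_composition"` (see [renormalize()]).
#' @export
simulate_eds <- function(template, acquisition_time = 10, seed = NULL) {
  stopifnot(inherits(template, "composition_template"))
  if (!is.finite(acquisition_time) || acquisition_time <= 0)
    stop("'acquisition_time' must be positive")
  draw <- function() {
    total <- max(1L, round(template$count_rate * acquisition_time))
    counts <- stats::rmultinom(1, total, prob = template$mass_pct / 100)[, 1]
    renormalize(setNames(as.numeric(counts), names(template$mass_pct)),
                acquisition_time = acquisition_time)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Erionite mass percentage of a bulk standard mix
#'
#' The spiked rock is `purity` erionite by mass, so mixing `spike_g` of it
#' into `silica_g` of silica gives
#' `100 * purity * spike_g / (silica_g + spike_g)` mass% erionite.
#'
#' @param silica_g Silica diluent mass, g (>= 0).
#' @param spike_g Spiked-rock mass, g (>= 0; not both zero).
#' @param purity Erionite mass fraction of the spiked rock (default 0.20).
#' @return Erionite mass percentage of the bulk mix.
#' @export
bulk_mix <- function(silica_g, spike_g, purity = 0.20) {
  if (silica_g < 0 || spike_g < 0) stop("masses must be non-negative")
  if (silica_g + spike_g == 0) stop("both masses are zero")
  if (purity <= 0 || purity > 1) stop("'purity' must be in (0, 1]")
  100 * purity * spike_g / (silica_g + spike_g)
}

#' The six performance-evaluation standards
#'
#' Bulk mixes of 3 g silica with increasing spiked-rock masses (20% erionite
#' by mass), spanning 0 to 1.70 mass% erionite — the series used to
#' calibrate concentration against mass loading. Spike masses are obtained
#' by inverting the mixing formula for the nominal series
#' 0, 0.02, 0.15, 0.37, 0.89, 1.70 mass%.
#'
#' @param silica_g Diluent mass per standard, g (default 3).
#' @param purity Erionite mass fraction of the spiked rock (default 0.20).
#' @return Data frame with `standard`, `silica_g`, `spike_g`, `mass_pct`.
#' @export
pe_standard_series <- function(silica_g = 3, purity = 0.20) {
  nominal <- c(0, 0.02, 0.15, 0.37, 0.89, 1.70)
  spike <- silica_g * nominal / (100 * purity - nominal)
  data.frame(standard = paste0("PC", seq_along(nominal)),
             silica_g = silica_g, spike_g = spike,
             mass_pct = mapply(function(s, g) if (g == 0) 0 else
               bulk_mix(silica_g, g, purity), nominal, spike),
             stringsAsFactors = FALSE)
}

#' Scene specification for the synthetic micrograph generator
#'
#' Describes a backscatter-like scene: bright fibers (rotated rectangles)
#' and granular distractors (ellipses and wide ribbons) on a dark porous
#' filter background. Geometry is specified in physical units so the same
#' scene can be rasterized at different magnifications.
#'
#' @param field_um Physical field size, micrometres, `c(width, height)`
#'   (default `c(64, 48)`, a 2000X field).
#' @param pixel_size Micrometres per pixel (default 0.03125, i.e. a
#'   2048 x 1536 raster over the default field).
#' @param fiber_count Number of fibers to place.
#' @param fiber_length `c(meanlog, sdlog)` of the log-normal fiber length,
#'   um; default median 1.5 um (mechanical agitation fragments fibers to
#'   short lengths).
#' @param length_cap_um Upper cap on fiber length, um (default 5; observed
#'   aerosolized fibers stay below this).
#' @param fiber_width `c(meanlog, sdlog)` of the log-normal fiber width, um
#'   (default median 0.3 um).
#' @param min_aspect Generated fibers have their width shrunk to at most
#'   `length/min_aspect` (default 4), keeping them safely above the
#'   counting criterion after rasterization.
#' @param distractor_disks,distractor_blobs,distractor_ribbons Numbers of
#'   round particles, low-aspect elliptical blobs, and wide ribbons
#'   (aspect >= 3 but width >= 3 um).
#' @param disk_diameter_um,blob_length_um,blob_aspect,ribbon_width_um,ribbon_aspect
#'   Uniform ranges for distractor geometry.
#' @param cluster_fraction Probability that a fiber is deliberately placed
#'   touching an already-placed particle (default 0).
#' @param pore_density Filter-pore dark spots per um^2 of field (default 0).
#' @param pore_diameter_um Pore diameter, um (default 0.8, the filter's
#'   nominal pore size).
#' @param background,particle_intensity,pore_intensity 8-bit intensity
#'   levels (defaults 20, 200, 5).
#' @param noise_sd Additive Gaussian intensity noise, standard deviation in
#'   intensity levels (default 0).
#' @param max_dim_um Hard cap on any particle's maximum dimension (default
#'   10 um, emulating the PM10 pre-separator).
#' @param margin_um Keep-out margin from the field edge (default 1 um) so
#'   placed particles do not touch the border.
#' @param seed Integer seed; every simulator output is a pure function of
#'   (spec, seed).
#' @return An object of class `"scene_spec"`.
#' @export
scene_spec <- function(field_um = c(64, 48), pixel_size = 0.03125,
                       fiber_count = 0,
                       fiber_length = c(meanlog = log(1.5), sdlog = 0.45),
                       length_cap_um = 5,
                       fiber_width = c(meanlog = log(0.3), sdlog = 0.35),
                       min_aspect = 4,
                       distractor_disks = 0, disk_diameter_um = c(1, 2.5),
                       distractor_blobs = 0, blob_length_um = c(1.5, 3.5),
                       blob_aspect = c(1.2, 2),
                       distractor_ribbons = 0, ribbon_width_um = c(3.5, 4.5),
                       ribbon_aspect = c(3, 4),
                       cluster_fraction = 0,
                       pore_density = 0, pore_diameter_um = 0.8,
                       background = 20, particle_intensity = 200,
                       pore_intensity = 5, noise_sd = 0,
                       max_dim_um = 10, margin_um = 1, seed = 1) {
  if (any(field_um <= 0) || pixel_size <= 0) stop("field and pixel size must be positive")
  if (cluster_fraction < 0 || cluster_fraction > 1)
    stop("'cluster_fraction' must be in [0, 1]")
  spec <- as.list(environment())
  structure(spec, class = "scene_spec")
}

# Draw ground-truth particle geometry (physical units) for a scene.
# Rejection placement keeps bounding circles separated unless a cluster
# draw forces touching. Uses the current RNG state.
draw_scene_truth <- function(spec) {
  W <- spec$field_um[1]; H <- spec$field_um[2]
  kinds <- c(rep("fiber", spec$fiber_count),
             rep("disk", spec$distractor_disks),
             rep("blob", spec$distractor_blobs),
             rep("ribbon", spec$distractor_ribbons))
  n <- length(kinds)
  if (n == 0L)
    return(data.frame(id = integer(), kind = character(), shape = character(),
                      x_um = numeric(), y_um = numeric(), length_um = numeric(),
                      width_um = numeric(), theta = numeric(),
                      template = character(), stringsAsFactors = FALSE))
  kinds <- sample(kinds)
  geom <- lapply(kinds, function(kind) {
    if (kind == "fiber") {
      L <- min(stats::rlnorm(1, spec$fiber_length[1], spec$fiber_length[2]),
               spec$length_cap_um, spec$max_dim_um)
      Wd <- min(stats::rlnorm(1, spec$fiber_width[1], spec$fiber_width[2]),
                L / spec$min_aspect)
      list(shape = "rect", L = L, W = Wd, template = "erionite")
    } else if (kind == "disk") {
      d <- min(stats::runif(1, spec$disk_diameter_um[1], spec$disk_diameter_um[2]),
               spec$max_dim_um)
      list(shape = "ellipse", L = d, W = d, template = "silica")
    } else if (kind == "blob") {
      L <- min(stats::runif(1, spec$blob_length_um[1], spec$blob_length_um[2]),
               spec$max_dim_um)
      ar <- stats::runif(1, spec$blob_aspect[1], spec$blob_aspect[2])
      list(shape = "ellipse", L = L, W = L / ar, template = "salt_halide")
    } else {
      Wd <- stats::runif(1, spec$ribbon_width_um[1], spec$ribbon_width_um[2])
      ar <- stats::runif(1, spec$ribbon_aspect[1], spec$ribbon_aspect[2])
      L <- min(Wd * ar, spec$max_dim_um)
      list(shape = "rect", L = L, W = Wd, template = "silica")
    }
  })
  diag_of <- function(g) sqrt(g$L^2 + g$W^2)
  placed <- data.frame(x = numeric(n), y = numeric(n), r = numeric(n))
  theta <- stats::runif(n, 0, pi)
  for (i in seq_len(n)) {
    r_i <- diag_of(geom[[i]]) / 2
    lo_x <- spec$margin_um + r_i; hi_x <- W - spec$margin_um - r_i
    lo_y <- spec$margin_um + r_i; hi_y <- H - spec$margin_um - r_i
    if (lo_x >= hi_x || lo_y >= hi_y)
      stop("particle geometry cannot fit the field with the requested margin")
    cluster <- i > 1L && kinds[i] == "fiber" &&
      stats::runif(1) < spec$cluster_fraction
    ok <- FALSE
    for (try in seq_len(400L)) {
      if (cluster) {
        j <- sample.int(i - 1L, 1L)
        ang <- stats::runif(1, 0, 2 * pi)
        d <- 0.8 * (r_i + placed$r[j])
        x <- placed$x[j] + d * cos(ang); y <- placed$y[j] + d * sin(ang)
        if (x < lo_x || x > hi_x || y < lo_y || y > hi_y) next
        ok <- TRUE; break
      }
      x <- stats::runif(1, lo_x, hi_x); y <- stats::runif(1, lo_y, hi_y)
      if (i == 1L ||
          all((placed$x[seq_len(i - 1L)] - x)^2 +
              (placed$y[seq_len(i - 1L)] - y)^2 >
              (placed$r[seq_len(i - 1L)] + r_i + 0.6)^2)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place particle ", i,
                  ": scene too crowded for non-overlapping placement")
    placed$x[i] <- x; placed$y[i] <- y; placed$r[i] <- r_i
  }
  data.frame(id = seq_len(n), kind = kinds,
             shape = vapply(geom, `[[`, character(1), "shape"),
             x_um = placed$x, y_um = placed$y,
             length_um = vapply(geom, `[[`, numeric(1), "L"),
             width_um = vapply(geom, `[[`, numeric(1), "W"),
             theta = theta,
             template = vapply(geom, `[[`, character(1), "template"),
             stringsAsFactors = FALSE)
}

#' Rasterize ground-truth geometry into a micrograph
#'
#' Pixel centers falling inside a placed shape take the particle intensity;
#' pores are dark disks drawn beneath the particles; optional additive
#' Gaussian noise is applied last and the result clipped to 0..255. Pixel
#' `(r, c)` (1-based) has its center at physical
#' `((c - 0.5) * pixel_size, (r - 0.5) * pixel_size)`.
#'
#' Two resolution effects are built in: shapes thinner than half a pixel do
#' not render (fibers below the pixel size cannot be detected), and visible
#' shapes render at a minimum thickness of about 1.45 px so a resolvable
#' thin fiber appears as a continuous bright line in any orientation, as it
#' does in a backscatter image. Together these make the detected fiber
#' count of a fixed physical scene non-decreasing as pixel size shrinks.
#'
#' Uses the current RNG state for pores and noise; call via
#' [simulate_scene()] for seeded, reproducible output.
#'
#' @param truth Ground-truth data frame (see [simulate_scene()]).
#' @param spec A [scene_spec()]; `pixel_size` may be overridden to render
#'   the same physical scene at a different resolution.
#' @param pixel_size Micrometres per pixel (default `spec$pixel_size`).
#' @return List with `image` (a [micrograph()]) and `mask` (logical ground
#'   truth: union of placed shapes, before pores and noise).
#' @export
render_scene <- function(truth, spec, pixel_size = spec$pixel_size) {
  nrp <- round(spec$field_um[2] / pixel_size)
  ncp <- round(spec$field_um[1] / pixel_size)
  img <- matrix(as.numeric(spec$background), nrp, ncp)
  mask <- matrix(FALSE, nrp, ncp)
  # filter pores: dark disks under the particles
  n_pores <- if (spec$pore_density > 0)
    stats::rpois(1, spec$pore_density * spec$field_um[1] * spec$field_um[2])
  else 0L
  if (n_pores > 0) {
    px <- stats::runif(n_pores, 0, spec$field_um[1])
    py <- stats::runif(n_pores, 0, spec$field_um[2])
    pr <- spec$pore_diameter_um / 2
    for (k in seq_len(n_pores)) {
      sel <- .pixels_in_shape(nrp, ncp, pixel_size, "ellipse",
                              px[k], py[k], 2 * pr, 2 * pr, 0)
      img[sel] <- spec$pore_intensity
    }
  }
  for (i in seq_len(nrow(truth))) {
    sel <- .pixels_in_shape(nrp, ncp, pixel_size, truth$shape[i],
                            truth$x_um[i], truth$y_um[i],
                            truth$length_um[i], truth$width_um[i],
                            truth$theta[i])
    img[sel] <- spec$particle_intensity
    mask[sel] <- TRUE
  }
  if (spec$noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), nrp, ncp)
  list(image = micrograph(img, pixel_size = pixel_size,
                          fov_id = sprintf("sim_seed%d", spec$seed)),
       mask = mask)
}

# Linear indices of pixels whose centers fall inside a rotated rectangle
# or ellipse (length L along the theta direction, width W across it).
# Shapes thinner than half a pixel are below the resolution limit and do
# not render at all; thinner-than-a-pixel but visible shapes render at a
# minimum thickness of sqrt(2) + eps pixels so they stay connected in any
# orientation (emulating the bright, continuous appearance of resolvable
# thin fibers in backscatter images).
.pixels_in_shape <- function(nrp, ncp, pixel_size, shape, x0, y0, L, W, theta) {
  if (W < 0.5 * pixel_size) return(integer(0))
  W <- max(W, 1.45 * pixel_size)
  L <- max(L, 1.45 * pixel_size)
  half_diag <- sqrt(L^2 + W^2) / 2
  c1 <- max(1L, floor((x0 - half_diag) / pixel_size))
  c2 <- min(ncp, ceiling((x0 + half_diag) / pixel_size) + 1L)
  r1 <- max(1L, floor((y0 - half_diag) / pixel_size))
  r2 <- min(nrp, ceiling((y0 + half_diag) / pixel_size) + 1L)
  if (c1 > c2 || r1 > r2) return(integer(0))
  cc <- c1:c2; rr <- r1:r2
  xs <- (cc - 0.5) * pixel_size - x0
  ys <- (rr - 0.5) * pixel_size - y0
  X <- matrix(xs, length(rr), length(cc), byrow = TRUE)
  Y <- matrix(ys, length(rr), length(cc))
  U <- X * cos(theta) + Y * sin(theta)
  V <- -X * sin(theta) + Y * cos(theta)
  inside <- if (shape == "rect")
    abs(U) <= L / 2 & abs(V) <= W / 2
  else
    (U / (L / 2))^2 + (V / (W / 2))^2 <= 1
  ij <- which(inside, arr.ind = TRUE)
  if (nrow(ij) == 0L) return(integer(0))
  (cc[ij[, 2L]] - 1L) * nrp + rr[ij[, 1L]]
}

#' Simulate a synthetic micrograph with ground truth
#'
#' Draws particle geometry and renders it, all under the spec's seed, so
#' repeated calls with the same spec are bit-identical.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (a [micrograph()]), `mask` (ground-truth
#'   logical particle mask), and `truth` (data frame: `id`, `kind`,
#'   `shape`, `x_um`, `y_um`, `length_um`, `width_um`, `theta`,
#'   `template`).
#' @export
simulate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    truth <- draw_scene_truth(spec)
    rend <- render_scene(truth, spec)
    list(image = rend$image, mask = rend$mask, truth = truth)
  })
}

#' Simulate fiber counts for a series of PE standards
#'
#' The aerosolization chamber deposits fibers in proportion to the bulk
#' erionite mass loading: the true concentration of standard `i` is
#' `k * mass_pct[i]` f/cc, so the expected count over the analyzed area is
#' `lambda = k * mass_pct / AS` with `AS` the analytical sensitivity. The
#' observed count is Poisson(`lambda`), split uniformly over the fields of
#' view.
#'
#' @param mass_pcts Erionite mass percentages of the standards (e.g.
#'   `pe_standard_series()$mass_pct`).
#' @param p A [sampling_params()] object.
#' @param k Aerosolization efficiency, f/cc per mass% (default
#'   `716 / 1.74` ~ 411.5, scaling the top standard to the observed
#'   concentration range 0-716 f/cc).
#' @param seed Optional integer seed.
#' @return Data frame with one row per standard: `mass_pct`, `lambda`,
#'   `n_fibers`, `concentration_fcc`, plus the per-FOV counts as a list
#'   column `per_fov_counts`.
#' @export
simulate_pe_experiment <- function(mass_pcts, p, k = 716 / 1.74, seed = NULL) {
  stopifnot(inherits(p, "sampling_params"))
  if (!is.finite(k) || k <= 0) stop("'k' must be positive")
  if (any(mass_pcts < 0)) stop("mass percentages must be non-negative")
  as_fcc <- analytical_sensitivity(p)
  run <- function() {
    lambda <- k * mass_pcts / as_fcc
    n <- stats::rpois(length(lambda), lambda)
    per_fov <- lapply(n, function(ni)
      stats::rmultinom(1, ni, rep(1 / p$n_fov, p$n_fov))[, 1])
    out <- data.frame(mass_pct = mass_pcts, lambda = lambda, n_fibers = n,
                      concentration_fcc = n * as_fcc)
    out$per_fov_counts <- per_fov
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
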