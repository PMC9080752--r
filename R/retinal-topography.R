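# Stereological density estimation, topographic maps and anatomical acuity.
#
# Counting sites come from systematic random sampling of a retinal
# whole-mount: at each grid position a counting frame of known area is
# counted. For 2-D whole-mount counting the section and height sampling
# fractions are 1, so the optical-fractionator total reduces to the summed
# counts times the inverse area sampling fraction (grid_step^2 / frame_area).

check_sites <- function(sites) {
  needed <- c("x_mm", "y_mm", "count", "frame_area_mm2", "grid_step_mm")
  miss <- setdiff(needed, names(sites))
  if (length(miss))
    stop("counting-site table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(sites$frame_area_mm2 <= 0)) stop("frame area must be positive")
  if (any(sites$count < 0)) stop("counts must be nonnegative")
  if (any(sites$frame_area_mm2 > sites$grid_step_mm^2 + 1e-12))
    stop("frame area cannot exceed grid_step^2")
  invisible(sites)
}

coarse_sites <- function(sites) {
  if ("subsample" %in% names(sites))
    sites[!sites$subsample, , drop = FALSE] else sites
}

#' Read a counting-site table
#'
#' Expects a CSV with columns `x_mm`, `y_mm`, `count`, `frame_area_mm2`,
#' `grid_step_mm` and optionally `cell_class` and `subsample` (logical;
#' TRUE for half-grid subsampling sites around the provisional peak).
#'
#' @param path CSV file.
#' @param cell_class Optional filter on the `cell_class` column.
#' @return Data frame of counting sites.
#' @export
read_counting_sites <- function(path, cell_class = NULL) {
  s <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(cell_class) && "cell_class" %in% names(s))
    s <- s[s$cell_class == cell_class, , drop = FALSE]
  check_sites(s)
}

#' Per-site cell density
#'
#' @param sites Counting-site table.
#' @return Numeric vector, cells per mm^2 (count / frame area).
#' @export
site_density <- function(sites) {
  check_sites(sites)
  sites$count / sites$frame_area_mm2
}

#' Optical-fractionator estimate of the total cell population
#'
#' Sum of counts times the inverse area sampling fraction
#' `grid_step^2 / frame_area`. Sites flagged as half-grid subsamples are
#' excluded (they oversample the peak region). All coarse sites must share
#' one grid step.
#'
#' @param sites Counting-site table.
#' @return Estimated number of cells in the sampled retina.
#' @export
total_population <- function(sites) {
  sites <- coarse_sites(check_sites(sites))
  g <- unique(sites$grid_step_mm)
  if (length(g) != 1)
    stop("mixed grid steps; the fractionator requires a uniform grid")
  f <- unique(sites$frame_area_mm2)
  if (length(f) != 1)
    stop("mixed frame areas; the fractionator requires a uniform frame")
  sum(sites$count) * g^2 / f
}

#' Scheaffer coefficient of error of a systematic count series
#'
#' Precision of the fractionator total, treating the counting frames as a
#' sample of the frames tiling the retina (one frame per grid cell):
#' `CE = sqrt((1 - n/N) / n) * s / mean`, with `N = n * grid_step^2 /
#' frame_area` the number of frame placements represented and `s` the
#' between-site standard deviation of counts. A sampling design is
#' conventionally judged adequate when CE < 0.1.
#'
#' @param sites Counting-site table (subsample sites excluded), or a bare
#'   numeric vector of counts combined with `fpc`.
#' @param fpc Finite population correction `1 - n/N` used when `sites` is a
#'   bare count vector (default 1, i.e. no correction).
#' @return Coefficient of error (dimensionless).
#' @export
scheaffer_ce <- function(sites, fpc = 1) {
  if (is.numeric(sites)) {
    counts <- sites
  } else {
    sites <- coarse_sites(check_sites(sites))
    counts <- sites$count
    fpc <- 1 - sites$frame_area_mm2[1] / sites$grid_step_mm[1]^2
  }
  n <- length(counts)
  if (n < 3) stop("at least 3 counting sites are required")
  if (all(counts == 0)) stop("all-zero count series")
  sqrt(fpc / n) * sd(counts) / mean(counts)
}

#' Gaussian-kernel smoothed topographic density map
#'
#' Each counting site contributes its fractionator mass
#' (`count * grid_step^2 / frame_area` cells) spread as an isotropic
#' Gaussian kernel with bandwidth `sigma` (default: the grid step, i.e.
#' sigma adjusted to the grid size). Kernels are renormalised over the
#' raster inside the retina outline, which acts as a reflective edge
#' correction and conserves total mass exactly on the raster.
#'
#' @param sites Counting-site table.
#' @param sigma Kernel bandwidth in mm (default: grid step).
#' @param outline Optional two-column matrix/data frame of a closed polygon
#'   (x_mm, y_mm); defaults to the bounding box of the sites padded by one
#'   grid step.
#' @param raster_step Raster spacing in mm (default: half the grid step).
#' @return Object of class `density_map`: list with `x`, `y`, `z` (cells per
#'   mm^2; `NA` outside the outline), `sigma_mm`, `outline`.
#' @export
density_map <- function(sites, sigma = NULL, outline = NULL,
                        raster_step = NULL) {
  sites <- coarse_sites(check_sites(sites))
  if (nrow(sites) < 10) stop("at least 10 counting sites are required")
  g <- sites$grid_step_mm[1]
  if (is.null(sigma)) sigma <- g
  if (sigma <= 0) stop("sigma must be positive")
  if (is.null(raster_step)) raster_step <- g / 2
  if (is.null(outline)) {
    pad <- g
    xr <- range(sites$x_mm) + c(-pad, pad)
    yr <- range(sites$y_mm) + c(-pad, pad)
    outline <- cbind(x = xr[c(1, 2, 2, 1)], y = yr[c(1, 1, 2, 2)])
  }
  outline <- as.matrix(outline)[, 1:2]
  if (nrow(outline) < 3 || diff(range(outline[, 1])) == 0 ||
      diff(range(outline[, 2])) == 0)
    stop("degenerate retina outline")
  x <- seq(min(outline[, 1]), max(outline[, 1]), by = raster_step)
  y <- seq(min(outline[, 2]), max(outline[, 2]), by = raster_step)
  gr <- expand.grid(x = x, y = y)
  inside <- in_polygon(gr$x, gr$y, outline)
  if (!any(inside)) stop("degenerate retina outline")
  cell_area <- raster_step^2
  mass <- sites$count * g^2 / sites$frame_area_mm2[1]
  z <- numeric(nrow(gr))
  for (i in seq_len(nrow(sites))) {
    k <- exp(-((gr$x - sites$x_mm[i])^2 + (gr$y - sites$y_mm[i])^2) /
               (2 * sigma^2))
    k[!inside] <- 0
    tot <- sum(k) * cell_area
    if (tot > 0) z <- z + mass[i] * k / tot
  }
  z[!inside] <- NA_real_
  structure(list(x = x, y = y,
                 z = matrix(z, nrow = length(x), ncol = length(y)),
                 sigma_mm = sigma, outline = outline),
            class = "density_map")
}

# ray-casting point-in-polygon; vertices on edges count as inside
in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d raster, sigma %.3g mm, peak %.0f cells/mm^2\n",
              length(x$x), length(x$y), x$sigma_mm, max(x$z, na.rm = TRUE)))
  invisible(x)
}

#' @exportS3Method base::plot
plot.density_map <- function(x, contour_step = 5000, ...) {
  z3 <- x$z / 1000  # iso-density contours in 10^3 cells per mm^2
  image(x$x, x$y, z3, xlab = "x (mm, temporal +)", ylab = "y (mm)",
        col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
        asp = 1, ...)
  contour(x$x, x$y, z3, add = TRUE,
          levels = pretty(range(z3, na.rm = TRUE), 8))
  lines(rbind(x$outline, x$outline[1, ]))
  invisible(x)
}

#' Integrated cell number of a density map
#'
#' @param map A [density_map()].
#' @return Sum of density times raster cell area over the outline.
#' @export
map_population <- function(map) {
  step_x <- diff(map$x[1:2]); step_y <- diff(map$y[1:2])
  sum(map$z, na.rm = TRUE) * step_x * step_y
}

#' Peak cell density with half-grid subsampling
#'
#' Finds the provisional peak among the coarse-grid sites, then returns the
#' maximum per-site density over all sites (including any half-grid
#' subsample sites) within one coarse grid step of the provisional peak.
#'
#' @param sites Counting-site table, optionally with a logical `subsample`
#'   column marking the denser sites around the peak.
#' @return Peak density in cells per mm^2.
#' @export
peak_density <- function(sites) {
  check_sites(sites)
  coarse <- coarse_sites(sites)
  d_coarse <- coarse$count / coarse$frame_area_mm2
  peak_idx <- which.max(d_coarse)
  px <- coarse$x_mm[peak_idx]; py <- coarse$y_mm[peak_idx]
  g <- coarse$grid_step_mm[peak_idx]
  near <- sqrt((sites$x_mm - px)^2 + (sites$y_mm - py)^2) <= g + 1e-9
  max(sites$count[near] / sites$frame_area_mm2[near])
}

#' Cone mosaic double:single ratio
#'
#' In the regular teleost cone mosaic one single cone sits at the centre of
#' a unit whose corners hold double cones, each shared between neighbouring
#' units. The resulting double-to-single cone ratio is
#' `n_double_neighbours / n_sharing_units` per single cone: with four
#' corner double cones each shared by two units the ratio is exactly 2.
#'
#' @param n_single Single cones per mosaic unit (default 1).
#' @param n_double_neighbours Double cones surrounding each single cone
#'   (default 4).
#' @param n_sharing_units Number of mosaic units sharing each double cone
#'   (default 2).
#' @return Double:single cone ratio.
#' @export
mosaic_ratio <- function(n_single = 1, n_double_neighbours = 4,
                         n_sharing_units = 2) {
  stopifnot(n_single > 0, n_double_neighbours > 0, n_sharing_units > 0)
  (n_double_neighbours / n_sharing_units) / n_single
}

#' Anatomical spatial resolving power from peak ganglion-cell density
#'
#' The focal length is Matthiessen's ratio (2.55) times the lens radius;
#' the visual angle subtended by 1 mm of retina is `a = atan(1/f)` in
#' degrees. With a linear cell density of `sqrt(peak_density)` cells per mm
#' and two ganglion cells needed per resolvable cycle, the spatial
#' resolving power is `(sqrt(peak_density) / a) / 2` cycles per degree.
#'
#' @param peak_density_mm2 Peak ganglion-cell density, cells per mm^2.
#' @param lens_radius_mm Lens radius in mm.
#' @param matthiessen Focal length / lens radius (default 2.55).
#' @param amacrine_correction Optional multiplicative correction of the peak
#'   density for displaced amacrine cells (e.g. 0.76); default 1 (none).
#' @return Object of class `acuity_estimate`.
#' @export
spatial_resolving_power <- function(peak_density_mm2, lens_radius_mm,
                                    matthiessen = 2.55,
                                    amacrine_correction = 1) {
  if (peak_density_mm2 <= 0 || lens_radius_mm <= 0)
    stop("peak density and lens radius must be positive")
  d <- peak_density_mm2 * amacrine_correction
  f <- matthiessen * lens_radius_mm
  a <- atan(1 / f) * 180 / pi          # degrees per mm of retina
  srp <- (sqrt(d) / a) / 2
  structure(list(peak_density_mm2 = d, lens_radius_mm = lens_radius_mm,
                 focal_length_mm = f, angle_deg_per_mm = a, srp_cpd = srp),
            class = "acuity_estimate")
}

#' @export
print.acuity_estimate <- function(x, ...) {
  cat(sprintf("<acuity_estimate> peak %.0f cells/mm^2, lens radius %.2f mm\n",
              x$peak_density_mm2, x$lens_radius_mm))
  cat(sprintf("  focal length %.2f mm; 1 mm subtends %.2f deg\n",
              x$focal_length_mm, x$angle_deg_per_mm))
  cat(sprintf("  spatial resolving power: %.1f cpd\n", x$srp_cpd))
  invisible(x)
}

#' Lens radius implied by a spatial resolving power
#'
#' Algebraic inversion of [spatial_resolving_power()]: given an SRP and a
#' peak density, the angle per mm is `sqrt(D) / (2 * srp)` and the lens
#' radius is `1 / (matthiessen * tan(a))`.
#'
#' @param srp_cpd Spatial resolving power in cycles per degree.
#' @param peak_density_mm2 Peak density in cells per mm^2.
#' @param matthiessen Matthiessen's ratio (default 2.55).
#' @return Lens radius in mm.
#' @export
lens_radius_for_srp <- function(srp_cpd, peak_density_mm2,
                                matthiessen = 2.55) {
  if (srp_cpd <= 0 || peak_density_mm2 <= 0)
    stop("inputs must be positive")
  a <- sqrt(peak_density_mm2) / (2 * srp_cpd)   # degrees per mm
  1 / (matthiessen * tan(a * pi / 180))
}
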