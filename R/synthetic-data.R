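# Seeded synthetic-data generators with planted-truth ledgers.
#
# Every generator returns list(data, ledger): the ledger records the seed,
# scenario name and the planted truths (substitutions applied, true
# proportions, density-surface parameters, observer threshold/slope), so
# recovery tests read the truth from the ledger rather than from constants.

new_ledger <- function(scenario, seed, truth) {
  structure(list(scenario = scenario, seed = seed, truth = truth),
            class = "generator_ledger")
}

#' @export
print.generator_ledger <- function(x, ...) {
  cat(sprintf("<generator_ledger> scenario '%s', seed %s\n", x$scenario,
              if (is.null(x$seed)) "none" else x$seed))
  utils::str(x$truth, give.attr = FALSE)
  invisible(x)
}

#' Write a generator ledger as JSON
#'
#' @param ledger A `generator_ledger`.
#' @param path Output path.
#' @export
write_ledger <- function(ledger, path) {
  jsonlite::write_json(unclass(ledger), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' Plant substitutions into an opsin sequence at bovine-numbered sites
#'
#' Builds a variant of `reference` that differs from it exactly at the
#' requested bovine sites. Errors when a requested site falls in a gap of
#' the reference's bovine alignment.
#'
#' @param reference An `opsin_sequence` (or amino-acid string).
#' @param substitutions Data frame with columns `bovine_site` and `to`
#'   (target residue); may be empty.
#' @param id Identifier of the variant.
#' @param bovine Bovine rhodopsin sequence.
#' @return List with `sequence` (the variant `opsin_sequence`) and `ledger`
#'   recording the planted (site, from, to) triples.
#' @export
make_opsin_variant <- function(reference, substitutions,
                               id = "variant", bovine = bovine_rhodopsin()) {
  if (!inherits(reference, "opsin_sequence"))
    reference <- opsin_sequence("reference", "RH1", amino_acids = reference)
  map <- bovine_site_map(reference, bovine)
  aa <- strsplit(reference$amino_acids, "")[[1]]
  planted <- data.frame(bovine_site = integer(), from = character(),
                        to = character())
  if (nrow(substitutions)) {
    for (i in seq_len(nrow(substitutions))) {
      site <- substitutions$bovine_site[i]
      idx <- map[site]
      if (is.na(idx))
        stop(sprintf("bovine site %d is unmapped (gap) in the reference",
                     site))
      planted <- rbind(planted, data.frame(
        bovine_site = site, from = aa[idx], to = substitutions$to[i]))
      aa[idx] <- substitutions$to[i]
    }
  }
  seq_out <- opsin_sequence(id, reference$opsin_class,
                            amino_acids = paste(aa, collapse = ""))
  list(sequence = seq_out,
       ledger = new_ledger("opsin_variant", NULL,
                           list(reference_id = reference$id,
                                planted = planted)))
}

#' Simulate multinomial opsin read counts with known true proportions
#'
#' Reads are drawn multinomially with per-gene probability proportional to
#' (true proportion x coding length), so that length normalisation recovers
#' the planted proportion.
#'
#' @param true_proportions Named vector of true expression proportions
#'   (sums to 1); names are gene ids.
#' @param cds_lengths Named vector of coding lengths (bp), same names.
#' @param gene_classes Named character vector of gene classes (`rod`,
#'   `single_cone`, `double_cone`).
#' @param total_reads Total opsin-mapped reads (default 1e6).
#' @param seed Integer seed.
#' @param individual_id Identifier for the simulated individual.
#' @return List with `counts` (a count table, see [read_opsin_counts()])
#'   and `ledger`.
#' @export
make_read_counts <- function(true_proportions, cds_lengths, gene_classes,
                             total_reads = 1e6, seed = 1,
                             individual_id = "sim1") {
  stopifnot(abs(sum(true_proportions) - 1) < 1e-8)
  genes <- names(true_proportions)
  stopifnot(!is.null(genes), all(genes %in% names(cds_lengths)),
            all(genes %in% names(gene_classes)))
  set.seed(seed)
  prob <- true_proportions * cds_lengths[genes]
  reads <- as.vector(rmultinom(1, total_reads, prob / sum(prob)))
  counts <- data.frame(individual_id = individual_id, gene_id = genes,
                       gene_class = unname(gene_classes[genes]),
                       reads = reads,
                       cds_length_bp = unname(cds_lengths[genes]))
  list(counts = counts,
       ledger = new_ledger("read_counts", seed,
                           list(true_proportions = as.list(true_proportions),
                                total_reads = total_reads)))
}

#' Default elliptical retina outline
#'
#' A closed polygon approximating a whole-mounted retina, an ellipse with
#' semi-axes `a` (naso-temporal) and `b` (dorso-ventral) in mm centred on
#' the origin.
#'
#' @param a,b Semi-axes in mm.
#' @param n Number of polygon vertices.
#' @return Two-column matrix of vertices.
#' @export
default_retina_outline <- function(a = 5, b = 4, n = 90) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = a * cos(th), y = b * sin(th))
}

streak_density <- function(x, y, background, peak, centre, sigma_y, elong) {
  background + (peak - background) *
    exp(-0.5 * (((x - centre[1]) / (sigma_y * elong))^2 +
                  ((y - centre[2]) / sigma_y)^2))
}

#' Simulate a stereologically sampled retina
#'
#' The planted density surface is a background plus an anisotropic Gaussian
#' elongated along the horizontal (naso-temporal) axis -- a horizontal
#' streak with its peak in the temporal retina. Counting sites lie on a
#' systematic grid with a random start; per-site counts are Poisson with
#' mean density x frame area. A half-grid-step subsample around the true
#' peak is included, flagged in the `subsample` column.
#'
#' @param peak_density True peak density, cells per mm^2 (default 38643).
#' @param background_density True background density (default 7000).
#' @param streak_elongation Horizontal:vertical extent of the streak
#'   (default 4; 1 gives a radially symmetric area centralis).
#' @param peak_centre Peak position (mm), default temporal at (2.5, 0).
#' @param sigma_y Vertical streak width in mm (default 1.2).
#' @param outline Closed polygon of the retina (default the 5 x 4 mm
#'   ellipse of [default_retina_outline()]).
#' @param grid_step_mm Grid spacing; default sized for about 200 sites.
#' @param frame_area_mm2 Counting-frame area (default 0.0025, a 50 x 50
#'   micrometre frame).
#' @param seed Integer seed.
#' @return List with `sites` (counting-site table) and `ledger` holding the
#'   surface parameters, the true peak density and the true total
#'   population (surface integrated over the outline).
#' @export
make_retina <- function(peak_density = 38643, background_density = 7000,
                        streak_elongation = 4, peak_centre = c(2.5, 0),
                        sigma_y = 1.2, outline = default_retina_outline(),
                        grid_step_mm = NULL, frame_area_mm2 = 0.0025,
                        seed = 1) {
  stopifnot(peak_density > background_density, background_density > 0)
  set.seed(seed)
  area <- polygon_area(outline)
  if (is.null(grid_step_mm)) grid_step_mm <- sqrt(area / 200)
  if (frame_area_mm2 > grid_step_mm^2)
    stop("frame area exceeds grid cell; reduce frame or grid")
  origin <- runif(2, 0, grid_step_mm)
  xs <- seq(min(outline[, 1]) + origin[1], max(outline[, 1]),
            by = grid_step_mm)
  ys <- seq(min(outline[, 2]) + origin[2], max(outline[, 2]),
            by = grid_step_mm)
  gr <- expand.grid(x_mm = xs, y_mm = ys)
  keep <- in_polygon(gr$x_mm, gr$y_mm, outline)
  gr <- gr[keep, , drop = FALSE]
  if (nrow(gr) < 50) stop("outline too small for at least 50 sites")
  dens <- streak_density(gr$x_mm, gr$y_mm, background_density, peak_density,
                         peak_centre, sigma_y, streak_elongation)
  sites <- data.frame(
    x_mm = gr$x_mm, y_mm = gr$y_mm,
    count = rpois(nrow(gr), dens * frame_area_mm2),
    frame_area_mm2 = frame_area_mm2, grid_step_mm = grid_step_mm,
    subsample = FALSE)
  # half-grid subsample around the true peak
  half <- grid_step_mm / 2
  sub <- expand.grid(x_mm = peak_centre[1] + half * (-2:2),
                     y_mm = peak_centre[2] + half * (-2:2))
  sub <- sub[in_polygon(sub$x_mm, sub$y_mm, outline), , drop = FALSE]
  dens_sub <- streak_density(sub$x_mm, sub$y_mm, background_density,
                             peak_density, peak_centre, sigma_y,
                             streak_elongation)
  sub_sites <- data.frame(
    x_mm = sub$x_mm, y_mm = sub$y_mm,
    count = rpois(nrow(sub), dens_sub * frame_area_mm2),
    frame_area_mm2 = frame_area_mm2, grid_step_mm = grid_step_mm,
    subsample = TRUE)
  # true total: integrate the surface on a fine raster inside the outline
  fx <- seq(min(outline[, 1]), max(outline[, 1]), length.out = 220)
  fy <- seq(min(outline[, 2]), max(outline[, 2]), length.out = 220)
  fg <- expand.grid(x = fx, y = fy)
  fin <- in_polygon(fg$x, fg$y, outline)
  cell <- diff(fx[1:2]) * diff(fy[1:2])
  total_true <- sum(streak_density(fg$x[fin], fg$y[fin], background_density,
                                   peak_density, peak_centre, sigma_y,
                                   streak_elongation)) * cell
  list(sites = rbind(sites, sub_sites),
       ledger = new_ledger("retina", seed, list(
         peak_density = peak_density,
         background_density = background_density,
         streak_elongation = streak_elongation,
         peak_centre = peak_centre, sigma_y = sigma_y,
         grid_step_mm = grid_step_mm, frame_area_mm2 = frame_area_mm2,
         total_population = total_true)))
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Simulate two-alternative grating choices from a logistic observer
#'
#' Bernoulli draws from the logistic psychometric function with guess rate
#' `guess`, parameterised so that the probability of a correct choice at
#' `true_threshold_cpd` equals `criterion` (default 0.62).
#'
#' @param true_threshold_cpd Planted acuity threshold.
#' @param slope Logistic slope `beta` (per cpd, default 2).
#' @param frequencies Tested spatial frequencies (default 0.5--5 cpd in 0.5
#'   steps, the achromatic design).
#' @param n_per_frequency Trials per grating (default 110).
#' @param guess Guess rate (default 0.5).
#' @param criterion Probability attained at the planted threshold
#'   (default 0.62).
#' @param seed Integer seed.
#' @param fish_id,treatment Labels for the trial records.
#' @return List with `trials` (data frame `fish_id`, `treatment`,
#'   `spatial_frequency_cpd`, `correct`) and `ledger`.
#' @export
make_trials <- function(true_threshold_cpd, slope = 2,
                        frequencies = seq(0.5, 5, by = 0.5),
                        n_per_frequency = 110, guess = 0.5,
                        criterion = 0.62, seed = 1,
                        fish_id = "sim_fish", treatment = "achromatic") {
  stopifnot(true_threshold_cpd >= min(frequencies),
            true_threshold_cpd <= max(frequencies), slope > 0)
  set.seed(seed)
  alpha <- true_threshold_cpd +
    qlogis((criterion - guess) / (1 - guess)) / slope
  x <- rep(frequencies, each = n_per_frequency)
  p <- psi_fun(x, alpha, slope, guess, 0)
  trials <- data.frame(fish_id = fish_id, treatment = treatment,
                       spatial_frequency_cpd = x,
                       correct = rbinom(length(x), 1, p))
  list(trials = trials,
       ledger = new_ledger("trials", seed, list(
         true_threshold_cpd = true_threshold_cpd, slope = slope,
         alpha = alpha, guess = guess, criterion = criterion,
         frequencies = frequencies, n_per_frequency = n_per_frequency)))
}

#' Simulate smooth Gaussian-band stimulus spectra and an illuminant
#'
#' Reflectances are sums of Gaussian bands clipped to `[0, 1]`; the
#' illuminant is flat or a broad Gaussian, strictly positive.
#'
#' @param band_centres Numeric vector of band centres (nm); empty gives a
#'   flat black reflectance.
#' @param band_widths Band standard deviations (nm), recycled.
#' @param band_heights Band peak reflectances, recycled (default 0.8).
#' @param illuminant_shape `"flat"` or `"daylight"` (broad 550 nm Gaussian).
#' @param grid Wavelength grid (default 300--750 nm).
#' @return List with `reflectance` and `illuminant` [spectrum()]s and
#'   `ledger`.
#' @export
make_spectra <- function(band_centres = numeric(), band_widths = 30,
                         band_heights = 0.8,
                         illuminant_shape = c("flat", "daylight"),
                         grid = 300:750) {
  illuminant_shape <- match.arg(illuminant_shape)
  grid <- as.numeric(grid)
  r <- rep(0, length(grid))
  if (length(band_centres)) {
    bw <- rep_len(band_widths, length(band_centres))
    bh <- rep_len(band_heights, length(band_centres))
    for (i in seq_along(band_centres))
      r <- r + bh[i] * exp(-0.5 * ((grid - band_centres[i]) / bw[i])^2)
    r <- pmin(r, 1)
  }
  ill <- if (illuminant_shape == "flat") rep(1, length(grid))
         else 0.2 + exp(-0.5 * ((grid - 550) / 150)^2)
  list(reflectance = spectrum(grid, r),
       illuminant = spectrum(grid, ill),
       ledger = new_ledger("spectra", NULL, list(
         band_centres = band_centres, band_widths = band_widths,
         band_heights = band_heights,
         illuminant_shape = illuminant_shape)))
}
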