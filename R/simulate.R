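# Reference seed-bag layout: bags per (strain x cultivar). Each bag is
# scanned six times. Row/column totals: Alto 36, Bronsyn 32, Maxsyn 10,
# Trojan 57 bags; 135 bags, 810 scans; strain WE = endophyte-free (E-).
BAG_LAYOUT <- local({
  m <- rbind(
    "AR1"    = c(2, 2, 0, 2),
    "NEA2/6" = c(2, 1, 0, 28),
    "NEA10"  = c(3, 3, 1, 3),
    "NEA2"   = c(4, 2, 1, 3),
    "NEA3"   = c(3, 2, 1, 3),
    "NEA6"   = c(4, 4, 0, 3),
    "SE"     = c(4, 4, 1, 0),
    "NEA11"  = c(3, 3, 1, 3),
    "AR37"   = c(3, 2, 0, 2),
    "NEA12"  = c(2, 0, 2, 2),
    "NEA21"  = c(0, 2, 1, 2),
    "NEA23"  = c(0, 2, 1, 2),
    "WE"     = c(6, 5, 1, 4))
  colnames(m) <- CULTIVARS
  m
})

#' Simulation designs: the reference seed-bag layout
#'
#' `default_design()` reproduces the reference study layout exactly: 135
#' bags of perennial ryegrass seed across four cultivars (Alto 36, Bronsyn
#' 32, Maxsyn 10, Trojan 57) hosting twelve endophyte strains or none (WE),
#' each bag scanned six times, for 810 scan records.
#' `benchmark_design()` is the scaled-down 100-bag benchmark layout
#' (Alto 27, Bronsyn 24, Maxsyn 7, Trojan 42; endophyte-free bags 4/4/1/3)
#' used by [benchmark_suite()]; 600 scan records.
#'
#' @param scans_per_bag Replicate scans per bag (default 6).
#' @param grid Wavenumber grid (default the full [acquisition_grid()]).
#' @return A `"sim_design"`: list with `bags` (`data.frame`: `bag_id`,
#'   `cultivar`, `endophyte_strain`, `endophyte_status`), `scans_per_bag`
#'   and `grid`.
#' @export
default_design <- function(scans_per_bag = 6, grid = acquisition_grid()) {
  design_from_layout(BAG_LAYOUT, scans_per_bag, grid)
}

#' @rdname default_design
#' @export
benchmark_design <- function(scans_per_bag = 6, grid = acquisition_grid()) {
  n_bags <- c(Alto = 27, Bronsyn = 24, Maxsyn = 7, Trojan = 42)
  n_we <- c(Alto = 4, Bronsyn = 4, Maxsyn = 1, Trojan = 3)
  strains <- setdiff(rownames(BAG_LAYOUT), "WE")
  layout <- matrix(0L, length(strains) + 1L, 4,
                   dimnames = list(c(strains, "WE"), CULTIVARS))
  for (cv in CULTIVARS) {
    layout["WE", cv] <- n_we[cv]
    avail <- strains[BAG_LAYOUT[strains, cv] > 0]
    k <- n_bags[cv] - n_we[cv]
    picks <- table(avail[(seq_len(k) - 1L) %% length(avail) + 1L])
    layout[names(picks), cv] <- as.integer(picks)
  }
  design_from_layout(layout, scans_per_bag, grid)
}

#' Custom simulation design
#'
#' Builds a `"sim_design"` from an explicit bag table, for scenarios other
#' than the built-in layouts.
#'
#' @param bags `data.frame` with columns `bag_id`, `cultivar`,
#'   `endophyte_strain`, `endophyte_status` (one row per bag).
#' @inheritParams default_design
#' @return A `"sim_design"`.
#' @export
sim_design <- function(bags, scans_per_bag = 6, grid = acquisition_grid()) {
  req <- c("bag_id", "cultivar", "endophyte_strain", "endophyte_status")
  missing <- setdiff(req, names(bags))
  if (length(missing))
    stop("bags is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(bags$bag_id)) stop("bag_id values must be unique")
  structure(list(bags = as.data.frame(bags),
                 scans_per_bag = as.integer(scans_per_bag), grid = grid),
            class = "sim_design")
}

design_from_layout <- function(layout, scans_per_bag, grid) {
  rows <- list()
  for (cv in colnames(layout)) {
    for (strain in rownames(layout)) {
      k <- layout[strain, cv]
      if (k == 0) next
      tag <- gsub("/", "-", strain)
      rows[[length(rows) + 1L]] <- data.frame(
        bag_id = sprintf("%s_%s_%02d", cv, tag, seq_len(k)),
        cultivar = cv,
        endophyte_strain = strain,
        endophyte_status = if (strain == "WE") "E-" else "E+",
        stringsAsFactors = FALSE)
    }
  }
  structure(list(bags = do.call(rbind, rows),
                 scans_per_bag = as.integer(scans_per_bag),
                 grid = grid),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("<sim_design> %d bags x %d scans = %d scan records\n",
              nrow(x$bags), x$scans_per_bag,
              nrow(x$bags) * x$scans_per_bag))
  print(table(cultivar = x$bags$cultivar, status = x$bags$endophyte_status))
  invisible(x)
}

#' Spectral effect parameters for the generator
#'
#' Defines the class-dependent absorption-band structure and the scan-level
#' artefact model of [generate_spectra()]. The six Gaussian bands sit at
#' the main NIR absorption features of seed material (8230, 6824, 5736,
#' 5176, 4776 and 4304 cm-1: C-H second overtone, N-H first overtone, S-H
#' first overtone, O-H combination, C-H combination, C-H/CH2 combination).
#'
#' Class effects are amplitude offsets on designated bands: each cultivar
#' has its own signed pattern on the 8230 and 4776 cm-1 bands (magnitude
#' `3 * noise_sd`), and endophyte presence (E+) adds `1.5 * noise_sd` on
#' the 6824 cm-1 band -- making endophyte status intrinsically harder to
#' classify than cultivar. Effect sizes are artifact choices (no reference
#' values exist), scaled so that scan-level classification is good but not
#' perfect and bag-level majority voting stays meaningful.
#'
#' Dispersion parameters, per scan unless noted: `bag_sd` (amplitude offset
#' common to all bands, shared by a bag's scans), `within_bag_sd`
#' (independent per-band amplitude jitter per scan: sub-samples are
#' different seeds), `scatter_slope_sd` (multiplicative scatter `1 + a`),
#' `scatter_offset_sd` (additive offset), `tilt_sd` (linear baseline tilt
#' across the grid), `noise_sd` (i.i.d. per-point noise). Units are
#' absorbance throughout.
#'
#' @param band_centers,band_widths,base_amplitudes Per-band Gaussian
#'   centers (cm-1), widths (sd, cm-1) and baseline amplitudes.
#' @param cultivar_effect 4 x 6 matrix (cultivar x band) of amplitude
#'   offsets.
#' @param endophyte_effect Length-6 amplitude offset added for E+ scans.
#' @param bag_sd,within_bag_sd,scatter_slope_sd,scatter_offset_sd,tilt_sd,noise_sd
#'   Dispersion parameters, all `>= 0`.
#' @param seed RNG seed used by [generate_spectra()].
#' @return A `"spectral_params"` list.
#' @export
spectral_effect_params <- function(
    band_centers = c(8230, 6824, 5736, 5176, 4776, 4304),
    band_widths = c(108, 90, 72, 84, 66, 60),
    base_amplitudes = c(0.45, 0.30, 0.25, 0.60, 0.50, 0.40),
    cultivar_effect = NULL,
    endophyte_effect = NULL,
    bag_sd = 0.003,
    within_bag_sd = 0.002,
    scatter_slope_sd = 0.05,
    scatter_offset_sd = 0.02,
    tilt_sd = 0.01,
    noise_sd = 0.003,
    seed = 1L) {
  nb <- length(band_centers)
  stopifnot(length(band_widths) == nb, length(base_amplitudes) == nb,
            all(band_widths > 0))
  if (is.null(cultivar_effect)) {
    d <- 3 * noise_sd
    cultivar_effect <- matrix(0, 4, nb,
                              dimnames = list(CULTIVARS, NULL))
    cultivar_effect[, 1] <- d * c(1, 1, -1, -1)   # 8230 cm-1 band
    cultivar_effect[, 5] <- d * c(1, -1, 1, -1)   # 4776 cm-1 band
  }
  if (is.null(endophyte_effect)) {
    endophyte_effect <- numeric(nb)
    endophyte_effect[2] <- 1.5 * noise_sd          # 6824 cm-1 band
  }
  sds <- c(bag_sd, within_bag_sd, scatter_slope_sd, scatter_offset_sd,
           tilt_sd, noise_sd)
  if (any(sds < 0)) stop("all dispersion parameters must be >= 0")
  structure(list(band_centers = band_centers, band_widths = band_widths,
                 base_amplitudes = base_amplitudes,
                 cultivar_effect = cultivar_effect,
                 endophyte_effect = endophyte_effect,
                 bag_sd = bag_sd, within_bag_sd = within_bag_sd,
                 scatter_slope_sd = scatter_slope_sd,
                 scatter_offset_sd = scatter_offset_sd,
                 tilt_sd = tilt_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "spectral_params")
}

#' Generate labelled synthetic NIR seed spectra
#'
#' Emulates replicated-scan FT-NIR acquisition of bagged seed. Each scan's
#' spectrum is a sum of Gaussian absorption bands whose amplitudes carry
#' the class structure,
#' `base + cultivar_effect + endophyte_effect + bag_effect + within_bag
#' jitter`, distorted by the scan-level artefacts the standard
#' pre-treatments are built to remove: multiplicative scatter `(1 + a)`,
#' additive offset `b`, linear baseline tilt and i.i.d. per-point noise.
#' Scan order is randomized (a seeded shuffle, recorded implicitly as the
#' row order) so that venetian-blinds folds interleave bags and classes.
#' Fully reproducible from `params$seed`.
#'
#' @param design A [default_design()]-style `"sim_design"`.
#' @param params A [spectral_effect_params()] list.
#' @param shuffle Randomize scan order (default `TRUE`).
#' @return A [spectra_set()] with `nrow(design$bags) * scans_per_bag`
#'   scans.
#' @export
generate_spectra <- function(design, params = spectral_effect_params(),
                             shuffle = TRUE) {
  stopifnot(inherits(design, "sim_design"),
            inherits(params, "spectral_params"))
  g <- design$grid
  if (any(params$band_centers > g$high | params$band_centers < g$low))
    stop("band center(s) outside the grid range [", g$low, ", ", g$high, "]: ",
         paste(params$band_centers[params$band_centers > g$high |
                                     params$band_centers < g$low],
               collapse = ", "))
  bags <- design$bags
  spb <- design$scans_per_bag
  n <- nrow(bags) * spb
  p <- length(g$points)
  nb <- length(params$band_centers)
  # band shapes, nb x p
  G <- t(vapply(seq_len(nb), function(b)
    exp(-0.5 * ((g$points - params$band_centers[b]) /
                  params$band_widths[b])^2), numeric(p)))

  set.seed(params$seed)
  bag_effect <- stats::rnorm(nrow(bags), 0, params$bag_sd)
  bag_row <- rep(seq_len(nrow(bags)), each = spb)
  amp <- matrix(rep(params$base_amplitudes, each = n), n, nb)
  amp <- amp + params$cultivar_effect[bags$cultivar[bag_row], , drop = FALSE]
  is_ep <- bags$endophyte_status[bag_row] == "E+"
  amp[is_ep, ] <- amp[is_ep, , drop = FALSE] +
    rep(params$endophyte_effect, each = sum(is_ep))
  amp <- amp + bag_effect[bag_row]
  amp <- amp + matrix(stats::rnorm(n * nb, 0, params$within_bag_sd), n, nb)

  signal <- amp %*% G
  a <- stats::rnorm(n, 0, params$scatter_slope_sd)
  b <- stats::rnorm(n, 0, params$scatter_offset_sd)
  tilt <- stats::rnorm(n, 0, params$tilt_sd)
  ramp <- seq(0, 1, length.out = p)
  eps <- matrix(stats::rnorm(n * p, 0, params$noise_sd), n, p)
  X <- signal * (1 + a) + b + outer(tilt, ramp) + eps

  md <- data.frame(bag_id = bags$bag_id[bag_row],
                   cultivar = bags$cultivar[bag_row],
                   endophyte_strain = bags$endophyte_strain[bag_row],
                   endophyte_status = bags$endophyte_status[bag_row],
                   scan_index = rep(seq_len(spb), nrow(bags)),
                   stringsAsFactors = FALSE)
  if (shuffle) {
    ord <- sample.int(n)
    X <- X[ord, , drop = FALSE]
    md <- md[ord, , drop = FALSE]
  }
  spectra_set(X, md, g)
}

#' Inject localized outlier artefacts into scans
#'
#' Adds a large narrow spike (default width 5 adjacent grid points) to the
#' designated scans, emulating gross acquisition faults, and flags them in
#' the metadata column `outlier_injected`. With `scans = NULL` the
#' reference outlier scenario is used: one scan of an Alto/NEA2 bag and two
#' scans of Alto/WE bags (3 corrupted scans in total).
#'
#' @param s A [spectra_set()].
#' @param scans Row indices of the scans to corrupt, or `NULL` for the
#'   reference scenario.
#' @param magnitude Spike height in absorbance (default 0.06, i.e. 20x the
#'   default per-point noise sd). Zero is the identity.
#' @param width Spike width in grid points (default 5).
#' @param seed Seed for the spike positions (default 1).
#' @return A new `spectra_set` with corrupted scans and an
#'   `outlier_injected` metadata column.
#' @export
inject_outliers <- function(s, scans = NULL, magnitude = 0.06, width = 5,
                            seed = 1L) {
  stopifnot(inherits(s, "spectra_set"))
  md <- s$metadata
  if (is.null(scans)) {
    nea2 <- which(md$cultivar == "Alto" & md$endophyte_strain == "NEA2")
    we <- which(md$cultivar == "Alto" & md$endophyte_strain == "WE")
    if (length(nea2) < 1 || length(we) < 2)
      stop("reference scenario needs Alto/NEA2 and Alto/WE scans")
    scans <- c(nea2[1], we[1:2])
  }
  X <- s$absorbance
  p <- ncol(X)
  set.seed(seed)
  pos <- sample.int(p - width + 1L, length(scans), replace = TRUE)
  for (k in seq_along(scans))
    X[scans[k], pos[k]:(pos[k] + width - 1L)] <-
      X[scans[k], pos[k]:(pos[k] + width - 1L)] + magnitude
  md$outlier_injected <- seq_len(nrow(X)) %in% scans
  spectra_set(X, md, s$grid)
}

#' The canonical synthetic benchmark
#'
#' Generates the 100-bag benchmark scenario (600 scans on the acquisition
#' grid) with default effect sizes, together with the truth table and the
#' documented pass thresholds for the end-to-end cultivar pipeline:
#' scan-level overall accuracy >= 0.90 on held-out scans and bag-level
#' 4-of-6 vote accuracy >= 0.98.
#'
#' @param seed RNG seed; the suite regenerates identically from it.
#' @return A `"benchmark_suite"`: list with `spectra` ([spectra_set()]),
#'   `truth` (metadata `data.frame`), and `thresholds`.
#' @export
benchmark_suite <- function(seed = 1L) {
  design <- benchmark_design()
  params <- spectral_effect_params(seed = seed)
  spectra <- generate_spectra(design, params)
  structure(list(spectra = spectra, truth = spectra$metadata,
                 thresholds = list(scan_accuracy = 0.90,
                                   bag_accuracy = 0.98)),
            class = "benchmark_suite")
}
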