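#' Specification of a synthetic accession panel
#'
#' Defines the study design emulated by the generator: rosettes of
#' superelliptical leaf blades with thin petioles radiating from a centre, a
#' bright-vein Compton raster, per-substructure metal enrichment with an
#' accession-level (genotype) random effect of controlled variance, and
#' per-pixel Gaussian detector noise.
#'
#' Substructure effects are multiplicative on a base intensity and drawn on
#' the log scale (keeping intensities positive), so they map directly onto
#' true concentration quotients with closed-form bookkeeping. The implied
#' true broad-sense heritability of every CQ trait,
#' `sigma_G^2 / (sigma_G^2 + sigma_e^2)`, is recorded in the returned spec.
#'
#' @param n_accessions number of accessions (default 86).
#' @param n_reps replicate plants per accession (default 3).
#' @param img_dim image height and width in pixels.
#' @param n_leaves leaves per rosette.
#' @param blade_a,blade_b blade superellipse semi-axes (px) at scale 1.
#' @param blade_exp superellipse exponent (2 = ellipse; larger = fuller tip).
#' @param petiole_width,petiole_length petiole strip width / length (px);
#'   the width must stay below the opening kernel and `2 * blade_b` above it
#'   for the blade/petiole split to be possible.
#' @param vein_midrib_halfwidth,vein_secondary_halfwidth rendered vein stroke
#'   half-widths (px); the defaults give 3-px midribs and 2-px secondaries.
#'   Set `vein_secondary_halfwidth = 0.5` for the "hard" 1-px fixture family.
#' @param n_secondary secondary veins per leaf side.
#' @param margin_width leaf-margin band width (px).
#' @param base_intensity named per-element plant base intensity (8-bit scale).
#' @param base_background background intensity of the metal rasters.
#' @param compton_levels named Compton intensities per class.
#' @param cq_mu 4x4 matrix of mean substructure enrichment multipliers
#'   (rows = [SUBSTRUCTURES], columns = [XRF_ELEMENTS]).
#' @param sigma_G,sigma_e accession-level and replicate-level standard
#'   deviations of the log-scale substructure effects. The defaults give a
#'   true H2 of 0.80.
#' @param size_sigma_G,size_sigma_e log-scale sd of the accession / replicate
#'   plant-size effect.
#' @param noise_sd Gaussian per-pixel detector noise sd (intensity units).
#' @param seed integer seed governing the whole panel.
#' @return an object of class `panel_spec` (a list, with `true_h2` filled in).
#' @export
panel_spec <- function(n_accessions = 86L, n_reps = 3L,
                       img_dim = c(256L, 256L), n_leaves = 5L,
                       blade_a = 22, blade_b = 17, blade_exp = 2,
                       petiole_width = 9, petiole_length = 21,
                       vein_midrib_halfwidth = 1.25,
                       vein_secondary_halfwidth = 1.0,
                       n_secondary = 3L, margin_width = 3L,
                       base_intensity = c(Zn = 80, K = 100, Ca = 90, Ni = 70),
                       base_background = 5,
                       compton_levels = c(background = 8, petiole = 190,
                                          margin = 140, vein = 230,
                                          tissue = 120),
                       cq_mu = default_cq_mu(),
                       sigma_G = 0.134, sigma_e = 0.067,
                       size_sigma_G = 0.08, size_sigma_e = 0.04,
                       noise_sd = 5, seed = 1L) {
  stopifnot(n_accessions >= 1L, n_reps >= 1L, length(img_dim) == 2L,
            all(img_dim > 0), n_leaves >= 1L, sigma_G >= 0, sigma_e >= 0,
            noise_sd >= 0, margin_width >= 1L)
  if (!all(XRF_ELEMENTS %in% names(base_intensity)))
    stop("base_intensity must name all of: ",
         paste(XRF_ELEMENTS, collapse = ", "))
  if (!identical(dim(cq_mu), c(4L, 4L)))
    stop("cq_mu must be a 4x4 matrix (substructures x elements)")
  spec <- list(n_accessions = as.integer(n_accessions),
               n_reps = as.integer(n_reps),
               img_dim = as.integer(img_dim), n_leaves = as.integer(n_leaves),
               blade_a = blade_a, blade_b = blade_b, blade_exp = blade_exp,
               petiole_width = petiole_width, petiole_length = petiole_length,
               vein_midrib_halfwidth = vein_midrib_halfwidth,
               vein_secondary_halfwidth = vein_secondary_halfwidth,
               n_secondary = as.integer(n_secondary),
               margin_width = as.integer(margin_width),
               base_intensity = base_intensity[XRF_ELEMENTS],
               base_background = base_background,
               compton_levels = compton_levels,
               cq_mu = cq_mu, sigma_G = sigma_G, sigma_e = sigma_e,
               size_sigma_G = size_sigma_G, size_sigma_e = size_sigma_e,
               noise_sd = noise_sd, seed = as.integer(seed))
  spec$true_h2 <- if (sigma_G^2 + sigma_e^2 > 0)
    sigma_G^2 / (sigma_G^2 + sigma_e^2) else NA_real_
  structure(spec, class = "panel_spec")
}

#' Default substructure enrichment multipliers
#'
#' Mean multiplicative enrichment of each substructure (rows, in
#' [SUBSTRUCTURES] order) for each element (columns, in [XRF_ELEMENTS]
#' order): veins and margins enriched in Zn/Ni, petioles in K, interveinal
#' tissue slightly depleted -- a substructure-specific spatial pattern.
#'
#' @return a 4x4 numeric matrix.
#' @export
default_cq_mu <- function() {
  matrix(c(
    # Zn    K     Ca    Ni
    1.35, 1.50, 0.90, 1.20,   # petiole
    1.60, 0.90, 1.30, 1.50,   # margin
    1.80, 1.30, 1.10, 1.60,   # vein
    0.80, 0.90, 1.00, 0.85),  # tissue
    nrow = 4L, byrow = TRUE,
    dimnames = list(SUBSTRUCTURES, XRF_ELEMENTS))
}

# Distance from points (u, v) to the segment (u0,v0)-(u1,v1), vectorized.
dist_to_segment <- function(u, v, u0, v0, u1, v1) {
  du <- u1 - u0; dv <- v1 - v0
  len2 <- du^2 + dv^2
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((u - u0) * du + (v - v0) * dv) / len2))
  sqrt((u - (u0 + t * du))^2 + (v - (v0 + t * dv))^2)
}

#' Generate ground-truth rosette geometry
#'
#' Renders a rosette of `n_leaves` superelliptical blades with thin petiole
#' strips radiating from the image centre, a 3-px margin rim, and a vein
#' system (midrib plus branching secondaries). The masks satisfy the
#' segmentation partition invariants by construction: margin, vein and tissue
#' are disjoint with union equal to the blade, and the petiole is the strip
#' residual outside the blade.
#'
#' @param spec a [panel_spec()].
#' @param scale overall plant size multiplier.
#' @param seed integer seed for the leaf-level jitter.
#' @return list with logical masks `petiole`, `margin`, `vein`, `tissue`,
#'   `blade`, `plant`, and the [seg_labels()] map `labels`.
#' @export
generate_geometry <- function(spec = panel_spec(), scale = 1, seed = 1L) {
  nr <- spec$img_dim[1L]; nc <- spec$img_dim[2L]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  # 1.08 = maximum per-leaf size jitter
  max_reach <- (spec$petiole_length + 4 + 2 * spec$blade_a +
                  spec$blade_b) * scale * 1.08
  if (max_reach > min(nr, nc) / 2 - 1)
    stop(sprintf("impossible geometry: rosette reach %.0f px exceeds image radius %.0f",
                 max_reach, min(nr, nc) / 2 - 1))
  # restrict all per-leaf work to the disc the rosette can reach
  R <- matrix(seq_len(nr) - cy, nr, nc)
  C <- matrix(seq_len(nc) - cx, nr, nc, byrow = TRUE)
  disc <- which(R * R + C * C <= (max_reach + 2)^2)
  Rd <- R[disc]; Cd <- C[disc]
  blade_d <- logical(length(disc))
  strips_d <- logical(length(disc))
  veins_d <- logical(length(disc))
  p <- spec$blade_exp
  with_seed(seed, {
    for (l in seq_len(spec$n_leaves)) {
      theta <- 2 * pi * (l - 1) / spec$n_leaves + stats::runif(1, -0.1, 0.1)
      sl <- scale * stats::runif(1, 0.92, 1.08)
      a <- spec$blade_a * sl; b <- spec$blade_b * sl
      r0 <- 4
      r1 <- r0 + spec$petiole_length * sl
      rc <- r1 + a - 3
      u <- Rd * cos(theta) + Cd * sin(theta)
      v <- -Rd * sin(theta) + Cd * cos(theta)
      strips_d <- strips_d |
        (u >= r0 & u <= r1 + 1 & abs(v) <= spec$petiole_width / 2)
      blade_d <- blade_d | ((abs(u - rc) / a)^p + (abs(v) / b)^p <= 1)
      # vein system in leaf coordinates: midrib + branching secondaries
      box <- which(abs(u - rc) <= a + 2 & abs(v) <= b + 2)
      ub <- u[box]; vb <- v[box]
      seg <- function(u0, v0, u1, v1, hw) {
        hit <- dist_to_segment(ub, vb, u0, v0, u1, v1) <= hw
        veins_d[box] <<- veins_d[box] | hit
      }
      seg(rc - 0.95 * a, 0, rc + 0.90 * a, 0, spec$vein_midrib_halfwidth)
      fr <- seq(0.25, 0.85, length.out = spec$n_secondary)
      phi <- 40 * pi / 180
      for (f in fr) {
        us <- rc - a + 2 * a * f
        vmax <- b * (1 - (abs(us - rc) / a)^p)^(1 / p)
        len <- 0.75 * vmax / sin(phi)
        for (sgn in c(-1, 1))
          seg(us, 0, us + len * cos(phi), sgn * len * sin(phi),
              spec$vein_secondary_halfwidth)
      }
    }
  })
  blade <- matrix(FALSE, nr, nc); blade[disc] <- blade_d
  strips <- matrix(FALSE, nr, nc); strips[disc] <- strips_d
  veins <- matrix(FALSE, nr, nc); veins[disc] <- veins_d
  eroded <- eb_to_mask(EBImage::erode(eb_binary(blade),
                                      box_kernel(2L * spec$margin_width + 1L)))
  margin <- blade & !eroded
  vein <- veins & blade & !margin
  tissue <- blade & !margin & !vein
  petiole <- strips & !blade
  plant <- petiole | blade
  codes <- matrix(LABEL_CODES[["background"]], nr, nc)
  codes[petiole] <- LABEL_CODES[["petiole"]]
  codes[margin] <- LABEL_CODES[["margin"]]
  codes[vein] <- LABEL_CODES[["vein"]]
  codes[tissue] <- LABEL_CODES[["tissue"]]
  list(petiole = petiole, margin = margin, vein = vein, tissue = tissue,
       blade = blade, plant = plant, labels = seg_labels(codes))
}

#' Render a scan bundle from ground-truth geometry
#'
#' Per element, each substructure's pixels get `base intensity x multiplier`;
#' Gaussian per-pixel noise is added and values are clipped to \[0, 255\]
#' (with a warning if clipping actually truncates the signal, since that
#' biases CQs). Rasters are kept real-valued in memory; [write_panel()]
#' rounds on TIFF export. The Compton raster has elevated vein and petiole
#' intensity so the Laplacian detector has signal, and carries no genotype
#' effect.
#'
#' The returned truth records the realized noiseless CQs, computed in closed
#' form from the substructure areas and multipliers; with `noise_sd = 0` the
#' measured CQ of the rendered raster equals the bookkeeping value exactly.
#'
#' @param geometry output of [generate_geometry()].
#' @param multipliers 4x4 matrix of realized substructure multipliers
#'   (rows = [SUBSTRUCTURES], columns = [XRF_ELEMENTS]).
#' @param spec a [panel_spec()].
#' @param sample_id,accession_id,replicate identifiers for the bundle.
#' @param seed integer seed for the pixel noise.
#' @return list with elements `bundle` (a [scan_bundle()]) and `truth`
#'   (list: `labels`, `cq` -- 4x4 realized CQ matrix -- `multipliers`,
#'   `plant_area`, per-class `areas`).
#' @export
render_bundle <- function(geometry, multipliers, spec = panel_spec(),
                          sample_id = "synthetic", accession_id = NA,
                          replicate = NA, seed = 1L) {
  stopifnot(identical(dim(multipliers), c(4L, 4L)))
  nr <- nrow(geometry$plant); nc <- ncol(geometry$plant)
  areas <- vapply(SUBSTRUCTURES, function(cl) sum(geometry[[cl]]), numeric(1))
  n_plant <- sum(geometry$plant)
  rasters <- list()
  clipped <- FALSE
  with_seed(seed, {
    for (j in seq_along(XRF_ELEMENTS)) {
      el <- XRF_ELEMENTS[j]
      img <- matrix(spec$base_background, nr, nc)
      for (i in seq_along(SUBSTRUCTURES)) {
        cl <- SUBSTRUCTURES[i]
        img[geometry[[cl]]] <- spec$base_intensity[[el]] * multipliers[i, j]
      }
      if (max(img) > 255) clipped <- TRUE
      if (spec$noise_sd > 0)
        img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
      rasters[[el]] <- pmin(pmax(img, 0), 255)
    }
    img <- matrix(spec$compton_levels[["background"]], nr, nc)
    for (cl in SUBSTRUCTURES)
      img[geometry[[cl]]] <- spec$compton_levels[[cl]]
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    rasters$Compton <- pmin(pmax(img, 0), 255)
  })
  if (clipped)
    warning("substructure mean intensity exceeds the 8-bit range; ",
            "clipping will bias CQs for ", sample_id)
  # closed-form realized CQ: multiplier over the area-weighted plant mean
  cq <- multipliers
  for (j in seq_len(4L)) {
    plant_mean <- sum(areas * multipliers[, j]) / n_plant
    cq[, j] <- multipliers[, j] / plant_mean
  }
  list(bundle = scan_bundle(rasters, sample_id, accession_id, replicate),
       truth = list(labels = geometry$labels, cq = cq,
                    multipliers = multipliers, plant_area = n_plant,
                    areas = areas))
}

#' Generate one synthetic plant
#'
#' Draws the replicate-level deviations (size jitter, log-scale substructure
#' effects, pixel noise) under `seed`, on top of the accession-level effects
#' supplied by the caller.
#'
#' @param spec a [panel_spec()].
#' @param accession_effects 4x4 matrix of accession-level log-scale effects.
#' @param size_effect accession-level log-scale size effect.
#' @param sample_id,accession_id,replicate identifiers.
#' @param seed integer seed for everything replicate-specific.
#' @return as [render_bundle()].
#' @export
generate_plant <- function(spec = panel_spec(),
                           accession_effects = matrix(0, 4L, 4L),
                           size_effect = 0,
                           sample_id = "synthetic", accession_id = NA,
                           replicate = NA, seed = 1L) {
  seeds <- derive_seeds(seed, 4L)
  eps <- with_seed(seeds[1L],
                   matrix(stats::rnorm(16L, 0, spec$sigma_e), 4L, 4L))
  size_e <- with_seed(seeds[4L], stats::rnorm(1L, 0, spec$size_sigma_e))
  # clamp so extreme accessions cannot outgrow the canvas (~3.3 sd)
  scale <- exp(pmin(pmax(size_effect + size_e, -0.3), 0.3))
  geometry <- generate_geometry(spec, scale = scale, seed = seeds[2L])
  multipliers <- spec$cq_mu * exp(accession_effects + eps)
  render_bundle(geometry, multipliers, spec, sample_id, accession_id,
                replicate, seed = seeds[3L])
}

#' Generate a synthetic accession panel
#'
#' Draws the accession-level effects once per accession (sd `sigma_G`) and a
#' per-plant seed stream, but does not materialize the images: individual
#' plants are rendered on demand with [panel_plant()], so arbitrarily large
#' panels stream in constant memory. The spec's seed makes the whole panel
#' reproducible.
#'
#' @param spec a [panel_spec()].
#' @return an object of class `xrf_panel`: list with `spec`, `accessions`,
#'   accession effect array `G` (accession x substructure x element),
#'   `size_G`, per-plant seed matrices, `true_h2` and `n_plants`.
#' @export
generate_panel <- function(spec = panel_spec()) {
  stopifnot(inherits(spec, "panel_spec"))
  n <- spec$n_accessions; k <- spec$n_reps
  panel <- with_seed(spec$seed, {
    G <- array(stats::rnorm(n * 16L, 0, spec$sigma_G), dim = c(n, 4L, 4L))
    size_G <- stats::rnorm(n, 0, spec$size_sigma_G)
    plant_seeds <- matrix(sample.int(.Machine$integer.max, n * k), n, k)
    rand_seeds <- matrix(sample.int(.Machine$integer.max, n * k), n, k)
    list(G = G, size_G = size_G, plant_seeds = plant_seeds,
         rand_seeds = rand_seeds)
  })
  panel$spec <- spec
  panel$accessions <- sprintf("acc%03d", seq_len(n))
  panel$true_h2 <- spec$true_h2
  panel$n_plants <- n * k
  structure(panel, class = "xrf_panel")
}

#' @export
print.xrf_panel <- function(x, ...) {
  cat(sprintf("<xrf_panel> %d accessions x %d reps (%d plants), true H2 = %.3f\n",
              x$spec$n_accessions, x$spec$n_reps, x$n_plants, x$true_h2))
  invisible(x)
}

#' Materialize one plant of a panel
#'
#' @param panel an `xrf_panel`.
#' @param i linear plant index in `1:panel$n_plants` (accession-major).
#' @return as [generate_plant()], plus `accession_id`, `replicate` and the
#'   plant's `rand_seed` (used for its random substructure).
#' @export
panel_plant <- function(panel, i) {
  stopifnot(inherits(panel, "xrf_panel"), i >= 1L, i <= panel$n_plants)
  k <- panel$spec$n_reps
  acc <- ((i - 1L) %/% k) + 1L
  rep <- ((i - 1L) %% k) + 1L
  out <- generate_plant(panel$spec,
                        accession_effects = panel$G[acc, , ],
                        size_effect = panel$size_G[acc],
                        sample_id = sprintf("%s_r%d", panel$accessions[acc], rep),
                        accession_id = panel$accessions[acc],
                        replicate = rep,
                        seed = panel$plant_seeds[acc, rep])
  out$accession_id <- panel$accessions[acc]
  out$replicate <- rep
  out$rand_seed <- panel$rand_seeds[acc, rep]
  out
}

#' Trait table of a synthetic panel
#'
#' Streams over the panel's plants, labels each one either with the
#' segmentation pipeline (`labels = "segment"`) or with the generator's
#' ground truth (`labels = "truth"`), and assembles the [plant_traits()]
#' rows. Optionally adds the random-substructure CQ control traits
#' (`cq_random_<element>`), drawn with each plant's dedicated seed.
#'
#' @param panel an `xrf_panel`.
#' @param labels `"segment"` or `"truth"`.
#' @param params a [seg_params()] (used for `labels = "segment"`).
#' @param random_cq add random-substructure CQ columns?
#' @param n_squares,square_side random-substructure parameters
#'   (see [random_substructure()]).
#' @param indices subset of plant indices (default: all).
#' @return data.frame, one row per plant.
#' @export
panel_trait_table <- function(panel, labels = c("segment", "truth"),
                              params = seg_params(), random_cq = TRUE,
                              n_squares = 5L, square_side = 30L,
                              indices = NULL) {
  labels <- match.arg(labels)
  if (is.null(indices)) indices <- seq_len(panel$n_plants)
  rows <- lapply(indices, function(i) {
    pl <- panel_plant(panel, i)
    lab <- if (labels == "segment")
      suppressWarnings(segment_bundle(pl$bundle, params)) else pl$truth$labels
    row <- suppressWarnings(plant_traits(pl$bundle, lab))
    if (random_cq) {
      plant <- unclass(lab) != 0L
      rmask <- random_substructure(plant, n_squares = n_squares,
                                   square_side = square_side,
                                   seed = pl$rand_seed)
      for (el in XRF_ELEMENTS)
        row[[sprintf("cq_random_%s", el)]] <- if (any(rmask))
          concentration_quotient(pl$bundle$rasters[[el]], rmask, plant)
        else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a panel to disk as TIFF bundles plus a manifest
#'
#' Rasters are rounded to integers for 8-bit TIFF export; truth labels are
#' written alongside. The manifest CSV lists one row per raster file; panel
#' metadata (seed, true H2) goes to `panel_meta.yaml`.
#'
#' @param panel an `xrf_panel`.
#' @param dir output directory (created if needed).
#' @param indices subset of plant indices (default: all).
#' @return the manifest data.frame, invisibly.
#' @export
write_panel <- function(panel, dir, indices = NULL) {
  if (is.null(indices)) indices <- seq_len(panel$n_plants)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in indices) {
    pl <- panel_plant(panel, i)
    sid <- pl$bundle$sample_id
    for (el in BUNDLE_ELEMENTS) {
      fn <- sprintf("%s_%s.tif", sid, el)
      write_raster(round(pl$bundle$rasters[[el]]), file.path(dir, fn))
      rows[[length(rows) + 1L]] <-
        data.frame(sample_id = sid, accession_id = pl$accession_id,
                   replicate = pl$replicate, element = el, path = fn,
                   stringsAsFactors = FALSE)
    }
    write_labels(pl$truth$labels, file.path(dir, sprintf("%s_truth.tif", sid)))
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  yaml::write_yaml(list(seed = panel$spec$seed, true_h2 = panel$true_h2,
                        n_accessions = panel$spec$n_accessions,
                        n_reps = panel$spec$n_reps),
                   file.path(dir, "panel_meta.yaml"))
  invisible(manifest)
}
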