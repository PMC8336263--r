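#' Random substructure mask
#'
#' Unions `n_squares` square patches whose centres are drawn uniformly from
#' the plant-foreground pixels, then intersects with the plant mask (squares
#' overlapping the background are cropped). Serves as the negative control
#' for CQ heritability: a random "substructure" carries no genotype-specific
#' spatial signal.
#'
#' @param plant logical plant-foreground mask (non-empty).
#' @param n_squares number of squares (default 5).
#' @param square_side square side in pixels (default 30).
#' @param seed integer seed.
#' @return logical mask, a subset of `plant`, with area at most
#'   `n_squares * square_side^2`.
#' @export
random_substructure <- function(plant, n_squares = 5L, square_side = 30L,
                                seed = 1L) {
  assert_mask(plant)
  stopifnot(n_squares >= 1L, square_side >= 1L)
  idx <- which(plant)
  if (length(idx) == 0L) stop("plant mask is empty")
  if (length(idx) < square_side^2)
    warning("plant smaller than one square; using the intersection only")
  nr <- nrow(plant)
  lo <- floor((square_side - 1) / 2)
  hi <- square_side - 1L - lo
  out <- matrix(FALSE, nr, ncol(plant))
  with_seed(seed, {
    centres <- idx[sample.int(length(idx), n_squares,
                              replace = length(idx) < n_squares)]
    for (p in centres) {
      ci <- (p - 1L) %% nr + 1L
      cj <- (p - 1L) %/% nr + 1L
      r <- max(1L, ci - lo):min(nr, ci + hi)
      cc <- max(1L, cj - lo):min(ncol(plant), cj + hi)
      out[r, cc] <- TRUE
    }
  })
  out & plant
}

#' Inject class-label noise into a segmentation
#'
#' Reassigns a uniformly sampled fraction of the non-background pixels
#' (exactly `ceiling(fraction * N_plant)` of them, without replacement) a
#' class drawn uniformly from the four substructure classes. The draw may
#' repeat the original class, so the effective corruption rate is
#' `0.75 * fraction`. Background pixels are never touched.
#'
#' @param labels a [seg_labels()] map.
#' @param fraction fraction of plant pixels to reassign, in \[0, 1\].
#' @param seed integer seed.
#' @return a new [seg_labels()] map.
#' @export
inject_label_noise <- function(labels, fraction, seed = 1L) {
  stopifnot(inherits(labels, "seg_labels"))
  if (is.na(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must be in [0, 1]")
  m <- unclass(labels)
  idx <- which(m != 0L)
  n_noise <- ceiling(fraction * length(idx))
  if (n_noise > 0L) {
    with_seed(seed, {
      pick <- idx[sample.int(length(idx), n_noise)]
      m[pick] <- sample(unname(LABEL_CODES[SUBSTRUCTURES]), n_noise,
                        replace = TRUE)
    })
  }
  seg_labels(m)
}

#' Default sensitivity-sweep grid for a parameter
#'
#' Five values, from two steps below to two steps above the base value:
#' opening kernel step 4, Laplacian kernel step 2, thick-vein threshold step
#' 500, thin-vein threshold step 100. With the default parameters this gives
#' opening 7..23, Laplacian 3..11, vein1 -3500..-1500 and vein2 -200..200.
#'
#' @param parameter one of `"opening_kernel"`, `"laplacian_kernel"`,
#'   `"vein1_threshold"`, `"vein2_threshold"`.
#' @param base_params a [seg_params()].
#' @return numeric vector of five grid values.
#' @export
default_sweep_grid <- function(parameter, base_params = seg_params()) {
  steps <- c(opening_kernel = 4, laplacian_kernel = 2,
             vein1_threshold = 500, vein2_threshold = 100)
  parameter <- match.arg(parameter, names(steps))
  base_params[[parameter]] + (-2:2) * steps[[parameter]]
}

#' Sensitivity sweep of segmentation quality over one parameter
#'
#' Re-segments the bundle at each grid value, re-evaluates the fixed
#' annotated pixel coordinates against the new predictions and reports
#' per-class precision, recall and F1. The base value is flagged in the
#' output. Classes that vanish at a grid value get missing metrics.
#'
#' @param bundle a [scan_bundle()].
#' @param truth annotated ground-truth data.frame (`row`, `col`,
#'   `true_class`), labelled once against a fixed pixel set.
#' @param parameter parameter to vary (see [default_sweep_grid()]).
#' @param grid value grid; defaults to the five-step grid.
#' @param base_params a [seg_params()].
#' @return long data.frame: `parameter`, `value`, `base`, `class`,
#'   `precision`, `recall`, `f1`.
#' @export
sensitivity_sweep <- function(bundle, truth, parameter, grid = NULL,
                              base_params = seg_params()) {
  parameter <- match.arg(parameter, c("opening_kernel", "laplacian_kernel",
                                      "vein1_threshold", "vein2_threshold"))
  if (is.null(grid)) grid <- default_sweep_grid(parameter, base_params)
  rows <- lapply(grid, function(val) {
    args <- unclass(base_params)
    args[[parameter]] <- val
    p <- do.call(seg_params, args)
    lab <- suppressWarnings(segment_bundle(bundle, p))
    ev <- evaluate_labels(lab, truth)
    data.frame(parameter = parameter, value = val,
               base = val == base_params[[parameter]],
               ev, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Heritability of CQ traits under increasing label noise
#'
#' For each noise fraction, the panel's plants are re-labelled by injecting
#' class noise into the (segmented or ground-truth) labels, the 16 CQ traits
#' are re-derived from the unchanged rasters, and per-trait H2 is refitted.
#' Deterministic under `seed`; fraction 0 reproduces the clean report.
#'
#' @param panel an `xrf_panel`.
#' @param fractions noise fractions to evaluate.
#' @param seed integer seed for the noise draws.
#' @param labels `"segment"` or `"truth"` (see [panel_trait_table()]).
#' @param params a [seg_params()].
#' @param indices subset of plant indices (default: all).
#' @return long data.frame: `trait`, `fraction`, `H2`, `var_G`, `var_e`.
#' @export
noise_robustness_curve <- function(panel, fractions = c(0, 0.05, 0.1, 0.2),
                                   seed = 1L, labels = c("segment", "truth"),
                                   params = seg_params(), indices = NULL) {
  stopifnot(inherits(panel, "xrf_panel"), all(fractions >= 0 & fractions <= 1))
  labels <- match.arg(labels)
  if (is.null(indices)) indices <- seq_len(panel$n_plants)
  noise_seeds <- matrix(derive_seeds(seed, length(indices) * length(fractions)),
                        nrow = length(indices))
  acc <- character(length(indices))
  cq <- vector("list", length(fractions))
  for (fi in seq_along(fractions)) cq[[fi]] <- vector("list", length(indices))
  for (ii in seq_along(indices)) {
    pl <- panel_plant(panel, indices[ii])
    acc[ii] <- pl$accession_id
    lab <- if (labels == "segment")
      suppressWarnings(segment_bundle(pl$bundle, params)) else pl$truth$labels
    for (fi in seq_along(fractions)) {
      noisy <- inject_label_noise(lab, fractions[fi], noise_seeds[ii, fi])
      cq[[fi]][[ii]] <- suppressWarnings(cq_traits(pl$bundle, noisy))
    }
  }
  rows <- list()
  for (fi in seq_along(fractions)) {
    tab <- as.data.frame(do.call(rbind, cq[[fi]]))
    for (tr in names(tab)) {
      v <- tab[[tr]]
      if (all(is.na(v)) || stats::var(v, na.rm = TRUE) == 0) next
      vc <- suppressMessages(fit_random_effects(v, acc))
      rows[[length(rows) + 1L]] <-
        data.frame(trait = tr, fraction = fractions[fi], H2 = vc$H2,
                   var_G = vc$var_G, var_e = vc$var_e,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
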