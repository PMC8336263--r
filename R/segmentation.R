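#' Segmentation parameters
#'
#' Tunable parameters of the substructure segmentation. Structuring elements
#' are square and all-ones throughout. The margin erosion kernel of side
#' \eqn{2w+1} produces a margin band of width \eqn{w} on straight edges; the
#' default 7 gives the 3-px margin band. The Laplacian thresholds are specific
#' to the aperture-k second-derivative kernel used here (see
#' [laplacian_response()]); bright ridges give negative responses, so
#' `vein1_threshold` is negative.
#'
#' @param opening_kernel odd integer >= 3; side of the square structuring
#'   element of the morphological opening that separates blade from petiole
#'   (default 15).
#' @param min_component_fraction connected components of the petiole residual
#'   smaller than this fraction of the full image area are discarded
#'   (default 1e-5, i.e. 0.001\%).
#' @param margin_erosion_kernel odd integer >= 3; side of the erosion kernel
#'   of the internal-gradient margin (default 7, giving a 3-px band).
#' @param laplacian_kernel odd integer >= 3; aperture of the Laplacian
#'   (default 7).
#' @param vein1_threshold Laplacian threshold for thick primary/secondary
#'   vasculature (default -2500).
#' @param vein2_threshold Laplacian threshold whose mask is skeletonized to
#'   locate thin tertiary vasculature (default 0, applied strictly: a flat
#'   response is excluded).
#' @return an object of class `seg_params`.
#' @export
seg_params <- function(opening_kernel = 15L,
                       min_component_fraction = 1e-5,
                       margin_erosion_kernel = 7L,
                       laplacian_kernel = 7L,
                       vein1_threshold = -2500,
                       vein2_threshold = 0) {
  for (k in c(opening_kernel, margin_erosion_kernel, laplacian_kernel)) {
    if (k < 3L || k %% 2L == 0L)
      stop("structuring-element and Laplacian kernel sides must be odd and >= 3")
  }
  if (min_component_fraction < 0 || min_component_fraction >= 1)
    stop("min_component_fraction must be in [0, 1)")
  structure(list(opening_kernel = as.integer(opening_kernel),
                 min_component_fraction = min_component_fraction,
                 margin_erosion_kernel = as.integer(margin_erosion_kernel),
                 laplacian_kernel = as.integer(laplacian_kernel),
                 vein1_threshold = vein1_threshold,
                 vein2_threshold = vein2_threshold),
            class = "seg_params")
}

box_kernel <- function(k) EBImage::makeBrush(as.integer(k), shape = "box")

eb_binary <- function(mask) EBImage::Image(mask * 1)

eb_to_mask <- function(img) EBImage::imageData(img) > 0.5

otsu_threshold_bins <- function(bins) {
  cnt <- tabulate(bins + 1L, nbins = 256L)
  idx <- 0:255
  n <- sum(cnt)
  w0 <- cumsum(cnt)
  m0 <- cumsum(cnt * idx)
  s0 <- cumsum(cnt * idx^2)
  ss0 <- ifelse(w0 > 0, s0 - m0^2 / w0, 0)
  w1 <- n - w0
  m1 <- m0[256L] - m0
  s1 <- s0[256L] - s0
  ss1 <- ifelse(w1 > 0, s1 - m1^2 / w1, 0)
  obj <- (ss0 + ss1) / n
  t <- which.min(obj) - 1L   # first minimum = smallest threshold
  structure(t, objective = obj[t + 1L])
}

raster_bins <- function(v) {
  if (max(v) > 255 || any(v != floor(v))) {
    # non-8-bit input: 256-bin histogram of min-max-scaled values
    b <- floor((v - min(v)) / (max(v) - min(v)) * 255)
    as.integer(pmin(b, 255))
  } else {
    as.integer(v)
  }
}

#' Otsu threshold of a raster
#'
#' The threshold minimizing the intra-class intensity variance over a 256-bin
#' histogram; ties are broken towards the smallest threshold. 8-bit rasters
#' are thresholded on their raw values; other inputs are min-max scaled into
#' 256 bins first.
#'
#' @param raster intensity raster (matrix).
#' @return integer threshold on the 0--255 bin scale, with the attained
#'   intra-class variance as attribute `objective`; `NA` for a constant
#'   raster.
#' @export
otsu_threshold <- function(raster) {
  v <- as.numeric(raster)
  if (length(v) == 0L) stop("raster is empty")
  if (max(v) == min(v)) return(NA_integer_)
  otsu_threshold_bins(raster_bins(v))
}

#' Binarize a raster with Otsu's method
#'
#' Mask is true where the (binned) pixel value strictly exceeds the Otsu
#' threshold. A constant raster has no separating threshold and yields an
#' all-false mask with a warning.
#'
#' @param raster intensity raster.
#' @return logical matrix.
#' @export
otsu_mask <- function(raster) {
  v <- as.numeric(raster)
  if (max(v) == min(v)) {
    warning("constant raster: no separating threshold, returning empty mask")
    return(matrix(FALSE, nrow(raster), ncol(raster)))
  }
  bins <- raster_bins(v)
  t <- otsu_threshold_bins(bins)
  matrix(bins > as.integer(t), nrow(raster), ncol(raster))
}

#' Plant foreground mask
#'
#' Pixel-wise union of the Otsu masks of the four metal rasters (Zn, K, Ca,
#' Ni); the Compton raster is not used here.
#'
#' @param bundle a [scan_bundle()].
#' @return logical matrix.
#' @export
plant_mask <- function(bundle) {
  stopifnot(inherits(bundle, "scan_bundle"))
  masks <- lapply(XRF_ELEMENTS, function(el) otsu_mask(bundle$rasters[[el]]))
  Reduce(`|`, masks)
}

#' Blade mask by morphological opening
#'
#' One iteration of opening (erosion then dilation) with a square all-ones
#' structuring element removes structures narrower than the kernel --
#' petioles -- and keeps the leaf blades.
#'
#' @param plant logical plant-foreground mask.
#' @param params a [seg_params()].
#' @return logical matrix, a subset of `plant`.
#' @export
blade_mask <- function(plant, params = seg_params()) {
  assert_mask(plant)
  eb_to_mask(EBImage::opening(eb_binary(plant),
                              box_kernel(params$opening_kernel)))
}

#' Petiole mask
#'
#' The residual `plant \ blade`, cleaned by dropping 8-connected components
#' smaller than `min_component_fraction` of the full image area (threshold
#' rounded up to an integer pixel count).
#'
#' @param plant,blade logical masks, `blade` a subset of `plant`.
#' @param params a [seg_params()].
#' @return logical matrix.
#' @export
petiole_mask <- function(plant, blade, params = seg_params()) {
  assert_mask(plant); assert_mask(blade)
  if (any(blade & !plant)) stop("blade mask must be a subset of the plant mask")
  resid <- plant & !blade
  if (!any(resid)) return(resid)
  lab <- label_components_8(resid)
  k <- max(lab)
  areas <- tabulate(lab[lab > 0L], nbins = k)
  thr <- ceiling(params$min_component_fraction * length(plant))
  keep <- which(areas >= thr)
  matrix(lab %in% keep & lab > 0L, nrow(plant), ncol(plant))
}

#' Leaf-margin mask by internal gradient
#'
#' The difference between the blade mask and its erosion with a square
#' structuring element; with the default 7x7 kernel the band is 3 px wide on
#' straight edges.
#'
#' @param blade logical blade mask.
#' @param params a [seg_params()].
#' @return logical matrix, a subset of `blade`.
#' @export
margin_mask <- function(blade, params = seg_params()) {
  assert_mask(blade)
  if (!any(blade)) return(blade)
  eroded <- eb_to_mask(EBImage::erode(eb_binary(blade),
                                      box_kernel(params$margin_erosion_kernel)))
  blade & !eroded
}

binom_row <- function(k) choose(k - 1L, 0:(k - 1L))

#' Aperture-k Laplacian kernel
#'
#' Sum of the two second-derivative kernels of the extended (Sobel-style)
#' difference family: a second-difference row `[1, -2, 1]` convolved with a
#' binomial smoothing row, smoothed with a binomial row in the perpendicular
#' direction. Unnormalized, so response magnitudes grow with the aperture;
#' thresholds are specific to this dialect. Bright ridges (veins) yield
#' strongly negative responses.
#'
#' @param k odd aperture >= 3.
#' @return a k x k numeric matrix with zero sum.
#' @export
laplacian_kernel <- function(k) {
  k <- as.integer(k)
  if (k < 3L || k %% 2L == 0L) stop("Laplacian aperture must be odd and >= 3")
  s <- binom_row(k)
  d <- if (k == 3L) c(1, -2, 1) else
    as.numeric(stats::convolve(c(1, -2, 1), rev(binom_row(k - 2L)),
                               type = "open"))
  outer(d, s) + outer(s, d)
}

#' Second-derivative (Laplacian) response of a raster
#'
#' Filters the raster with the [laplacian_kernel()] of the configured
#' aperture; borders are handled by edge replication.
#'
#' @param raster intensity raster (typically the Compton scatter image).
#' @param params a [seg_params()].
#' @return real-valued matrix of the same dimensions.
#' @export
laplacian_response <- function(raster, params = seg_params()) {
  k <- params$laplacian_kernel
  if (k > min(dim(raster)))
    stop(sprintf("Laplacian aperture (%d) exceeds image size (%d x %d)",
                 k, nrow(raster), ncol(raster)))
  m <- matrix(as.numeric(raster), nrow(raster), ncol(raster))
  out <- EBImage::filter2(m, laplacian_kernel(k), boundary = "replicate")
  out <- matrix(as.numeric(out), nrow(raster), ncol(raster))
  # snap FFT round-off to exact zero so strict thresholds (e.g. "< 0") are
  # deterministic on flat regions
  out[abs(out) < 1e-6 * max(1, max(abs(m)))] <- 0
  out
}

#' Skeletonize a binary mask
#'
#' Topology-preserving (Zhang-Suen) thinning to a 1-px-wide, 8-connected
#' skeleton; the skeleton is always a subset of the input mask.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
skeletonize <- function(mask) {
  assert_mask(mask)
  thin_mask_cpp(mask)
}

#' Vein (vasculature) mask
#'
#' Thick primary/secondary vasculature is the Laplacian response below
#' `vein1_threshold`; thin tertiary vasculature is the skeleton of the
#' response below `vein2_threshold` (strictly, so a flat response detects
#' nothing). Their union is intersected with `blade \ margin` to exclude
#' detections on the leaf margin.
#'
#' @param compton Compton scatter raster.
#' @param blade,margin logical masks.
#' @param params a [seg_params()].
#' @return logical matrix, a subset of `blade \ margin`.
#' @export
vein_mask <- function(compton, blade, margin, params = seg_params()) {
  assert_mask(blade); assert_mask(margin)
  lap <- laplacian_response(compton, params)
  v1 <- lap < params$vein1_threshold
  v2 <- skeletonize(lap < params$vein2_threshold)
  (v1 | v2) & blade & !margin
}

#' Segment a scan bundle into substructure labels
#'
#' Composes the full pipeline: Otsu-union plant mask, opening-based blade /
#' petiole split with small-component cleaning, internal-gradient margin,
#' Laplacian vein detection, and tissue as the blade remainder. The output is
#' a partition: margin, vein and tissue are pairwise disjoint with union equal
#' to the blade; the petiole is disjoint from the blade; everything else is
#' background. Deterministic for fixed inputs and parameters.
#'
#' A plant whose blade mask is empty (too small for the opening kernel) is
#' still processed -- everything becomes petiole -- with a warning.
#'
#' @param bundle a [scan_bundle()].
#' @param params a [seg_params()].
#' @return a [seg_labels()] map with the parameters attached as attribute
#'   `params`.
#' @export
segment_bundle <- function(bundle, params = seg_params()) {
  stopifnot(inherits(bundle, "scan_bundle"), inherits(params, "seg_params"))
  plant <- plant_mask(bundle)
  blade <- blade_mask(plant, params)
  if (any(plant) && !any(blade))
    warning("empty blade mask: plant too small for the opening kernel; ",
            "all plant pixels classified as petiole")
  petiole <- petiole_mask(plant, blade, params)
  margin <- margin_mask(blade, params)
  vein <- vein_mask(bundle$rasters$Compton, blade, margin, params)
  tissue <- blade & !margin & !vein
  codes <- matrix(LABEL_CODES[["background"]], nrow(plant), ncol(plant))
  codes[petiole] <- LABEL_CODES[["petiole"]]
  codes[margin] <- LABEL_CODES[["margin"]]
  codes[vein] <- LABEL_CODES[["vein"]]
  codes[tissue] <- LABEL_CODES[["tissue"]]
  out <- seg_labels(codes)
  attr(out, "params") <- params
  out
}
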