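test_that("otsu_mask separates a two-valued raster and flags constant input", {
  r <- matrix(c(rep(10L, 50), rep(200L, 50)), 10L, 10L)
  m <- otsu_mask(r)
  expect_same_mask(m, r == 200L)

  expect_warning(m0 <- otsu_mask(matrix(42L, 8L, 8L)), "constant")
  expect_false(any(m0))
})

test_that("otsu threshold matches the exhaustive intra-class-variance search", {
  set.seed(11)
  for (i in 1:30) {
    v <- sample(0:255, 400, replace = TRUE)
    r <- matrix(v, 20L)
    obj <- vapply(0:255, function(t) {
      lo <- v[v <= t]; hi <- v[v > t]
      s <- 0
      if (length(lo) > 1) s <- s + sum((lo - mean(lo))^2)
      if (length(hi) > 1) s <- s + sum((hi - mean(hi))^2)
      s / length(v)
    }, numeric(1))
    expect_identical(as.integer(otsu_threshold(r)), which.min(obj) - 1L)
  }
  # independent implementation cross-check (bin-centre convention differs by <= 1)
  v <- sample(0:255, 2500, replace = TRUE)
  t_eb <- EBImage::otsu(EBImage::Image(matrix(v, 50L) / 255),
                        range = c(0, 1), levels = 256) * 255
  expect_lt(abs(as.integer(otsu_threshold(matrix(v, 50L))) - t_eb), 1.5)
})

test_that("plant_mask is the union of the four metal masks", {
  pl <- fixture_plant(seed = 2L)
  b <- pl$bundle
  pm <- plant_mask(b)
  for (el in XRF_ELEMENTS)
    expect_true(all(pm[otsu_mask(b$rasters[[el]])]))

  # four identical rasters: union is the single-element mask
  r <- matrix(c(rep(5L, 60), rep(150L, 40)), 10L)
  b2 <- bundle_from_rasters(r)
  expect_same_mask(plant_mask(b2), otsu_mask(r))
})

test_that("opening keeps blades, removes strips, and is idempotent", {
  plant <- matrix(FALSE, 80L, 80L)
  plant[11:60, 11:60] <- TRUE   # 50x50 blade
  plant[30:34, 61:75] <- TRUE   # 5-px-wide strip
  blade <- blade_mask(plant)
  expect_same_mask(blade, {
    sq <- matrix(FALSE, 80L, 80L); sq[11:60, 11:60] <- TRUE; sq
  })

  # a blob entirely narrower than the kernel vanishes
  thin <- matrix(FALSE, 40L, 40L); thin[10:12, 5:35] <- TRUE
  expect_false(any(blade_mask(thin)))

  # idempotence on a real fixture
  pm <- plant_mask(fixture_plant(seed = 4L)$bundle)
  once <- blade_mask(pm)
  expect_same_mask(blade_mask(once), once)
})

test_that("petiole_mask drops components below the image-area fraction", {
  # 1000 x 1000 image: threshold is ceiling(1e-5 * 1e6) = 10 px
  plant <- matrix(FALSE, 1000L, 1000L)
  plant[1:30, 1:30] <- TRUE            # stands in for the blade
  blade <- plant
  plant[500, 100:104] <- TRUE          # 5-px residual: dropped
  plant[600, 200:209] <- TRUE          # 10-px residual: kept
  pet <- petiole_mask(plant, blade)
  expect_equal(sum(pet), 10L)
  expect_true(all(which(pet) %in% which(plant & !blade)))

  # plant == blade gives an empty petiole
  expect_false(any(petiole_mask(blade, blade)))
  expect_error(petiole_mask(blade, plant), "subset")
})

test_that("margin band has the contracted width", {
  blade <- matrix(FALSE, 40L, 40L)
  blade[11:30, 11:30] <- TRUE
  m <- margin_mask(blade)
  expect_equal(sum(m), 20L^2 - 14L^2)   # 204: 3-px band each side
  expect_true(all(blade[m]))            # anti-extensive
  expect_same_mask(m[14:27, 11:13], matrix(TRUE, 14L, 3L))  # width 3 on an edge

  expect_false(any(margin_mask(matrix(FALSE, 10L, 10L))))

  thin <- matrix(FALSE, 20L, 20L); thin[9:13, 3:18] <- TRUE  # 5 px < kernel 7
  expect_same_mask(margin_mask(thin), thin)
})

test_that("laplacian response behaves like a second derivative", {
  expect_equal(sum(laplacian_kernel(7L)), 0)
  expect_equal(laplacian_kernel(3L),
               outer(c(1, -2, 1), c(1, 2, 1)) + outer(c(1, 2, 1), c(1, -2, 1)))

  # constant image: zero (up to FFT round-off in the convolution)
  expect_true(all(abs(laplacian_response(matrix(9, 30L, 30L))) < 1e-6))

  # linear ramp: zero away from the replicated borders
  ramp <- matrix(rep(1:30, each = 30), 30L)
  lap <- laplacian_response(ramp)
  expect_true(all(abs(lap[7:24, 7:24]) < 1e-8))

  # bright ridge: most negative response on the crest
  ridge <- matrix(10, 31L, 31L); ridge[15:17, ] <- 200
  lap <- laplacian_response(ridge)
  expect_true(all(which(lap == min(lap), arr.ind = TRUE)[, 1L] %in% 15:17))
  expect_lt(min(lap), -2500)

  expect_error(laplacian_response(matrix(1, 5L, 5L)), "exceeds image size")
})

test_that("skeletonization thins to 1-px subsets and preserves thin lines", {
  line <- matrix(FALSE, 20L, 20L); line[10, 3:18] <- TRUE
  expect_same_mask(skeletonize(line), line)

  bar <- matrix(FALSE, 15L, 60L); bar[6:10, 6:55] <- TRUE
  sk <- skeletonize(bar)
  expect_true(all(bar[sk]))                       # subset of the input
  expect_true(all(colSums(sk[, 10:50]) <= 1))     # 1 px wide along the bar
  expect_gt(sum(sk), 40L)                         # spans most of the length

  expect_false(any(skeletonize(matrix(FALSE, 5L, 5L))))
})

test_that("vein mask is empty on flat input and confined to blade minus margin", {
  flat <- matrix(100, 40L, 40L)
  blade <- matrix(TRUE, 40L, 40L)
  margin <- matrix(FALSE, 40L, 40L)
  expect_false(any(vein_mask(flat, blade, margin)))

  pl <- fixture_plant(seed = 5L)
  b <- pl$bundle
  pm <- plant_mask(b); bl <- blade_mask(pm); mg <- margin_mask(bl)
  vn <- vein_mask(b$rasters$Compton, bl, mg)
  expect_true(all((bl & !mg)[vn]))
})

test_that("segment_bundle yields an exact partition, deterministically", {
  pl <- fixture_plant(seed = 6L)
  lab <- segment_bundle(pl$bundle)
  mk <- label_masks(lab)
  pm <- plant_mask(pl$bundle)
  bl <- blade_mask(pm)

  expect_same_mask(mk$margin | mk$vein | mk$tissue, bl)
  expect_false(any(mk$margin & mk$vein))
  expect_false(any(mk$margin & mk$tissue))
  expect_false(any(mk$vein & mk$tissue))
  expect_false(any(mk$petiole & bl))
  expect_true(all(pm[mk$plant]))

  expect_identical(unclass(segment_bundle(pl$bundle))[, ],
                   unclass(lab)[, ])  # pure function, bit-for-bit

  # one constant-raster warning per element raster
  suppressWarnings(
    expect_warning(lab0 <- segment_bundle(constant_bundle(0)), "constant"))
  expect_true(all(lab0 == 0L))
})

test_that("tiny plants collapse to petiole with a warning", {
  r <- matrix(5L, 48L, 48L)
  r[20:27, 20:27] <- 180L   # 8x8 plant, narrower than the opening kernel
  b <- bundle_from_rasters(r)
  expect_warning(lab <- segment_bundle(b), "petiole")
  expect_true(all(unclass(lab)[r == 180L] == LABEL_CODES[["petiole"]]))
})

test_that("petiole area never decreases with the opening kernel", {
  pm <- plant_mask(fixture_plant(seed = 7L)$bundle)
  areas <- vapply(c(7L, 11L, 15L, 19L, 23L), function(k) {
    p <- seg_params(opening_kernel = k)
    sum(petiole_mask(pm, blade_mask(pm, p), p))
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
})
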