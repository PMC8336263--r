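test_that("random substructures stay inside the plant with bounded area", {
  pl <- fixture_plant(seed = 12L)
  plant <- unclass(pl$truth$labels) != 0L
  for (seed in 1:5) {
    m <- random_substructure(plant, n_squares = 5L, square_side = 30L,
                             seed = seed)
    expect_true(all(plant[m]))
    expect_lte(sum(m), 5L * 30L^2)
    expect_gt(sum(m), 0L)
  }
  expect_identical(random_substructure(plant, seed = 42L),
                   random_substructure(plant, seed = 42L))

  tiny <- matrix(FALSE, 20L, 20L); tiny[8:9, 8:12] <- TRUE  # 10 px plant
  expect_warning(m <- random_substructure(tiny, seed = 1L), "smaller than")
  expect_true(all(tiny[m]))
})

test_that("label-noise injection reassigns the right number of plant pixels", {
  pl <- fixture_plant(seed = 13L)
  lab <- pl$truth$labels
  n_plant <- sum(lab != 0L)

  expect_identical(unclass(inject_label_noise(lab, 0, seed = 1L))[, ],
                   unclass(lab)[, ])
  expect_error(inject_label_noise(lab, 1.2, 1L), "fraction")

  for (f in c(0.1, 0.5)) {
    noisy <- inject_label_noise(lab, f, seed = 2L)
    expect_equal(sum(noisy != 0L), n_plant)            # background untouched
    changed <- sum(noisy != lab)
    n_drawn <- ceiling(f * n_plant)
    expect_lte(changed, n_drawn)
    # the redraw repeats the original class 1/4 of the time
    expect_equal(changed / n_drawn, 0.75, tolerance = 0.08)
  }

  # full noise: classes uniform over the plant within binomial tolerance
  full <- inject_label_noise(lab, 1, seed = 3L)
  counts <- vapply(1:4, function(k) sum(full == k), numeric(1))
  expect_equal(counts / n_plant, rep(0.25, 4L), tolerance = 0.05)
})

test_that("default sweep grids reproduce the published ranges", {
  p <- seg_params()
  expect_equal(default_sweep_grid("opening_kernel", p), seq(7, 23, by = 4))
  expect_equal(default_sweep_grid("laplacian_kernel", p), seq(3, 11, by = 2))
  expect_equal(default_sweep_grid("vein1_threshold", p),
               seq(-3500, -1500, by = 500))
  expect_equal(default_sweep_grid("vein2_threshold", p), seq(-200, 200, by = 100))
})

test_that("sensitivity sweep re-evaluates fixed coordinates per grid value", {
  pl <- fixture_plant(seed = 14L)
  truth <- ground_truth_from_labels(pl$truth$labels)

  # a one-value grid equals a direct evaluation
  lab <- segment_bundle(pl$bundle)
  direct <- evaluate_labels(lab, truth)
  one <- sensitivity_sweep(pl$bundle, truth, "opening_kernel", grid = 15L)
  expect_equal(one$f1, direct$f1)
  expect_true(all(one$base))

  # full default sweep: 5 values x 4 classes, base flagged once per class
  sw <- sensitivity_sweep(pl$bundle, truth, "laplacian_kernel")
  expect_equal(nrow(sw), 20L)
  expect_equal(sum(sw$base), 4L)
  expect_true(all(c("precision", "recall", "f1") %in% names(sw)))
})

test_that("noise curve at fraction zero reproduces the clean report", {
  panel <- generate_panel(panel_spec(n_accessions = 6L, seed = 15L))
  curve <- noise_robustness_curve(panel, fractions = c(0, 0.2), seed = 8L,
                                  labels = "truth")
  clean <- curve[curve$fraction == 0, ]
  tt <- panel_trait_table(panel, labels = "truth", random_cq = FALSE)
  rep <- heritability_report(tt, traits = grep("^cq_", names(tt), value = TRUE))
  expect_equal(clean$H2[match(rep$trait, clean$trait)], rep$H2)

  # deterministic under seed
  curve2 <- noise_robustness_curve(panel, fractions = c(0, 0.2), seed = 8L,
                                   labels = "truth")
  expect_identical(curve, curve2)

  noisy <- curve[curve$fraction == 0.2, ]
  expect_true(all(is.finite(noisy$H2)))
})

test_that("full label noise drives the substructure CQs into one another", {
  # dominant-class argument: at fraction 1 every noisy class is a uniform
  # sample of plant pixels, so the four CQ traits collapse onto each other
  pl <- fixture_plant(seed = 16L)
  lab <- pl$truth$labels
  full <- inject_label_noise(lab, 1, seed = 9L)
  cq_clean <- cq_traits(pl$bundle, lab)
  cq_full <- cq_traits(pl$bundle, full)
  for (el in XRF_ELEMENTS) {
    nm <- sprintf("cq_%s_%s", el, SUBSTRUCTURES)
    expect_gt(diff(range(cq_clean[nm])), 0.3)   # distinct when clean
    expect_lt(diff(range(cq_full[nm])), 0.05)   # collapsed under full noise
    expect_equal(unname(cq_full[nm]), rep(1, 4L), tolerance = 0.05)
  }
})
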