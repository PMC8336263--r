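test_that("concentration quotient matches hand arithmetic and its contracts", {
  plant <- matrix(FALSE, 5L, 5L); plant[1:2, 1:5] <- TRUE  # 10 px
  sub <- matrix(FALSE, 5L, 5L); sub[1, 1:2] <- TRUE        # 2 px
  r <- matrix(0, 5L, 5L); r[plant] <- 1; r[sub] <- 4
  # substructure mean 4, plant mean (2*4 + 8*1)/10 = 1.6
  expect_equal(concentration_quotient(r, sub, plant), 2.5)
  expect_equal(concentration_quotient(r * 10, sub, plant), 2.5)  # scale-free

  expect_equal(concentration_quotient(matrix(7, 5L, 5L), sub, plant), 1)

  empty <- matrix(FALSE, 5L, 5L)
  expect_warning(cq <- concentration_quotient(r, empty, plant), "empty")
  expect_true(is.na(cq))
  expect_error(concentration_quotient(r, plant, sub), "subset")
  expect_error(concentration_quotient(matrix(0, 5L, 5L), sub, plant), "zero")
})

test_that("CQ conservation: area-weighted mean over substructures is exactly 1", {
  pl <- fixture_plant(seed = 8L)
  lab <- segment_bundle(pl$bundle)
  mk <- label_masks(lab)
  for (el in XRF_ELEMENTS) {
    r <- pl$bundle$rasters[[el]]
    cq <- vapply(SUBSTRUCTURES, function(cl)
      concentration_quotient(r, mk[[cl]], mk$plant), numeric(1))
    ns <- vapply(SUBSTRUCTURES, function(cl) sum(mk[[cl]]), numeric(1))
    expect_equal(sum(cq * ns) / sum(ns), 1, tolerance = 1e-12)
  }
})

test_that("colocalization behaves like a Pearson correlation", {
  pl <- fixture_plant(seed = 9L, spec = panel_spec(noise_sd = 5))
  plant <- unclass(pl$truth$labels) != 0L
  r <- pl$bundle$rasters$Zn
  expect_equal(colocalization(r, r, plant), 1)
  expect_equal(colocalization(r, 300 - r, plant), -1)
  expect_equal(colocalization(r, 2 * r + 7, plant), 1)     # affine-invariant
  expect_equal(colocalization(r, pl$bundle$rasters$Ni, plant),
               colocalization(pl$bundle$rasters$Ni, r, plant))  # symmetric

  # independent noise rasters decorrelate at n = 1e4
  withr::with_seed(5L, {
    a <- matrix(abs(rnorm(1e4, 100, 10)), 100L)
    b <- matrix(abs(rnorm(1e4, 100, 10)), 100L)
  })
  expect_lt(abs(colocalization(a, b, matrix(TRUE, 100L, 100L))), 0.05)

  expect_warning(r0 <- colocalization(matrix(3, 10L, 10L), a[1:10, 1:10],
                                      matrix(TRUE, 10L, 10L)), "zero variance")
  expect_true(is.na(r0))
})

test_that("substructure z-scores match scalar arithmetic", {
  lab <- tiny_labels()
  r <- matrix(0, 6L, 6L)
  vals <- c(4, 4, 8, 8, 2, 2, 6, 6, 6, 6)  # petiole, margin, vein, 4x tissue
  r[1, 1:2] <- vals[1:2]; r[2, 1:2] <- vals[3:4]; r[3, 1:2] <- vals[5:6]
  r[4, 1:2] <- vals[7:8]; r[5, 1:2] <- vals[9:10]
  z <- zscore_substructure_means(r, lab)
  mp <- mean(vals); sp <- sd(vals)
  expect_equal(unname(z), c((4 - mp) / sp, (8 - mp) / sp,
                            (2 - mp) / sp, (6 - mp) / sp))

  expect_warning(z0 <- zscore_substructure_means(matrix(5, 6L, 6L), lab),
                 "zero plant standard deviation")
  expect_true(all(is.na(z0)))

  # a substructure at the plant mean scores 0
  r2 <- r; r2[1, 1:2] <- mp  # within-class constant, equal to overall mean?
  z2 <- zscore_substructure_means(r2, lab)
  expect_equal(unname(z2["petiole"]),
               (mp - mean(r2[unclass(lab) != 0])) / sd(r2[unclass(lab) != 0]))
})

test_that("ground-truth sampling is blind, capped and reproducible", {
  pl <- fixture_plant(seed = 10L)
  lab <- pl$truth$labels
  s1 <- sample_ground_truth_pixels(lab, n_per_class = 50L, seed = 3L)
  expect_equal(nrow(s1), 200L)
  expect_true(all(is.na(s1$true_class)))
  # records really carry their predicted class
  looked <- names(LABEL_CODES)[unclass(lab)[cbind(s1$row, s1$col)] + 1L]
  expect_identical(looked, s1$predicted_class)
  # shuffled output: classes are not grouped in blocks
  expect_gt(length(rle(s1$predicted_class)$lengths), 50L)
  # reproducible
  expect_identical(s1, sample_ground_truth_pixels(lab, 50L, seed = 3L))
  expect_false(identical(s1, sample_ground_truth_pixels(lab, 50L, seed = 4L)))

  # a scarce class yields all its pixels plus a warning (one per scarce class)
  suppressWarnings(
    expect_warning(s2 <- sample_ground_truth_pixels(lab, 10000L, seed = 1L),
                   "all taken"))
  expect_equal(nrow(s2), sum(lab != 0L))

  # an absent class is skipped with a warning
  m <- matrix(0L, 8L, 8L); m[1, ] <- 1L; m[2, ] <- 2L; m[3, ] <- 4L
  expect_warning(s3 <- sample_ground_truth_pixels(seg_labels(m), 5L, seed = 1L),
                 "vein")
  expect_setequal(unique(s3$predicted_class), c("petiole", "margin", "tissue"))
})

test_that("confusion matrix counts truth rows against prediction columns", {
  s <- data.frame(row = 1:3, col = 1:3,
                  predicted_class = c("petiole", "petiole", "vein"),
                  true_class = c("petiole", "margin", "vein"))
  m <- confusion_matrix(s)
  expect_equal(sum(m), 3L)
  expect_equal(m["petiole", "petiole"], 1L)
  expect_equal(m["margin", "petiole"], 1L)
  expect_equal(m["vein", "vein"], 1L)

  s$true_class[2] <- NA
  expect_error(confusion_matrix(s), "blank true_class")
})

test_that("precision/recall/F1 match a naive counting oracle", {
  withr::with_seed(7L, {
    for (i in 1:5) {
      m <- matrix(sample(0:40, 16L, replace = TRUE), 4L,
                  dimnames = list(SUBSTRUCTURES, SUBSTRUCTURES))
      got <- precision_recall_f1(m)
      # naive oracle: expand to records and recount per class
      recs <- do.call(rbind, lapply(seq_len(16L), function(k) {
        r <- (k - 1L) %% 4L + 1L; c <- (k - 1L) %/% 4L + 1L
        if (m[r, c] == 0L) return(NULL)
        data.frame(truth = SUBSTRUCTURES[r], pred = SUBSTRUCTURES[c],
                   n = m[r, c])
      }))
      for (cl in SUBSTRUCTURES) {
        tp <- sum(recs$n[recs$truth == cl & recs$pred == cl])
        p_or <- tp / sum(recs$n[recs$pred == cl])
        r_or <- tp / sum(recs$n[recs$truth == cl])
        expect_equal(got$precision[got$class == cl], p_or)
        expect_equal(got$recall[got$class == cl], r_or)
      }
    }
  })

  d <- diag(4L); dimnames(d) <- list(SUBSTRUCTURES, SUBSTRUCTURES)
  perfect <- precision_recall_f1(d)
  expect_true(all(perfect$precision == 1 & perfect$recall == 1 &
                    perfect$f1 == 1))
})

test_that("F1 is the harmonic mean: bounded by P and R, equal iff P == R", {
  withr::with_seed(21L, {
    p <- runif(50, 0.05, 1); r <- runif(50, 0.05, 1)
    f <- f1_score(p, r)
    expect_true(all(f >= pmin(p, r) - 1e-12 & f <= pmax(p, r) + 1e-12))
    expect_equal(f1_score(p, p), p)
    expect_true(all(f[abs(p - r) > 1e-3] < pmax(p, r)[abs(p - r) > 1e-3]))
  })
})

test_that("plant_traits assembles the 16 CQs and flags empty plants", {
  pl <- fixture_plant(seed = 11L)
  row <- plant_traits(pl$bundle, pl$truth$labels)
  expect_equal(row$plant_size, pl$truth$plant_area)
  expect_equal(unname(unlist(row[sprintf("relsize_%s", SUBSTRUCTURES)])),
               unname(pl$truth$areas / pl$truth$plant_area))
  # noiseless rendering: CQ from the image equals the generator bookkeeping
  for (el in XRF_ELEMENTS)
    for (cl in SUBSTRUCTURES)
      expect_equal(row[[sprintf("cq_%s_%s", el, cl)]],
                   pl$truth$cq[cl, el], tolerance = 1e-12)

  expect_warning(
    empty_row <- plant_traits(pl$bundle, seg_labels(matrix(0L, 256L, 256L))),
    "all-background")
  expect_true(all(is.na(unlist(empty_row[cq_names <- sprintf("cq_Zn_%s", SUBSTRUCTURES)]))))
})
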