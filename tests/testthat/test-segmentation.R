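test_that("max projection equals the elementwise loop oracle", {
  one <- shg_stack(matrix(1:12, 3, 4), 1)
  expect_equal(max_project(one)$pixels, matrix(1:12, 3, 4))

  two <- shg_stack(array(c(1, 5, 3, 2), dim = c(1, 2, 2)), 1)
  expect_equal(max_project(two)$pixels, matrix(c(3, 5), 1, 2))

  vox <- withr::with_seed(3, array(stats::runif(4 * 4 * 3), c(4, 4, 3)))
  got <- max_project(shg_stack(vox, 1))$pixels
  want <- matrix(0, 4, 4)
  for (r in 1:4) {
    for (c in 1:4) {
      want[r, c] <- max(vox[r, c, ])
    }
  }
  expect_equal(got, want)
})

test_that("feature bank behaves on constant, near-raw, and edge images", {
  const <- compute_features(matrix(7, 8, 8), scales = c(1, 2))
  expect_true(all(const[, , "smooth_s1"] == 7))
  expect_true(all(const[, , "grad_s1"] == 0))
  expect_true(all(abs(const[, , "var_s2"]) < 1e-9))

  img <- withr::with_seed(4, matrix(stats::runif(64, 0, 10), 8, 8))
  tiny <- compute_features(img, scales = 0.05)
  expect_lt(max(abs(tiny[, , 2] - img)), 1e-6)  # sigma -> 0 approaches raw

  step <- cbind(matrix(0, 10, 5), matrix(10, 10, 5))
  f <- compute_features(step, scales = 1)
  grad_by_col <- colMeans(f[, , "grad_s1"])
  expect_true(which.max(grad_by_col) %in% c(5L, 6L))
})

test_that("hysteresis matches its definition on hand cases", {
  all_high <- matrix(0.95, 4, 4)
  expect_true(all(hysteresis_segment(all_high, 0.5, 0.8)))
  no_seed <- matrix(0.7, 4, 4)
  expect_false(any(hysteresis_segment(no_seed, 0.5, 0.8)))
  row <- matrix(c(0.9, 0.6, 0.4, 0.6, 0.9), 1, 5)
  expect_equal(as.vector(hysteresis_segment(row, 0.5, 0.8)),
               c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_error(hysteresis_segment(row, 0.9, 0.2))
})

test_that("hysteresis equals the flood-fill oracle and obeys the sandwich", {
  withr::with_seed(21, {
    for (case in 1:25) {
      probs <- rand_prob_map(24, 24)
      low <- stats::runif(1, 0.2, 0.6)
      high <- stats::runif(1, low, 0.9)
      got <- hysteresis_segment(probs, low, high)
      expect_identical(got, hysteresis_oracle(probs, low, high))
      expect_true(all(got[probs > high]))          # seeds included
      expect_true(all(probs[got] > low))           # inside low superset
      comp <- label_components(got, 8)
      if (max(comp) > 0) {
        for (k in seq_len(max(comp))) {
          expect_true(any(probs[comp == k] > high))  # every component seeded
        }
      }
    }
  })
})

test_that("postprocessing fills holes, filters by area, flags borders", {
  px <- 1
  # 17x17 = 289 um^2 discarded; 18x18 = 324 um^2 kept
  m <- matrix(FALSE, 60, 60)
  m[2:18, 2:18] <- TRUE
  m[30:47, 30:47] <- TRUE
  map <- postprocess_labels(m, px, min_area_um2 = 300)
  expect_equal(n_labels(map), 1L)
  expect_equal(sum(map$labels > 0), 18L * 18L)

  # ring: 20x20 outer with 10x10 hole -> filled to 400 um^2
  ring <- matrix(FALSE, 30, 30)
  ring[5:24, 5:24] <- TRUE
  ring[10:19, 10:19] <- FALSE
  filled <- postprocess_labels(ring, px)
  expect_equal(n_labels(filled), 1L)
  expect_equal(sum(filled$labels == 1L), 400L)

  # border flag for an object in row 1
  edge <- matrix(FALSE, 40, 40)
  edge[1:18, 5:22] <- TRUE
  expect_true(postprocess_labels(edge, px)$border_flags[1])

  # labels ordered by descending area
  duo <- matrix(FALSE, 60, 60)
  duo[2:19, 2:19] <- TRUE      # 324
  duo[30:52, 30:52] <- TRUE    # 529
  lab <- postprocess_labels(duo, px)
  expect_equal(sum(lab$labels == 1L), 529L)
  expect_equal(sum(lab$labels == 2L), 324L)
})

test_that("postprocessing is idempotent", {
  withr::with_seed(31, {
    for (case in 1:5) {
      m <- rand_prob_map(40, 40) > 0.6
      map <- postprocess_labels(m, 1, min_area_um2 = 4)
      again <- postprocess_labels(map$labels > 0, 1, min_area_um2 = 4)
      expect_identical(again$labels, map$labels)
    }
  })
})

test_that("classifier separates separable features and respects the formula", {
  # separable: two intensity blocks
  img <- image2d(cbind(matrix(10, 20, 10), matrix(200, 20, 10)), 1)
  mask <- cbind(matrix(1L, 20, 10), matrix(2L, 20, 10))
  cl <- train_pixel_classifier(list(img), list(mask), n_stages = 1)
  p <- predict_probability(cl, img)
  expect_true(all(p$probs[, 1:10] > 0.5))
  expect_true(all(p$probs[, 11:20] < 0.5))

  # zero-weight classifier -> sigmoid(0) = 0.5 everywhere
  cl0 <- cl
  cl0$stages[[1]]$coef[] <- 0
  expect_true(all(predict_probability(cl0, img)$probs == 0.5))

  # linear-predictor formula oracle on a random small image
  rimg <- withr::with_seed(8, image2d(matrix(stats::runif(64, 0, 255), 8), 1))
  feats <- compute_features(rimg, cl$scales)
  st <- cl$stages[[1]]
  want <- matrix(0, 8, 8)
  for (r in 1:8) {
    for (c in 1:8) {
      x <- (feats[r, c, ] - st$center) / st$scale
      want[r, c] <- stats::plogis(st$coef[1] + sum(st$coef[-1] * x))
    }
  }
  expect_equal(predict_probability(cl, rimg)$probs, want, tolerance = 1e-9)

  # degenerate label sets are rejected
  expect_error(train_pixel_classifier(list(img), list(matrix(0L, 20, 20))),
               "empty")
  one_class <- matrix(0L, 20, 20)
  one_class[1:5, 1:5] <- 1L
  expect_error(train_pixel_classifier(list(img), list(one_class)),
               "one class")
  expect_error(predict_probability(cl, image2d(matrix(1, 4, 4), 1)), NA)
})

test_that("held-out accuracy is high and autocontext does not hurt", {
  mo <- generate_mosaic(mosaic_spec(image_shape = c(128L, 128L),
                                    pixel_size_um = 1, n_crypts = 10,
                                    crypt_radius_mean_um = 9,
                                    crypt_radius_sd_um = 1,
                                    crypt_radius_min_um = 7,
                                    min_gap_um = 5, wall_thickness_um = 4,
                                    noise_sd = 10, seed = 41L))
  gt <- mo$truth$label_map$labels
  mask <- withr::with_seed(42, sparse_labels_from_gt(gt, 1500L, 3000L))
  acc <- function(cl) {
    pr <- predict_probability(cl, mo$image)$probs
    held <- mask == 0L
    mean((pr[held] > 0.5) == (gt[held] > 0L))
  }
  cl1 <- train_pixel_classifier(list(mo$image), list(mask), n_stages = 1)
  cl2 <- train_pixel_classifier(list(mo$image), list(mask), n_stages = 2)
  expect_gte(acc(cl1), 0.95)
  expect_gte(acc(cl2), acc(cl1) - 0.005)
  # complementary classes: crypt prob + collagen prob = 1 by construction
  pr <- predict_probability(cl2, mo$image)$probs
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("full pipeline recovers interior crypts on noise-free mosaics", {
  mo <- generate_mosaic(mosaic_spec(image_shape = c(160L, 160L),
                                    pixel_size_um = 1, n_crypts = 12,
                                    crypt_radius_mean_um = 10,
                                    crypt_radius_sd_um = 1,
                                    crypt_radius_min_um = 10,
                                    min_gap_um = 6, wall_thickness_um = 4,
                                    noise_sd = 0,
                                    fiber_texture_amplitude = 0,
                                    seed = 51L))
  gt <- mo$truth$label_map
  mask <- withr::with_seed(52, sparse_labels_from_gt(gt$labels))
  cl <- train_pixel_classifier(list(mo$image), list(mask), n_stages = 2)
  seg <- segment_crypts(mo$image, classifier = cl)
  expect_equal(sum(!seg$border_flags), sum(!gt$border_flags))
  interior <- which(!gt$border_flags)
  ious <- iou_per_label(gt$labels, seg$labels)[interior]
  expect_true(all(ious >= 0.95))
})
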