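test_that("boundary pixels match the definition and the brute-force scan", {
  single <- matrix(0L, 5, 5)
  single[3, 3] <- 1L
  expect_equal(unname(boundary_pixels(crypt_label_map(single, 1), 1)),
               cbind(3L, 3L))

  solid <- matrix(0L, 7, 7)
  solid[3:5, 3:5] <- 1L
  b <- boundary_pixels(crypt_label_map(solid, 1), 1)
  expect_equal(nrow(b), 8L)  # 3x3 square: all but the center pixel
  expect_false(any(b[, 1] == 4 & b[, 2] == 4))

  expect_error(boundary_pixels(crypt_label_map(solid, 1), 9), "unknown label")

  withr::with_seed(61, {
    for (case in 1:5) {
      map <- rand_label_map(32, 32, 4)
      for (lab in seq_len(n_labels(map))) {
        got <- boundary_pixels(map, lab)
        px <- which(map$labels == lab, arr.ind = TRUE)
        want <- px[apply(px, 1, function(p) {
          any(vapply(1:8, function(o) {
            d <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                       c(0, 1), c(1, -1), c(1, 0), c(1, 1))[o, ]
            r <- p[1] + d[1]
            c <- p[2] + d[2]
            r < 1 || r > 32 || c < 1 || c > 32 || map$labels[r, c] == 0L
          }, logical(1)))
        }), , drop = FALSE]
        expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                     unname(want[order(want[, 1], want[, 2]), , drop = FALSE]),
                     ignore_attr = TRUE)
      }
    }
  })
})

test_that("pairwise distances: hand cases, symmetry, and the 2px lower bound", {
  two <- matrix(0L, 3, 6)
  two[2, 2] <- 1L
  two[2, 5] <- 2L
  d <- pairwise_border_distances(crypt_label_map(two, 1), radius_um = 40)
  expect_equal(nrow(d), 1L)
  expect_equal(d$distance_um, 3)

  lone <- matrix(0L, 8, 8)
  lone[3:5, 3:5] <- 1L
  expect_equal(nrow(pairwise_border_distances(crypt_label_map(lone, 1), 40)),
               0L)

  withr::with_seed(62, {
    for (case in 1:10) {
      map <- rand_label_map(48, 48, 5, pixel_size_um = 0.75)
      d <- pairwise_border_distances(map, radius_um = 60)
      expect_true(all(d$i < d$j))
      expect_true(all(d$distance_um >= 2 * map$pixel_size_um))
    }
  })
})

test_that("fast distances equal the exhaustive oracle on random maps", {
  withr::with_seed(63, {
    for (case in 1:25) {
      map <- rand_label_map(sample(24:64, 1), sample(24:64, 1),
                            sample(1:6, 1),
                            pixel_size_um = sample(c(0.5, 1), 1))
      expect_tables_equal(crypt_metrics(map), gt_metrics(map))
    }
  })
})

test_that("nearest-crypt and neighbor rules use the stated radii", {
  # pairwise {A-B: 10, A-C: 30, B-C: 15} built from three 1-px crypts is
  # awkward; drive the query functions directly on a synthetic table
  d <- tibble::tibble(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                      distance_um = c(10, 30, 15))
  attr(d, "radius_um") <- 40
  attr(d, "n_labels") <- 3L
  class(d) <- c("pairwise_distances", class(d))
  nn <- nearest_crypt_distance(d, 1L)
  expect_equal(nn$distance_um, 10)
  expect_equal(nn$partner, 2L)

  # nearest at 45 um with 40 um search radius -> undefined, excluded
  d2 <- tibble::tibble(i = 1L, j = 2L, distance_um = 45)
  attr(d2, "radius_um") <- 60
  attr(d2, "n_labels") <- 2L
  class(d2) <- c("pairwise_distances", class(d2))
  expect_true(is.na(nearest_crypt_distance(d2, 1L, 40)$distance_um))
  expect_equal(nearest_crypt_distance(d2, 1L, 60)$distance_um, 45)

  # neighbor count at 20 um is inclusive: {10, 19, 21} -> 2; {20} counts
  d3 <- tibble::tibble(i = c(1L, 1L, 1L, 2L), j = c(2L, 3L, 4L, 3L),
                       distance_um = c(10, 19, 21, 20))
  attr(d3, "radius_um") <- 40
  attr(d3, "n_labels") <- 4L
  class(d3) <- c("pairwise_distances", class(d3))
  expect_equal(neighbor_count(d3, 1L), 2L)
  expect_equal(neighbor_count(d3, 2L, 20), 2L)  # the 20 um pair is included
  expect_equal(neighbor_count(d3, 4L, 20), 0L)  # isolated at this radius

  # querying beyond the computed radius is refused
  expect_error(nearest_crypt_distance(d3, 1L, 80), "smaller radius")
})

test_that("image summaries exclude border crypts but keep them as partners", {
  tab <- tibble::tibble(
    label = 1:4, area_um2 = c(400, 500, 600, 1000),
    centroid_row = 1:4, centroid_col = 1:4,
    is_border = c(FALSE, FALSE, FALSE, TRUE),
    nn_distance_um = c(12, NA, 20, 5), nn_label = c(2L, NA, 4L, 3L),
    neighbor_count = c(1L, 0L, 2L, 1L))
  s <- summarize_image(tab)
  expect_equal(s$n_interior, 3L)
  expect_equal(s$mean_area_um2, 500)
  expect_equal(s$mean_nn_distance_um, 16)  # over the two defined interior
  expect_equal(s$n_nn_defined, 2L)
  expect_equal(s$n_border, 1L)
  expect_equal(s$n_interior + s$n_border, nrow(tab))

  empty <- summarize_image(gt_metrics(crypt_label_map(matrix(0L, 5, 5), 1)))
  expect_equal(empty$n_interior, 0L)
  expect_true(is.na(empty$mean_area_um2))
})

test_that("a border crypt still serves as nearest partner of interior ones", {
  m <- matrix(0L, 10, 14)
  m[4:7, 4:7] <- 1L   # interior
  m[1:2, 9:12] <- 2L  # touches row 1 -> border
  tab <- crypt_metrics(crypt_label_map(m, 1))
  expect_true(tab$is_border[2])
  expect_equal(tab$nn_label[1], 2L)
  expect_false(is.na(tab$nn_distance_um[1]))
})

test_that("metrics are invariant under translation away from edges", {
  withr::with_seed(64, {
    base <- rand_label_map(30, 30, 4)
    big <- matrix(0L, 45, 45)
    big[1:30, 1:30] <- base$labels
    base45 <- crypt_label_map(big, base$pixel_size_um)
    moved <- matrix(0L, 45, 45)
    moved[7:36, 10:39] <- base$labels
    shifted <- crypt_label_map(moved, base$pixel_size_um)
    t1 <- crypt_metrics(base45)
    t2 <- crypt_metrics(shifted)
    expect_equal(t1$nn_distance_um, t2$nn_distance_um)
    expect_equal(t1$neighbor_count, t2$neighbor_count)
    expect_equal(t1$area_um2, t2$area_um2)
    expect_equal(t2$centroid_row - t1$centroid_row, rep(6, nrow(t1)))
  })
})

test_that("heatmaps map values monotonically with reserved neutral colors", {
  m <- matrix(0L, 12, 20)
  m[3:5, 3:5] <- 1L
  m[8:10, 3:5] <- 2L
  m[3:5, 10:12] <- 3L
  m[1:2, 16:19] <- 4L  # border crypt
  map <- crypt_label_map(m, 1)

  hm_eq <- render_heatmap(map, c(5, 5, 5, 5))
  interior_cols <- hm_eq$table$color[!hm_eq$table$is_border]
  expect_equal(length(unique(interior_cols)), 1L)

  hm <- render_heatmap(map, c(0, 1, 0.5, NA))
  pal <- grDevices::hcl.colors(256, "viridis")
  expect_equal(hm$table$color[1], pal[1])
  expect_equal(hm$table$color[2], pal[256])
  expect_equal(hm$table$color[4], "#808080")  # border reserved
  hm_na <- render_heatmap(map, c(0, 1, NA, NA))
  expect_equal(hm_na$table$color[3], "#C8C8C8")  # undefined reserved
  # rank order preserved for random values
  withr::with_seed(65, {
    v <- stats::runif(4)
    hmr <- render_heatmap(map, v)
    idx <- match(hmr$table$color[1:3], pal)
    expect_equal(order(idx), order(v[1:3]))
  })
  # background is black
  expect_equal(hm$raster[1, 1, ], c(0, 0, 0))
})

test_that("update mode reproduces, merges, and tracks edited geometry", {
  m <- matrix(0L, 40, 40)
  m[5:12, 5:12] <- 1L    # 64 px
  m[5:12, 20:27] <- 2L
  m[25:32, 5:12] <- 3L
  map <- crypt_label_map(m, 1)
  cfg <- analysis_config(min_area_um2 = 30)
  path <- withr::local_tempfile(fileext = ".json")
  save_contours(map, path)

  # unedited round trip reproduces every output exactly
  orig_tab <- crypt_metrics(map, cfg$nn_radius_um, cfg$neighbor_radius_um)
  upd <- update_from_contours(path, cfg)
  expect_identical(upd$label_map$labels, map$labels)
  expect_tables_equal(upd$crypt_table, orig_tab)
  expect_tables_equal(upd$summary, summarize_image(orig_tab))

  # merging two labels into one polygon drops the count by exactly 1
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  doc$crypts[[1]]$rings <- list(list(
    role = "outer", coords = rbind(c(4, 4), c(4, 27), c(12, 27), c(12, 4))))
  doc$crypts <- doc$crypts[-2]
  merged_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, merged_path, auto_unbox = TRUE, digits = NA)
  upd2 <- update_from_contours(merged_path, cfg)
  expect_equal(n_labels(upd2$label_map), n_labels(map) - 1L)

  # moving crypt 3 ten pixels farther increases its nn distance to match
  # the brute-force recomputation on the edited map
  doc3 <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = TRUE)
  doc3$crypts[[3]]$rings[[1]]$coords[, 1] <-
    doc3$crypts[[3]]$rings[[1]]$coords[, 1] + 6
  moved_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc3, moved_path, auto_unbox = TRUE, digits = NA)
  upd3 <- update_from_contours(moved_path, cfg)
  expect_tables_equal(upd3$crypt_table,
                      gt_metrics(upd3$label_map, cfg$nn_radius_um,
                                 cfg$neighbor_radius_um))
  expect_equal(upd3$crypt_table$nn_distance_um[3],
               orig_tab$nn_distance_um[3] + 6)

  # shrinking an object below the minimum area warns and drops it
  doc4 <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = TRUE)
  doc4$crypts[[3]]$rings[[1]]$coords <-
    rbind(c(25, 5), c(25, 8), c(28, 8), c(28, 5))  # 9 px < 30 um^2
  small_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc4, small_path, auto_unbox = TRUE, digits = NA)
  expect_warning(upd4 <- update_from_contours(small_path, cfg), "dropping")
  expect_equal(n_labels(upd4$label_map), 2L)
})
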