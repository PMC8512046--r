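seg_fixture <- function(h, w, R, seed = 1, M = NULL, a = 0.02) {
  set.seed(seed)
  rgb <- random_rgb(h, w)
  params <- if (is.null(M)) grid_params(R = R, a = a)
            else grid_params(R = R, strategy = "topM", M = M)
  segment_image(rgb, params)
}

test_that("label map covers every pixel with its nearest point's label", {
  # 16x16, R = 8, all four points in one cluster
  scene <- make_two_region(16, 16, color_left = c(50, 0, 0),
                           color_right = c(50, 0, 0), noise_sd = 0)
  seg <- segment_image(scene$rgb, grid_params(R = 8))
  expect_true(all(seg$map == 1L))

  # left/right clusters -> two full-height rectangles; the equidistant
  # column between the centers (col 9: 4 px from both) ties to the lower
  # raster index, i.e. the left cell
  scene <- make_two_region(16, 16, noise_sd = 0)
  seg <- segment_image(scene$rgb, grid_params(R = 8, strategy = "topM",
                                              M = 2))
  expect_identical(length(unique(as.vector(seg$map[, 1:9]))), 1L)
  expect_identical(length(unique(as.vector(seg$map[, 10:16]))), 1L)
  expect_false(seg$map[1, 1] == seg$map[1, 16])

  # remainder strips (17x17, R = 8) join adjacent cells; oracle agreement
  for (case in list(c(17, 17, 8), c(16, 16, 8), c(21, 13, 4))) {
    seg <- seg_fixture(case[1], case[2], case[3], seed = sum(case))
    exp <- oracle_nearest_label(seg$features$points, seg$model$labels,
                                case[1], case[2])
    expect_identical(unclass(seg$map), exp, ignore_attr = TRUE)
    expect_true(all(seg$map >= 1L))          # full coverage
  }
})

test_that("quantize_labels agrees with the label-map geometry", {
  scene <- make_disk(40, 40, noise_sd = 0)
  q <- quantize_labels(scene$gt, 8)
  expect_identical(dim(q), dim(scene$gt))
  # quantizing a map that is already grid-constant is the identity
  seg <- seg_fixture(40, 40, 8, seed = 2)
  expect_identical(quantize_labels(seg$map, 8), unclass(seg$map),
                   ignore_attr = TRUE)
})

test_that("boundary extraction flags exactly the 4-neighbor disagreements", {
  expect_false(any(extract_boundaries(matrix(1L, 6, 6))))

  half <- cbind(matrix(1L, 6, 3), matrix(2L, 6, 3))
  b <- extract_boundaries(half)
  expect_true(all(b[, 3:4]))
  expect_false(any(b[, c(1:2, 5:6)]))

  set.seed(17)
  m <- matrix(sample(1:3, 80, replace = TRUE), 8, 10)
  expect_identical(extract_boundaries(m), oracle_boundary(m))

  # symmetry: every flagged pixel has a flagged differing 4-neighbor
  b <- extract_boundaries(m)
  for (k in which(b)) {
    i <- (k - 1) %% 8 + 1; j <- (k - 1) %/% 8 + 1
    ok <- FALSE
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= 8 && jj >= 1 && jj <= 10 &&
          m[ii, jj] != m[i, j] && b[ii, jj]) ok <- TRUE
    }
    expect_true(ok)
  }
})

test_that("thinned boundaries count each interface once", {
  half <- cbind(matrix(1L, 6, 3), matrix(2L, 6, 3))
  bt <- boundary_pixels_thin(half)
  expect_true(all(bt[, 3]))
  expect_identical(sum(bt), 6L)
})

test_that("mean-fill rendering averages per superpixel", {
  const <- array(77, c(12, 12, 3))
  m <- matrix(rep(1:3, each = 48), 12, 12)
  expect_equal(render_superpixel_image(const, m, "mean_fill"), const)

  set.seed(23)
  rgb <- random_rgb(12, 12)
  out <- render_superpixel_image(rgb, m, "mean_fill")
  for (lab in 1:3) for (ch in 1:3) {
    px <- rgb[, , ch][m == lab]
    expect_true(all(out[, , ch][m == lab] == round(mean(px))))
  }
})

test_that("boundary overlay paints boundary pixels the given color", {
  rgb <- array(200, c(8, 8, 3))
  m <- cbind(matrix(1L, 8, 4), matrix(2L, 8, 4))
  out <- render_superpixel_image(rgb, m, "boundary_overlay",
                                 color = c(255, 0, 0))
  b <- extract_boundaries(m)
  expect_true(all(out[, , 1][b] == 255))
  expect_true(all(out[, , 2][b] == 0))
  expect_true(all(out[, , 2][!b] == 200))
  expect_error(render_superpixel_image(rgb, matrix(1L, 4, 4)),
               "dimensions differ")
})

test_that("connectivity enforcement splits disconnected components", {
  m <- matrix(2L, 9, 9)
  m[1:2, 1:2] <- 1L
  m[8:9, 8:9] <- 1L                          # same label, two islands
  out <- enforce_connectivity(m)
  expect_identical(length(unique(as.vector(out))), 3L)
  expect_identical(length(unique(as.vector(out[1:2, 1:2]))), 1L)
  expect_false(out[1, 1] == out[9, 9])
  # already-connected maps keep their component count
  half <- cbind(matrix(1L, 6, 3), matrix(2L, 6, 3))
  expect_identical(length(unique(as.vector(enforce_connectivity(half)))), 2L)
})

test_that("map superpixel count equals the cluster model's M", {
  seg <- seg_fixture(32, 40, 8, seed = 3, M = 4)
  expect_identical(seg$M, length(unique(as.vector(seg$map))))
  expect_identical(seg$model$M, 4L)
})
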