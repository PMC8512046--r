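random_fp <- function(h, w, R, seed) {
  set.seed(seed)
  extract_feature_points(rgb_to_lab(random_rgb(h, w)), grid_params(R = R))
}

test_that("a single feature point has rho = 1", {
  fp <- extract_feature_points(array(0, c(5, 5, 3)), grid_params(R = 5))
  expect_identical(nrow(fp$points), 1L)
  expect_identical(compute_density(fp, K = 6.5, psi = 13), 1L)
})

test_that("uniform image: interior rho = 5 at K = 1.3R (self + 4 axial)", {
  lab <- array(rep(c(50, 0, 0), each = 48 * 64), c(48, 64, 3))
  fp <- extract_feature_points(lab, grid_params(R = 8))
  rho <- compute_density(fp, K = 1.3 * 8, psi = 13)
  interior <- fp$points$h > 8 & fp$points$h < 40 &
              fp$points$w > 8 & fp$points$w < 56
  expect_true(all(rho[interior] == 5L))
  expect_true(all(rho[interior] == rho[interior][1]))  # shared value
  # corners see only 2 axial neighbors
  expect_identical(rho[1], 3L)
})

test_that("rho equals the O(N^2) oracle on random images", {
  for (seed in 1:6) {
    h <- 20 + 4 * seed; w <- 16 + 2 * seed
    R <- c(4, 5, 6)[seed %% 3 + 1]
    fp <- random_fp(h, w, R, seed)
    K <- 1.3 * R; psi <- c(13, 50, 200)[seed %% 3 + 1]
    expect_identical(compute_density(fp, K, psi),
                     oracle_density(fp$points, K, psi))
  }
})

test_that("rho is bounded by [1, N] and monotone in K and psi", {
  fp <- random_fp(32, 32, 4, 77)
  n <- nrow(fp$points)
  r1 <- compute_density(fp, K = 1.3 * 4, psi = 13)
  expect_true(all(r1 >= 1L & r1 <= n))
  r2 <- compute_density(fp, K = 2.2 * 4, psi = 13)
  r3 <- compute_density(fp, K = 1.3 * 4, psi = 100)
  expect_true(all(r2 >= r1))
  expect_true(all(r3 >= r1))
})

test_that("density gating is symmetric between point pairs", {
  fp <- random_fp(24, 24, 4, 5)
  pts <- fp$points
  n <- nrow(pts)
  K <- 1.3 * 4; psi <- 60
  contrib <- matrix(FALSE, n, n)
  for (p in seq_len(n)) for (q in seq_len(n)) {
    ds <- sqrt((pts$h[q] - pts$h[p])^2 + (pts$w[q] - pts$w[p])^2)
    dc <- (pts$Lbar[q] - pts$Lbar[p])^2 + (pts$abar[q] - pts$abar[p])^2 +
          (pts$bbar[q] - pts$bbar[p])^2
    contrib[p, q] <- ds <= K && dc <= psi
  }
  expect_identical(contrib, t(contrib))
})

test_that("strict-literal mode gates space on the squared distance", {
  lab <- array(rep(c(50, 0, 0), each = 48 * 48), c(48, 48, 3))
  fp <- extract_feature_points(lab, grid_params(R = 8))
  # squared distance to the axial neighbor is 64 > K = 10.4 -> self only
  rho <- compute_density(fp, K = 1.3 * 8, psi = 13, strict_literal = TRUE)
  expect_true(all(rho == 1L))
})

test_that("delta, parent and rank match the exhaustive oracle", {
  # the two-point anchor: both deltas equal their separation
  dl <- compute_delta(c(5L, 3L), rbind(c(1, 1), c(1, 11)))
  expect_equal(dl$delta, c(10, 10))
  expect_identical(dl$parent, c(NA_integer_, 1L))

  for (seed in 1:5) {
    set.seed(seed + 100)
    n <- sample(10:40, 1)
    idx <- sample(600, n)                    # distinct positions
    pos <- cbind((idx - 1) %/% 24 + 1, (idx - 1) %% 24 + 1)
    rho <- sample(1:6, n, replace = TRUE)    # plateaus force tie-breaks
    got <- compute_delta(rho, pos)
    exp <- oracle_delta(rho, pos)
    expect_equal(got$delta, exp$delta, tolerance = 1e-12)
    expect_identical(got$parent, exp$parent)
    expect_identical(got$order, exp$order)
    # parents sit strictly earlier in the ranking
    rk <- got$rank
    nz <- !is.na(got$parent)
    expect_true(all(rk[got$parent[nz]] < rk[nz]))
    # the densest point's delta is the max of the others
    expect_equal(got$delta[got$order[1]], max(got$delta[got$order[-1]]))
  }
})

test_that("normalize01 rescales linearly with the all-equal convention", {
  expect_equal(normalize01(c(2, 4, 6)), c(0, 0.5, 1))
  v <- c(3, -1, 10, 5)
  nv <- normalize01(v)
  expect_equal(nv[which.min(v)], 0)
  expect_equal(nv[which.max(v)], 1)
  expect_equal(normalize01(c(7, 7, 7)), c(0, 0, 0))
  expect_error(normalize01(numeric(0)), "empty")
})

test_that("parameter and degenerate-input errors", {
  fp <- random_fp(16, 16, 4, 1)
  expect_error(compute_density(fp, K = 0, psi = 13), "K must be")
  expect_error(compute_density(fp, K = 5, psi = -1), "psi must be")
  expect_error(compute_delta(5L, cbind(1, 1)), "fewer than 2")
})

test_that("density_table assembles normalized columns and lam", {
  fp <- random_fp(32, 24, 4, 9)
  tab <- density_table(fp, grid_params(R = 4))
  expect_s3_class(tab, "density_table")
  expect_true(all(tab$rho_norm >= 0 & tab$rho_norm <= 1))
  expect_true(all(tab$delta_norm >= 0 & tab$delta_norm <= 1))
  expect_equal(tab$lam, tab$rho_norm * tab$delta_norm)
  expect_setequal(tab$rank, 0:(nrow(tab) - 1))
  # rho non-increasing along increasing rank
  expect_true(all(diff(tab$rho[order(tab$rank)]) <= 0))
  expect_true(all(tab$delta[tab$rank > 0] > 0))
})
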