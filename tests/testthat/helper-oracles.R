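# Independent brute-force oracles. Everything here is a deliberately
# naive scalar re-derivation of the definitions; nothing calls the
# package's vectorized paths.

random_rgb <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3L))
}

# scalar Lab conversion for one pixel, written from the definitions
oracle_lab_pixel <- function(r, g, b) {
  v <- c(r, g, b) / 255
  X <- 0.4124 * v[1] + 0.3576 * v[2] + 0.1805 * v[3]
  Y <- 0.2126 * v[1] + 0.7152 * v[2] + 0.0722 * v[3]
  Z <- 0.0193 * v[1] + 0.1192 * v[2] + 0.9505 * v[3]
  f <- function(t) {
    if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  }
  fx <- f(X / 0.9505); fy <- f(Y / 1.0); fz <- f(Z / 1.089)
  c(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
}

oracle_lab_image <- function(rgb) {
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  out <- array(0, dim = c(h, w, 3L))
  for (i in seq_len(h)) for (j in seq_len(w))
    out[i, j, ] <- oracle_lab_pixel(rgb[i, j, 1], rgb[i, j, 2], rgb[i, j, 3])
  out
}

# nested-loop block means over full R x R cells
oracle_block_means <- function(lab, R) {
  gr <- nrow(lab) %/% R; gc <- ncol(lab) %/% R
  out <- matrix(0, gr * gc, 3)
  k <- 0L
  for (r in seq_len(gr)) for (c in seq_len(gc)) {
    k <- k + 1L
    rows <- ((r - 1L) * R + 1L):(r * R)
    cols <- ((c - 1L) * R + 1L):(c * R)
    for (ch in 1:3) {
      s <- 0
      for (i in rows) for (j in cols) s <- s + lab[i, j, ch]
      out[k, ch] <- s / (R * R)
    }
  }
  out
}

# O(N^2) density: Euclidean spatial gate vs K, squared color gate vs psi
oracle_density <- function(pts, K, psi) {
  n <- nrow(pts)
  rho <- integer(n)
  for (p in seq_len(n)) {
    cnt <- 0L
    for (q in seq_len(n)) {
      ds <- sqrt((pts$h[q] - pts$h[p])^2 + (pts$w[q] - pts$w[p])^2)
      dc <- (pts$Lbar[q] - pts$Lbar[p])^2 + (pts$abar[q] - pts$abar[p])^2 +
            (pts$bbar[q] - pts$bbar[p])^2
      if (ds <= K && dc <= psi) cnt <- cnt + 1L
    }
    rho[p] <- cnt
  }
  rho
}

# exhaustive delta/parent: rank by (-rho, index), then pairwise scan in
# rank order; ties keep the earliest-ranked (densest) candidate
oracle_delta <- function(rho, pos) {
  n <- length(rho)
  ord <- order(-rho, seq_len(n))
  delta <- numeric(n); parent <- rep(NA_integer_, n)
  for (k in 2:n) {
    m <- ord[k]
    best_d <- Inf; best_j <- NA_integer_
    for (l in seq_len(k - 1L)) {
      j <- ord[l]
      d <- sqrt((pos[j, 1] - pos[m, 1])^2 + (pos[j, 2] - pos[m, 2])^2)
      if (d < best_d - 1e-12) {
        best_d <- d; best_j <- j
      }
    }
    delta[m] <- best_d; parent[m] <- best_j
  }
  delta[ord[1]] <- max(delta[-ord[1]])
  list(delta = delta, parent = parent, order = ord)
}

# recursive chain walk: follow parents until a center
oracle_chain_labels <- function(parent, centers) {
  walk <- function(m) {
    if (m %in% centers) return(match(m, centers))
    walk(parent[m])
  }
  vapply(seq_along(parent), walk, integer(1))
}

# nearest feature point per pixel, ties -> lowest raster index m
oracle_nearest_label <- function(pts, labels, h, w) {
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    best_d <- Inf; best_m <- NA_integer_
    for (m in seq_len(nrow(pts))) {
      d <- (pts$h[m] - i)^2 + (pts$w[m] - j)^2
      if (d < best_d) { best_d <- d; best_m <- m }
    }
    out[i, j] <- labels[best_m]
  }
  out
}

# per-pixel 4-neighbor scan
oracle_boundary <- function(map) {
  h <- nrow(map); w <- ncol(map)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
          map[ii, jj] != map[i, j]) out[i, j] <- TRUE
    }
  }
  out
}

# contingency-table ASA by explicit counting
oracle_asa <- function(map, gt) {
  total <- 0
  for (s in unique(as.vector(map))) {
    in_s <- map == s
    best <- 0
    for (g in unique(as.vector(gt)))
      best <- max(best, sum(in_s & gt == g))
    total <- total + best
  }
  total / length(map)
}

# per-gt-boundary-pixel Chebyshev scan against all pred boundary pixels
oracle_br <- function(predB, gt, eps) {
  h <- nrow(gt); w <- ncol(gt)
  gtB <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (i < h && gt[i + 1, j] != gt[i, j]) gtB[i, j] <- TRUE
    if (j < w && gt[i, j + 1] != gt[i, j]) gtB[i, j] <- TRUE
  }
  if (!any(gtB)) return(1)
  pred_idx <- which(predB, arr.ind = TRUE)
  hits <- 0L
  for (k in which(gtB)) {
    i <- (k - 1L) %% h + 1L; j <- (k - 1L) %/% h + 1L
    if (nrow(pred_idx) > 0 &&
        any(pmax(abs(pred_idx[, 1] - i), abs(pred_idx[, 2] - j)) <= eps))
      hits <- hits + 1L
  }
  hits / sum(gtB)
}

# feature-point agreement: each cluster votes for its majority gt region
fp_agreement <- function(seg, gt) {
  fpgt <- gt[cbind(seg$features$points$h, seg$features$points$w)]
  tab <- table(seg$model$labels, fpgt)
  sum(apply(tab, 1, max)) / length(fpgt)
}
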