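# Brute-force reference implementations used as independent oracles.
# All are direct per-pixel scans, deliberately naive.

rand_mat <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

rand_rgb <- function(h, w, seed) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}

# windowed mean with shrinking borders, O(r^2) per pixel
naive_box_mean <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ri <- max(1, i - r):min(h, i + r)
    rj <- max(1, j - r):min(w, j + r)
    out[i, j] <- mean(m[ri, rj])
  }
  out
}

# scalar-guide guided filter via explicit per-window affine coefficients:
# q_p = mean over windows k containing p of (a_k * I_p + b_k), where a_k
# and b_k come from the window's own (count-correct) statistics
naive_guided_gray <- function(guide, input, r, eps) {
  h <- nrow(guide); w <- ncol(guide)
  asum <- matrix(0, h, w); bsum <- matrix(0, h, w); cnt <- matrix(0, h, w)
  for (ki in seq_len(h)) for (kj in seq_len(w)) {
    ri <- max(1, ki - r):min(h, ki + r)
    rj <- max(1, kj - r):min(w, kj + r)
    gi <- guide[ri, rj]; pi <- input[ri, rj]
    mu <- mean(gi); var_k <- mean(gi^2) - mu^2
    a <- (mean(gi * pi) - mu * mean(pi)) / (var_k + eps)
    b <- mean(pi) - a * mu
    asum[ri, rj] <- asum[ri, rj] + a
    bsum[ri, rj] <- bsum[ri, rj] + b
    cnt[ri, rj] <- cnt[ri, rj] + 1
  }
  (asum / cnt) * guide + bsum / cnt
}

# per-pixel weighted median scan
naive_weighted_median <- function(d, guide, radius, sigma_G, sigma_M) {
  h <- nrow(d); w <- ncol(d)
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- c(); wts <- c()
    for (ii in max(1, i - radius):min(h, i + radius))
      for (jj in max(1, j - radius):min(w, j + radius)) {
        if (is.na(d[ii, jj])) next
        sw <- exp(-((ii - i)^2 + (jj - j)^2) / sigma_G^2)
        cw <- exp(-sum((guide[i, j, ] - guide[ii, jj, ])^2) / sigma_M^2)
        vals <- c(vals, d[ii, jj]); wts <- c(wts, sw * cw)
      }
    if (length(vals) == 0) next
    o <- order(vals)
    cw <- cumsum(wts[o])
    out[i, j] <- vals[o][which(cw >= cw[length(cw)] / 2)[1]]
  }
  out
}

# per-pixel nearest-valid scanline fill, min of the two sides
naive_fill <- function(d, valid) {
  h <- nrow(d); w <- ncol(d)
  out <- d
  for (i in seq_len(h)) {
    v <- which(valid[i, ])
    if (length(v) == 0) next
    for (j in which(!valid[i, ])) {
      lv <- v[v <= j]; rv <- v[v >= j]
      cands <- c(if (length(lv) > 0) d[i, max(lv)],
                 if (length(rv) > 0) d[i, min(rv)])
      out[i, j] <- min(cands)
    }
  }
  for (i in which(!apply(valid, 1, any))) {
    good <- which(apply(valid, 1, any))
    out[i, ] <- out[good[which.min(abs(good - i))], ]
  }
  out
}

# exhaustive rectangular-window extreme
naive_window_extreme <- function(m, rx, ry, fun) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ri <- max(1, i - ry):min(h, i + ry)
    rj <- max(1, j - rx):min(w, j + rx)
    out[i, j] <- fun(m[ri, rj])
  }
  out
}

# per-pixel argmin over valid entries, ties toward smaller disparity
naive_wta <- function(vol) {
  dm <- dim(vol$costs)
  out <- matrix(NA_real_, dm[1], dm[2])
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) {
    best <- Inf
    for (k in seq_len(dm[3])) {
      if (!vol$valid[i, j, k]) next
      if (vol$costs[i, j, k] < best) {
        best <- vol$costs[i, j, k]
        out[i, j] <- vol$d_min + k - 1
      }
    }
  }
  out
}

# a small textured pair with uniform integer disparity, via the generator
plane_fixture <- function(d = 6, h = 40, w = 56, seed = 3, d_max = 16) {
  spec <- scene_spec(height = h, width = w, surface = "plane", d_base = d,
                     d_amplitude = 0, texture = "noise", seed = seed,
                     d_max_global = d_max)
  generate_scene(spec)[[1]]
}

test_params <- function(...) {
  aswi_params(d_min_global = 0L, d_max_global = 12L, median_radius = 3L, ...)
}
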