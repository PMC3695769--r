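# Shared fixture builders and independent brute-force oracles.
# Oracles deliberately avoid the package's computational paths.

make_circle <- function(cx, cy, r, role = "generic", n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour_polygon(cx + r * cos(th), cy + r * sin(th), role)
}

make_ellipse <- function(cx, cy, a, b, role = "generic", n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour_polygon(cx + a * cos(th), cy + b * sin(th), role)
}

# pixel-coordinate grids (pixel centers at (col-1, row-1) mm)
grid_xy <- function(n) {
  list(x = matrix(rep(0:(n - 1), each = n), n, n),
       y = matrix(rep(0:(n - 1), times = n), n, n))
}

# brute-force max least-squares slope over all windows of length w between
# frames a and p (frame index as abscissa)
oracle_max_window_slope <- function(si, a, p, w) {
  best <- -Inf
  for (st in a:max(a, p - w + 1)) {
    en <- min(st + w - 1, length(si))
    if (en - st + 1 < 2) next
    ii <- st:en
    fit <- stats::lm(si[ii] ~ ii)
    best <- max(best, coef(fit)[[2]])
  }
  best
}

# brute-force n x n neighborhood-mean peak |velocity| over ROI mask
oracle_neighborhood_peak <- function(frames, mask, n) {
  h <- (n - 1) %/% 2
  best <- 0; best_signed <- NA
  for (v in frames) {
    ij <- which(mask, arr.ind = TRUE)
    for (k in seq_len(nrow(ij))) {
      vals <- c()
      for (dr in -h:h) for (dc in -h:h) {
        r <- ij[k, 1] + dr; c <- ij[k, 2] + dc
        if (r >= 1 && r <= nrow(v) && c >= 1 && c <= ncol(v) && mask[r, c])
          vals <- c(vals, v[r, c])
      }
      mu <- mean(vals)
      if (abs(mu) > best) { best <- abs(mu); best_signed <- mu }
    }
  }
  best_signed
}

# nearest-boundary-distance layer classification by dense boundary sampling
oracle_layer_split <- function(endo, epi, dim, n_boundary = 4000) {
  sample_bd <- function(p) {
    x <- c(p$x, p$x[1]); y <- c(p$y, p$y[1])
    seg <- sqrt(diff(x)^2 + diff(y)^2)
    cs <- c(0, cumsum(seg))
    tt <- seq(0, cs[length(cs)], length.out = n_boundary)
    k <- pmin(findInterval(tt, cs, rightmost.closed = TRUE), length(seg))
    w <- (tt - cs[k]) / pmax(seg[k], 1e-12)
    cbind(x[k] + w * (x[k + 1] - x[k]), y[k] + w * (y[k + 1] - y[k]))
  }
  be <- sample_bd(endo); bp <- sample_bd(epi)
  myo <- myocardium_mask(endo, epi, dim)
  ij <- which(myo, arr.ind = TRUE)
  endo_layer <- matrix(FALSE, dim[1], dim[2])
  for (k in seq_len(nrow(ij))) {
    px <- ij[k, 2] - 1; py <- ij[k, 1] - 1
    de <- sqrt(min((be[, 1] - px)^2 + (be[, 2] - py)^2))
    dp <- sqrt(min((bp[, 1] - px)^2 + (bp[, 2] - py)^2))
    if (de / (de + dp) < 0.5) endo_layer[ij[k, 1], ij[k, 2]] <- TRUE
  }
  list(endo_layer = endo_layer, epi_layer = myo & !endo_layer)
}

# stack with one slice per geometry and given endo/epi areas via squares
square_poly <- function(side, role, cx = 0, cy = 0) {
  h <- side / 2
  contour_polygon(cx + c(-h, h, h, -h), cy + c(-h, -h, h, h), role)
}
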