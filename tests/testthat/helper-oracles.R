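# Shape builders and brute-force oracles used across the suite. Oracles are
# written independently of the package internals they check.

circle_pts <- function(n = 120, r = 25, center = c(0, 0), closed = TRUE) {
  theta <- seq(0, 2 * pi, length.out = n + 1)
  if (!closed) theta <- theta[-(n + 1)]
  tibble::tibble(x_mm = center[1] + r * cos(theta),
                 y_mm = center[2] + r * sin(theta))
}

# Open elliptical arc with an annulus gap centred at angle -pi/2 (same
# parameterisation family as the LA phantom but built locally).
ellipse_gap_pts <- function(a = 30, b = 24, gap_deg = 50, n = 200, rot = 0,
                            center = c(0, 0)) {
  g <- gap_deg / 2 * pi / 180
  theta <- seq(-pi / 2 + g, 3 * pi / 2 - g, length.out = n)
  p <- cbind(a * cos(theta), b * sin(theta))
  rotm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  p <- p %*% t(rotm)
  tibble::tibble(x_mm = p[, 1] + center[1], y_mm = p[, 2] + center[2])
}

rotate_pts <- function(df, angle, about = c(0, 0)) {
  rotm <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  p <- sweep(cbind(df$x_mm, df$y_mm), 2, about) %*% t(rotm)
  tibble::tibble(x_mm = p[, 1] + about[1], y_mm = p[, 2] + about[2])
}

# Brute-force polyline length: explicit pairwise distances in a loop.
brute_length <- function(df) {
  tot <- 0
  for (i in seq_len(nrow(df) - 1)) {
    tot <- tot + sqrt((df$x_mm[i + 1] - df$x_mm[i])^2 + (df$y_mm[i + 1] - df$y_mm[i])^2)
  }
  tot
}

# Dense arc-length table: subdivide each edge into `sub` pieces; returns the
# dense points and their cumulative arc positions.
dense_arc_table <- function(df, sub = 2000L) {
  xs <- df$x_mm; ys <- df$y_mm
  px <- c(); py <- c()
  for (i in seq_len(length(xs) - 1)) {
    f <- seq(0, 1, length.out = sub + 1)[-(sub + 1)]
    px <- c(px, xs[i] + f * (xs[i + 1] - xs[i]))
    py <- c(py, ys[i] + f * (ys[i + 1] - ys[i]))
  }
  px <- c(px, xs[length(xs)]); py <- c(py, ys[length(ys)])
  d <- sqrt(diff(px)^2 + diff(py)^2)
  list(x = px, y = py, s = c(0, cumsum(d)))
}

# Arc position of query points on a polyline, via nearest dense sample.
arc_position_of <- function(df, qx, qy, sub = 2000L) {
  tab <- dense_arc_table(df, sub)
  vapply(seq_along(qx), function(i) {
    tab$s[which.min((tab$x - qx[i])^2 + (tab$y - qy[i])^2)]
  }, numeric(1))
}

# Build a valid la_sequence by repeating/transforming a base contour.
make_seq <- function(frames, times_ms = NULL, view = "4-chamber", mv = NULL) {
  if (is.null(times_ms)) times_ms <- seq(0, by = 50, length.out = length(frames))
  lamotion::la_sequence(frames, times_ms, view = view, mv_points = mv)
}

# A mildly irregular star-shaped test contour (fixed, not random per run).
blob_pts <- function(n = 140, seed = 42) {
  set.seed(seed)
  k <- stats::runif(3, -0.12, 0.12)
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- 28 * (1 + k[1] * sin(2 * theta) + k[2] * cos(3 * theta) + k[3] * sin(5 * theta))
  tibble::tibble(x_mm = r * cos(theta), y_mm = r * sin(theta))
}

# Otsu-style exhaustive threshold sweep on 1-D intensities: threshold
# minimising within-class variance; returns fraction above the threshold.
otsu_fraction <- function(vals, n_grid = 512L) {
  qs <- seq(min(vals), max(vals), length.out = n_grid)
  best <- Inf; best_frac <- NA_real_
  for (thr in qs[-c(1, n_grid)]) {
    hi <- vals > thr
    if (!any(hi) || all(hi)) next
    wcv <- sum((vals[hi] - mean(vals[hi]))^2) + sum((vals[!hi] - mean(vals[!hi]))^2)
    if (wcv < best) {
      best <- wcv
      best_frac <- mean(hi)
    }
  }
  best_frac
}

contour_tibble_rot <- function(m, rotm) {
  p <- m %*% t(rotm)
  tibble::tibble(x_mm = p[, 1], y_mm = p[, 2])
}

# Closed-form area of a regular n-gon inscribed in a circle of radius r.
polygon_area_oracle <- function(r, n) 0.5 * n * r^2 * sin(2 * pi / n)
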