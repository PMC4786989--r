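# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# per-cell loop over all footprints: overlap-area-weighted mean
oracle_regrid <- function(rects, vals, spec, min_frac = 0.01) {
  latc <- grid_lat_centers(spec)
  out <- matrix(NA_real_, spec$nlat, spec$nlon)
  wgt <- matrix(0, spec$nlat, spec$nlon)
  for (i in seq_len(spec$nlat)) {
    y0 <- spec$lat0 + (i - 1) * spec$cellsize
    y1 <- y0 + spec$cellsize
    for (j in seq_len(spec$nlon)) {
      x0 <- spec$lon0 + (j - 1) * spec$cellsize
      x1 <- x0 + spec$cellsize
      sw <- 0
      swv <- 0
      for (k in seq_len(nrow(rects))) {
        dx <- min(x1, rects[k, 2]) - max(x0, rects[k, 1])
        dy <- min(y1, rects[k, 4]) - max(y0, rects[k, 3])
        if (dx <= 0 || dy <= 0) next
        if (dx * dy < min_frac * spec$cellsize^2) next
        w <- dx * dy * cos(latc[i] * pi / 180)
        sw <- sw + w
        swv <- swv + w * vals[k]
      }
      if (sw > 0) {
        out[i, j] <- swv / sw
        wgt[i, j] <- sw
      }
    }
  }
  list(values = out, weight = wgt)
}

# area-weighted mean of a field over one rectangle, by per-cell loop
oracle_rect_mean <- function(field, rect, min_frac = 0.01) {
  spec <- field$spec
  latc <- grid_lat_centers(spec)
  sw <- 0
  swv <- 0
  for (i in seq_len(spec$nlat)) {
    y0 <- spec$lat0 + (i - 1) * spec$cellsize
    y1 <- y0 + spec$cellsize
    dy <- min(y1, rect[4]) - max(y0, rect[3])
    if (dy <= 0) next
    for (j in seq_len(spec$nlon)) {
      x0 <- spec$lon0 + (j - 1) * spec$cellsize
      x1 <- x0 + spec$cellsize
      dx <- min(x1, rect[2]) - max(x0, rect[1])
      if (dx <= 0 || dx * dy < min_frac * spec$cellsize^2) next
      v <- field$values[i, j]
      if (is.na(v)) next
      w <- dx * dy * cos(latc[i] * pi / 180)
      sw <- sw + w
      swv <- swv + w * v
    }
  }
  if (sw > 0) swv / sw else NA_real_
}

# direct double-loop moving-window mean with edge truncation and mask
oracle_boxcar <- function(values, kx, ky) {
  hr <- (ky - 1) %/% 2
  hc <- (kx - 1) %/% 2
  n <- nrow(values)
  m <- ncol(values)
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      block <- values[max(1, i - hr):min(n, i + hr),
                      max(1, j - hc):min(m, j + hc)]
      if (any(!is.na(block))) out[i, j] <- mean(block, na.rm = TRUE)
    }
  }
  out
}

# closed-form OLS via sum formulas
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  resid <- y - intercept - slope * x
  se <- sqrt(sum(resid^2) / (n - 2) / (sxx - sx^2 / n))
  list(slope = slope, intercept = intercept, se = se)
}

# weighted percentile by direct cumulative enumeration with interpolation
oracle_pw_percentile <- function(conc, pop, q) {
  ord <- order(conc)
  conc <- conc[ord]
  cf <- cumsum(pop[ord]) / sum(pop)
  target <- q / 100
  if (target <= cf[1]) return(conc[1])
  i <- which(cf >= target)[1]
  if (cf[i] == target) return(conc[i])
  # interpolate between boundary (i-1) and i in cumulative space
  conc[i - 1] + (conc[i] - conc[i - 1]) * (target - cf[i - 1]) / (cf[i] - cf[i - 1])
}
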