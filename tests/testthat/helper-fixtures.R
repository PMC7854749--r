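# Shared fixtures. Everything is generated in code; no binary data.

# A bare obs_series with full control over bands/doys/validity.
make_series <- function(doys, reflectance, valid = rep(TRUE, length(doys)),
                        label = 0L, subtype = "crop", zone = "SJ") {
  structure(list(doys = doys, reflectance = reflectance,
                 screen = cbind(aerosols = reflectance[, "blue"] + 0.02,
                                green = reflectance[, "blue"]),
                 valid = valid, label = label,
                 class_label = crop_label(label), subtype = subtype,
                 zone = zone),
            class = "obs_series")
}

# Constant-band reflectance matrix.
flat_bands <- function(n, value = 0.2) {
  matrix(value, n, 8, dimnames = list(NULL, band_names()))
}

# Independent Savitzky-Golay weights via an explicit lm() polynomial fit:
# fit degree-`order` polynomial to y over x = -h..h, predict at `at`.
sg_oracle <- function(window, order, at = 0) {
  h <- (window - 1) / 2
  x <- seq(-h, h)
  vapply(seq_len(window), function(i) {
    y <- rep(0, window); y[i] <- 1
    fit <- stats::lm(y ~ poly(x, order, raw = TRUE))
    unname(stats::predict(fit, newdata = data.frame(x = at)))
  }, numeric(1))
}

# Brute-force GLCM oracle: enumerate all ordered pixel pairs per offset,
# accumulate a dense co-occurrence table, and compute the 18 statistics with
# straightforward (slow) code independent of the package implementation.
glcm_oracle <- function(img, levels = 32L) {
  q <- quantize_image(img, levels)
  offsets <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  per_offset <- lapply(offsets, function(off) {
    counts <- matrix(0, levels, levels)
    for (r in seq_len(nrow(q))) for (c in seq_len(ncol(q))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
      a <- q[r, c]; b <- q[r2, c2]
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
    P <- counts / sum(counts)
    present <- which(rowSums(P) > 0)
    p <- P[present, present, drop = FALSE]
    G <- length(present)
    px <- rowSums(p)
    mu <- sum(present * px)
    s2 <- sum((present - mu)^2 * px)

    st <- numeric(18)
    ent <- 0
    for (i in seq_len(G)) for (j in seq_len(G)) {
      v <- p[i, j]
      li <- present[i]; lj <- present[j]
      st[1] <- st[1] + v^2
      st[2] <- st[2] + (li - lj)^2 * v
      st[4] <- st[4] + (li - mu)^2 * v
      st[5] <- st[5] + v / (1 + (li - lj)^2)
      st[15] <- st[15] + abs(li - lj) * v
      st[17] <- st[17] + (li + lj - 2 * mu)^3 * v
      st[18] <- st[18] + (li + lj - 2 * mu)^4 * v
      if (v > 0) ent <- ent - v * log(v)
    }
    st[3] <- if (s2 == 0) 1 else
      (sum(outer(present, present) * p) - mu^2) / s2
    st[9] <- ent
    # sum / difference distributions over level values
    sums <- sort(unique(as.vector(outer(present, present, `+`))))
    ps <- vapply(sums, function(k)
      sum(p[outer(present, present, `+`) == k]), numeric(1))
    st[6] <- sum(sums * ps)
    st[7] <- sum((sums - st[6])^2 * ps)
    st[8] <- -sum(ps[ps > 0] * log(ps[ps > 0]))
    difs <- sort(unique(as.vector(abs(outer(present, present, `-`)))))
    pdv <- vapply(difs, function(k)
      sum(p[abs(outer(present, present, `-`)) == k]), numeric(1))
    dmu <- sum(difs * pdv)
    st[10] <- sum((difs - dmu)^2 * pdv)
    st[11] <- -sum(pdv[pdv > 0] * log(pdv[pdv > 0]))
    hx <- -sum(px[px > 0] * log(px[px > 0]))
    pij <- outer(px, px)
    hxy1 <- -sum((p * log(pij))[p > 0])
    hxy2 <- -sum((pij * log(pij))[pij > 0])
    st[12] <- if (hx == 0) 0 else (ent - hxy1) / hx
    st[13] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
    st[14] <- if (G == 1) 1 else {
      Q <- matrix(0, G, G)
      for (i in seq_len(G)) for (j in seq_len(G))
        Q[i, j] <- sum(p[i, ] * p[j, ] / (px[i] * px))
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(0, ev[2]))
    }
    st[16] <- st[2]
    st
  })
  stats::setNames(Reduce(`+`, per_offset) / 4, glcm_stat_names())
}

# Raster with embedded rectangular patches on a uniform background.
patchwork_raster <- function(nr = 60, nc = 60, background = 1L) {
  m <- matrix(background, nr, nc)
  m
}
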