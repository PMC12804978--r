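# Internal raster helpers shared by the segmentation and detection modules.

# Separable Gaussian blur with edge renormalisation (kernel truncated at
# 4 sigma; weights falling outside the image are dropped and the remainder
# renormalised, so flat images stay flat).
gaussianBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  n <- nrow(img); m <- ncol(img)
  bandMat <- function(size) {
    A <- matrix(0, size, size)
    for (o in -half:half) {
      idx <- seq_len(size)
      j <- idx + o
      keep <- j >= 1 & j <= size
      A[cbind(idx[keep], j[keep])] <- k[o + half + 1]
    }
    A / rowSums(A)
  }
  Ar <- bandMat(n)
  Ac <- bandMat(m)
  Ar %*% img %*% t(Ac)
}

# Otsu's global threshold on a 256-bin histogram of the intensity range.
otsuThreshold <- function(img) {
  v <- as.numeric(img)
  rng <- range(v)
  if (diff(rng) == 0) stop("cannot threshold a constant image")
  nb <- 256L
  h <- tabulate(pmin(nb, 1L + floor((v - rng[1]) / diff(rng) * nb)), nb)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nb) - 0.5) / nb * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nb]
  between <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# shift a matrix by (dr, dc), padding with `fill`
shiftMat <- function(m, dr, dc, fill = 0) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(p, p + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-neighbour count of a logical mask (degree map restricted to the mask)
neighborCount8 <- function(mask) {
  m <- mask * 1
  acc <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + shiftMat(m, dr, dc)
  }
  acc * (mask * 1)
}

# grayscale 3x3 maximum of the 8-neighbourhood (centre excluded)
neighborMax8 <- function(img) {
  acc <- matrix(-Inf, nrow(img), ncol(img))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- pmax(acc, shiftMat(img, dr, dc, fill = -Inf))
  }
  acc
}

# one-pixel Chebyshev (8-neighbourhood) binary dilation
dilate8 <- function(mask) {
  acc <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc | shiftMat(mask, dr, dc, fill = FALSE) > 0
  }
  acc
}

diskOffsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}
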