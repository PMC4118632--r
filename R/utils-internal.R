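# Internal helpers shared across the pipeline. Images are numeric arrays
# dim = c(rows, cols, 3) on a 0..255 scale; masks are integer matrices on the
# same pixel grid (0 background, 1 normal tissue, 2 abnormal tissue).

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# FFT Gaussian blur with mirror padding; handles sigma of any size relative to
# the image (EBImage::gblur requires the kernel to fit inside the image).
gauss_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  h <- nrow(mat); w <- ncol(mat)
  pad <- ceiling(3 * sigma)
  ph <- min(pad, h - 1L); pw <- min(pad, w - 1L)
  big <- matrix(0, h + 2 * ph, w + 2 * pw)
  big[(ph + 1):(ph + h), (pw + 1):(pw + w)] <- mat
  if (ph > 0) {
    big[ph:1, ] <- big[(ph + 1):(ph + ph), ]
    big[(ph + h + 1):(ph + h + ph), ] <- big[(ph + h):(h + 1), ]
  }
  if (pw > 0) {
    big[, pw:1] <- big[, (pw + 1):(pw + pw)]
    big[, (pw + w + 1):(pw + w + pw)] <- big[, (pw + w):(w + 1)]
  }
  hh <- nrow(big); ww <- ncol(big)
  dr <- pmin(0:(hh - 1), hh - (0:(hh - 1)))
  dc <- pmin(0:(ww - 1), ww - (0:(ww - 1)))
  kr <- exp(-dr^2 / (2 * sigma^2))
  kc <- exp(-dc^2 / (2 * sigma^2))
  ker <- outer(kr, kc)
  ker <- ker / sum(ker)
  out <- Re(stats::fft(stats::fft(big) * stats::fft(ker), inverse = TRUE)) / (hh * ww)
  out[(ph + 1):(ph + h), (pw + 1):(pw + w)]
}

# Large-sigma blur computed on a downsampled copy and upsampled back;
# equivalent at coarse scale and much cheaper than blurring full resolution.
coarse_blur <- function(mat, sigma, target_w = 64L) {
  h <- nrow(mat); w <- ncol(mat)
  if (w <= target_w) return(gauss_blur(mat, sigma))
  f <- target_w / w
  small <- EBImage::resize(mat, w = round(h * f), h = target_w)
  sm <- gauss_blur(small, sigma * f)
  EBImage::resize(sm, w = h, h = w)
}

# Rec. 601 luma on 0..255 RGB arrays.
luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# HSV-style saturation per pixel, in [0,1].
pixel_saturation <- function(img) {
  mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
  mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
  s <- (mx - mn) / pmax(mx, 1e-8)
  s[mx <= 0] <- 0
  s
}

clip255 <- function(img) {
  img[img < 0] <- 0
  img[img > 255] <- 255
  img
}

# sRGB (0..255 array) <-> CIELAB, via grDevices::convertColor.
rgb_to_lab <- function(img) {
  d <- dim(img)
  m <- matrix(as.vector(img) / 255, ncol = 3)
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  array(lab, dim = d)
}

lab_to_rgb <- function(lab) {
  d <- dim(lab)
  m <- matrix(as.vector(lab), ncol = 3)
  rgb <- grDevices::convertColor(m, from = "Lab", to = "sRGB", clip = TRUE)
  array(rgb * 255, dim = d)
}

# Pixel (row, col) pairs covered by an ellipse; NULL when it spills outside
# the canvas.
ellipse_pixels <- function(r0, c0, a, b, theta, h, w) {
  rad <- ceiling(max(a, b))
  rmin <- floor(r0 - rad); rmax <- ceiling(r0 + rad)
  cmin <- floor(c0 - rad); cmax <- ceiling(c0 + rad)
  if (rmin < 1 || cmin < 1 || rmax > h || cmax > w) return(NULL)
  rr <- rmin:rmax; cc <- cmin:cmax
  g <- expand.grid(row = rr, col = cc)
  dr <- g$row - r0; dc <- g$col - c0
  u <- (dr * cos(theta) + dc * sin(theta)) / a
  v <- (-dr * sin(theta) + dc * cos(theta)) / b
  keep <- u^2 + v^2 <= 1
  if (!any(keep)) return(NULL)
  cbind(row = g$row[keep], col = g$col[keep])
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_pq <- function(msg, class) {
  rlang::abort(msg, class = c(class, "pulleyquant_error"))
}
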