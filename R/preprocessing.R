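# Training-time augmentation and evaluation-time normalization.
#
# Pipeline (training): bicubic resize to target_size -> random horizontal
# flip -> n_rand_ops operations drawn from the enhancement pool at a fixed
# magnitude -> random erasing -> per-channel standardization.
# Evaluation uses only the resize and the standardization.

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_STD <- c(0.229, 0.224, 0.225)

#' Augmentation configuration
#'
#' @param target_size Output side length in pixels.
#' @param n_rand_ops Number of pool operations applied per image.
#' @param magnitude Applied magnitude, `0 <= magnitude < magnitude_bins`.
#' @param magnitude_bins Number of magnitude levels.
#' @param erase_prob Probability of random erasing.
#' @param erase_area `(min, max)` erased-area fractions.
#' @param hflip_prob Probability of a horizontal flip.
#' @return An `augment_config` list.
#' @export
augment_config <- function(target_size = 224L, n_rand_ops = 2L, magnitude = 9L,
                           magnitude_bins = 10L, erase_prob = 0.25,
                           erase_area = c(0.02, 0.33), hflip_prob = 0.5) {
  if (magnitude < 0 || magnitude >= magnitude_bins) {
    stopf("magnitude must satisfy 0 <= magnitude < magnitude_bins")
  }
  if (!(erase_area[1] > 0 && erase_area[1] < erase_area[2] && erase_area[2] < 1)) {
    stopf("erase_area must satisfy 0 < min < max < 1")
  }
  structure(
    list(target_size = as.integer(target_size),
         n_rand_ops = as.integer(n_rand_ops),
         magnitude = as.integer(magnitude),
         magnitude_bins = as.integer(magnitude_bins),
         erase_prob = erase_prob, erase_area = erase_area,
         hflip_prob = hflip_prob),
    class = "augment_config"
  )
}

# --- bicubic resize ----------------------------------------------------------

# Keys cubic-convolution kernel, a = -0.5 (the classical bicubic choice).
cubic_kernel <- function(t) {
  a <- -0.5
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  i2 <- at > 1 & at < 2
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  w[i2] <- a * at[i2]^3 - 5 * a * at[i2]^2 + 8 * a * at[i2] - 4 * a
  w
}

# out_n x in_n interpolation matrix mapping pixel centers; edges replicate.
resize_matrix <- function(in_n, out_n) {
  W <- matrix(0, out_n, in_n)
  scale <- in_n / out_n
  for (i in seq_len(out_n)) {
    src <- (i - 0.5) * scale + 0.5
    base <- floor(src)
    for (j in (base - 1L):(base + 2L)) {
      w <- cubic_kernel(src - j)
      jj <- min(max(j, 1L), in_n)
      W[i, jj] <- W[i, jj] + w
    }
  }
  W
}

#' Bicubic image resize
#'
#' Separable cubic-convolution resampling (Keys kernel, a = -0.5) with
#' replicated edges, applied channel-wise.
#'
#' @param pixels H x W x 3 numeric array.
#' @param out_h,out_w Output size in pixels.
#' @return `out_h` x `out_w` x 3 numeric array (not clamped).
#' @export
resize_bicubic <- function(pixels, out_h, out_w = out_h) {
  d <- dim(pixels)
  Wr <- resize_matrix(d[1], out_h)
  Wc <- resize_matrix(d[2], out_w)
  out <- array(0, dim = c(out_h, out_w, d[3]))
  for (c in seq_len(d[3])) {
    out[, , c] <- Wr %*% pixels[, , c] %*% t(Wc)
  }
  out
}

# --- enhancement pool --------------------------------------------------------

blend <- function(base, img, factor) clamp(base * (1 - factor) + img * factor, 0, 255)

luminance <- function(img) 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]

op_autocontrast <- function(img, mag, bins, sign) {
  for (c in 1:3) {
    ch <- img[, , c]
    lo <- min(ch); hi <- max(ch)
    if (hi > lo) img[, , c] <- (ch - lo) * (255 / (hi - lo))
  }
  img
}

op_equalize <- function(img, mag, bins, sign) {
  for (c in 1:3) {
    ch <- as.integer(round(clamp(img[, , c], 0, 255)))
    h <- tabulate(ch + 1L, nbins = 256L)
    cdf <- cumsum(h)
    nz <- cdf[cdf > 0]
    if (length(nz) <= 1L || cdf[256] == nz[1]) next
    lut <- round((cdf - nz[1]) / (cdf[256] - nz[1]) * 255)
    img[, , c] <- matrix(lut[ch + 1L], dim(img)[1], dim(img)[2])
  }
  clamp(img, 0, 255)
}

# bilinear rotation about the image center, constant pale fill
op_rotate <- function(img, mag, bins, sign) {
  deg <- 30 * mag / bins * sign
  th <- deg * pi / 180
  H <- dim(img)[1]; W <- dim(img)[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ys <- matrix(rep(seq_len(H), times = W), H, W)
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  # inverse map: source coords for each target pixel
  sx <- cos(th) * (xs - cx) + sin(th) * (ys - cy) + cx
  sy <- -sin(th) * (xs - cx) + cos(th) * (ys - cy) + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  inside <- x0 >= 1 & x0 + 1 <= W & y0 >= 1 & y0 + 1 <= H
  out <- img
  fill <- 244
  for (c in 1:3) {
    ch <- img[, , c]
    res <- matrix(fill, H, W)
    idx <- function(y, x) (x - 1L) * H + y
    v00 <- ch[idx(y0[inside], x0[inside])]
    v01 <- ch[idx(y0[inside], x0[inside] + 1L)]
    v10 <- ch[idx(y0[inside] + 1L, x0[inside])]
    v11 <- ch[idx(y0[inside] + 1L, x0[inside] + 1L)]
    res[inside] <- v00 * (1 - fx[inside]) * (1 - fy[inside]) +
      v01 * fx[inside] * (1 - fy[inside]) +
      v10 * (1 - fx[inside]) * fy[inside] +
      v11 * fx[inside] * fy[inside]
    out[, , c] <- res
  }
  clamp(out, 0, 255)
}

op_flip <- function(img, mag, bins, sign) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]

op_solarize <- function(img, mag, bins, sign) {
  threshold <- 255 * (1 - mag / bins)
  inv <- img >= threshold
  img[inv] <- 255 - img[inv]
  img
}

op_posterize <- function(img, mag, bins, sign) {
  bits <- 8L - as.integer(round(4 * mag / bins))
  step <- 2^(8L - bits)
  clamp(floor(img / step) * step, 0, 255)
}

op_color <- function(img, mag, bins, sign) {
  f <- 1 + 0.9 * mag / bins * sign
  gray <- luminance(img)
  base <- array(rep(gray, 3L), dim = dim(img))
  blend(base, img, f)
}

op_contrast <- function(img, mag, bins, sign) {
  f <- 1 + 0.9 * mag / bins * sign
  blend(mean(luminance(img)), img, f)
}

op_brightness <- function(img, mag, bins, sign) {
  f <- 1 + 0.9 * mag / bins * sign
  blend(0, img, f)
}

op_sharpness <- function(img, mag, bins, sign) {
  f <- 1 + 0.9 * mag / bins * sign
  H <- dim(img)[1]; W <- dim(img)[2]
  sm <- img
  if (H >= 3 && W >= 3) {
    # 3x3 smoothing kernel [[1,1,1],[1,5,1],[1,1,1]]/13 on the interior
    for (c in 1:3) {
      ch <- img[, , c]
      pad <- ch
      inner <- (pad[1:(H - 2), 1:(W - 2)] + pad[1:(H - 2), 2:(W - 1)] + pad[1:(H - 2), 3:W] +
                pad[2:(H - 1), 1:(W - 2)] + 5 * pad[2:(H - 1), 2:(W - 1)] + pad[2:(H - 1), 3:W] +
                pad[3:H, 1:(W - 2)] + pad[3:H, 2:(W - 1)] + pad[3:H, 3:W]) / 13
      smc <- ch
      smc[2:(H - 1), 2:(W - 1)] <- inner
      sm[, , c] <- smc
    }
  }
  blend(sm, img, f)
}

#' The random-enhancement operation pool
#'
#' Named list of the image operations one of which is drawn at each
#' enhancement step: auto-contrast, histogram equalization, rotation,
#' horizontal flip, solarize, posterize (the exposure-adjustment pair),
#' color balance, contrast, brightness and sharpening. Each takes
#' `(img, magnitude, magnitude_bins, sign)` on a `[0, 255]` array and
#' returns an array in the same range.
#'
#' @return Named list of functions.
#' @export
enhancement_pool <- function() {
  list(
    autocontrast = op_autocontrast,
    equalize = op_equalize,
    rotate = op_rotate,
    flip = op_flip,
    solarize = op_solarize,
    posterize = op_posterize,
    color = op_color,
    contrast = op_contrast,
    brightness = op_brightness,
    sharpness = op_sharpness
  )
}

standardize <- function(img) {
  out <- img / 255
  for (c in 1:3) out[, , c] <- (out[, , c] - IMAGENET_MEAN[c]) / IMAGENET_STD[c]
  out
}

random_erase <- function(img, area_range) {
  H <- dim(img)[1]; W <- dim(img)[2]
  for (attempt in 1:100) {
    frac <- stats::runif(1, area_range[1], area_range[2])
    aspect <- exp(stats::runif(1, log(0.3), log(1 / 0.3)))
    eh <- as.integer(round(sqrt(frac * H * W * aspect)))
    ew <- as.integer(round(sqrt(frac * H * W / aspect)))
    if (eh < 1L || ew < 1L || eh > H || ew > W) next
    got <- eh * ew / (H * W)
    if (got < area_range[1] || got > area_range[2]) next
    y <- sample.int(H - eh + 1L, 1L)
    x <- sample.int(W - ew + 1L, 1L)
    img[y:(y + eh - 1L), x:(x + ew - 1L), ] <-
      array(stats::runif(eh * ew * 3, 0, 255), dim = c(eh, ew, 3))
    attr(img, "erased") <- c(y = y, x = x, h = eh, w = ew)
    return(img)
  }
  img
}

#' Training-time preprocessing of one image
#'
#' Bicubic resize to `cfg$target_size`, random horizontal flip, then
#' `cfg$n_rand_ops` operations drawn uniformly (with replacement) from
#' [enhancement_pool()] at magnitude `cfg$magnitude`, then random erasing
#' with probability `cfg$erase_prob`, then per-channel standardization
#' using the ImageNet mean/std convention.
#'
#' @param pixels H x W x 3 array in `[0, 255]` (H, W >= 8).
#' @param cfg An [augment_config()].
#' @param seed Optional integer; when given, the augmentation draws come
#'   from a temporary RNG stream seeded with it.
#' @return `target_size` x `target_size` x 3 standardized numeric array.
#' @export
preprocess_train <- function(pixels, cfg = augment_config(), seed = NULL) {
  run <- function() {
    img <- clamp(resize_bicubic(pixels, cfg$target_size), 0, 255)
    if (stats::runif(1) < cfg$hflip_prob) {
      img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
    }
    pool <- enhancement_pool()
    if (cfg$n_rand_ops > 0L) {
      for (k in seq_len(cfg$n_rand_ops)) {
        op <- pool[[sample.int(length(pool), 1L)]]
        sign <- if (stats::runif(1) < 0.5) -1 else 1
        img <- op(img, cfg$magnitude, cfg$magnitude_bins, sign)
      }
    }
    if (stats::runif(1) < cfg$erase_prob) {
      img <- random_erase(img, cfg$erase_area)
    }
    erased <- attr(img, "erased")
    out <- standardize(img)
    attr(out, "erased") <- erased
    out
  }
  if (is.null(seed)) run() else with_seed(as.integer(seed), run())
}

#' Evaluation-time preprocessing of one image
#'
#' Deterministic bicubic resize plus per-channel standardization.
#'
#' @param pixels H x W x 3 array in `[0, 255]`.
#' @param target_size Output side length.
#' @return `target_size` x `target_size` x 3 standardized numeric array.
#' @export
preprocess_eval <- function(pixels, target_size = 224L) {
  standardize(clamp(resize_bicubic(pixels, target_size), 0, 255))
}
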