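# Synthetic stained-cell image generation.
#
# Emulates single-cell microscopy crops: one elliptical cell body with a
# class-specific cytoplasm hue, a darker (possibly multi-lobed) nucleus and
# granular texture on a pale background. Class structure (hue, lobe count,
# nucleus size, granularity) and per-class image counts are fully
# configurable, so imbalanced fine-grained datasets can be emulated at any
# scale.

#' Define a synthetic cell class
#'
#' @param name Class name (used as the image-folder subdirectory).
#' @param count Number of images to generate for this class (positive).
#' @param hue Cytoplasm hue in degrees, in \[0, 360).
#' @param nucleus_lobes Number of nuclear lobes (>= 1); segmented
#'   granulocytes have several, blasts have one.
#' @param nucleus_fraction Fraction of the cell area occupied by the
#'   nucleus, in (0, 1).
#' @param granularity Standard deviation (in 8-bit intensity units) of the
#'   additive cytoplasmic texture noise; >= 0.
#' @return A `cell_class_spec` list.
#' @export
cell_class_spec <- function(name, count, hue, nucleus_lobes = 1L,
                            nucleus_fraction = 0.3, granularity = 6) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stopf("class name must be a non-empty string")
  }
  count <- as.integer(count)
  if (is.na(count) || count <= 0L) {
    stopf("class '%s': count must be a positive integer", name)
  }
  if (hue < 0 || hue >= 360) stopf("class '%s': hue must be in [0, 360)", name)
  nucleus_lobes <- as.integer(nucleus_lobes)
  if (nucleus_lobes < 1L) stopf("class '%s': nucleus_lobes must be >= 1", name)
  if (nucleus_fraction <= 0 || nucleus_fraction >= 1) {
    stopf("class '%s': nucleus_fraction must be in (0, 1)", name)
  }
  if (granularity < 0) stopf("class '%s': granularity must be >= 0", name)
  structure(
    list(name = name, count = count, hue = hue,
         nucleus_lobes = nucleus_lobes, nucleus_fraction = nucleus_fraction,
         granularity = granularity),
    class = "cell_class_spec"
  )
}

#' Default class specifications mirroring an imbalanced 10-class blood smear
#'
#' Ten classes whose training-set counts follow the canonical imbalanced
#' profile (800, 435, 800, 800, 678, 315, 800, 280, 165, 310) scaled by
#' `scale`, with hues spread around the red-to-violet range typical of
#' Romanowsky-type stains and lobe counts increasing with granulocyte
#' maturation.
#'
#' @param scale Divisor applied to the reference counts (counts are
#'   rounded down, minimum 1).
#' @return List of [cell_class_spec()] objects.
#' @export
default_cell_specs <- function(scale = 5) {
  counts <- c(NGS = 800, NGB = 435, LYT = 800, MON = 800, EOS = 678,
              BAS = 315, MYO = 800, PMO = 280, MYB = 165, EBO = 310)
  hues <- c(300, 280, 220, 200, 20, 260, 320, 340, 240, 0)
  lobes <- c(4L, 2L, 1L, 1L, 2L, 2L, 1L, 1L, 1L, 1L)
  nf <- c(0.35, 0.4, 0.6, 0.45, 0.35, 0.4, 0.55, 0.5, 0.5, 0.65)
  gr <- c(4, 4, 2, 3, 12, 14, 2, 8, 5, 2)
  lapply(seq_along(counts), function(i) {
    cell_class_spec(names(counts)[i], max(1L, round(counts[i] / scale)),
                    hues[i], lobes[i], nf[i], gr[i])
  })
}

hsv255 <- function(h, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv((h %% 360) / 360, s, v)))
}

# Render one cell image as an S x S x 3 integer array in [0, 255].
# Consumes the current RNG stream (callers seed it).
render_cell_image <- function(size, spec) {
  S <- size
  xs <- matrix(rep(seq_len(S), each = S), nrow = S)   # column index
  ys <- matrix(rep(seq_len(S), times = S), nrow = S)  # row index

  # pale background with mild vignette-free sensor noise
  img <- array(0, dim = c(S, S, 3))
  bg <- c(244, 240, 246) + stats::runif(3, -4, 4)
  for (c in 1:3) img[, , c] <- bg[c] + matrix(stats::rnorm(S * S, 0, 2.5), S, S)

  # elliptical cell body
  cx <- S / 2 + stats::runif(1, -0.05, 0.05) * S
  cy <- S / 2 + stats::runif(1, -0.05, 0.05) * S
  a <- S * stats::runif(1, 0.28, 0.38)
  b <- S * stats::runif(1, 0.28, 0.38)
  phi <- stats::runif(1, 0, pi)
  dx <- xs - cx
  dy <- ys - cy
  u <- (dx * cos(phi) + dy * sin(phi)) / a
  v <- (-dx * sin(phi) + dy * cos(phi)) / b
  cell <- u^2 + v^2 <= 1

  cyto <- hsv255(spec$hue + stats::runif(1, -8, 8),
                 stats::runif(1, 0.4, 0.55), stats::runif(1, 0.72, 0.82))
  for (c in 1:3) {
    ch <- img[, , c]
    ch[cell] <- cyto[c]
    if (spec$granularity > 0) {
      ch[cell] <- ch[cell] + stats::rnorm(sum(cell), 0, spec$granularity)
    }
    img[, , c] <- ch
  }

  # nucleus: `nucleus_lobes` disks totalling nucleus_fraction of the cell area
  lob <- spec$nucleus_lobes
  r_lobe <- sqrt(spec$nucleus_fraction * a * b / lob)
  ring <- if (lob == 1L) 0 else 0.5 * sqrt(a * b)
  ang0 <- stats::runif(1, 0, 2 * pi)
  nuc_col <- hsv255(spec$hue + 25 + stats::runif(1, -5, 5),
                    stats::runif(1, 0.6, 0.7), stats::runif(1, 0.3, 0.4))
  for (k in seq_len(lob)) {
    ang <- ang0 + 2 * pi * (k - 1) / lob
    ncx <- cx + ring * cos(ang)
    ncy <- cy + ring * sin(ang)
    nuc <- (xs - ncx)^2 + (ys - ncy)^2 <= r_lobe^2
    nuc <- nuc & cell
    for (c in 1:3) {
      ch <- img[, , c]
      ch[nuc] <- nuc_col[c] + stats::rnorm(sum(nuc), 0, 3)
      img[, , c] <- ch
    }
  }

  storage.mode(img) <- "double"
  array(as.integer(round(clamp(img, 0, 255))), dim = dim(img))
}

circ_dist <- function(h1, h2) {
  d <- abs(h1 - h2) %% 360
  pmin(d, 360 - d)
}

#' Generate a labeled synthetic cell-image dataset
#'
#' Deterministic for a given `(specs, seed)` pair: images are rendered from
#' a seeded RNG stream, and the caller's RNG state is left untouched.
#'
#' @param specs List of [cell_class_spec()] objects (at least 2 classes).
#' @param image_size_range Integer `(min, max)` side lengths; each image is
#'   square with a side drawn uniformly from this range.
#' @param seed Integer seed controlling all randomness.
#' @param split_fractions Named fractions for split assignment; must sum
#'   to 1. Default 0.8 train / 0.2 val.
#' @param min_hue_separation Minimum circular hue distance (degrees)
#'   required between every pair of classes, so classes stay learnable.
#' @return List of image records, each
#'   `list(pixels = HxWx3 integer array in [0,255], label = 1-based class
#'   index, class = name, split = "train"|"val"|"test")`.
#' @export
generate_dataset <- function(specs, image_size_range = c(64L, 256L), seed = 1L,
                             split_fractions = c(train = 0.8, val = 0.2),
                             min_hue_separation = 15) {
  if (length(specs) < 2L) stopf("need at least 2 classes, got %d", length(specs))
  ok <- vapply(specs, inherits, logical(1), "cell_class_spec")
  if (!all(ok)) stopf("all specs must be cell_class_spec objects")
  hues <- vapply(specs, `[[`, numeric(1), "hue")
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stopf("class names must be unique")
  for (i in seq_along(hues)) {
    for (j in seq_len(i - 1L)) {
      if (circ_dist(hues[i], hues[j]) < min_hue_separation) {
        stopf("classes '%s' and '%s' have hue separation %.1f < %.1f",
              nm[i], nm[j], circ_dist(hues[i], hues[j]), min_hue_separation)
      }
    }
  }
  if (abs(sum(split_fractions) - 1) > 1e-8) {
    stopf("split_fractions must sum to 1")
  }
  lo <- as.integer(image_size_range[1])
  hi <- as.integer(image_size_range[2])
  if (lo < 32L || hi < lo) stopf("image_size_range must satisfy 32 <= min <= max")

  with_seed(as.integer(seed), {
    records <- list()
    for (ci in seq_along(specs)) {
      sp <- specs[[ci]]
      for (i in seq_len(sp$count)) {
        size <- if (lo == hi) lo else sample(lo:hi, 1L)
        split <- sample(names(split_fractions), 1L, prob = split_fractions)
        records[[length(records) + 1L]] <- list(
          pixels = render_cell_image(size, sp),
          label = ci,
          class = sp$name,
          split = split
        )
      }
    }
    records
  })
}

#' Write image records to a one-folder-per-class tree
#'
#' Layout: `root/<class_name>/<file>.png`, plus a `splits.csv` with columns
#' `(path, label, split)` recording split assignments.
#'
#' @param records List of image records from [generate_dataset()].
#' @param root_path Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_image_folder <- function(records, root_path) {
  if (length(records) == 0L) stopf("no records to write")
  dir.create(root_path, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(records))
  counters <- new.env(parent = emptyenv())
  for (i in seq_along(records)) {
    r <- records[[i]]
    cls_dir <- file.path(root_path, r$class)
    dir.create(cls_dir, showWarnings = FALSE)
    n <- (get0(r$class, envir = counters) %||% 0L) + 1L
    assign(r$class, n, envir = counters)
    fn <- file.path(r$class, sprintf("%s_%05d.png", r$class, n))
    png::writePNG(r$pixels / 255, file.path(root_path, fn))
    paths[i] <- fn
  }
  splits <- data.frame(
    path = paths,
    label = vapply(records, `[[`, integer(1), "label"),
    split = vapply(records, `[[`, character(1), "split"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(splits, file.path(root_path, "splits.csv"),
                   row.names = FALSE)
  invisible(paths)
}

#' Read an image-folder tree back into image records
#'
#' Subdirectories of `root_path` (sorted by name) define the class
#' vocabulary. Non-image files are skipped with a message; empty class
#' folders produce a warning and are skipped. If a `splits.csv` is present
#' its split assignments are attached, otherwise every record is "train".
#'
#' @param root_path Directory written by [write_image_folder()] or any
#'   folder-per-class PNG tree.
#' @return List of image records (see [generate_dataset()]).
#' @export
read_image_folder <- function(root_path) {
  if (!dir.exists(root_path)) stopf("directory '%s' does not exist", root_path)
  classes <- sort(list.dirs(root_path, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) stopf("no class subfolders under '%s'", root_path)

  split_map <- NULL
  sp_file <- file.path(root_path, "splits.csv")
  if (file.exists(sp_file)) {
    sp <- utils::read.csv(sp_file, stringsAsFactors = FALSE)
    split_map <- stats::setNames(sp$split, sp$path)
  }

  records <- list()
  for (ci in seq_along(classes)) {
    cls_dir <- file.path(root_path, classes[ci])
    files <- sort(list.files(cls_dir, full.names = FALSE))
    n_read <- 0L
    for (f in files) {
      rel <- file.path(classes[ci], f)
      px <- tryCatch(
        png::readPNG(file.path(cls_dir, f)),
        error = function(e) NULL
      )
      if (is.null(px)) {
        message(sprintf("skipping non-image file: %s", rel))
        next
      }
      if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
      px <- px[, , 1:3, drop = FALSE]
      pixels <- array(as.integer(round(px * 255)), dim = dim(px))
      split <- if (!is.null(split_map) && !is.na(split_map[rel])) {
        unname(split_map[rel])
      } else {
        "train"
      }
      records[[length(records) + 1L]] <- list(
        pixels = pixels, label = ci, class = classes[ci], split = split
      )
      n_read <- n_read + 1L
    }
    if (n_read == 0L) {
      warning(sprintf("class folder '%s' contains no readable images; skipped",
                      classes[ci]), call. = FALSE)
    }
  }
  records
}

#' Split records by their split tag
#' @param records List of image records.
#' @param split Split name ("train", "val" or "test").
#' @return The subset of records with that tag.
#' @export
records_split <- function(records, split) {
  Filter(function(r) identical(r$split, split), records)
}
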