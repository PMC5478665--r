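#' Size classes for puncta area distributions
#'
#' Default edges 0.45 and 0.9 um^2 split endosome areas into small
#' (< 0.45), median (0.45-0.9, closed interval) and large (> 0.9) classes.
#' Arbitrary increasing edges (e.g. for soma-area histograms) are allowed;
#' an area exactly equal to an internal edge is assigned to the class below
#' it, so both default edges fall in the median class.
#'
#' @param edges Strictly increasing positive numeric vector of class edges.
#' @param labels Class labels, `length(edges) + 1`.
#' @return An object of class `size_bins`.
#' @export
size_bins <- function(edges = c(0.45, 0.9),
                      labels = if (length(edges) == 2)
                        c("small", "median", "large")
                      else paste0("class_", seq_len(length(edges) + 1))) {
  if (!is.numeric(edges) || length(edges) < 1 || any(edges <= 0) ||
      is.unsorted(edges, strictly = TRUE)) {
    stop("'edges' must be strictly increasing positive numbers",
         call. = FALSE)
  }
  if (length(labels) != length(edges) + 1) {
    stop("need one more label than edges", call. = FALSE)
  }
  structure(list(edges = edges, labels = labels), class = "size_bins")
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged with a small union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  nr <- nrow(lab)
  nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    parent <- seq_len(nlab)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1])
      b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    roots <- vapply(seq_len(nlab), find, numeric(1))
    compact <- match(roots, sort(unique(roots)))
    lab[lab > 0] <- compact[lab[lab > 0]]
  }
  lab
}

#' Segment fluorescent objects and measure calibrated areas
#'
#' Global Otsu threshold, 8-connected component labelling, removal of
#' objects below `min_area_px`, and per-object area calibration
#' (`pixel count x pixel_size^2`).
#'
#' @param image Single-channel nonnegative numeric matrix.
#' @param pixel_size Calibration, um per px.
#' @param min_area_px Minimum object size in pixels (default 4; suppresses
#'   single-pixel noise).
#' @param threshold Optional manual threshold in image intensity units;
#'   overrides Otsu.
#' @return Data frame of puncta records: `id`, `area_px`, `area_um2`,
#'   `centroid_x`, `centroid_y`, `mean_intensity`. Zero rows (with a
#'   warning) for a constant image, where the Otsu threshold is undefined.
#' @export
segment_objects <- function(image, pixel_size, min_area_px = 4,
                            threshold = NULL) {
  image <- as.matrix(image)
  if (!is.numeric(image) || any(image < 0)) {
    stop("'image' must be a nonnegative numeric matrix", call. = FALSE)
  }
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  empty <- data.frame(id = integer(0), area_px = numeric(0),
                      area_um2 = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), mean_intensity = numeric(0))
  rng <- range(image)
  if (diff(rng) == 0) {
    warning("constant image: Otsu threshold undefined, no objects")
    return(empty)
  }
  if (is.null(threshold)) {
    x01 <- (image - rng[1]) / diff(rng)
    th01 <- EBImage::otsu(x01, range = c(0, 1))
    mask <- x01 > th01
  } else {
    mask <- image > threshold
  }
  if (!any(mask)) return(empty)
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  if (!length(keep)) return(empty)
  idx <- which(lab > 0)
  li <- lab[idx]
  rows <- (idx - 1) %% nrow(lab) + 1
  cols <- (idx - 1) %/% nrow(lab) + 1
  recs <- lapply(seq_along(keep), function(k) {
    l <- keep[k]
    sel <- li == l
    data.frame(id = k, area_px = sizes[l],
               area_um2 = sizes[l] * pixel_size^2,
               centroid_x = mean(cols[sel]), centroid_y = mean(rows[sel]),
               mean_intensity = mean(image[idx[sel]]))
  })
  do.call(rbind, recs)
}

#' Bin calibrated areas into size-class frequencies
#'
#' @param areas Numeric vector of areas (um^2), or a puncta record data
#'   frame with an `area_um2` column.
#' @param bins A [size_bins()] object.
#' @return Data frame with `class`, `count` and `percent`; percentages sum
#'   to exactly 100 (the last class absorbs the floating-point remainder).
#' @export
bin_areas <- function(areas, bins = size_bins()) {
  stopifnot(inherits(bins, "size_bins"))
  if (is.data.frame(areas)) areas <- areas$area_um2
  if (!length(areas)) stop("no areas to bin", call. = FALSE)
  if (any(!is.finite(areas)) || any(areas <= 0)) {
    stop("areas must be positive and finite", call. = FALSE)
  }
  idx <- findInterval(areas, bins$edges) + 1L
  # closed upper boundaries: an exact hit on edge j >= 2 stays in class j
  for (j in seq_along(bins$edges)[-1]) idx[areas == bins$edges[j]] <- j
  counts <- tabulate(idx, nbins = length(bins$labels))
  percent <- 100 * counts / sum(counts)
  k <- length(percent)
  percent[k] <- 100 - sum(percent[-k])
  data.frame(class = bins$labels, count = counts, percent = percent,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic puncta image with ground truth
#'
#' Places `n_objects` non-overlapping anti-aliased disks, applies a
#' Gaussian edge blur and additive Gaussian noise, and returns both the
#' image and the ground-truth records (centre, radius, true area) for
#' oracle tests. Deterministic given `seed`.
#'
#' @param n_objects Number of disks (0 allowed: blank image, empty truth).
#' @param radius_px Disk radii in px: a vector (recycled to `n_objects`) or
#'   a function `f(n)` drawing `n` radii.
#' @param image_size `c(rows, cols)` of the canvas.
#' @param pixel_size um per px (default 0.1, a typical 100x calibration).
#' @param amplitude Disk intensity above background.
#' @param background Background intensity.
#' @param noise_sd Additive Gaussian noise sigma.
#' @param blur_sigma Gaussian edge blur sigma, px.
#' @param seed Integer seed.
#' @param max_tries Placement attempts per object before giving up.
#' @return List with `image` (matrix), `truth` (data frame: `id`, `x`, `y`,
#'   `radius_px`, `area_um2`) and `pixel_size`.
#' @export
generate_puncta_image <- function(n_objects, radius_px = 5,
                                  image_size = c(256, 256), pixel_size = 0.1,
                                  amplitude = 1, background = 0.05,
                                  noise_sd = 0.02, blur_sigma = 1,
                                  seed = 1, max_tries = 2000) {
  check_number(n_objects, "n_objects", lower = 0)
  h <- image_size[1]
  w <- image_size[2]
  run_seeded(seed, {
    radii <- if (is.function(radius_px)) radius_px(n_objects)
             else rep_len(radius_px, max(n_objects, 1))[seq_len(n_objects)]
    if (n_objects > 0 && any(radii <= 0)) {
      stop("radii must be positive", call. = FALSE)
    }
    xs <- ys <- numeric(0)
    for (i in seq_len(n_objects)) {
      m <- radii[i] + 3 * blur_sigma + 2
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        x <- stats::runif(1, m, w - m)
        y <- stats::runif(1, m, h - m)
        if (!length(xs) ||
            all(sqrt((xs - x)^2 + (ys - y)^2) >
                radii[i] + radii[seq_along(xs)] + 2 * blur_sigma + 2)) {
          xs <- c(xs, x)
          ys <- c(ys, y)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place ", n_objects, " non-overlapping objects ",
             "after ", max_tries, " tries (object ", i, ")", call. = FALSE)
      }
    }
    img <- matrix(0, h, w)
    for (i in seq_len(n_objects)) {
      r <- radii[i]
      jx <- max(1, floor(xs[i] - r - 2)):min(w, ceiling(xs[i] + r + 2))
      iy <- max(1, floor(ys[i] - r - 2)):min(h, ceiling(ys[i] + r + 2))
      d <- sqrt(outer((iy - ys[i])^2, (jx - xs[i])^2, "+"))
      img[iy, jx] <- img[iy, jx] + amplitude * pmin(1, pmax(0, r + 0.5 - d))
    }
    if (blur_sigma > 0) {
      img <- EBImage::imageData(EBImage::gblur(img, sigma = blur_sigma))
    }
    img <- img + background
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, sd = noise_sd), h, w)
    }
    img <- pmax(img, 0)
    truth <- if (n_objects == 0) {
      data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                 radius_px = numeric(0), area_um2 = numeric(0))
    } else {
      data.frame(id = seq_len(n_objects), x = xs, y = ys, radius_px = radii,
                 area_um2 = pi * radii^2 * pixel_size^2)
    }
    list(image = img, truth = truth, pixel_size = pixel_size)
  })
}
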