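# Segmentation and nine-feature morphometry of label-free images.
#
# Conventions (fixed across the package):
#  - foreground connectivity 8, hole/background connectivity 4;
#  - perimeter = length of the simplified outer pixel-edge outline polygon
#    of the hole-filled object (hole boundaries excluded): exact 4k for a
#    filled axis-aligned k x k square, ~2*pi*r for a rasterized disk;
#  - fiber length/breadth from the ribbon model x^2 - (P/2) x + A = 0 with
#    the discriminant clamped at zero for circle-like objects.

as_pixels <- function(image) {
  if (inherits(image, "image_record")) image$pixels else {
    stopifnot(is.matrix(image))
    image
  }
}

#' Binarize an image at a threshold and label connected objects
#'
#' Foreground is `pixels > threshold`; objects are 8-connected components.
#'
#' @param image An `image_record` or an intensity matrix.
#' @param threshold Intensity cut in `[0, 255]`.
#' @return Integer label matrix (0 = background) with attribute
#'   `n_objects`.
#' @export
binarize_and_label <- function(image, threshold) {
  px <- as_pixels(image)
  if (threshold < 0 || threshold > 255)
    stop("threshold must lie in [0, 255]")
  .cc_label(px > threshold, 8L)
}

# Douglas-Peucker simplification of an open polyline (matrix of points);
# returns indices of retained vertices. Iterative stack formulation.
dp_simplify <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2) return(seq_len(n))
  keep <- logical(n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    len2 <- sum(ab^2)
    mid <- (i + 1):(j - 1)
    dy <- pts[mid, 1] - a[1]; dx <- pts[mid, 2] - a[2]
    d <- if (len2 == 0) sqrt(dy^2 + dx^2) else
      abs(dy * ab[2] - dx * ab[1]) / sqrt(len2)
    k <- which.max(d)
    if (d[k] > eps) {
      km <- mid[k]
      keep[km] <- TRUE
      stack <- c(stack, list(c(i, km)), list(c(km, j)))
    }
  }
  which(keep)
}

# Outer-boundary perimeter of a filled (hole-free) mask: the pixel-edge
# outline cycle is simplified by cyclic Douglas-Peucker (eps = 1.2 px, just
# above the half-diagonal staircase oscillation) and the simplified
# polygon's length is returned. Exact on axis-aligned rectangles (a 20x20
# square gives 80, since straight runs deviate 0 from their chord) and
# convergent to the true contour length on smooth shapes (a rasterized disk
# gives ~2*pi*r, so its shape factor approaches 1 with resolution).
outer_perimeter <- function(filled) {
  pts <- .trace_outline(filled)
  pts <- pts[-nrow(pts), , drop = FALSE]  # drop closing duplicate
  n <- nrow(pts)
  if (n <= 3) {
    poly <- rbind(pts, pts[1, ])
    return(sum(sqrt(rowSums((poly[-1, , drop = FALSE] -
                               poly[-nrow(poly), , drop = FALSE])^2))))
  }
  # anchor the cyclic simplification at the start vertex (an extreme point)
  # and the vertex farthest from it
  d0 <- (pts[, 1] - pts[1, 1])^2 + (pts[, 2] - pts[1, 2])^2
  far <- which.max(d0)
  chain1 <- pts[1:far, , drop = FALSE]
  chain2 <- pts[c(far:n, 1), , drop = FALSE]
  k1 <- dp_simplify(chain1, 1.2)
  k2 <- dp_simplify(chain2, 1.2)
  poly <- rbind(chain1[k1, , drop = FALSE],
                chain2[k2[-1], , drop = FALSE])
  sum(sqrt(rowSums((poly[-1, , drop = FALSE] -
                      poly[-nrow(poly), , drop = FALSE])^2)))
}

# Minimum Feret diameter (minimum caliper width over rotation) of a set of
# pixel centres, in pixel units: min over angles of projected extent + 1.
min_feret <- function(rows, cols, step_deg = 1) {
  ang <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  ca <- cos(ang); sa <- sin(ang)
  # boundary of the convex set determines the caliper; using all points is
  # correct, just use range of projections
  w <- vapply(seq_along(ang), function(i) {
    p <- rows * ca[i] + cols * sa[i]
    diff(range(p))
  }, numeric(1))
  min(w) + 1
}

#' Measure the nine morphological features of a single object
#'
#' @param mask Logical (or 0/1) matrix containing exactly one 8-connected
#'   foreground object.
#' @param pixel_size Physical length per pixel; lengths scale linearly and
#'   areas quadratically with it. Default 1 (units = pixels).
#' @return One-row data frame with columns `breadth`,
#'   `elliptical_form_factor`, `fiber_breadth`, `fiber_length`,
#'   `hole_area`, `inner_radius`, `relative_hole_area`, `shape_factor`,
#'   `total_area`.
#'
#' @details
#' With `A` the hole-filled pixel area and `P` the outer-boundary perimeter:
#' shape factor is `4*pi*A/P^2` clamped to at most 1; fiber length is
#' `(P + sqrt(max(0, P^2 - 16 A))) / 4` and fiber breadth `A / fiber
#' length`, capped at the fiber length for circle-like objects whose
#' ribbon discriminant clamps at zero; breadth is the minimum Feret
#' (caliper) diameter; elliptical
#' form factor is the axis ratio of the equal-second-moment ellipse (pixel
#' variance corrected); inner radius is the maximum of the Euclidean
#' distance transform of the filled object; hole area is the enclosed
#' background area and relative hole area its fraction of the total area.
#' @export
measure_object <- function(mask, pixel_size = 1) {
  if (!is.logical(mask)) mask <- mask > 0
  if (!any(mask)) stop("empty mask: no object to measure")
  lab <- .cc_label(mask, 8L)
  if (attr(lab, "n_objects") != 1)
    stop("mask must contain exactly one 8-connected object, found ",
         attr(lab, "n_objects"))
  filled <- .cc_fill_holes(mask)
  A_px <- sum(filled)
  hole_px <- A_px - sum(mask)
  P_px <- outer_perimeter(filled)

  idx <- which(filled, arr.ind = TRUE)
  rows <- idx[, 1]; cols <- idx[, 2]

  # equal-second-moment ellipse axis ratio; +1/12 treats pixels as unit
  # squares so a single pixel is a unit square, not a point
  mu20 <- mean((rows - mean(rows))^2) + 1 / 12
  mu02 <- mean((cols - mean(cols))^2) + 1 / 12
  mu11 <- mean((rows - mean(rows)) * (cols - mean(cols)))
  comm <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  eff <- sqrt((mu20 + mu02 + comm) / max(mu20 + mu02 - comm, 1e-12))

  # pad with a background ring: the crop edge counts as outside the object
  padded <- matrix(0, nrow(filled) + 2, ncol(filled) + 2)
  padded[2:(nrow(filled) + 1), 2:(ncol(filled) + 1)] <- filled
  inner <- max(EBImage::distmap(padded))

  disc <- max(0, P_px^2 - 16 * A_px)
  fl <- (P_px + sqrt(disc)) / 4
  # ribbon-model companion root; for circle-like objects the clamped
  # discriminant makes A/fl exceed fl, so the double root fl is used
  fb <- min(A_px / fl, fl)

  data.frame(
    breadth = min_feret(rows, cols) * pixel_size,
    elliptical_form_factor = eff,
    fiber_breadth = fb * pixel_size,
    fiber_length = fl * pixel_size,
    hole_area = hole_px * pixel_size^2,
    inner_radius = inner * pixel_size,
    relative_hole_area = hole_px / A_px,
    shape_factor = min(1, 4 * pi * A_px / P_px^2),
    total_area = A_px * pixel_size^2
  )
}

#' Remove noise objects by size and border contact
#'
#' Drops objects with `total_area < min_area` and objects touching the
#' image border; retained row order is preserved.
#'
#' @param objects Data frame of object measurements with a `total_area`
#'   column and (optionally) a logical `touches_border` column.
#' @param min_area Minimum retained object area (same units as
#'   `total_area`).
#' @return The filtered data frame.
#' @export
filter_noise <- function(objects, min_area = 0) {
  stopifnot(min_area >= 0, "total_area" %in% names(objects))
  keep <- objects$total_area >= min_area
  if ("touches_border" %in% names(objects))
    keep <- keep & !objects$touches_border
  objects[keep, , drop = FALSE]
}

# Fast object counting used by threshold calibration: label, size-filter,
# border-filter. Returns the retained object count.
count_objects <- function(pixels, threshold, min_area) {
  lab <- .cc_label(pixels > threshold, 8L)
  n <- attr(lab, "n_objects")
  if (n == 0) return(0L)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  keep <- sizes >= min_area
  keep[border] <- FALSE
  sum(keep)
}

#' Calibrate the universal binarization threshold
#'
#' Selects, from a candidate grid, the single threshold that minimises the
#' total absolute error between automatic object counts and manually
#' determined cell numbers over a set of calibration images (the study
#' design uses 30 images picked randomly from all lots and time points).
#' Ties are broken by the (lower) median element of the argmin set, i.e.
#' the centre of the stable plateau of the error curve.
#'
#' @param calibration_images List of `image_record`s or intensity matrices.
#' @param manual_counts Integer vector of reference cell counts, one per
#'   image.
#' @param candidate_grid Numeric vector of candidate thresholds.
#' @param min_area Minimum object area used by the noise filter during
#'   counting. If `NULL`, it is set to the 5th percentile of object areas
#'   observed in the calibration images at the median grid threshold.
#' @return The selected threshold (numeric scalar) with attributes
#'   `error_curve` (data frame: threshold, total_abs_error) and `min_area`.
#' @export
calibrate_universal_threshold <- function(calibration_images, manual_counts,
                                          candidate_grid, min_area = NULL) {
  if (length(candidate_grid) == 0) stop("candidate_grid must be non-empty")
  if (length(calibration_images) != length(manual_counts))
    stop("need one manual count per calibration image (got ",
         length(calibration_images), " images, ", length(manual_counts),
         " counts)")
  pixel_list <- lapply(calibration_images, as_pixels)
  if (is.null(min_area)) {
    t0 <- sort(candidate_grid)[ceiling(length(candidate_grid) / 2)]
    areas <- unlist(lapply(pixel_list, function(px) {
      lab <- .cc_label(px > t0, 8L)
      n <- attr(lab, "n_objects")
      if (n == 0) numeric(0) else tabulate(lab[lab > 0L], nbins = n)
    }))
    min_area <- if (length(areas)) unname(quantile(areas, 0.05)) else 0
  }
  grid <- sort(unique(candidate_grid))
  errs <- vapply(grid, function(t) {
    sum(vapply(seq_along(pixel_list), function(i)
      abs(count_objects(pixel_list[[i]], t, min_area) - manual_counts[i]),
      numeric(1)))
  }, numeric(1))
  argmin <- grid[errs == min(errs)]
  thr <- argmin[ceiling(length(argmin) / 2)]
  structure(thr,
            error_curve = data.frame(threshold = grid,
                                     total_abs_error = errs),
            min_area = min_area)
}

#' Segment and measure every cell object in one image
#'
#' Composition of [binarize_and_label()], [measure_object()] per object and
#' [filter_noise()]. The retained object count is the tenth feature.
#'
#' @param image An `image_record` or intensity matrix.
#' @param threshold Universal binarization threshold.
#' @param min_area Noise-filter minimum object area.
#' @param pixel_size Physical length per pixel (default 1).
#' @return An `image_morphology`: list with the image metadata, `objects`
#'   (data frame: `object_id`, nine features, `touches_border`) and
#'   `object_count` (retained objects after noise filtering).
#' @export
measure_image <- function(image, threshold, min_area = 50, pixel_size = 1) {
  px <- as_pixels(image)
  lab <- binarize_and_label(px, threshold)
  n <- attr(lab, "n_objects")
  nr <- nrow(px); nc <- ncol(px)
  rows_out <- vector("list", n)
  if (n > 0) {
    idx_all <- which(lab > 0L, arr.ind = TRUE)
    labs <- lab[idx_all]
    ord <- order(labs)
    idx_all <- idx_all[ord, , drop = FALSE]
    labs <- labs[ord]
    starts <- c(1, which(diff(labs) > 0) + 1, length(labs) + 1)
    for (k in seq_len(n)) {
      sel <- starts[k]:(starts[k + 1] - 1)
      rr <- idx_all[sel, 1]; cc <- idx_all[sel, 2]
      r0 <- min(rr); r1 <- max(rr); c0 <- min(cc); c1 <- max(cc)
      sub <- matrix(FALSE, r1 - r0 + 1, c1 - c0 + 1)
      sub[cbind(rr - r0 + 1, cc - c0 + 1)] <- TRUE
      m <- measure_object(sub, pixel_size)
      m$object_id <- k
      m$touches_border <- r0 == 1 || c0 == 1 || r1 == nr || c1 == nc
      rows_out[[k]] <- m
    }
  }
  objects <- if (n > 0) do.call(rbind, rows_out) else
    cbind(data.frame(matrix(numeric(0), 0, length(MORPH_FEATURES),
                            dimnames = list(NULL, MORPH_FEATURES))),
          data.frame(object_id = integer(0), touches_border = logical(0)))
  objects <- objects[, c("object_id", MORPH_FEATURES, "touches_border")]
  retained <- filter_noise(objects, min_area * pixel_size^2)
  meta <- if (inherits(image, "image_record"))
    image[c("lot", "passage", "well", "field", "hour")] else
      list(lot = NA, passage = NA, well = NA, field = NA, hour = NA)
  structure(c(meta, list(objects = retained,
                         all_objects = objects,
                         object_count = nrow(retained),
                         threshold = threshold, min_area = min_area,
                         pixel_size = pixel_size)),
            class = "image_morphology")
}
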