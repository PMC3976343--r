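# Rendering the ground-truth morphology model to 8-bit grey-scale images.

CELL_LEVEL <- 195   # mean foreground intensity
BG_LEVEL <- 30      # background base intensity
TRUE_THRESHOLD <- 110L  # generative separation between cells and background

# Pixel mask of one lobed ellipse in its bounding box.
# Returns list(rows, cols, inside, inflated) or NULL if out of bounds.
cell_mask_at <- function(cx, cy, aa, bb, ro, th, ph1, ph2, shape, gap = 1.5) {
  R <- ceiling(aa * (1 + ro) + gap + 1)
  r0 <- round(cy) - R; r1 <- round(cy) + R
  c0 <- round(cx) - R; c1 <- round(cx) + R
  if (r0 < 1 || c0 < 1 || r1 > shape[1] || c1 > shape[2]) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  DY <- matrix(rows - cy, length(rows), length(cols))
  DX <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  u <- DX * cos(th) + DY * sin(th)
  v <- -DX * sin(th) + DY * cos(th)
  phi <- atan2(v, u)
  rell <- aa * bb / sqrt((bb * cos(phi))^2 + (aa * sin(phi))^2)
  rmod <- rell * (1 + ro * (0.6 * sin(2 * phi + ph1) +
                              0.4 * sin(3 * phi + ph2)))
  d2 <- u^2 + v^2
  list(rows = rows, cols = cols, u = u, v = v,
       inside = d2 <= rmod^2, inflated = d2 <= (rmod + gap)^2)
}

# Render one field of view. Cells are bright lobed ellipses on a dark noisy
# background. Placement is collision-checked on actual pixel occupancy
# (with a 2 px gap so 8-connected components never merge); a cell that
# cannot be placed raises an error rather than overlapping silently.
# Returns list(pixels = integer matrix, cells = data.frame of placed cells).
render_field <- function(cells, shape, noise_sd, n_speckles) {
  nr <- shape[1]; nc <- shape[2]
  img <- matrix(BG_LEVEL + rnorm(nr * nc, 0, noise_sd), nr, nc)
  occ <- matrix(FALSE, nr, nc)
  n <- nrow(cells)
  keep <- integer(0); xs <- numeric(0); ys <- numeric(0)
  if (n > 0) {
    aa_all <- sqrt(cells$area * cells$aspect / pi)
    bb_all <- sqrt(cells$area / (pi * cells$aspect))
    ord <- order(aa_all, decreasing = TRUE)  # big cells first: easier packing
    lv <- pmin(240, pmax(165, rnorm(n, CELL_LEVEL, 12)))
    th <- runif(n, 0, pi)
    ph1 <- runif(n, 0, 2 * pi); ph2 <- runif(n, 0, 2 * pi)
    for (i in ord) {
      aa <- aa_all[i]; bb <- bb_all[i]; ro <- cells$rough[i]
      if (2 * (aa * (1 + ro) + 4) > min(nr, nc))
        stop("image too small to place a cell of radius ", round(aa))
      placed_ok <- FALSE
      for (att in seq_len(2000)) {
        R <- aa * (1 + ro) + 3
        cy <- runif(1, R + 1, nr - R)
        cx <- runif(1, R + 1, nc - R)
        m <- cell_mask_at(cx, cy, aa, bb, ro, th[i], ph1[i], ph2[i], shape)
        if (is.null(m)) next
        if (any(occ[m$rows, m$cols] & m$inflated)) next
        sub <- img[m$rows, m$cols]
        sub[m$inside] <- lv[i]
        if (cells$hole_area[i] > 0) {
          rh <- sqrt(cells$hole_area[i] / pi)
          if (rh >= 1 && rh < 0.7 * bb) {
            hu <- runif(1, -0.3, 0.3) * bb; hv <- runif(1, -0.3, 0.3) * bb
            hole <- ((m$u - hu)^2 + (m$v - hv)^2) <= rh^2 & m$inside
            sub[hole] <- BG_LEVEL
          }
        }
        img[m$rows, m$cols] <- sub
        om <- occ[m$rows, m$cols]
        occ[m$rows, m$cols] <- om | m$inside
        keep <- c(keep, i); xs <- c(xs, cx); ys <- c(ys, cy)
        placed_ok <- TRUE
        break
      }
      if (!placed_ok)
        stop("image too small to place ", n,
             " requested cells without overlap")
    }
  }
  placed <- cells[keep, , drop = FALSE]
  if (length(keep)) { placed$x <- xs; placed$y <- ys }
  rownames(placed) <- NULL
  # small bright speckles: non-cell noise objects for the noise filter
  ns <- rpois(1, n_speckles)
  for (s in seq_len(ns)) {
    y <- sample(2:(nr - 2), 1); x <- sample(2:(nc - 2), 1)
    sz <- sample(1:3, 1)
    img[y:(y + sz - 1), x:(x + sz - 1)] <- 200
  }
  list(pixels = matrix(as.integer(pmin(255, pmax(0, round(img)))), nr, nc),
       cells = placed)
}

#' Generate the full synthetic phase-contrast image set
#'
#' Renders every field of view of the experimental design (lots x passages
#' x wells x fields x hours) as an 8-bit grey-scale image of bright,
#' non-overlapping lobed-ellipse cells on a dark noisy background, together
#' with complete per-image and per-cell ground truth. Cell counts grow
#' between time points according to each sample's true doubling time; the
#' per-cell shape distribution drifts with passage as configured.
#'
#' Each (lot, passage, well, field) has its own RNG stream derived from the
#' master seed, so a fixed seed yields byte-identical images.
#'
#' @param config An [synthetic_config()] object.
#' @param dir Output directory. If supplied, images are written as 8-bit
#'   grey-scale TIFF files named `lot{L}_p{P}_w{W}_f{F}_h{H}.tif` plus a
#'   `manifest.csv`, and pixel arrays are not kept in memory (use this for
#'   the full 1,920-image design). If `NULL`, pixel matrices are returned
#'   in the result (suitable for small configurations only).
#' @param progress Print a line per sample while rendering.
#' @return A list with `manifest` (one row per image: path, lot, passage,
#'   well, field, hour, n_cells), `images` (named list of integer pixel
#'   matrices when `dir` is `NULL`), `truth` (the
#'   [generate_morphology_truth()] model plus `threshold`, per-image
#'   realized counts and a per-cell table with true shape parameters), and
#'   `config`.
#' @export
generate_image_set <- function(config, dir = NULL, progress = FALSE) {
  validate_config(config)
  truth <- generate_morphology_truth(config)
  md <- config$morphology_drift
  lots <- LETTERS[seq_len(config$n_lots)]
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)

  n_total <- config$n_lots * length(config$passages) * config$n_wells *
    config$n_fields * length(config$hours)
  manifest <- data.frame(
    path = character(n_total), lot = character(n_total),
    passage = integer(n_total), well = integer(n_total),
    field = integer(n_total), hour = integer(n_total),
    n_cells = integer(n_total), stringsAsFactors = FALSE)
  images <- if (is.null(dir)) vector("list", n_total) else NULL
  cell_tabs <- vector("list", n_total)
  row <- 0L

  for (li in seq_along(lots)) {
    for (pp in config$passages) {
      sid <- sample_id(lots[li], pp)
      prm_s <- truth$params[truth$params$sample_id == sid, , drop = FALSE]
      if (progress) message("rendering ", sid)
      for (w in seq_len(config$n_wells)) {
        for (f in seq_len(config$n_fields)) {
          stream <- substream_seed(config$seed, 707, li, pp, w, f)
          res <- with_seed(stream, {
            lapply(config$hours, function(h) {
              prm <- prm_s[prm_s$hour == h, ]
              n <- rpois(1, prm$count_mean)
              cells <- draw_cells(n, prm, md)
              render_field(cells, config$image_shape, config$noise_sd,
                           config$n_speckles)
            })
          })
          for (hi in seq_along(config$hours)) {
            row <- row + 1L
            h <- config$hours[hi]
            name <- sprintf("lot%s_p%d_w%d_f%d_h%d", lots[li], pp, w, f, h)
            placed <- res[[hi]]$cells
            manifest[row, c("lot", "passage", "well", "field", "hour",
                            "n_cells")] <-
              list(lots[li], pp, w, f, h, nrow(placed))
            if (is.null(dir)) {
              images[[row]] <- res[[hi]]$pixels
              names(images)[row] <- name
            } else {
              path <- file.path(dir, paste0(name, ".tif"))
              tiff::writeTIFF(res[[hi]]$pixels / 255, path,
                              bits.per.sample = 8, compression = "none")
              manifest$path[row] <- path
            }
            if (nrow(placed) > 0) {
              placed$image <- name
              cell_tabs[[row]] <- placed
            }
          }
        }
      }
    }
  }
  if (!is.null(dir))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  truth$threshold <- TRUE_THRESHOLD
  truth$images <- manifest[, c("lot", "passage", "well", "field", "hour",
                               "n_cells")]
  truth$cells <- do.call(rbind, cell_tabs[!vapply(cell_tabs, is.null,
                                                  logical(1))])
  out <- list(manifest = manifest, truth = truth, config = config)
  if (is.null(dir)) out$images <- images
  out
}

#' Read one grey-scale image with its acquisition metadata
#'
#' @param path Path to an 8-bit grey-scale TIFF.
#' @param lot,passage,well,field,hour Acquisition metadata; parsed from the
#'   generator's file-name convention when omitted.
#' @return An `image_record`: list with `pixels` (integer matrix, 0-255)
#'   and the metadata fields.
#' @export
read_image_record <- function(path, lot = NULL, passage = NULL, well = NULL,
                              field = NULL, hour = NULL) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  meta <- regmatches(basename(path),
                     regexec("lot([^_]+)_p(\\d+)_w(\\d+)_f(\\d+)_h(\\d+)",
                             basename(path)))[[1]]
  if (length(meta) == 6 && is.null(lot)) {
    lot <- meta[2]; passage <- as.integer(meta[3]); well <- as.integer(meta[4])
    field <- as.integer(meta[5]); hour <- as.integer(meta[6])
  }
  image_record(matrix(as.integer(round(px * 255)), nrow(px), ncol(px)),
               lot = lot, passage = passage, well = well, field = field,
               hour = hour)
}

#' Construct an image record from a pixel matrix
#'
#' @param pixels Integer matrix of 8-bit intensities (0-255).
#' @param lot,passage,well,field,hour Optional acquisition metadata.
#' @return An object of class `image_record`.
#' @export
image_record <- function(pixels, lot = NA, passage = NA, well = NA,
                         field = NA, hour = NA) {
  stopifnot(is.matrix(pixels))
  if (length(pixels) && (min(pixels) < 0 || max(pixels) > 255))
    stop("pixel intensities must lie in [0, 255]")
  structure(list(pixels = pixels, lot = lot, passage = passage, well = well,
                 field = field, hour = hour), class = "image_record")
}
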