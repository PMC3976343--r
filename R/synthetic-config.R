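#' Configuration for the synthetic hBMSC dataset generator
#'
#' Bundles the experimental-design constants (lots, passages, wells, fields
#' of view, acquisition hours), the morphology drift model, the growth model
#' and the sparse teacher-signal model into a single validated object. The
#' defaults reproduce the full study design: 3 lots x 8 passages (P2-P9) x
#' 4 wells x 5 fields x 4 daily time points = 1,920 images, 24 samples.
#'
#' @param n_lots Number of donor cell lots.
#' @param passages Integer vector of passage numbers (default 2:9).
#' @param n_wells Replicate wells per sample.
#' @param n_fields Fields of view per well.
#' @param hours Acquisition schedule in hours, strictly increasing
#'   (default 24, 48, 72, 96).
#' @param image_shape Image dimensions in pixels, `c(rows, cols)`.
#' @param cells_per_field Expected cell count per field at the first
#'   acquisition (24 h). May be 0 for background-only images.
#' @param morphology_drift Named list of per-passage drift parameters; see
#'   Details. Any subset may be supplied, the remainder keep defaults.
#' @param growth_rate Named list with `pdt_start` (population doubling time
#'   in hours at the first passage) and `pdt_slope` (hours added per
#'   passage), plus `lot_sd` (log-scale lot-to-lot variability).
#' @param noise_sd Standard deviation of the additive background intensity
#'   noise (8-bit grey levels).
#' @param true_beta Named list with one named sparse coefficient vector per
#'   staining potential (`osteo`, `adipo`, `chondro`). Names refer to
#'   M-pattern 1 feature labels plus `"(Intercept)"`. PDT is generated from
#'   the growth model, not from `true_beta`.
#' @param noise_potential_sd Named numeric vector of Gaussian teacher-signal
#'   noise standard deviations for `osteo`, `adipo`, `chondro` (in potential
#'   units) and `pdt` (log-scale sd applied to the harvest count).
#' @param n_speckles Expected number of small bright non-cell artefacts per
#'   image (removed downstream by the noise filter).
#' @param seed Master seed; every random stream is derived from it.
#'
#' @details
#' `morphology_drift` controls how the per-cell morphology distribution
#' drifts from spindle-shaped (small, elongated) to flat/polygonal (large,
#' round, rough-edged) with passage: `area_start` (mean cell area in px^2 at
#' the first passage and 24 h), `area_slope` (log-area increment per
#' passage), `area_hour_slope` (log-area increment per 24 h of spreading),
#' `aspect_start`/`aspect_slope` (mean major/minor axis ratio and its
#' per-passage log decrement), `rough_start`/`rough_slope` (boundary lobe
#' amplitude), `hole_prob_start`/`hole_prob_slope` (probability of an
#' intracellular hole), `hole_frac` (hole area as a fraction of cell area),
#' `sample_sd` (log-scale sample-to-sample jitter of every parameter),
#' `summary_sd` (log-scale independent per-sample, per-feature variability
#' of the population summary: biological and sampling variation beyond what
#' the four shape parameters encode, which keeps the 40 M-pattern 1
#' features identifiable rather than collinear) and
#' `cell_sd_area`/`cell_sd_aspect` (within-population log-scale spread).
#'
#' @return An object of class `msc_config` (a validated named list).
#' @export
synthetic_config <- function(n_lots = 3,
                             passages = 2:9,
                             n_wells = 4,
                             n_fields = 5,
                             hours = c(24, 48, 72, 96),
                             image_shape = c(512, 512),
                             cells_per_field = 15,
                             morphology_drift = list(),
                             growth_rate = list(),
                             noise_sd = 8,
                             true_beta = NULL,
                             noise_potential_sd = NULL,
                             n_speckles = 8,
                             seed = 1L) {
  drift_def <- list(
    area_start = 600, area_slope = 0.10, area_hour_slope = 0.08,
    aspect_start = 3.2, aspect_slope = -0.07,
    rough_start = 0.05, rough_slope = 0.010,
    hole_prob_start = 0.02, hole_prob_slope = 0.012, hole_frac = 0.04,
    sample_sd = 0.06, summary_sd = 0.08,
    cell_sd_area = 0.32, cell_sd_aspect = 0.25
  )
  growth_def <- list(pdt_start = 40, pdt_slope = 7, lot_sd = 0.05)
  stopifnot(is.list(morphology_drift), is.list(growth_rate))
  bad <- setdiff(names(morphology_drift), names(drift_def))
  if (length(bad)) stop("unknown morphology_drift parameter(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(names(growth_rate), names(growth_def))
  if (length(bad)) stop("unknown growth_rate parameter(s): ",
                        paste(bad, collapse = ", "))
  drift_def[names(morphology_drift)] <- morphology_drift
  growth_def[names(growth_rate)] <- growth_rate

  cfg <- list(
    n_lots = as.integer(n_lots),
    passages = as.integer(passages),
    n_wells = as.integer(n_wells),
    n_fields = as.integer(n_fields),
    hours = as.integer(hours),
    image_shape = as.integer(image_shape),
    cells_per_field = cells_per_field,
    morphology_drift = drift_def,
    growth_rate = growth_def,
    noise_sd = noise_sd,
    true_beta = true_beta %||% default_true_beta(hours),
    noise_potential_sd = noise_potential_sd %||%
      c(osteo = 8000, adipo = 5000, chondro = 0.015, pdt = 0.03),
    n_speckles = n_speckles,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "msc_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$n_lots >= 1, length(cfg$passages) >= 1, cfg$n_wells >= 1,
    cfg$n_fields >= 1, length(cfg$hours) >= 1,
    length(cfg$image_shape) == 2, all(cfg$image_shape >= 8),
    cfg$cells_per_field >= 0, cfg$noise_sd >= 0
  )
  if (is.unsorted(cfg$hours, strictly = TRUE))
    stop("hours must be strictly increasing")
  if (anyDuplicated(cfg$passages)) stop("passages must be distinct")
  invisible(cfg)
}

# Default sparse teacher coefficients on the raw M-pattern 1 feature scale.
# Signs encode the biology the generator emulates: early-passage cultures
# (elongated, small, fast-growing cells) carry high differentiation
# potential, late-passage cultures (flat, large, slow) have lost it.
default_true_beta <- function(hours = c(24, 48, 72, 96)) {
  h <- function(i) hours[min(i, length(hours))]
  list(
    osteo = c(
      "(Intercept)" = 5e4,
      setNames(6e4,  sprintf("elliptical_form_factor_AVE_h%d", h(1))),
      setNames(-60,  sprintf("total_area_AVE_h%d", h(4))),
      setNames(1500, sprintf("object_count_h%d", h(2))),
      setNames(-8e4, sprintf("shape_factor_AVE_h%d", h(3))),
      setNames(-3e3, sprintf("inner_radius_AVE_h%d", h(1)))
    ),
    adipo = c(
      "(Intercept)" = 2e4,
      setNames(2000, sprintf("object_count_h%d", h(4))),
      setNames(3e4,  sprintf("elliptical_form_factor_AVE_h%d", h(2))),
      setNames(-40,  sprintf("total_area_AVE_h%d", h(1))),
      setNames(-1500, sprintf("fiber_breadth_AVE_h%d", h(4)))
    ),
    chondro = c(
      "(Intercept)" = 0.12,
      setNames(-0.45, sprintf("shape_factor_AVE_h%d", h(1))),
      setNames(0.12,  sprintf("elliptical_form_factor_AVE_h%d", h(4))),
      setNames(-15,   sprintf("relative_hole_area_AVE_h%d", h(3))),
      setNames(0.004, sprintf("breadth_AVE_h%d", h(1)))
    )
  )
}

#' @export
print.msc_config <- function(x, ...) {
  n_img <- x$n_lots * length(x$passages) * x$n_wells * x$n_fields *
    length(x$hours)
  cat("Synthetic hBMSC dataset configuration\n")
  cat(sprintf("  design: %d lot(s) x %d passage(s) x %d well(s) x %d field(s) x %d hour(s) = %d images\n",
              x$n_lots, length(x$passages), x$n_wells, x$n_fields,
              length(x$hours), n_img))
  cat(sprintf("  samples: %d; image %d x %d px; seed %d\n",
              x$n_lots * length(x$passages), x$image_shape[1],
              x$image_shape[2], x$seed))
  invisible(x)
}
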