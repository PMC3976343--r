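# Ground-truth morphology model: the generative layer shared by the image
# renderer, the teacher-signal generator and the truth-route feature bundle.

# Map mean shape parameters to the nine "true" morphological feature values
# of an idealised lobed ellipse of area A, axis ratio q >= 1, boundary lobe
# amplitude `rough` and expected hole area `hole_ev`. Vectorised.
truth_feature_map <- function(A, q, rough, hole_ev) {
  a <- sqrt(A * q / pi)            # semi-major axis
  b <- sqrt(A / (pi * q))          # semi-minor axis
  t <- (a - b) / (a + b)
  P <- pi * (a + b) * (1 + 3 * t^2 / (10 + sqrt(4 - 3 * t^2)))
  P <- P * (1 + 1.5 * rough)       # lobes lengthen the boundary
  disc <- pmax(0, P^2 - 16 * A)
  fl <- (P + sqrt(disc)) / 4
  cbind(
    breadth = 2 * b,
    elliptical_form_factor = q,
    fiber_breadth = pmin(A / fl, fl),
    fiber_length = fl,
    hole_area = hole_ev,
    inner_radius = b * (1 - rough),
    relative_hole_area = hole_ev / A,
    shape_factor = pmin(1, 4 * pi * A / P^2),
    total_area = A
  )
}

#' Generate the per-sample ground-truth morphology model
#'
#' Draws, for every (lot, passage) sample and acquisition hour, the mean
#' parameters of the per-cell morphology distribution (cell area, axis
#' ratio, boundary roughness, hole probability) together with the expected
#' per-field cell count and the true population doubling time. The drift
#' model moves cells from spindle-shaped to flat/polygonal with passage:
#' mean area grows and mean axis ratio shrinks monotonically in expectation.
#'
#' This is the layer both [generate_image_set()] (which renders it to
#' pixels) and [generate_potentials()] (which converts it to teacher
#' signals) consume, so a fixed seed yields one consistent dataset whether
#' or not images are rendered.
#'
#' @param config An [synthetic_config()] object.
#' @return A list with elements `samples` (one row per (lot, passage):
#'   `sample_id`, `lot`, `passage`, `pdt_true`), `params` (one row per
#'   sample x hour with the distribution parameters and `count_mean`, the
#'   expected cells per field) and `summary` (samples x 40 matrix of true
#'   M-pattern 1 feature values: per-hour means of the nine features plus
#'   per-hour expected object counts).
#' @export
generate_morphology_truth <- function(config) {
  validate_config(config)
  md <- config$morphology_drift
  gr <- config$growth_rate
  lots <- LETTERS[seq_len(config$n_lots)]
  grid <- expand.grid(passage = config$passages, lot = lots,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$lot, grid$passage), , drop = FALSE]
  rownames(grid) <- NULL

  # lot-level multipliers (one stream per lot)
  lot_eff <- do.call(rbind, lapply(seq_along(lots), function(i) {
    with_seed(substream_seed(config$seed, 101, i), {
      data.frame(lot = lots[i],
                 area_mult = exp(rnorm(1, 0, md$sample_sd)),
                 aspect_mult = exp(rnorm(1, 0, md$sample_sd)),
                 pdt_mult = exp(rnorm(1, 0, gr$lot_sd)))
    })
  }))

  params <- vector("list", nrow(grid))
  samples <- grid
  samples$sample_id <- sample_id(grid$lot, grid$passage)
  samples$pdt_true <- NA_real_
  ip_all <- match(grid$passage, sort(config$passages)) - 1L

  for (i in seq_len(nrow(grid))) {
    lot <- grid$lot[i]; pp <- grid$passage[i]; ip <- ip_all[i]
    le <- lot_eff[lot_eff$lot == lot, ]
    st <- with_seed(substream_seed(config$seed, 202, match(lot, lots), pp), {
      # sample-level jitter, one independent draw per parameter and hour so
      # the 40 summary features are informative rather than collinear
      nh <- length(config$hours)
      jit <- function() exp(rnorm(nh, 0, md$sample_sd))
      pdt <- max(8, (gr$pdt_start + gr$pdt_slope * ip) * le$pdt_mult *
                   exp(rnorm(1, 0, gr$lot_sd)))
      area <- md$area_start * exp(md$area_slope * ip) * le$area_mult *
        exp(md$area_hour_slope * (config$hours - config$hours[1]) / 24) * jit()
      aspect <- 1 + (md$aspect_start - 1) * exp(md$aspect_slope * ip) *
        le$aspect_mult * jit()
      rough <- pmax(0.01, (md$rough_start + md$rough_slope * ip) * jit())
      hole_prob <- pmin(0.5, pmax(0, (md$hole_prob_start +
                                        md$hole_prob_slope * ip) * jit()))
      count <- config$cells_per_field *
        2^((config$hours - config$hours[1]) / pdt) * jit()
      list(pdt = pdt, area = area, aspect = aspect, rough = rough,
           hole_prob = hole_prob, count = count)
    })
    samples$pdt_true[i] <- st$pdt
    params[[i]] <- data.frame(
      sample_id = samples$sample_id[i], lot = lot, passage = pp,
      hour = config$hours, area_mean = st$area, aspect_mean = st$aspect,
      rough = st$rough, hole_prob = st$hole_prob, hole_frac = md$hole_frac,
      count_mean = st$count, stringsAsFactors = FALSE)
  }
  params <- do.call(rbind, params)
  rownames(params) <- NULL

  base <- truth_summary_matrix(params, config$hours)
  # independent per-(sample, feature) variability: the population summary is
  # not a deterministic function of the shape parameters
  jit <- with_seed(substream_seed(config$seed, 808),
                   matrix(exp(rnorm(length(base), 0, md$summary_sd)),
                          nrow(base), ncol(base), dimnames = dimnames(base)))
  list(samples = samples[, c("sample_id", "lot", "passage", "pdt_true")],
       params = params, summary = base * jit, summary_jitter = jit)
}

# samples x 40 matrix of true M-pattern 1 values (per-hour means of the
# nine features, then per-hour expected object counts), feature-major order.
truth_summary_matrix <- function(params, hours) {
  ids <- unique(params$sample_id)
  nm <- mpattern_names(1, hours)
  out <- matrix(NA_real_, length(ids), length(nm),
                dimnames = list(ids, nm))
  for (sid in ids) {
    pp <- params[params$sample_id == sid, , drop = FALSE]
    pp <- pp[match(hours, pp$hour), , drop = FALSE]
    fmat <- truth_feature_map(pp$area_mean, pp$aspect_mean, pp$rough,
                              pp$hole_prob * pp$hole_frac * pp$area_mean)
    for (f in MORPH_FEATURES)
      out[sid, sprintf("%s_AVE_h%d", f, hours)] <- fmat[, f]
    out[sid, sprintf("object_count_h%d", hours)] <- pp$count_mean
  }
  out
}

# Draw per-cell shape parameters and their derived true feature values for
# one (sample, hour). Used by the renderer and by simulate_feature_bundle().
# Assumes the RNG state is already positioned on the right stream.
draw_cells <- function(n, prm, md) {
  if (n == 0) {
    return(data.frame(area = numeric(0), aspect = numeric(0),
                      rough = numeric(0), hole_area = numeric(0)))
  }
  sa <- md$cell_sd_area; sq <- md$cell_sd_aspect
  area <- prm$area_mean * exp(rnorm(n, -sa^2 / 2, sa))
  aspect <- 1 + (prm$aspect_mean - 1) * exp(rnorm(n, -sq^2 / 2, sq))
  rough <- pmax(0.005, prm$rough * exp(rnorm(n, 0, 0.2)))
  has_hole <- rbinom(n, 1, prm$hole_prob)
  hole_area <- has_hole * prm$hole_frac * area * exp(rnorm(n, 0, 0.3))
  data.frame(area = area, aspect = aspect, rough = rough,
             hole_area = hole_area)
}

cell_true_features <- function(cells) {
  if (nrow(cells) == 0) {
    m <- matrix(numeric(0), 0, length(MORPH_FEATURES))
    colnames(m) <- MORPH_FEATURES
    return(m)
  }
  truth_feature_map(cells$area, cells$aspect, cells$rough, cells$hole_area)
}

#' Simulate a full modelling bundle from the generative truth
#'
#' Produces everything the prediction benchmark needs -- the six M-pattern
#' feature tables, the normalised 69-gene expression table and the four
#' teacher potentials for all samples -- directly from the generative
#' morphology distributions, without rendering or segmenting pixels. Cells
#' are drawn per sample and time point from the same distributions the
#' renderer uses (pooled across all wells and fields, as in the imaging
#' route), then summarised with [summarize_distribution()] and converted
#' with [build_mpattern()].
#'
#' @param config An [synthetic_config()] object.
#' @param truth Optional pre-computed [generate_morphology_truth()] result.
#' @return A list with `features` (list of 6 sample x feature matrices),
#'   `genes` (normalised samples x genes matrix), `potentials` (data frame
#'   from [generate_potentials()]), `truth`, and `config`.
#' @export
simulate_feature_bundle <- function(config, truth = NULL) {
  validate_config(config)
  truth <- truth %||% generate_morphology_truth(config)
  md <- config$morphology_drift
  n_img <- config$n_wells * config$n_fields
  ids <- truth$samples$sample_id

  summaries <- quiet_degenerate(lapply(ids, function(sid) {
    pp <- truth$params[truth$params$sample_id == sid, , drop = FALSE]
    per_hour <- lapply(config$hours, function(h) {
      prm <- pp[pp$hour == h, ]
      with_seed(substream_seed(config$seed, 303, match(sid, ids), h), {
        counts <- rpois(n_img, prm$count_mean)
        cells <- draw_cells(sum(counts), prm, md)
        fmat <- cell_true_features(cells)
        # apply the sample's per-feature variability (multiplicative, so it
        # commutes with quantiles and matches the truth summary)
        jrow <- truth$summary_jitter[sid, ]
        for (f in MORPH_FEATURES)
          fmat[, f] <- fmat[, f] * jrow[[sprintf("%s_AVE_h%d", f, h)]]
        stats <- do.call(rbind, lapply(MORPH_FEATURES, function(f)
          summarize_distribution(fmat[, f])))
        rownames(stats) <- MORPH_FEATURES
        list(stats = as.data.frame(stats),
             count = mean(counts) * jrow[[sprintf("object_count_h%d", h)]])
      })
    })
    names(per_hour) <- as.character(config$hours)
    per_hour
  }))
  names(summaries) <- ids

  features <- quiet_degenerate(lapply(1:6, function(k) {
    m <- do.call(rbind, lapply(ids, function(sid) {
      v <- build_mpattern(k, summaries[[sid]], hours = config$hours)
      v$values
    }))
    rownames(m) <- ids
    colnames(m) <- mpattern_names(k, config$hours)
    m
  }))
  names(features) <- paste0("mp", 1:6)

  genes <- generate_gene_expression(config, truth)
  potentials <- generate_potentials(config, truth)
  list(features = features, genes = normalize_genes(genes),
       potentials = potentials, truth = truth, config = config)
}
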