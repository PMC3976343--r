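# Teacher signals: staining potentials as a known sparse linear function of
# the true morphology summary, and PDT from the growth model.

#' Generate ground-truth differentiation potentials and PDT
#'
#' Converts the ground-truth morphology model into the four per-sample
#' teacher signals. The three staining potentials are
#' `max(0, beta . true_summary + noise)` with the sparse coefficient
#' vectors from `config$true_beta` applied to the true M-pattern 1 summary
#' (so that downstream sparse-regression recovery is verifiable against a
#' known support). The PDT teacher is obtained the way it is measured in
#' the laboratory: a seeded cell count, a harvest count drawn from the true
#' doubling time (with multiplicative counting noise), and
#' [compute_pdt()] applied to the pair.
#'
#' @param config An [synthetic_config()] object.
#' @param truth A [generate_morphology_truth()] result for the same config.
#' @return A data frame with one row per sample: `sample_id`, `lot`,
#'   `passage`, `osteo`, `adipo`, `chondro` (stained-pixel scale), `pdt`
#'   (hours). The per-passage cell counts used for PDT are attached as
#'   `attr(, "cell_counts")`.
#' @export
generate_potentials <- function(config, truth) {
  validate_config(config)
  S <- truth$summary
  ids <- rownames(S)
  nsd <- config$noise_potential_sd
  out <- truth$samples[match(ids, truth$samples$sample_id),
                       c("sample_id", "lot", "passage")]

  for (p in c("osteo", "adipo", "chondro")) {
    beta <- config$true_beta[[p]]
    if (is.null(beta)) stop("true_beta missing for potential: ", p)
    feats <- setdiff(names(beta), "(Intercept)")
    missing <- setdiff(feats, colnames(S))
    if (length(missing))
      stop("true_beta for ", p, " names unknown features: ",
           paste(missing, collapse = ", "))
    icpt <- if ("(Intercept)" %in% names(beta)) beta[["(Intercept)"]] else 0
    lin <- icpt +
      as.numeric(S[, feats, drop = FALSE] %*% beta[feats])
    noise <- with_seed(substream_seed(config$seed, 505, match(p, POTENTIAL_TYPES)),
                       rnorm(length(ids), 0, nsd[[p]]))
    out[[p]] <- pmax(0, lin + noise)
  }

  # PDT via the counting route
  n_seed <- 1e5
  duration <- 120  # hours between seeding and harvest counting
  pdt_true <- truth$samples$pdt_true[match(ids, truth$samples$sample_id)]
  mult <- with_seed(substream_seed(config$seed, 505, 4),
                    exp(rnorm(length(ids), 0, nsd[["pdt"]])))
  n_harvest <- pmax(n_seed + 1, round(n_seed * 2^(duration / pdt_true) * mult))
  out$pdt <- vapply(n_harvest, function(nh)
    compute_pdt(n_seed, nh, duration), numeric(1))
  attr(out, "cell_counts") <- data.frame(
    sample_id = ids, n_seed = n_seed, n_harvest = n_harvest,
    duration = duration)
  rownames(out) <- NULL
  out
}

# The 19 named expression archetypes: senescence effectors, cytoskeleton /
# adhesion regulators, and lineage differentiation markers.
GENE_ARCHETYPES <- c(
  "CDKN1A", "CDKN2A", "TP53",                       # senescence
  "PTK2", "MCAM", "ITGA1", "RAC1", "RHOA", "ACTA2", # cytoskeleton/adhesion
  "IQGAP1", "PIK3CA",
  "SPP1", "ALPI", "BMP2", "BGLAP",                  # osteogenic markers
  "ADIPOQ", "LEP", "LPL",                           # adipogenic markers
  "ACAN"                                            # chondrogenic marker
)

#' Generate a synthetic 69-gene expression table
#'
#' Emits a raw (un-normalised) genes x samples expression matrix with the
#' structure the passage-correlation screen expects: a configurable subset
#' of named archetype genes drifts monotonically with passage number in
#' every lot (senescence genes up, cytoskeleton and differentiation markers
#' down), a block of genes carries lot-specific offsets, and the remainder
#' is stationary noise.
#'
#' @param config An [synthetic_config()] object.
#' @param truth Optional [generate_morphology_truth()] result (used only
#'   for the sample grid; regenerated if missing).
#' @param passage_linked Character vector of archetype genes to tie to
#'   passage number. May be `character(0)` for a null table.
#' @param trend_sd Residual noise sd around the passage trend.
#' @return A 69 x n_samples numeric matrix, rownames genes, colnames
#'   sample ids, with attribute `passage_linked` recording the injected set.
#' @export
generate_gene_expression <- function(config, truth = NULL,
                                     passage_linked = c("CDKN1A", "CDKN2A",
                                                        "PTK2", "MCAM",
                                                        "ITGA1"),
                                     trend_sd = 0.25) {
  validate_config(config)
  truth <- truth %||% generate_morphology_truth(config)
  stopifnot(all(passage_linked %in% GENE_ARCHETYPES))
  genes <- c(GENE_ARCHETYPES,
             sprintf("GENE%02d", seq_len(69 - length(GENE_ARCHETYPES))))
  ids <- truth$samples$sample_id
  pas <- truth$samples$passage
  lot <- truth$samples$lot
  up <- c("CDKN1A", "CDKN2A", "TP53")  # senescence rises with passage

  with_seed(substream_seed(config$seed, 404), {
    base <- rnorm(length(genes), 8, 1)
    M <- matrix(rnorm(length(genes) * length(ids), 0, 0.8),
                length(genes), length(ids),
                dimnames = list(genes, ids))
    M <- M + base
    # lot-specific block: a third of the unnamed genes
    lot_genes <- sample(setdiff(genes, GENE_ARCHETYPES),
                        max(1, (69 - length(GENE_ARCHETYPES)) %/% 3))
    for (g in lot_genes) {
      off <- rnorm(length(unique(lot)), 0, 1.5)
      M[g, ] <- M[g, ] + off[match(lot, unique(lot))]
    }
    z <- (pas - mean(pas)) / sd(pas)
    for (g in passage_linked) {
      slope <- if (g %in% up) 2.5 else -2.5
      M[g, ] <- base[match(g, genes)] + slope * z +
        rnorm(length(ids), 0, trend_sd)
    }
    attr(M, "passage_linked") <- passage_linked
    M
  })
}

#' Construct a stained-culture fixture image with a known stained area
#'
#' Builds an RGB image in which exactly `target_area` pixels satisfy the
#' corresponding colour-classification rule used by the quantitation
#' functions: red for Alizarin red (calcium) and Oil red (lipid droplets),
#' blue for Alcian blue (glycosaminoglycans). Stained pixels are laid down
#' as overlapping blobs and then trimmed to the exact target, so round
#' trips through [quantify_alizarin()], [quantify_oilred()] and
#' [quantify_alcian()] recover the constructed area exactly.
#'
#' @param kind One of `"alizarin"`, `"oilred"`, `"alcian"`.
#' @param target_area Exact number of stained pixels to place.
#' @param shape Image dimensions `c(rows, cols)`.
#' @param seed Seed for blob placement.
#' @param droplet_radius For `"oilred"`, range of droplet radii in pixels.
#' @return A list with `image` (rows x cols x 3 integer array, 0-255) and,
#'   for `"alcian"`, `pellet_mask` (logical matrix) covering the pellet
#'   section that stained pixels are confined to.
#' @export
generate_stained_image <- function(kind = c("alizarin", "oilred", "alcian"),
                                   target_area, shape = c(256, 256),
                                   seed = 1L, droplet_radius = c(4, 10)) {
  kind <- match.arg(kind)
  nr <- shape[1]; nc <- shape[2]
  if (target_area < 0) stop("target_area must be >= 0")
  if (target_area > nr * nc)
    stop("target_area ", target_area, " exceeds the ", nr, "x", nc, " canvas")

  pellet <- NULL
  if (kind == "alcian") {
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    rad <- 0.38 * min(nr, nc)
    d2 <- outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, `+`)
    pellet <- d2 <= rad^2
    if (target_area > sum(pellet))
      stop("target_area ", target_area, " exceeds the pellet area ",
           sum(pellet))
  }
  allowed <- if (is.null(pellet)) matrix(TRUE, nr, nc) else pellet

  stained <- with_seed(substream_seed(seed, 606, match(kind, c("alizarin", "oilred", "alcian"))), {
    sel <- logical(nr * nc)
    dim(sel) <- c(nr, nc)
    n_in <- 0L
    while (n_in < target_area) {
      r0 <- if (kind == "oilred")
        runif(1, droplet_radius[1], droplet_radius[2]) else
          runif(1, 6, 0.12 * min(nr, nc))
      cy <- runif(1, 1, nr); cx <- runif(1, 1, nc)
      rr <- max(1, floor(cy - r0)):min(nr, ceiling(cy + r0))
      cc <- max(1, floor(cx - r0)):min(nc, ceiling(cx + r0))
      d2 <- outer((rr - cy)^2, (cc - cx)^2, `+`)
      disk <- d2 <= r0^2
      new_idx <- which(disk & !sel[rr, cc] & allowed[rr, cc], arr.ind = TRUE)
      if (nrow(new_idx) == 0) next
      take <- nrow(new_idx)
      if (n_in + take > target_area) {
        # trim the outermost freshly added pixels to hit the target exactly
        dd <- d2[cbind(new_idx[, 1], new_idx[, 2])]
        keep <- order(dd)[seq_len(target_area - n_in)]
        new_idx <- new_idx[keep, , drop = FALSE]
        take <- nrow(new_idx)
      }
      sel[cbind(rr[new_idx[, 1]], cc[new_idx[, 2]])] <- TRUE
      n_in <- n_in + take
    }
    sel
  })

  img <- array(0L, c(nr, nc, 3))
  if (kind == "alcian") {
    # white background, grey-pink pellet tissue, saturated blue stain
    img[, , 1] <- 245L; img[, , 2] <- 245L; img[, , 3] <- 245L
    img[, , 1][pellet] <- 205L; img[, , 2][pellet] <- 195L
    img[, , 3][pellet] <- 205L
    img[, , 1][stained] <- 40L; img[, , 2][stained] <- 60L
    img[, , 3][stained] <- 200L
  } else {
    # pale culture background, saturated red stain
    img[, , 1] <- 225L; img[, , 2] <- 215L; img[, , 3] <- 210L
    img[, , 1][stained] <- 200L; img[, , 2][stained] <- 40L
    img[, , 3][stained] <- 45L
  }
  out <- list(image = img, target_area = as.integer(target_area))
  if (kind == "alcian") out$pellet_mask <- pellet
  out
}
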