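# Teacher-signal quantitation from stained-culture images and cell counts,
# and gene-expression preprocessing.
#
# Colour classification uses channel-dominance rules (deterministic and
# bit-exact rather than hue bands): a pixel is "red" when R > r_min and
# R - max(G, B) > delta, and "blue" when B > b_min and B - max(R, G) >
# delta. Thresholds are exposed as arguments.

check_rgb <- function(image) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop("expected an RGB image (rows x cols x 3 array)")
  invisible(d)
}

red_mask <- function(image, r_min, delta) {
  check_rgb(image)
  R <- image[, , 1]; G <- image[, , 2]; B <- image[, , 3]
  R > r_min & (R - pmax(G, B)) > delta
}

blue_mask <- function(image, b_min, delta) {
  check_rgb(image)
  R <- image[, , 1]; G <- image[, , 2]; B <- image[, , 3]
  B > b_min & (B - pmax(R, G)) > delta
}

#' Quantify osteogenic differentiation from an Alizarin-red image
#'
#' The count of red-classified pixels is the quantitated value (calcium
#' deposition).
#'
#' @param image RGB array (rows x cols x 3, 0-255).
#' @param r_min,delta Red-classification thresholds.
#' @return Integer red-pixel count.
#' @export
quantify_alizarin <- function(image, r_min = 100, delta = 30) {
  sum(red_mask(image, r_min, delta))
}

#' Quantify adipogenic differentiation from an Oil-red image
#'
#' Red-classified pixels are grouped into 8-connected components (stained
#' lipid droplets); the total pixel area of droplets at least
#' `min_droplet_area` large is the quantitated value.
#'
#' @param image RGB array.
#' @param min_droplet_area Smallest droplet (in pixels) counted as lipid.
#' @param r_min,delta Red-classification thresholds.
#' @return Integer stained droplet area.
#' @export
quantify_oilred <- function(image, min_droplet_area = 10, r_min = 100,
                            delta = 30) {
  m <- red_mask(image, r_min, delta)
  lab <- .cc_label(m, 8L)
  n <- attr(lab, "n_objects")
  if (n == 0) return(0L)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  sum(sizes[sizes >= min_droplet_area])
}

#' Quantify chondrogenic differentiation from an Alcian-blue pellet image
#'
#' The fraction of pellet pixels classified blue (glycosaminoglycan
#' staining normalised against total pellet size).
#'
#' @param image RGB array.
#' @param pellet_mask Logical matrix marking the pellet section; must be
#'   non-empty.
#' @param b_min,delta Blue-classification thresholds.
#' @return Fraction in `[0, 1]`.
#' @export
quantify_alcian <- function(image, pellet_mask, b_min = 100, delta = 30) {
  check_rgb(image)
  stopifnot(is.logical(pellet_mask) || all(pellet_mask %in% 0:1))
  if (!any(pellet_mask)) stop("empty pellet mask")
  m <- blue_mask(image, b_min, delta)
  sum(m & pellet_mask) / sum(pellet_mask)
}

#' Population doubling time from seed and harvest counts
#'
#' `PDT = duration * ln(2) / ln(n_harvest / n_seed)` hours.
#'
#' @param n_seed Cells seeded (> 0).
#' @param n_harvest Cells harvested (> `n_seed`: the culture must have
#'   grown for a doubling time to exist).
#' @param duration Hours between seeding and harvest (> 0).
#' @return PDT in hours.
#' @export
compute_pdt <- function(n_seed, n_harvest, duration) {
  stopifnot(n_seed > 0, duration > 0)
  if (n_harvest <= n_seed)
    stop("undefined growth: n_harvest (", n_harvest,
         ") must exceed n_seed (", n_seed, ")")
  duration * log(2) / log(n_harvest / n_seed)
}

#' Standard normalisation of a gene-expression table
#'
#' Scales between arrays and genes: each sample (array) column is z-scored,
#' then each gene row is z-scored, so that every gene has mean 0 and unit
#' standard deviation across samples.
#'
#' @param table Genes x samples numeric matrix, no missing values.
#' @return Normalised matrix with attribute `normalized = TRUE`.
#' @export
normalize_genes <- function(table) {
  table <- as.matrix(table)
  if (any(!is.finite(table))) stop("gene table contains missing values")
  rz0 <- apply(table, 1, sd)
  if (any(rz0 == 0))
    stop("zero-variance gene(s): ",
         paste(rownames(table)[rz0 == 0], collapse = ", "))
  cz <- apply(table, 2, sd)
  if (any(cz == 0)) stop("zero-variance array(s): ",
                         paste(colnames(table)[cz == 0], collapse = ", "))
  M <- scale(table)  # per-array (column) z-score
  rz <- apply(M, 1, sd)
  if (any(rz == 0))
    stop("zero-variance gene(s): ",
         paste(rownames(table)[rz == 0], collapse = ", "))
  M <- t(scale(t(M)))  # per-gene (row) z-score
  out <- matrix(as.numeric(M), nrow(table), ncol(table),
                dimnames = dimnames(table))
  attr(out, "normalized") <- TRUE
  out
}

#' Screen genes synchronised with passage number in every lot
#'
#' Returns the genes whose absolute Pearson correlation with passage
#' number exceeds the threshold within every lot separately -- the
#' "genetic signature of potential collapse" screen. An undefined
#' correlation (zero variance within a lot) is treated as 0, so constant
#' genes are never selected.
#'
#' @param table Genes x samples matrix (normalised).
#' @param passages Integer vector of passage numbers, one per sample
#'   (column).
#' @param lots Lot identifier per sample; every lot needs at least 3
#'   distinct passages.
#' @param threshold Correlation threshold (default 0.673).
#' @return Character vector of selected genes, with attribute
#'   `correlations` (genes x lots matrix of within-lot correlations).
#' @export
passage_correlated_genes <- function(table, passages, lots,
                                     threshold = 0.673) {
  table <- as.matrix(table)
  stopifnot(ncol(table) == length(passages), length(passages) == length(lots))
  for (l in unique(lots))
    if (length(unique(passages[lots == l])) < 3)
      stop("lot ", l, " has fewer than 3 distinct passages")
  cors <- sapply(unique(lots), function(l) {
    sel <- lots == l
    apply(table[, sel, drop = FALSE], 1, function(v) {
      if (sd(v) == 0) 0 else cor(v, passages[sel])
    })
  })
  cors <- matrix(cors, nrow(table),
                 dimnames = list(rownames(table), unique(lots)))
  hit <- apply(abs(cors) > threshold, 1, all)
  structure(rownames(table)[hit], correlations = cors)
}
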