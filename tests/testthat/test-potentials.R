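test_that("alizarin quantitation counts exactly the red-classified pixels", {
  img <- array(255L, c(20, 20, 3))           # all white
  expect_equal(quantify_alizarin(img), 0)
  img2 <- array(0L, c(40, 30, 3))
  idx <- cbind(sample(40, 20, TRUE), sample(30, 20, TRUE))
  idx <- unique(idx)
  img2[cbind(idx[, 1], idx[, 2], 1)] <- 255L  # pure red pixels
  expect_equal(quantify_alizarin(img2), nrow(idx))
  expect_error(quantify_alizarin(matrix(0, 5, 5)), "RGB")
})

test_that("all three stain rules equal exhaustive per-pixel oracles", {
  set.seed(99)
  for (rep in 1:20) {
    img <- random_rgb(24, 24)
    R <- img[, , 1]; G <- img[, , 2]; B <- img[, , 3]
    red_oracle <- sum(R > 100 & (R - pmax(G, B)) > 30)
    expect_equal(quantify_alizarin(img), red_oracle)
    # oil red with no size filter equals the plain red count
    expect_equal(quantify_oilred(img, min_droplet_area = 1), red_oracle)
    pellet <- matrix(TRUE, 24, 24)
    blue_oracle <- sum(B > 100 & (B - pmax(R, G)) > 30) / sum(pellet)
    expect_equal(quantify_alcian(img, pellet), blue_oracle)
  }
})

test_that("oil red sums only droplets above the size threshold", {
  img <- array(255L, c(40, 60, 3))
  paint <- function(rows, cols) {
    img[cbind(rep(rows, length(cols)), rep(cols, each = length(rows)), 2)] <<- 40L
    img[cbind(rep(rows, length(cols)), rep(cols, each = length(rows)), 3)] <<- 40L
  }
  paint(2:6, 2:11)     # 5 x 10 = 50
  paint(12:17, 20:29)  # 6 x 10 = 60
  paint(25:31, 40:49)  # 7 x 10 = 70
  expect_equal(quantify_oilred(img, min_droplet_area = 10), 180)
  expect_equal(quantify_oilred(img, min_droplet_area = 65), 70)
  expect_equal(quantify_oilred(img, min_droplet_area = 200), 0)
  # droplet grouping agrees with the BFS component oracle
  set.seed(5)
  sp <- random_rgb(30, 30)
  mask <- sp[, , 1] > 100 & (sp[, , 1] - pmax(sp[, , 2], sp[, , 3])) > 30
  sizes <- bfs_component_sizes(mask)
  expect_equal(quantify_oilred(sp, min_droplet_area = 3),
               sum(sizes[sizes >= 3]))
})

test_that("alcian quantitation is a fraction of the pellet", {
  img <- array(255L, c(100, 100, 3))
  pellet <- matrix(FALSE, 100, 100)
  pellet[1:50, 1:100] <- TRUE  # 5000 pellet pixels
  img[cbind(rep(1:10, 50), rep(1:50, each = 10), 1)] <- 30L
  img[cbind(rep(1:10, 50), rep(1:50, each = 10), 2)] <- 30L
  img[cbind(rep(1:10, 50), rep(1:50, each = 10), 3)] <- 220L  # 500 blue
  expect_equal(quantify_alcian(img, pellet), 0.1)
  img_wh <- array(255L, c(10, 10, 3))
  expect_equal(quantify_alcian(img_wh, matrix(TRUE, 10, 10)), 0)
  expect_error(quantify_alcian(img_wh, matrix(FALSE, 10, 10)), "empty pellet")
  # always within [0, 1]
  set.seed(2)
  for (rep in 1:10) {
    im <- random_rgb(16, 16)
    pm <- matrix(sample(c(TRUE, FALSE), 256, TRUE), 16, 16)
    if (!any(pm)) next
    v <- quantify_alcian(im, pm)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("population doubling time follows the log-ratio closed form", {
  expect_equal(compute_pdt(1e5, 8e5, 72), 24)
  expect_equal(compute_pdt(3000, 6000, 55), 55)     # one doubling
  expect_equal(compute_pdt(1e5, 3e5, 100), 100 * log(2) / log(3))
  # scale invariance in cell numbers
  expect_equal(compute_pdt(2e5, 6e5, 100), compute_pdt(1e5, 3e5, 100))
  expect_error(compute_pdt(1e5, 9e4, 72), "undefined growth")
  expect_error(compute_pdt(1e5, 1e5, 72), "undefined growth")
})

test_that("gene normalisation standardises arrays then genes", {
  set.seed(7)
  g <- matrix(rnorm(69 * 12, 8, 2), 69, 12,
              dimnames = list(sprintf("G%02d", 1:69), sprintf("s%02d", 1:12)))
  n <- normalize_genes(g)
  expect_true(all(abs(rowMeans(n)) < 1e-12))
  expect_true(all(abs(apply(n, 1, sd) - 1) < 1e-12))
  expect_true(isTRUE(attr(n, "normalized")))

  # 2x2 hand-computed: columns z-score to +-1/sqrt(2), rows then stay
  h <- matrix(c(1, 2, 5, 3), 2, 2, dimnames = list(c("g1", "g2"), NULL))
  expect_equal(unname(normalize_genes(h)),
               matrix(c(-1, 1, 1, -1) / sqrt(2), 2, 2),
               tolerance = 1e-12, ignore_attr = TRUE)

  # iterated normalisation converges to a fixed point
  x <- n
  for (i in 1:30) x <- normalize_genes(x)
  expect_equal(normalize_genes(x), x, tolerance = 1e-6,
               ignore_attr = TRUE)

  gz <- g; gz["G05", ] <- 4
  expect_error(normalize_genes(gz), "G05")
  gna <- g; gna[1, 1] <- NA
  expect_error(normalize_genes(gna), "missing")
})

test_that("the passage screen keeps only genes synchronised in every lot", {
  passages <- rep(2:9, 3)
  lots <- rep(c("A", "B", "C"), each = 8)
  set.seed(21)
  tab <- matrix(rnorm(10 * 24), 10, 24,
                dimnames = list(sprintf("G%02d", 1:10), NULL))
  tab["G01", ] <- passages                    # perfect synchronisation
  tab["G02", ] <- 5                           # constant: undefined r -> 0
  tab["G03", ] <- ifelse(lots == "A", passages, rnorm(24))  # one lot only
  hits <- passage_correlated_genes(tab, passages, lots)
  expect_true("G01" %in% hits)
  expect_false("G02" %in% hits)
  expect_false("G03" %in% hits)
  cors <- attr(hits, "correlations")
  expect_equal(unname(cors["G01", ]), rep(1, 3))
  expect_error(passage_correlated_genes(tab[, 1:10], passages[1:10],
                                        c(rep("A", 8), "B", "B")),
               "fewer than 3")
})

test_that("injected passage-linked genes are recovered at matched SNR", {
  cfg <- synthetic_config(n_wells = 1, n_fields = 1, seed = 33)
  truth <- generate_morphology_truth(cfg)
  linked <- c("CDKN1A", "CDKN2A", "PTK2", "MCAM", "ITGA1")
  g <- generate_gene_expression(cfg, truth, passage_linked = linked,
                                trend_sd = 0.2)
  hits <- passage_correlated_genes(normalize_genes(g),
                                   truth$samples$passage,
                                   truth$samples$lot)
  expect_setequal(as.character(hits), linked)
})
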