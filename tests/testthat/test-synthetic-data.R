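test_that("image count equals the product of design factors", {
  cfg <- tiny_config()
  gs <- generate_image_set(cfg)
  expect_equal(nrow(gs$manifest),
               cfg$n_lots * length(cfg$passages) * cfg$n_wells *
                 cfg$n_fields * length(cfg$hours))
  expect_equal(length(gs$images), nrow(gs$manifest))
  # realized per-image count matches the rendered per-cell table
  tab <- table(gs$truth$cells$image)
  nonzero <- gs$manifest[gs$manifest$n_cells > 0, ]
  key <- sprintf("lot%s_p%d_w%d_f%d_h%d", nonzero$lot, nonzero$passage,
                 nonzero$well, nonzero$field, nonzero$hour)
  expect_equal(unname(as.integer(tab[key])), nonzero$n_cells)
})

test_that("a zero-cell configuration yields pure background", {
  cfg <- synthetic_config(n_lots = 1, passages = 2, n_wells = 1,
                          n_fields = 1, hours = 24, cells_per_field = 0,
                          image_shape = c(64, 64), n_speckles = 0, seed = 3)
  gs <- generate_image_set(cfg)
  expect_equal(nrow(gs$manifest), 1)
  expect_equal(gs$manifest$n_cells, 0L)
  # background + noise never approaches the generative threshold
  expect_lt(max(gs$images[[1]]), gs$truth$threshold)
})

test_that("a fixed seed reproduces images and ground truth exactly", {
  cfg <- synthetic_config(n_lots = 1, passages = c(2, 5), n_wells = 1,
                          n_fields = 1, image_shape = c(256, 256),
                          cells_per_field = 4, seed = 42)
  g1 <- generate_image_set(cfg)
  g2 <- generate_image_set(cfg)
  expect_identical(g1$images, g2$images)
  expect_identical(g1$truth$summary, g2$truth$summary)
  expect_identical(g1$truth$cells, g2$truth$cells)
  # truth computed without rendering matches the rendered run
  expect_identical(generate_morphology_truth(cfg)$summary, g1$truth$summary)
})

test_that("overfilled images fail loudly instead of overlapping", {
  cfg <- synthetic_config(n_lots = 1, passages = 2, n_wells = 1,
                          n_fields = 1, hours = 24, cells_per_field = 60,
                          image_shape = c(64, 64), seed = 1)
  expect_error(generate_image_set(cfg), "too small")
})

test_that("expected cell area rises and aspect ratio falls with passage", {
  # Monte-Carlo over seeds: parameter means across lots per passage
  n_seeds <- 100
  agg <- 0
  for (s in seq_len(n_seeds)) {
    cfg <- synthetic_config(n_wells = 1, n_fields = 1, seed = 9000 + s)
    prm <- generate_morphology_truth(cfg)$params
    prm <- prm[prm$hour == 24, ]
    agg <- agg + cbind(tapply(prm$area_mean, prm$passage, mean),
                       tapply(prm$aspect_mean, prm$passage, mean))
  }
  agg <- agg / n_seeds
  expect_true(all(diff(agg[, 1]) > 0))   # area non-decreasing
  expect_true(all(diff(agg[, 2]) < 0))   # aspect non-increasing
})

test_that("per-cell draws follow the drift in expectation", {
  cfg <- synthetic_config(seed = 5)
  truth <- generate_morphology_truth(cfg)
  set.seed(1)
  mean_stats <- t(vapply(sort(cfg$passages), function(p) {
    prm <- truth$params[truth$params$passage == p & truth$params$hour == 24 &
                          truth$params$lot == "A", ]
    cells <- mscmorph:::draw_cells(500, prm, cfg$morphology_drift)
    c(area = mean(cells$area), aspect = mean(cells$aspect))
  }, numeric(2)))
  fit_a <- coef(lm(mean_stats[, "area"] ~ sort(cfg$passages)))[2]
  fit_q <- coef(lm(mean_stats[, "aspect"] ~ sort(cfg$passages)))[2]
  expect_gt(fit_a, 0)
  expect_lt(fit_q, 0)
})

test_that("noiseless potentials reproduce the sparse linear formula", {
  nb <- c(osteo = 0, adipo = 0, chondro = 0, pdt = 0)
  cfg <- synthetic_config(noise_potential_sd = nb, seed = 21)
  truth <- generate_morphology_truth(cfg)
  pot <- generate_potentials(cfg, truth)
  for (p in c("osteo", "adipo", "chondro")) {
    beta <- cfg$true_beta[[p]]
    feats <- setdiff(names(beta), "(Intercept)")
    manual <- pmax(0, beta[["(Intercept)"]] +
                     as.numeric(truth$summary[pot$sample_id, feats] %*%
                                  beta[feats]))
    expect_equal(pot[[p]], manual, tolerance = 1e-12)
  }
  # PDT from the counting route equals the true PDT when noise is off
  expect_equal(pot$pdt,
               truth$samples$pdt_true[match(pot$sample_id,
                                            truth$samples$sample_id)],
               tolerance = 1e-3)
})

test_that("an intercept-only teacher model emits a constant potential", {
  tb <- list(osteo = c("(Intercept)" = 7), adipo = c("(Intercept)" = 3),
             chondro = c("(Intercept)" = 0.5))
  cfg <- synthetic_config(true_beta = tb,
                          noise_potential_sd = c(osteo = 0, adipo = 0,
                                                 chondro = 0, pdt = 0),
                          seed = 2)
  pot <- generate_potentials(cfg, generate_morphology_truth(cfg))
  expect_true(all(pot$osteo == 7))
  expect_true(all(pot$adipo == 3))
  expect_true(all(pot$chondro == 0.5))
})

test_that("adipogenic-like potential decreases with passage on average", {
  slopes <- vapply(seq_len(100), function(s) {
    cfg <- synthetic_config(seed = 3000 + s)
    pot <- generate_potentials(cfg, generate_morphology_truth(cfg))
    cor(pot$adipo, pot$passage)
  }, numeric(1))
  expect_lt(mean(slopes), 0)
})

test_that("stained-image round trips recover constructed areas exactly", {
  set.seed(1)
  targets <- sample(0:4000, 6)
  for (ta in targets) {
    al <- generate_stained_image("alizarin", ta, shape = c(128, 128),
                                 seed = ta + 1)
    expect_identical(quantify_alizarin(al$image), as.integer(ta))
    oi <- generate_stained_image("oilred", ta, shape = c(128, 128),
                                 seed = ta + 2)
    expect_identical(quantify_oilred(oi$image, min_droplet_area = 1),
                     as.integer(ta))
  }
  ac <- generate_stained_image("alcian", 500, shape = c(128, 128), seed = 5)
  expect_equal(quantify_alcian(ac$image, ac$pellet_mask),
               500 / sum(ac$pellet_mask))
  ac0 <- generate_stained_image("alcian", 0, shape = c(128, 128), seed = 6)
  expect_true(is.matrix(ac0$pellet_mask))
  expect_equal(quantify_alcian(ac0$image, ac0$pellet_mask), 0)
  expect_error(generate_stained_image("alizarin", 1e9, shape = c(64, 64)),
               "exceeds")
})

test_that("the gene table has 69 rows with the injected passage structure", {
  # 3 lots x 8 passages: the all-lots requirement of the screen suppresses
  # chance correlations of noise genes
  cfg <- synthetic_config(n_wells = 1, n_fields = 1, seed = 13)
  g <- generate_gene_expression(cfg)
  expect_equal(nrow(g), 69)
  expect_equal(ncol(g), length(cfg$passages) * cfg$n_lots)
  expect_true(all(attr(g, "passage_linked") %in% rownames(g)))
  g0 <- generate_gene_expression(cfg, passage_linked = character(0))
  truth <- generate_morphology_truth(cfg)
  hits <- passage_correlated_genes(normalize_genes(g0),
                                   truth$samples$passage,
                                   truth$samples$lot)
  expect_length(hits, 0)
})
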