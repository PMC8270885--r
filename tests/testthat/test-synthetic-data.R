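test_that("empty and zero-rate scenes degenerate cleanly", {
  sc0 <- simulate_sg_scene(scene_config(n_cells = 0, seed = 1))
  expect_equal(nrow(sc0$truth$cells), 0L)
  expect_equal(nrow(sc0$truth$spots), 0L)
  expect_true(all(sc0$channels$nuclei == 10))
  expect_true(all(sc0$channels$tial1 == 10))

  scz <- simulate_sg_scene(scene_config(n_cells = 8, sg_rate = 0,
                                        sg_rate_untransfected = 0, seed = 2))
  expect_equal(nrow(scz$truth$spots), 0L)
  expect_true(all(scz$truth$spot_labels == 0L))
})

test_that("scene generation is deterministic given the seed", {
  cfg <- scene_config(n_cells = 10, transfected_fraction = 0.5,
                      noise_sd = 2, seed = 1)
  a <- simulate_sg_scene(cfg)
  b <- simulate_sg_scene(cfg)
  expect_identical(a$channels, b$channels)
  expect_identical(a$truth, b$truth)
})

test_that("planted cell and spot bookkeeping is conserved", {
  for (seed in c(3, 11)) {
    cfg <- scene_config(n_cells = 14, transfected_fraction = 0.5,
                        sg_rate = 2, seed = seed)
    sc <- simulate_sg_scene(cfg)
    expect_equal(sum(sc$truth$cells$transfected), round(0.5 * 14))
    # conservation: planted spot count equals the sum of per-cell counts
    expect_equal(nrow(sc$truth$spots), sum(sc$truth$cells$n_spots))
    # every spot lies in its owning cell's cytoplasm
    for (j in seq_len(nrow(sc$truth$spots))) {
      r <- round(sc$truth$spots$center_r[j]); c <- round(sc$truth$spots$center_c[j])
      expect_equal(sc$truth$cell_labels[r, c], sc$truth$spots$cell_id[j])
      expect_equal(sc$truth$nucleus_labels[r, c], 0L)
    }
  }
})

test_that("impossible placements fail naming the constraint", {
  expect_error(simulate_sg_scene(scene_config(image_size = c(120, 120),
                                              n_cells = 40, seed = 1)),
               "non-overlapping nuclei")
})

test_that("experiment simulation respects design cardinality and determinism", {
  design <- expand.grid(construct = c("WT", "S78N"),
                        treatment = c("NT", "MG"),
                        replicate = 1:2, stringsAsFactors = FALSE)
  cfg <- scene_config(n_cells = 6, seed = 9)
  ex1 <- simulate_experiment(design, cfg)
  expect_length(ex1$scenes, 8L)
  expect_equal(nrow(ex1$metadata), 8L)
  ex2 <- simulate_experiment(design, cfg)
  expect_identical(ex1$scenes[[3]]$channels, ex2$scenes[[3]]$channels)

  expect_length(simulate_experiment(design[0, ], cfg)$scenes, 0L)
  expect_error(simulate_experiment(rbind(design, design[1, ]), cfg),
               "duplicate")
})

test_that("design columns override scene config per row", {
  design <- data.frame(construct = c("WT", "MUT"), treatment = "NT",
                       replicate = 1, sg_rate = c(0, 4))
  ex <- simulate_experiment(design, scene_config(n_cells = 8,
                                                 transfected_fraction = 1,
                                                 sg_rate_untransfected = 0,
                                                 seed = 4))
  expect_equal(nrow(ex$scenes[[1]]$truth$spots), 0L)
  expect_gt(nrow(ex$scenes[[2]]$truth$spots), 0L)
})

test_that("genotype panels plant a recoverable shared segment", {
  cfg <- genotype_panel_config(seed = 21)
  p1 <- simulate_genotype_panel(cfg)
  p2 <- simulate_genotype_panel(cfg)
  expect_identical(p1$genotypes, p2$genotypes)

  g <- p1$genotypes
  shared <- cfg$shared_interval_bp
  inside <- g$pos_bp >= shared[1] & g$pos_bp <= shared[2]
  carriers <- as.matrix(g[, p1$carrier_ids])
  expect_true(all(apply(carriers[inside, , drop = FALSE], 1,
                        function(a) all(a == a[1]))))
  # boundary markers exist exactly at the planted interval ends
  expect_true(all(shared %in% g$pos_bp))
  # first marker outside each end is discordant
  left <- max(which(g$pos_bp < shared[1]))
  right <- min(which(g$pos_bp > shared[2]))
  expect_gt(length(unique(carriers[left, ])), 1L)
  expect_gt(length(unique(carriers[right, ])), 1L)
})

test_that("genotype panel preconditions are enforced", {
  expect_error(genotype_panel_config(carrier_ids = "one"), "two carriers")
  expect_error(genotype_panel_config(shared_interval_bp = c(1e6, 50e6)),
               "strictly inside")
  # too few markers to flank the interval
  expect_error(genotype_panel_config(n_markers = 3), ">= 5 markers")
})

test_that("densitometry tables have the planted structure", {
  cfg <- densitometry_config(noise_cv = 0, seed = 1)
  tab <- simulate_densitometry(cfg)
  # three triplicate experiments: 9 rows per construct and fraction
  counts <- table(tab$construct, tab$fraction)
  expect_true(all(counts == 9L))
  # noise_cv = 0: intensities exactly at expected means
  wt_sup <- tab$band_intensity[tab$construct == "WT" &
                                 tab$fraction == "supernatant"]
  expect_true(all(wt_sup == 100))
  p7t_sup <- tab$band_intensity[tab$construct == "P7T" &
                                  tab$fraction == "supernatant"]
  expect_true(all(p7t_sup == 100 * (1 - 0.6)))
  # the shift moves signal, never creates it: totals equal across constructs
  totals <- tapply(tab$band_intensity, tab$construct, sum)
  expect_true(all(abs(totals - totals["WT"]) < 1e-9))
})

test_that("zero solubility shift reproduces the wild-type split", {
  cfg <- densitometry_config(constructs = c("WT", "M1"),
                             solubility_shift = c(WT = 0, M1 = 0),
                             noise_cv = 0, seed = 2)
  tab <- simulate_densitometry(cfg)
  sup <- tapply(tab$band_intensity[tab$fraction == "supernatant"],
                tab$construct[tab$fraction == "supernatant"], mean)
  expect_equal(unname(sup["M1"]), unname(sup["WT"]))
})
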