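test_that("cell segmentation recovers planted cells exactly on clean scenes", {
  sc <- simulate_sg_scene(scene_config(n_cells = 20, seed = 2))
  cells <- segment_cells(sc)
  expect_equal(nrow(cells$cells), 20L)
  # cytoplasm excludes every nucleus pixel
  expect_true(all(cells$cyto_labels[cells$nucleus_labels > 0] == 0L))
})

test_that("blank or degenerate nuclei channels yield no cells", {
  blank <- structure(list(channels = list(nuclei = matrix(5, 64, 64),
                                          v5 = matrix(5, 64, 64),
                                          tial1 = matrix(5, 64, 64))),
                     class = "sg_scene")
  expect_equal(nrow(segment_cells(blank)$cells), 0L)
  expect_error(segment_cells(list(channels = list(v5 = matrix(0, 4, 4)))),
               "nuclei")
})

test_that("nuclei below the minimum area are excluded", {
  sc <- handmade_scene()
  sc$channels$nuclei[10:11, 10:11] <- 110  # 4-px speck
  cells <- segment_cells(sc, segmentation_params(nucleus_min_area_px = 30))
  expect_equal(nrow(cells$cells), 1L)  # only the 81-px nucleus survives
})

test_that("transfection recovery matches planted status", {
  sc <- simulate_sg_scene(scene_config(n_cells = 16, transfected_fraction = 0.5,
                                       seed = 7))
  s <- quantify_image(sc, scene_id = "s")
  det <- s$per_cell$is_transfected
  # map detected cells to truth by centroid ownership
  truth <- vapply(seq_len(nrow(s$cells$cells)), function(i) {
    lab <- sc$truth$cell_labels[round(s$cells$cells$centroid_r[i]),
                                round(s$cells$cells$centroid_c[i])]
    sc$truth$cells$transfected[lab]
  }, logical(1))
  expect_equal(det, truth)
})

test_that("k-sigma transfection calls respect a reference population", {
  sc0 <- simulate_sg_scene(scene_config(n_cells = 10, transfected_fraction = 0,
                                        seed = 3))
  p <- segmentation_params(v5_positive_method = "k_sigma_over_untransfected")
  cells0 <- classify_transfection(segment_cells(sc0, p), sc0, p)
  expect_false(any(cells0$cells$is_transfected))

  sc1 <- simulate_sg_scene(scene_config(n_cells = 10, transfected_fraction = 1,
                                        seed = 3))
  ref <- cells0$cells$mean_v5
  cells1 <- classify_transfection(segment_cells(sc1, p), sc1, p,
                                  reference_means = ref)
  expect_true(all(cells1$cells$is_transfected))
})

test_that("otsu transfection split fails informatively on constant V5", {
  sc <- simulate_sg_scene(scene_config(n_cells = 6, transfected_fraction = 0,
                                       seed = 5))
  sc$channels$v5[] <- 10  # a flat channel makes every cell mean identical
  cells <- segment_cells(sc)
  expect_error(classify_transfection(cells, sc), "k_sigma")
})

test_that("granule detection is restricted to cytoplasm", {
  sc <- handmade_scene()
  # one spot in the cytoplasm, one inside the nucleus
  bump <- function(m, r0, c0, rad = 3, amp = 80) {
    for (dr in -rad:rad) for (dc in -rad:rad)
      if (dr^2 + dc^2 <= rad^2)
        m[r0 + dr, c0 + dc] <- m[r0 + dr, c0 + dc] +
          amp * exp(-(dr^2 + dc^2) / (2 * (rad / 1.5)^2))
    m
  }
  sc$channels$tial1 <- bump(sc$channels$tial1, 48, 64)  # cytoplasmic
  sc$channels$tial1 <- bump(sc$channels$tial1, 48, 48)  # nuclear
  cells <- segment_cells(sc)
  g <- detect_granules(sc, cells)
  expect_equal(nrow(g$granules), 1L)
  expect_gt(g$granules$centroid_c, 56)
})

test_that("flat TIAL1 yields no granules", {
  sc <- simulate_sg_scene(scene_config(n_cells = 6, sg_rate = 0,
                                       sg_rate_untransfected = 0, seed = 8))
  cells <- segment_cells(sc)
  expect_equal(nrow(detect_granules(sc, cells)$granules), 0L)
})

test_that("donut ratio uses medians with strict threshold semantics", {
  sc <- handmade_scene(bg = 100)
  cells <- segment_cells(sc)
  # square spot of V5 130 over uniform 100 background in the cytoplasm
  spot_labels <- matrix(0L, 96, 96)
  spot_labels[46:50, 62:66] <- 1L
  sc$channels$v5[46:50, 62:66] <- 130
  g <- structure(list(granules = data.frame(granule_id = 1L,
                                            cell_id = cells$cells$cell_id[1],
                                            pixel_count = 25L,
                                            median_tial1 = NA_real_,
                                            centroid_r = 48, centroid_c = 64),
                      spot_labels = spot_labels), class = "sg_granules")
  scored <- score_v5_enrichment(g, sc, cells)
  expect_equal(scored$granules$enrichment_ratio, 1.3)
  expect_true(scored$granules$is_v5_enriched)

  # uniform V5: ratio exactly 1, not enriched
  sc$channels$v5[] <- 100
  scored <- score_v5_enrichment(g, sc, cells)
  expect_equal(scored$granules$enrichment_ratio, 1)
  expect_false(scored$granules$is_v5_enriched)

  # ratio exactly at the 1.2 threshold is NOT enriched (strict >)
  sc$channels$v5[] <- 100
  sc$channels$v5[46:50, 62:66] <- 120
  scored <- score_v5_enrichment(g, sc, cells)
  expect_equal(scored$granules$enrichment_ratio, 1.2)
  expect_false(scored$granules$is_v5_enriched)
})

test_that("zero donut median reports an infinite ratio with a warning", {
  sc <- handmade_scene(bg = 0)
  sc$channels$nuclei[44:52, 44:52] <- 100
  cells <- segment_cells(sc)
  spot_labels <- matrix(0L, 96, 96)
  spot_labels[46:50, 62:66] <- 1L
  sc$channels$v5[46:50, 62:66] <- 50
  g <- structure(list(granules = data.frame(granule_id = 1L,
                                            cell_id = cells$cells$cell_id[1],
                                            pixel_count = 25L,
                                            median_tial1 = NA_real_,
                                            centroid_r = 48, centroid_c = 64),
                      spot_labels = spot_labels), class = "sg_granules")
  expect_warning(scored <- score_v5_enrichment(g, sc, cells), "zero")
  expect_equal(scored$granules$enrichment_ratio, Inf)
  expect_true(scored$granules$is_v5_enriched)
})

test_that("donut pixels avoid all granules and stay in the owning cytoplasm", {
  sc <- simulate_sg_scene(scene_config(n_cells = 10, transfected_fraction = 1,
                                       sg_rate = 3, enriched_fraction = 0.5,
                                       seed = 12))
  p <- segmentation_params(v5_positive_method = "k_sigma_over_untransfected")
  cells <- classify_transfection(segment_cells(sc, p), sc, p,
                                 reference_means = rep(15, 10))
  g <- score_v5_enrichment(detect_granules(sc, cells, p), sc, cells, p)
  # enriched flags match the planted truth for every matched granule
  for (j in seq_len(nrow(g$granules))) {
    ts <- sc$truth$spot_labels[round(g$granules$centroid_r[j]),
                               round(g$granules$centroid_c[j])]
    if (ts > 0 && !is.na(g$granules$is_v5_enriched[j]))
      expect_equal(g$granules$is_v5_enriched[j], sc$truth$spots$enriched[ts])
  }
})

test_that("classification is invariant under global intensity scaling", {
  sc <- simulate_sg_scene(scene_config(n_cells = 10, transfected_fraction = 0.5,
                                       sg_rate = 2, seed = 6))
  s1 <- quantify_image(sc, scene_id = "a")
  sc2 <- sc
  sc2$channels <- lapply(sc$channels, function(m) 3.7 * m)
  s2 <- quantify_image(sc2, scene_id = "b")
  expect_equal(s1$n_cells, s2$n_cells)
  expect_equal(s1$n_granules, s2$n_granules)
  expect_equal(s1$granules$granules$enrichment_ratio,
               s2$granules$granules$enrichment_ratio, tolerance = 1e-10)
  expect_equal(s1$per_cell$is_transfected, s2$per_cell$is_transfected)
})

test_that("image summaries conserve granule counts", {
  sc <- simulate_sg_scene(scene_config(n_cells = 12, transfected_fraction = 0.5,
                                       sg_rate = 2, seed = 10))
  s <- quantify_image(sc, scene_id = "s")
  expect_equal(sum(s$per_cell$n_sg), s$n_granules)
  expect_true(all(s$per_cell$n_enriched + s$per_cell$n_nonenriched <=
                    s$per_cell$n_sg))
  f <- s$fraction_cells_with_sg["all"]
  expect_equal(unname(f), mean(s$per_cell$n_sg > 0))
})
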