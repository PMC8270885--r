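#' Configuration for a synthetic stress-granule microscopy scene
#'
#' Builds the parameter set for [simulate_sg_scene()].  The generator
#' emulates a field of adherent cells stained for nuclei (Hoechst-like),
#' a V5 epitope tag on the transfected protein, and the stress-granule
#' marker TIAL1: nuclei are ellipses, cytoplasms irregular star-convex
#' regions around them, and stress granules are planted as compact
#' Gaussian bumps in the TIAL1 channel.  A planted granule may be
#' V5-enriched, in which case a co-located bump multiplies the local
#' cytoplasmic V5 level by `enrichment_factor` at the spot centre.
#'
#' @param image_size integer vector `c(height, width)` in pixels.
#' @param n_cells number of cells to place (non-overlapping nuclei).
#' @param transfected_fraction proportion of cells carrying the V5
#'   construct; the planted count is `round(fraction * n_cells)`.
#' @param sg_rate Poisson mean granule count per transfected cell.
#' @param sg_rate_untransfected Poisson mean per untransfected cell.
#' @param enriched_fraction probability that a planted granule is
#'   V5-enriched.
#' @param enrichment_factor peak multiplicative V5 boost inside enriched
#'   spots (must exceed 1).
#' @param spot_radius_px range `c(min, max)` of granule radii in pixels
#'   (minimum 2).
#' @param noise_sd additive Gaussian noise SD on every channel (images
#'   are clipped at zero).
#' @param background_level baseline intensity of all channels.
#' @param nucleus_radius_px range of nucleus ellipse semi-axes.
#' @param cyto_radius_px mean cytoplasm radius from the nucleus centre.
#' @param v5_untransfected,v5_transfected cytoplasmic V5 level added over
#'   background for untransfected and transfected cells.
#' @param tial1_cyto baseline cytoplasmic TIAL1 level over background.
#' @param spot_amplitude peak TIAL1 intensity added at a granule centre.
#' @param seed integer seed; identical configs give bit-identical scenes.
#' @return an object of class `scene_config` (a validated list).
#' @export
scene_config <- function(image_size = c(360L, 360L),
                         n_cells = 20,
                         transfected_fraction = 0.5,
                         sg_rate = 2,
                         sg_rate_untransfected = 0.5,
                         enriched_fraction = 0.5,
                         enrichment_factor = 2,
                         spot_radius_px = c(2.5, 4),
                         noise_sd = 0,
                         background_level = 10,
                         nucleus_radius_px = c(5, 8),
                         cyto_radius_px = 24,
                         v5_untransfected = 5,
                         v5_transfected = 60,
                         tial1_cyto = 5,
                         spot_amplitude = 80,
                         seed = 1L) {
  if (length(image_size) != 2L || any(image_size < 32))
    stopf("`image_size` must be c(height, width) with both >= 32")
  check_number(n_cells, "n_cells", lower = 0)
  check_proportion(transfected_fraction, "transfected_fraction")
  check_number(sg_rate, "sg_rate", lower = 0)
  check_number(sg_rate_untransfected, "sg_rate_untransfected", lower = 0)
  check_proportion(enriched_fraction, "enriched_fraction")
  if (enrichment_factor <= 1)
    stopf("`enrichment_factor` must be > 1")
  if (length(spot_radius_px) != 2L || spot_radius_px[1] < 2 ||
      diff(spot_radius_px) < 0)
    stopf("`spot_radius_px` must be an increasing range with minimum >= 2")
  check_number(noise_sd, "noise_sd", lower = 0)
  cfg <- list(image_size = as.integer(image_size), n_cells = as.integer(n_cells),
              transfected_fraction = transfected_fraction, sg_rate = sg_rate,
              sg_rate_untransfected = sg_rate_untransfected,
              enriched_fraction = enriched_fraction,
              enrichment_factor = enrichment_factor,
              spot_radius_px = spot_radius_px, noise_sd = noise_sd,
              background_level = background_level,
              nucleus_radius_px = nucleus_radius_px,
              cyto_radius_px = cyto_radius_px,
              v5_untransfected = v5_untransfected,
              v5_transfected = v5_transfected, tial1_cyto = tial1_cyto,
              spot_amplitude = spot_amplitude, seed = as.integer(seed))
  class(cfg) <- "scene_config"
  cfg
}

#' Simulate a multi-channel stress-granule scene with ground truth
#'
#' @param config a [scene_config()].
#' @return an object of class `sg_scene`: a list with
#'   \describe{
#'     \item{channels}{named list of matrices `nuclei`, `v5`, `tial1`
#'       (non-negative intensities, identical dimensions).}
#'     \item{truth}{ground truth: `cells` data frame (id, centre,
#'       transfected flag, planted granule count), `spots` data frame
#'       (id, owning cell, centre, radius, enriched flag), plus label
#'       matrices `cell_labels`, `nucleus_labels`, `spot_labels`.}
#'   }
#' @details Cells are placed with non-overlapping nuclei and a margin of
#'   one cytoplasm radius from the image border; if `n_cells` do not fit
#'   after bounded retries the function fails naming the constraint.
#'   Granule counts per cell are Poisson with the configured rates; each
#'   granule is enriched with probability `enriched_fraction`.
#' @export
simulate_sg_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, simulate_sg_scene_impl(config))
}

simulate_sg_scene_impl <- function(cfg) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  bg <- cfg$background_level
  chan <- list(nuclei = matrix(bg, H, W), v5 = matrix(bg, H, W),
               tial1 = matrix(bg, H, W))
  empty_truth <- list(
    cells = data.frame(cell_id = integer(), center_r = numeric(),
                       center_c = numeric(), transfected = logical(),
                       n_spots = integer()),
    spots = data.frame(spot_id = integer(), cell_id = integer(),
                       center_r = numeric(), center_c = numeric(),
                       radius = numeric(), enriched = logical()),
    cell_labels = matrix(0L, H, W), nucleus_labels = matrix(0L, H, W),
    spot_labels = matrix(0L, H, W))

  if (cfg$n_cells == 0L) {
    sc <- list(channels = add_noise(chan, cfg$noise_sd), truth = empty_truth)
    class(sc) <- "sg_scene"
    return(sc)
  }

  ## --- place nuclei: margin keeps the whole cell (and the reach of a
  ## downstream nucleus-plus-cytoplasm segmentation) off the border ---
  margin <- ceiling(cfg$cyto_radius_px * 1.2 + cfg$nucleus_radius_px[2] + 8)
  min_sep <- 2 * cfg$cyto_radius_px * 0.85  # keeps cytoplasm overlap moderate
  if (H - 2 * margin < 1 || W - 2 * margin < 1)
    stopf("image_size too small for cyto_radius_px margin of %d px", margin)
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < cfg$n_cells) {
    tries <- tries + 1L
    if (tries > 400L * cfg$n_cells)
      stopf(paste0("could not place %d non-overlapping nuclei in a %dx%d ",
                   "image (min centre separation %.1f px, border margin %d px)"),
            cfg$n_cells, H, W, min_sep, margin)
    cand <- c(stats::runif(1, margin, H - margin),
              stats::runif(1, margin, W - margin))
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                           byrow = TRUE))^2)) >= min_sep))
      centers <- rbind(centers, cand)
  }

  n <- cfg$n_cells
  n_transfected <- round(cfg$transfected_fraction * n)
  transfected <- rep(FALSE, n)
  if (n_transfected > 0) transfected[sample.int(n, n_transfected)] <- TRUE

  ax_a <- stats::runif(n, cfg$nucleus_radius_px[1], cfg$nucleus_radius_px[2])
  ax_b <- stats::runif(n, cfg$nucleus_radius_px[1], cfg$nucleus_radius_px[2])
  theta <- stats::runif(n, 0, pi)
  # irregular star-convex cytoplasm: radius modulated by two harmonics
  h_amp <- cbind(stats::runif(n, 0, 0.10), stats::runif(n, 0, 0.07))
  h_ph <- cbind(stats::runif(n, 0, 2 * pi), stats::runif(n, 0, 2 * pi))

  cell_labels <- matrix(0L, H, W)
  nucleus_labels <- matrix(0L, H, W)
  best_score <- matrix(Inf, H, W)
  r_max_all <- cfg$cyto_radius_px * 1.2

  for (i in seq_len(n)) {
    r0 <- max(1L, floor(centers[i, 1] - r_max_all))
    r1 <- min(H, ceiling(centers[i, 1] + r_max_all))
    c0 <- max(1L, floor(centers[i, 2] - r_max_all))
    c1 <- min(W, ceiling(centers[i, 2] + r_max_all))
    dr <- (r0:r1) - centers[i, 1]
    dc <- (c0:c1) - centers[i, 2]
    DR <- matrix(dr, length(dr), length(dc))
    DC <- matrix(dc, length(dr), length(dc), byrow = TRUE)
    d <- sqrt(DR^2 + DC^2)
    phi <- atan2(DC, DR)
    rad <- cfg$cyto_radius_px *
      (1 + h_amp[i, 1] * sin(2 * phi + h_ph[i, 1]) +
         h_amp[i, 2] * sin(3 * phi + h_ph[i, 2]))
    score <- d / rad
    inside <- score <= 1
    sub_best <- best_score[r0:r1, c0:c1]
    take <- inside & score < sub_best
    sub_lab <- cell_labels[r0:r1, c0:c1]
    sub_lab[take] <- i
    cell_labels[r0:r1, c0:c1] <- sub_lab
    sub_best[take] <- score[take]
    best_score[r0:r1, c0:c1] <- sub_best
    # nucleus ellipse (placement guarantees no nucleus overlap)
    u <- DR * cos(theta[i]) + DC * sin(theta[i])
    v <- -DR * sin(theta[i]) + DC * cos(theta[i])
    nuc <- (u / ax_a[i])^2 + (v / ax_b[i])^2 <= 1
    sub_n <- nucleus_labels[r0:r1, c0:c1]
    sub_n[nuc] <- i
    nucleus_labels[r0:r1, c0:c1] <- sub_n
  }
  # a nucleus pixel always belongs to its own cell
  cell_labels[nucleus_labels > 0] <- nucleus_labels[nucleus_labels > 0]
  cyto <- cell_labels > 0 & nucleus_labels == 0

  chan$nuclei[nucleus_labels > 0] <- bg + 100
  v5_level <- bg + ifelse(transfected, cfg$v5_transfected, cfg$v5_untransfected)
  cell_px <- cell_labels > 0
  chan$v5[cell_px] <- v5_level[cell_labels[cell_px]]
  chan$tial1[cyto] <- bg + cfg$tial1_cyto

  ## --- plant granules ---
  n_spots_cell <- stats::rpois(n, ifelse(transfected, cfg$sg_rate,
                                         cfg$sg_rate_untransfected))
  spot_labels <- matrix(0L, H, W)
  spots <- list()
  spot_id <- 0L
  for (i in seq_len(n)) {
    if (n_spots_cell[i] == 0L) next
    cyto_idx <- which(cyto & cell_labels == i, arr.ind = TRUE)
    placed <- matrix(numeric(0), 0, 2)
    for (s in seq_len(n_spots_cell[i])) {
      r <- stats::runif(1, cfg$spot_radius_px[1], cfg$spot_radius_px[2])
      ok <- FALSE
      for (att in seq_len(800L)) {
        ctr <- cyto_idx[sample.int(nrow(cyto_idx), 1L), ]
        if (nrow(placed) > 0 &&
            min(sqrt(rowSums((placed - matrix(ctr, nrow(placed), 2,
                                              byrow = TRUE))^2))) <
            2 * cfg$spot_radius_px[2] + 3) next
        rr <- max(1L, floor(ctr[1] - r - 1)):min(H, ceiling(ctr[1] + r + 1))
        cc <- max(1L, floor(ctr[2] - r - 1)):min(W, ceiling(ctr[2] + r + 1))
        DR <- matrix(rr - ctr[1], length(rr), length(cc))
        DC <- matrix(cc - ctr[2], length(rr), length(cc), byrow = TRUE)
        disk1 <- sqrt(DR^2 + DC^2) <= r + 1
        sub_ok <- cyto[rr, cc] & cell_labels[rr, cc] == i
        if (all(sub_ok[disk1])) { ok <- TRUE; break }
      }
      if (!ok)
        stopf(paste0("could not place granule %d of cell %d inside its ",
                     "cytoplasm (radius %.1f px + 1 px margin); reduce ",
                     "sg_rate or spot_radius_px"), s, i, r)
      placed <- rbind(placed, ctr)
      spot_id <- spot_id + 1L
      enriched <- stats::runif(1) < cfg$enriched_fraction
      d <- sqrt(DR^2 + DC^2)
      disk <- d <= r
      sub_sp <- spot_labels[rr, cc]
      sub_sp[disk] <- spot_id
      spot_labels[rr, cc] <- sub_sp
      # TIAL1 bump (truncated Gaussian, support = the spot disk)
      bump <- cfg$spot_amplitude * exp(-d^2 / (2 * (r / 1.5)^2))
      sub_t <- chan$tial1[rr, cc]
      sub_t[disk] <- sub_t[disk] + bump[disk]
      chan$tial1[rr, cc] <- sub_t
      if (enriched) {
        local_v5 <- v5_level[i]
        vb <- (cfg$enrichment_factor - 1) * local_v5 * exp(-d^2 / (2 * r^2))
        sub_v <- chan$v5[rr, cc]
        sub_v[disk] <- sub_v[disk] + vb[disk]
        chan$v5[rr, cc] <- sub_v
      }
      spots[[spot_id]] <- data.frame(spot_id = spot_id, cell_id = i,
                                     center_r = ctr[1], center_c = ctr[2],
                                     radius = r, enriched = enriched)
    }
  }
  spots <- if (length(spots)) do.call(rbind, spots) else empty_truth$spots

  truth <- list(
    cells = data.frame(cell_id = seq_len(n), center_r = centers[, 1],
                       center_c = centers[, 2], transfected = transfected,
                       n_spots = n_spots_cell),
    spots = spots, cell_labels = cell_labels,
    nucleus_labels = nucleus_labels, spot_labels = spot_labels)

  sc <- list(channels = add_noise(chan, cfg$noise_sd), truth = truth)
  class(sc) <- "sg_scene"
  sc
}

add_noise <- function(channels, sd) {
  if (sd > 0)
    channels <- lapply(channels, function(m)
      pmax(m + matrix(stats::rnorm(length(m), 0, sd), nrow(m)), 0))
  channels
}

#' @export
print.sg_scene <- function(x, ...) {
  d <- dim(x$channels$nuclei)
  cat(sprintf("<sg_scene> %d x %d px, %d cells (%d transfected), %d granules\n",
              d[1], d[2], nrow(x$truth$cells),
              sum(x$truth$cells$transfected), nrow(x$truth$spots)))
  invisible(x)
}

#' Simulate a full imaging experiment from a design table
#'
#' One scene is generated per design row; per-row seeds are derived
#' deterministically from `config$seed` so the whole collection is
#' reproducible.  Columns of `design` whose names match [scene_config()]
#' fields (e.g. `sg_rate`, `enriched_fraction`) override the base
#' configuration row-wise, which is how construct or treatment effects
#' are planted.
#'
#' @param design data frame with columns `construct`, `treatment`,
#'   `replicate` (rows must be unique) and optional config-override
#'   columns.
#' @param config base [scene_config()].
#' @return object of class `sg_experiment`: list of `scenes` and a
#'   `metadata` data frame (`scene_id`, `construct`, `treatment`,
#'   `replicate`).
#' @export
simulate_experiment <- function(design, config = scene_config()) {
  stopifnot(is.data.frame(design), inherits(config, "scene_config"))
  need <- c("construct", "treatment", "replicate")
  if (!all(need %in% names(design)))
    stopf("`design` must have columns construct, treatment, replicate")
  key <- interaction(design$construct, design$treatment, design$replicate,
                     drop = TRUE)
  if (anyDuplicated(key))
    stopf("duplicate design rows (construct x treatment x replicate)")
  m <- nrow(design)
  if (m == 0L)
    return(structure(list(scenes = list(),
                          metadata = cbind(data.frame(scene_id = character()),
                                           design)),
                     class = "sg_experiment"))
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L, m))
  overrides <- setdiff(intersect(names(design), names(config)), "seed")
  scenes <- vector("list", m)
  for (i in seq_len(m)) {
    cfg_i <- config
    for (f in overrides) cfg_i[[f]] <- design[[f]][i]
    cfg_i$seed <- seeds[i]
    scenes[[i]] <- simulate_sg_scene(cfg_i)
  }
  metadata <- data.frame(scene_id = sprintf("scene_%03d", seq_len(m)),
                         construct = design$construct,
                         treatment = design$treatment,
                         replicate = design$replicate,
                         stringsAsFactors = FALSE)
  structure(list(scenes = scenes, metadata = metadata),
            class = "sg_experiment")
}
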