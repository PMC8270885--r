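#' Parameters for cell segmentation and granule detection
#'
#' @param nucleus_min_area_px smallest retained nucleus area (pixels).
#' @param cytoplasm_radius_px cytoplasm reach: pixels within this
#'   distance of a nucleus are cytoplasm, assigned to the nearest
#'   nucleus.
#' @param spot_min_area_px,spot_max_area_px retained granule area band
#'   (`>=` min, `<=` max).
#' @param spot_detection_sigma_px inner scale of the difference-of-
#'   Gaussians band-pass used for spot detection (outer scale is 1.6x).
#' @param spot_threshold_k spot pixels must exceed this multiple of the
#'   per-cell cytoplasmic background (median TIAL1 over the cytoplasm).
#' @param v5_positive_method `"otsu_global"` (Otsu split of per-cell mean
#'   cytoplasmic V5) or `"k_sigma_over_untransfected"` (threshold at
#'   mean + `v5_k` SD of a reference untransfected population).
#' @param v5_k multiplier for the `k_sigma_over_untransfected` method.
#' @param donut_width_px width of the annulus ("donut") of local
#'   background sampled around each granule; the field-standard readout
#'   uses 5 px.
#' @param donut_gap_px gap between the granule boundary and the inner
#'   donut edge (default 0: the donut immediately surrounds the spot).
#' @param enrichment_ratio_threshold granules whose spot/donut median V5
#'   ratio strictly exceeds this are classified V5-enriched (default
#'   1.2).
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(nucleus_min_area_px = 30,
                                cytoplasm_radius_px = 30,
                                spot_min_area_px = 4,
                                spot_max_area_px = 400,
                                spot_detection_sigma_px = 2,
                                spot_threshold_k = 3,
                                v5_positive_method = c("otsu_global",
                                  "k_sigma_over_untransfected"),
                                v5_k = 3,
                                donut_width_px = 5,
                                donut_gap_px = 0,
                                enrichment_ratio_threshold = 1.2) {
  if (donut_width_px < 1) stopf("`donut_width_px` must be >= 1")
  if (enrichment_ratio_threshold <= 0)
    stopf("`enrichment_ratio_threshold` must be > 0")
  if (spot_min_area_px > spot_max_area_px)
    stopf("`spot_min_area_px` must be <= `spot_max_area_px`")
  structure(list(nucleus_min_area_px = nucleus_min_area_px,
                 cytoplasm_radius_px = cytoplasm_radius_px,
                 spot_min_area_px = spot_min_area_px,
                 spot_max_area_px = spot_max_area_px,
                 spot_detection_sigma_px = spot_detection_sigma_px,
                 spot_threshold_k = spot_threshold_k,
                 v5_positive_method = match.arg(v5_positive_method),
                 v5_k = v5_k, donut_width_px = donut_width_px,
                 donut_gap_px = donut_gap_px,
                 enrichment_ratio_threshold = enrichment_ratio_threshold),
            class = "segmentation_params")
}

get_channel <- function(scene, name) {
  ch <- scene$channels[[name]]
  if (is.null(ch)) stopf("scene is missing the `%s` channel", name)
  ch
}

#' Segment nuclei and assign cytoplasm regions
#'
#' Nuclei are thresholded (Otsu) in the nuclei channel, labelled, and
#' filtered by `nucleus_min_area_px`.  Cytoplasm is every non-nuclear
#' pixel within `cytoplasm_radius_px` of a nucleus, assigned to the
#' nearest nucleus.  Cells whose cytoplasm touches the image border are
#' discarded entirely, as partial cells bias per-cell counts.
#'
#' @param scene an `sg_scene` (or any list with a `channels` list of
#'   matrices including `nuclei`).
#' @param params a [segmentation_params()].
#' @return object of class `sg_cells`: list with `cells` data frame
#'   (`cell_id`, `nucleus_area`, `centroid_r`, `centroid_c`, `mean_v5`,
#'   `is_transfected` — the last two filled by
#'   [classify_transfection()]), and label matrices `nucleus_labels`,
#'   `cyto_labels`.
#' @export
segment_cells <- function(scene, params = segmentation_params()) {
  nuclei <- get_channel(scene, "nuclei")
  H <- nrow(nuclei); W <- ncol(nuclei)
  empty <- function() {
    structure(list(cells = data.frame(cell_id = integer(),
                                      nucleus_area = integer(),
                                      centroid_r = numeric(),
                                      centroid_c = numeric(),
                                      mean_v5 = numeric(),
                                      is_transfected = logical()),
                   nucleus_labels = matrix(0L, H, W),
                   cyto_labels = matrix(0L, H, W)),
              class = "sg_cells")
  }
  if (diff(range(nuclei)) == 0) return(empty())  # blank channel: no cells
  thr <- otsu_threshold(as.numeric(nuclei))
  mask <- nuclei > thr
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= params$nucleus_min_area_px)
  if (length(keep) == 0L) return(empty())

  # relabel retained nuclei 1..n
  relab <- integer(length(areas)); relab[keep] <- seq_along(keep)
  nucleus_labels <- matrix(0L, H, W)
  nz <- lab > 0
  nucleus_labels[nz] <- relab[lab[nz]]
  n <- length(keep)

  # cytoplasm: nearest-nucleus assignment within cytoplasm_radius_px,
  # computed per nucleus on a cropped window via a distance map
  rad <- params$cytoplasm_radius_px
  best_d <- matrix(Inf, H, W)
  cyto_labels <- matrix(0L, H, W)
  idx <- which(nucleus_labels > 0, arr.ind = TRUE)
  for (i in seq_len(n)) {
    pix <- idx[nucleus_labels[idx] == i, , drop = FALSE]
    r0 <- max(1L, min(pix[, 1]) - ceiling(rad))
    r1 <- min(H, max(pix[, 1]) + ceiling(rad))
    c0 <- max(1L, min(pix[, 2]) - ceiling(rad))
    c1 <- min(W, max(pix[, 2]) + ceiling(rad))
    sub <- nucleus_labels[r0:r1, c0:c1] == i
    d <- dist_to_set(sub)
    take <- d <= rad & d < best_d[r0:r1, c0:c1]
    bl <- cyto_labels[r0:r1, c0:c1]; bl[take] <- i
    cyto_labels[r0:r1, c0:c1] <- bl
    bd <- best_d[r0:r1, c0:c1]; bd[take] <- d[take]
    best_d[r0:r1, c0:c1] <- bd
  }
  cyto_labels[nucleus_labels > 0] <- 0L  # cytoplasm excludes every nucleus

  # discard border-touching cells entirely
  border <- unique(c(cyto_labels[1, ], cyto_labels[H, ],
                     cyto_labels[, 1], cyto_labels[, W],
                     nucleus_labels[1, ], nucleus_labels[H, ],
                     nucleus_labels[, 1], nucleus_labels[, W]))
  border <- border[border > 0]
  if (length(border)) {
    cyto_labels[cyto_labels %in% border] <- 0L
    nucleus_labels[nucleus_labels %in% border] <- 0L
  }
  ids <- sort(unique(nucleus_labels[nucleus_labels > 0]))
  if (length(ids) == 0L) return(empty())

  cent_r <- vapply(ids, function(i)
    mean(which(nucleus_labels == i, arr.ind = TRUE)[, 1]), numeric(1))
  cent_c <- vapply(ids, function(i)
    mean(which(nucleus_labels == i, arr.ind = TRUE)[, 2]), numeric(1))
  area <- vapply(ids, function(i) sum(nucleus_labels == i), integer(1))

  # compact ids to 1..k after border removal
  relab2 <- integer(max(ids)); relab2[ids] <- seq_along(ids)
  nz <- nucleus_labels > 0
  nucleus_labels[nz] <- relab2[nucleus_labels[nz]]
  nz <- cyto_labels > 0
  cyto_labels[nz] <- relab2[cyto_labels[nz]]

  structure(list(cells = data.frame(cell_id = seq_along(ids),
                                    nucleus_area = area,
                                    centroid_r = cent_r,
                                    centroid_c = cent_c,
                                    mean_v5 = NA_real_,
                                    is_transfected = NA),
                 nucleus_labels = nucleus_labels,
                 cyto_labels = cyto_labels),
            class = "sg_cells")
}

#' @export
print.sg_cells <- function(x, ...) {
  cat(sprintf("<sg_cells> %d cells", nrow(x$cells)))
  if (!all(is.na(x$cells$is_transfected)))
    cat(sprintf(" (%d transfected)", sum(x$cells$is_transfected)))
  cat("\n")
  invisible(x)
}

#' Classify cells as transfected from cytoplasmic V5 intensity
#'
#' Computes the mean cytoplasmic V5 per cell and applies the configured
#' decision rule: `otsu_global` splits the per-cell means with a 1-D
#' Otsu threshold; `k_sigma_over_untransfected` calls a cell transfected
#' when its mean exceeds `mean(ref) + v5_k * sd(ref)` of a reference
#' untransfected population (pass the per-cell means of an untransfected
#' control scene as `reference_means`; without a reference a robust
#' median + k * MAD of the scene's own cells is used, floored at 1.5x
#' the median, which assumes untransfected cells are the majority).
#'
#' @param cells an `sg_cells` from [segment_cells()].
#' @param scene the scene (for its `v5` channel).
#' @param params a [segmentation_params()].
#' @param reference_means optional numeric vector of mean cytoplasmic V5
#'   of known-untransfected cells.
#' @return the `sg_cells` object with `mean_v5` and `is_transfected`
#'   filled; the applied method and threshold are stored in attributes
#'   `"v5_method"` and `"v5_threshold"` of the `cells` data frame.
#' @export
classify_transfection <- function(cells, scene,
                                  params = segmentation_params(),
                                  reference_means = NULL) {
  stopifnot(inherits(cells, "sg_cells"))
  v5 <- get_channel(scene, "v5")
  df <- cells$cells
  if (nrow(df) == 0L) return(cells)
  means <- vapply(df$cell_id, function(i)
    mean(v5[cells$cyto_labels == i]), numeric(1))
  method <- params$v5_positive_method
  if (method == "otsu_global") {
    if (diff(range(means)) == 0)
      stopf(paste0("all per-cell V5 means are equal; otsu_global cannot ",
                   "split them - use v5_positive_method = ",
                   "\"k_sigma_over_untransfected\" with a reference"))
    thr <- otsu_threshold(means)
  } else {
    thr <- if (!is.null(reference_means)) {
      mean(reference_means) + params$v5_k * stats::sd(reference_means)
    } else {
      # self-calibrated fallback: robust location + scale of the scene's
      # own cells, with a 1.5x multiplicative floor so pure geometric
      # variation among untransfected cells is never called positive
      max(stats::median(means) + params$v5_k * mad0(means),
          1.5 * stats::median(means))
    }
  }
  df$mean_v5 <- means
  df$is_transfected <- means > thr
  attr(df, "v5_method") <- method
  attr(df, "v5_threshold") <- thr
  cells$cells <- df
  cells
}

#' Detect cytoplasmic TIAL1 granules
#'
#' A spot pixel must (i) exceed `spot_threshold_k` times the cell's
#' cytoplasmic background (the median TIAL1 intensity over the cell's
#' cytoplasm) and (ii) have a positive difference-of-Gaussians band-pass
#' response at `spot_detection_sigma_px`, which restricts detections to
#' compact bright structures and splits nearby spots.  Connected
#' components restricted to cytoplasm are filtered to the
#' `[spot_min_area_px, spot_max_area_px]` band and assigned to the cell
#' containing their centroid.
#'
#' @param scene the scene (for its `tial1` channel).
#' @param cells an `sg_cells` from [segment_cells()].
#' @param params a [segmentation_params()].
#' @return object of class `sg_granules`: list with `granules` data
#'   frame (`granule_id`, `cell_id`, `pixel_count`, `median_tial1`,
#'   `centroid_r`, `centroid_c`; enrichment columns added by
#'   [score_v5_enrichment()]) and the `spot_labels` matrix.
#' @export
detect_granules <- function(scene, cells, params = segmentation_params()) {
  stopifnot(inherits(cells, "sg_cells"))
  tial1 <- get_channel(scene, "tial1")
  H <- nrow(tial1); W <- ncol(tial1)
  empty <- function() structure(
    list(granules = data.frame(granule_id = integer(), cell_id = integer(),
                               pixel_count = integer(),
                               median_tial1 = numeric(),
                               centroid_r = numeric(), centroid_c = numeric()),
         spot_labels = matrix(0L, H, W)),
    class = "sg_granules")
  if (nrow(cells$cells) == 0L) return(empty())

  s1 <- params$spot_detection_sigma_px
  resp <- EBImage::gblur(tial1, sigma = s1) -
    EBImage::gblur(tial1, sigma = 1.6 * s1)

  mask <- matrix(FALSE, H, W)
  for (i in cells$cells$cell_id) {
    pix <- cells$cyto_labels == i
    bg <- stats::median(tial1[pix])  # per-cell cytoplasmic background
    mask[pix] <- tial1[pix] > params$spot_threshold_k * bg & resp[pix] > 0
  }
  if (!any(mask)) return(empty())

  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= params$spot_min_area_px &
                areas <= params$spot_max_area_px)
  if (length(keep) == 0L) return(empty())

  idx <- which(lab > 0, arr.ind = TRUE)
  labv <- lab[idx]
  ord <- order(labv)
  idx <- idx[ord, , drop = FALSE]; labv <- labv[ord]
  rows <- split(seq_along(labv), labv)

  spot_labels <- matrix(0L, H, W)
  out <- vector("list", length(keep))
  gid <- 0L
  for (k in keep) {
    sel <- idx[rows[[as.character(k)]], , drop = FALSE]
    cr <- mean(sel[, 1]); cc <- mean(sel[, 2])
    cell <- cells$cyto_labels[round(cr), round(cc)]
    if (cell == 0L) {  # centroid off-cytoplasm: majority cytoplasm label
      labs <- cells$cyto_labels[sel]
      labs <- labs[labs > 0]
      if (length(labs) == 0L) next
      cell <- as.integer(names(which.max(table(labs))))
    }
    gid <- gid + 1L
    spot_labels[sel] <- gid
    out[[gid]] <- data.frame(granule_id = gid, cell_id = cell,
                             pixel_count = nrow(sel),
                             median_tial1 = stats::median(tial1[sel]),
                             centroid_r = cr, centroid_c = cc)
  }
  if (gid == 0L) return(empty())
  structure(list(granules = do.call(rbind, out[seq_len(gid)]),
                 spot_labels = spot_labels),
            class = "sg_granules")
}

#' @export
print.sg_granules <- function(x, ...) {
  cat(sprintf("<sg_granules> %d granules in %d cells\n",
              nrow(x$granules), length(unique(x$granules$cell_id))))
  if ("is_v5_enriched" %in% names(x$granules))
    cat(sprintf("  V5-enriched: %d of %d scored\n",
                sum(x$granules$is_v5_enriched, na.rm = TRUE),
                sum(!is.na(x$granules$is_v5_enriched))))
  invisible(x)
}

#' Score V5 enrichment of each granule by the donut ratio
#'
#' For each granule the donut is the annulus obtained by dilating the
#' spot by `donut_gap_px + donut_width_px` and removing (i) pixels
#' closer than `donut_gap_px`, (ii) every granule's pixels, and (iii)
#' anything outside the owning cell's cytoplasm.  The enrichment ratio
#' is `median(spot V5) / median(donut V5)`; a granule is V5-enriched
#' when the ratio strictly exceeds `enrichment_ratio_threshold`.  A
#' granule with an empty donut gets an `NA` ratio and is excluded from
#' enrichment tallies (it still counts as a granule); a zero donut
#' median yields ratio `Inf`, an enriched flag, and a warning.
#'
#' @param granules an `sg_granules` from [detect_granules()].
#' @param scene the scene (for its `v5` channel).
#' @param cells the `sg_cells` used for detection.
#' @param params a [segmentation_params()].
#' @return the `sg_granules` object with columns `median_v5_spot`,
#'   `median_v5_donut`, `enrichment_ratio`, `is_v5_enriched` added.
#' @export
score_v5_enrichment <- function(granules, scene, cells,
                                params = segmentation_params()) {
  stopifnot(inherits(granules, "sg_granules"), inherits(cells, "sg_cells"))
  v5 <- get_channel(scene, "v5")
  g <- granules$granules
  H <- nrow(v5); W <- ncol(v5)
  reach <- params$donut_gap_px + params$donut_width_px
  med_spot <- med_donut <- ratio <- rep(NA_real_, nrow(g))
  flag <- rep(NA, nrow(g))
  any_spot <- granules$spot_labels > 0
  for (j in seq_len(nrow(g))) {
    id <- g$granule_id[j]
    pix <- which(granules$spot_labels == id, arr.ind = TRUE)
    r0 <- max(1L, min(pix[, 1]) - ceiling(reach) - 1L)
    r1 <- min(H, max(pix[, 1]) + ceiling(reach) + 1L)
    c0 <- max(1L, min(pix[, 2]) - ceiling(reach) - 1L)
    c1 <- min(W, max(pix[, 2]) + ceiling(reach) + 1L)
    sub_spot <- granules$spot_labels[r0:r1, c0:c1] == id
    d <- dist_to_set(sub_spot)
    donut <- d > params$donut_gap_px & d <= reach &
      !any_spot[r0:r1, c0:c1] &
      cells$cyto_labels[r0:r1, c0:c1] == g$cell_id[j]
    med_spot[j] <- stats::median(v5[pix])
    if (!any(donut)) next  # empty donut: ratio undefined
    med_donut[j] <- stats::median(v5[r0:r1, c0:c1][donut])
    if (med_donut[j] == 0) {
      warning(sprintf("granule %d: donut median V5 is zero; ratio = Inf", id),
              call. = FALSE)
      ratio[j] <- Inf
      flag[j] <- TRUE
    } else {
      ratio[j] <- med_spot[j] / med_donut[j]
      flag[j] <- ratio[j] > params$enrichment_ratio_threshold
    }
  }
  g$median_v5_spot <- med_spot
  g$median_v5_donut <- med_donut
  g$enrichment_ratio <- ratio
  g$is_v5_enriched <- flag
  granules$granules <- g
  granules
}

#' Quantify one scene: cells, granules, enrichment, summary
#'
#' Runs [segment_cells()], [classify_transfection()],
#' [detect_granules()] and [score_v5_enrichment()] and summarises the
#' result per cell and per transfection status.  A "SG-containing cell"
#' is a cell with at least one detected granule.
#'
#' @param scene an `sg_scene`.
#' @param params a [segmentation_params()].
#' @param reference_means optional reference for
#'   [classify_transfection()].
#' @param scene_id identifier carried into the summary.
#' @return object of class `sg_image_summary`: list with `per_cell`
#'   data frame (`cell_id`, `is_transfected`, `n_sg`, `n_enriched`,
#'   `n_nonenriched`), scalar counts (`n_cells`, `n_transfected`,
#'   `n_granules`) and per-status summaries `fraction_cells_with_sg`
#'   and `mean_sg_per_cell` (named: `transfected`, `untransfected`,
#'   `all`), plus the underlying `cells` and `granules` objects.
#' @export
quantify_image <- function(scene, params = segmentation_params(),
                           reference_means = NULL, scene_id = "scene") {
  cells <- segment_cells(scene, params)
  if (nrow(cells$cells) > 0)
    cells <- classify_transfection(cells, scene, params, reference_means)
  granules <- detect_granules(scene, cells, params)
  if (nrow(granules$granules) > 0)
    granules <- score_v5_enrichment(granules, scene, cells, params)

  df <- cells$cells
  g <- granules$granules
  n_sg <- tabulate(g$cell_id, nbins = max(df$cell_id, 0L))
  enr <- g$cell_id[!is.na(g$is_v5_enriched) & g$is_v5_enriched]
  non <- g$cell_id[!is.na(g$is_v5_enriched) & !g$is_v5_enriched]
  per_cell <- data.frame(cell_id = df$cell_id,
                         is_transfected = df$is_transfected,
                         n_sg = n_sg[df$cell_id],
                         n_enriched = tabulate(enr,
                                               nbins = max(df$cell_id, 0L))[df$cell_id],
                         n_nonenriched = tabulate(non,
                                                  nbins = max(df$cell_id, 0L))[df$cell_id])
  status_summary <- function(sel) {
    if (!any(sel)) return(c(fraction = NA_real_, mean_sg = NA_real_))
    c(fraction = mean(per_cell$n_sg[sel] > 0),
      mean_sg = mean(per_cell$n_sg[sel]))
  }
  tr <- per_cell$is_transfected %in% TRUE
  un <- per_cell$is_transfected %in% FALSE
  al <- rep(TRUE, nrow(per_cell))
  sm <- rbind(transfected = status_summary(tr),
              untransfected = status_summary(un),
              all = status_summary(al))
  structure(list(scene_id = scene_id, per_cell = per_cell,
                 n_cells = nrow(per_cell),
                 n_transfected = sum(tr),
                 n_granules = nrow(g),
                 fraction_cells_with_sg = sm[, "fraction"],
                 mean_sg_per_cell = sm[, "mean_sg"],
                 cells = cells, granules = granules),
            class = "sg_image_summary")
}

#' @export
print.sg_image_summary <- function(x, ...) {
  cat(sprintf("<sg_image_summary> %s: %d cells (%d transfected), %d granules\n",
              x$scene_id, x$n_cells, x$n_transfected, x$n_granules))
  cat(sprintf("  fraction of cells with >= 1 SG: %.3f (transfected), %.3f (untransfected)\n",
              x$fraction_cells_with_sg["transfected"],
              x$fraction_cells_with_sg["untransfected"]))
  invisible(x)
}
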