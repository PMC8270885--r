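# External-interface helpers: scenes as multi-page TIFF + truth sidecars,
# genotype panels as TSV, genetic maps as TSV.

#' Write a scene as a multi-page 16-bit TIFF with truth sidecars
#'
#' One TIFF page per channel (order: nuclei, v5, tial1), intensities
#' scaled by a fixed factor (`1/scale`, clipped to \[0, 1\]) so images
#' from one experiment are directly comparable.  If the scene carries
#' ground truth, a `<stem>_truth_cells.csv`, `<stem>_truth_spots.csv`
#' and a `<stem>_labels.png` (cell labels, scaled) are written next to
#' the TIFF.
#'
#' @param scene an `sg_scene`.
#' @param path output TIFF path.
#' @param scale intensity corresponding to full scale (default 1024).
#' @return `path`, invisibly.
#' @export
write_scene_tiff <- function(scene, path, scale = 1024) {
  pages <- lapply(scene$channels[c("nuclei", "v5", "tial1")],
                  function(m) pmin(pmax(m / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (!is.null(scene$truth)) {
    stem <- sub("\\.tiff?$", "", path)
    utils::write.csv(scene$truth$cells,
                     paste0(stem, "_truth_cells.csv"), row.names = FALSE)
    utils::write.csv(scene$truth$spots,
                     paste0(stem, "_truth_spots.csv"), row.names = FALSE)
    lab <- scene$truth$cell_labels
    png_path <- paste0(stem, "_labels.png")
    png::writePNG(lab / max(max(lab), 1L), png_path)
  }
  invisible(path)
}

#' Read a multi-page TIFF scene written by [write_scene_tiff()]
#'
#' @param path TIFF path.
#' @param scale the intensity scale used at write time.
#' @param channel_order channel names of the pages, in order.
#' @return an `sg_scene` (without ground truth).
#' @export
read_scene_tiff <- function(path, scale = 1024,
                            channel_order = c("nuclei", "v5", "tial1")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(channel_order))
    stopf("expected %d pages, found %d", length(channel_order),
          length(pages))
  channels <- stats::setNames(lapply(pages, function(p) p * scale),
                              channel_order)
  structure(list(channels = channels, truth = NULL), class = "sg_scene")
}

#' Write / read a genotype panel as TSV (+ JSON truth sidecar)
#'
#' @param panel a `genotype_panel`.
#' @param path output TSV path; the planted truth interval, if present,
#'   is written to `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(panel, path) {
  utils::write.table(panel$genotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(panel$truth))
    jsonlite::write_json(c(as.list(panel$truth),
                           list(carriers = panel$carrier_ids)),
                         paste0(path, ".truth.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @param carrier_ids carrier sample ids of the stored panel.
#' @export
read_genotype_tsv <- function(path, carrier_ids) {
  genotypes <- utils::read.table(path, sep = "\t", header = TRUE,
                                 colClasses = "character",
                                 check.names = FALSE)
  genotypes$pos_bp <- as.numeric(genotypes$pos_bp)
  if ("cM" %in% names(genotypes))
    genotypes$cM <- as.numeric(genotypes$cM)
  structure(list(genotypes = genotypes,
                 carrier_ids = carrier_ids, truth = NULL),
            class = "genotype_panel")
}

#' Read a genetic map TSV (`pos_bp`, `cM`)
#'
#' @param path TSV path with columns `pos_bp` and `cM`.
#' @return two-column matrix `(bp, cM)`.
#' @export
read_genetic_map <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  cbind(bp = d$pos_bp, cM = d$cM)
}
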