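#' Configuration for a synthetic hemizygous X-chromosome genotype panel
#'
#' Emulates SNP-array genotypes of male (hemizygous, one allele per
#' marker) mutation carriers plus unrelated non-carriers, with a planted
#' identical-by-descent segment shared by all carriers.  Markers are
#' always placed exactly at the planted segment boundaries, and the first
#' marker outside each boundary is forced to be discordant between at
#' least two carriers, so the planted interval is recoverable exactly by
#' [find_shared_segment()].
#'
#' @param n_markers total marker count (must allow at least one marker
#'   inside the segment and one flanking marker on each side).
#' @param chrom_span_bp physical range `c(start, end)` covered by markers.
#' @param shared_interval_bp planted shared segment `c(start, end)`;
#'   must lie strictly inside `chrom_span_bp`.
#' @param carrier_ids character vector of at least two carrier sample ids.
#' @param n_noncarriers number of unrelated control samples.
#' @param allele_freqs optional per-marker minor-allele frequency vector
#'   (recycled); default draws uniform in \[0.1, 0.5\].
#' @param map_points two-column matrix/data frame `(bp, cM)`, strictly
#'   increasing in both columns, used to annotate marker cM positions.
#' @param seed integer seed.
#' @return object of class `genotype_panel_config`.
#' @export
genotype_panel_config <- function(n_markers = 80,
                                  chrom_span_bp = c(5e6, 45e6),
                                  shared_interval_bp = c(17499443, 22849591),
                                  carrier_ids = c("carrier_1", "carrier_2"),
                                  n_noncarriers = 20,
                                  allele_freqs = NULL,
                                  map_points = default_genetic_map(),
                                  seed = 1L) {
  if (length(carrier_ids) < 2L)
    stopf("at least two carriers are required for haplotype sharing")
  if (shared_interval_bp[1] <= chrom_span_bp[1] ||
      shared_interval_bp[2] >= chrom_span_bp[2] ||
      shared_interval_bp[1] >= shared_interval_bp[2])
    stopf("`shared_interval_bp` must lie strictly inside `chrom_span_bp`")
  if (n_markers < 5L)
    stopf("need >= 5 markers (interval boundaries plus flanking markers)")
  map_points <- as.matrix(map_points)
  if (any(diff(map_points[, 1]) <= 0) || any(diff(map_points[, 2]) <= 0))
    stopf("`map_points` must be strictly increasing in both bp and cM")
  structure(list(n_markers = as.integer(n_markers),
                 chrom_span_bp = chrom_span_bp,
                 shared_interval_bp = shared_interval_bp,
                 carrier_ids = as.character(carrier_ids),
                 n_noncarriers = as.integer(n_noncarriers),
                 allele_freqs = allele_freqs, map_points = map_points,
                 seed = as.integer(seed)),
            class = "genotype_panel_config")
}

# synthetic X genetic map, roughly 1.5 cM/Mb with mild rate variation
default_genetic_map <- function() {
  bp <- c(0, 10e6, 20e6, 30e6, 45e6, 60e6, 155e6)
  cM <- c(0, 17, 31, 46, 66, 88, 215)
  cbind(bp = bp, cM = cM)
}

#' Simulate a hemizygous genotype panel with a planted shared segment
#'
#' @param config a [genotype_panel_config()].
#' @return object of class `genotype_panel`: list with
#'   \describe{
#'     \item{genotypes}{data frame `marker_id`, `pos_bp`, `cM`, then one
#'       single-allele ("A"/"B") column per sample.}
#'     \item{carrier_ids}{the carrier sample ids.}
#'     \item{truth}{planted interval `c(start_bp, end_bp)`.}
#'   }
#' @export
simulate_genotype_panel <- function(config) {
  stopifnot(inherits(config, "genotype_panel_config"))
  with_seed(config$seed, simulate_genotype_panel_impl(config))
}

simulate_genotype_panel_impl <- function(cfg) {
  span <- cfg$chrom_span_bp; shared <- cfg$shared_interval_bp
  n_free <- cfg$n_markers - 2L  # boundaries are always markers
  pos <- sort(round(stats::runif(n_free, span[1], span[2])))
  pos <- sort(unique(c(pos, shared)))
  # precondition: >= 1 interior marker and >= 1 flanking marker each side
  if (!any(pos > shared[1] & pos < shared[2]) ||
      !any(pos < shared[1]) || !any(pos > shared[2]))
    stopf(paste0("marker coverage insufficient: need >= 1 marker inside ",
                 "the shared interval and >= 1 flanking marker on each side"))
  m <- length(pos)
  af <- if (is.null(cfg$allele_freqs)) stats::runif(m, 0.1, 0.5)
        else rep_len(cfg$allele_freqs, m)

  samples <- c(cfg$carrier_ids,
               sprintf("control_%02d", seq_len(cfg$n_noncarriers)))
  n_car <- length(cfg$carrier_ids)
  draw <- function() ifelse(stats::runif(m) < af, "B", "A")

  geno <- matrix("", m, length(samples), dimnames = list(NULL, samples))
  founder <- draw()  # the shared ancestral haplotype
  inside <- pos >= shared[1] & pos <= shared[2]
  for (j in seq_len(n_car)) {
    g <- draw()
    g[inside] <- founder[inside]
    geno[, j] <- g
  }
  # force discordance at the first marker outside each boundary
  left <- max(which(pos < shared[1]))
  right <- min(which(pos > shared[2]))
  for (k in c(left, right)) {
    geno[k, 1] <- "A"
    geno[k, 2] <- "B"
  }
  for (j in seq_len(cfg$n_noncarriers)) geno[, n_car + j] <- draw()

  genotypes <- data.frame(marker_id = sprintf("rsX%05d", seq_len(m)),
                          pos_bp = pos,
                          cM = interpolate_cm(pos, cfg$map_points),
                          stringsAsFactors = FALSE)
  genotypes <- cbind(genotypes, as.data.frame(geno, stringsAsFactors = FALSE))
  structure(list(genotypes = genotypes, carrier_ids = cfg$carrier_ids,
                 truth = c(start_bp = shared[1], end_bp = shared[2])),
            class = "genotype_panel")
}

# piecewise-linear bp -> cM interpolation (linear extrapolation outside)
interpolate_cm <- function(bp, map_points) {
  x <- map_points[, 1]; y <- map_points[, 2]
  out <- stats::approx(x, y, xout = bp, rule = 1)$y
  lo <- bp < x[1]; hi <- bp > x[length(x)]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + (bp[lo] - x[1]) * s
  }
  if (any(hi)) {
    k <- length(x)
    s <- (y[k] - y[k - 1]) / (x[k] - x[k - 1])
    out[hi] <- y[k] + (bp[hi] - x[k]) * s
  }
  out
}
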