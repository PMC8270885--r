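#' Read variants from a VCF into a flat record table
#'
#' Thin wrapper around \pkg{vcfR} that extracts the fields the
#' prioritization filters need: position, alleles, gene symbol and
#' population allele-frequency INFO fields.  Any further INFO fields
#' named in `score_fields` (e.g. external predictor scores such as CADD
#' or SIFT) are carried through untouched as annotation columns.
#'
#' @param file path to a VCF (v4.x, plain or bgzipped).
#' @param gene_field INFO key holding the gene symbol (default
#'   `"GENE"`).
#' @param af_fields character vector of INFO keys holding population
#'   allele frequencies (default `c("AF_GNOMAD", "AF_EXAC")`); missing
#'   keys yield `NA` columns (treated as "absent from the database").
#' @param score_fields optional INFO keys passed through as-is.
#' @return data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, one column per AF field (lower-cased name), and any
#'   pass-through score columns.
#' @export
read_variant_table <- function(file, gene_field = "GENE",
                               af_fields = c("AF_GNOMAD", "AF_EXAC"),
                               score_fields = character()) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  out <- data.frame(chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    gene = vcfR::extract.info(v, gene_field),
                    stringsAsFactors = FALSE)
  for (f in af_fields)
    out[[tolower(f)]] <- vcfR::extract.info(v, f)
  for (f in score_fields)
    out[[f]] <- vcfR::extract.info(v, f)
  attr(out, "af_fields") <- tolower(af_fields)
  out
}

parse_af <- function(x) {
  # absent: NA / "" / "."  -> NA_real_ with ok = TRUE
  # malformed: non-numeric -> ok = FALSE
  absent <- is.na(x) | x == "" | x == "."
  num <- suppressWarnings(as.numeric(x))
  list(value = ifelse(absent, NA_real_, num),
       malformed = !absent & is.na(num))
}

#' Filter variants by population allele frequency
#'
#' A variant passes when its allele frequency is strictly below
#' `af_threshold` in \emph{every} provided database column.  A variant
#' absent from a database (`NA`, `"."` or empty) is treated as
#' frequency zero there ("absent from public genome aggregation
#' databases") and passes that column.  Malformed values mark the
#' variant `fail_other` with the offending field recorded.
#'
#' @param variants data frame (e.g. from [read_variant_table()]).
#' @param af_threshold strict upper bound (default 0.001, the
#'   standard rare-disease minor-allele-frequency cut-off).
#' @param af_fields columns holding allele frequencies; defaults to the
#'   attribute set by [read_variant_table()], else all columns whose
#'   name starts with `"af"`.
#' @return `variants` with columns `filter_status`
#'   (`"pass"`/`"fail_af"`/`"fail_other"`) and `filter_detail` (the
#'   database responsible for a failure).
#' @export
filter_rare <- function(variants, af_threshold = 0.001, af_fields = NULL) {
  if (is.null(af_fields)) af_fields <- attr(variants, "af_fields")
  if (is.null(af_fields))
    af_fields <- grep("^af", names(variants), value = TRUE)
  if (length(af_fields) == 0L)
    stopf("no allele-frequency columns found")
  status <- if ("filter_status" %in% names(variants))
    variants$filter_status else rep("pass", nrow(variants))
  detail <- if ("filter_detail" %in% names(variants))
    variants$filter_detail else rep(NA_character_, nrow(variants))
  for (f in af_fields) {
    p <- parse_af(variants[[f]])
    bad <- p$malformed & status == "pass"
    status[bad] <- "fail_other"
    detail[bad] <- sprintf("malformed value in %s", f)
    hit <- !p$malformed & !is.na(p$value) & p$value >= af_threshold &
      status == "pass"
    status[hit] <- "fail_af"
    detail[hit] <- f
  }
  variants$filter_status <- status
  variants$filter_detail <- detail
  variants
}

#' Restrict variants to a gene list
#'
#' Passes variants whose gene symbol (case-normalized) is in the list,
#' e.g. a muscle-expressed gene list derived from the skeletal-muscle
#' transcriptome.  Variants without a gene annotation fail.
#'
#' @param variants data frame with a `gene` column.
#' @param gene_list character vector of gene symbols (non-empty).
#' @return `variants` with `filter_status` set to `"pass"` or
#'   `"fail_gene_list"` (existing non-pass statuses are preserved).
#' @export
prioritize_gene_list <- function(variants, gene_list) {
  if (length(gene_list) == 0L) stopf("`gene_list` must be non-empty")
  genes <- toupper(trimws(gene_list))
  g <- toupper(trimws(variants$gene))
  in_list <- !is.na(g) & g %in% genes
  if (!"filter_status" %in% names(variants))
    variants$filter_status <- "pass"
  fail <- !in_list & variants$filter_status == "pass"
  variants$filter_status[fail] <- "fail_gene_list"
  variants
}

#' Allele frequency from allele counts
#'
#' @param allele_count observed alternate allele count (0 <= count <=
#'   number).
#' @param allele_number total number of alleles observed (> 0).
#' @return `allele_count / allele_number`, reported at 3 significant
#'   figures (the convention under which 6/205,256 is 2.92e-5).
#' @export
allele_frequency <- function(allele_count, allele_number) {
  if (any(allele_number <= 0)) stopf("`allele_number` must be > 0")
  if (any(allele_count < 0 | allele_count > allele_number))
    stopf("`allele_count` must be in [0, allele_number]")
  signif(allele_count / allele_number, 3)
}

#' Map a coding (CDS) position to its codon
#'
#' @param cds_pos 1-based coding-sequence nucleotide position(s).
#' @return data frame with `codon_index` (`ceiling(cds_pos / 3)`, the
#'   affected amino-acid residue, e.g. c.233 is in codon 78) and
#'   `position_in_codon` (1-3).
#' @export
cds_to_codon <- function(cds_pos) {
  if (any(cds_pos < 1) || any(cds_pos != round(cds_pos)))
    stopf("`cds_pos` must be a positive integer position")
  data.frame(codon_index = as.integer(ceiling(cds_pos / 3)),
             position_in_codon = as.integer((cds_pos - 1) %% 3 + 1))
}

#' Parse an HGVS coding single-nucleotide substitution
#'
#' Accepts the `c.<pos><ref>><alt>` substitution grammar
#' (whitespace-tolerant, as printed in clinical tables, e.g.
#' `"c.233G > A"`).  Everything else — indels, duplications,
#' intronic/splice offsets — is rejected explicitly.
#'
#' @param notation character scalar.
#' @return list with `cds_pos`, `ref_base`, `alt_base`.
#' @seealso [format_hgvs_c()] for the round-trip formatter.
#' @export
parse_hgvs_c <- function(notation) {
  m <- regmatches(notation,
                  regexec("^\\s*c\\.\\s*([0-9]+)\\s*([ACGT])\\s*>\\s*([ACGT])\\s*$",
                          notation))[[1]]
  if (length(m) != 4L)
    stopf(paste0("unsupported HGVS syntax: \"%s\" (only single-nucleotide ",
                 "substitutions \"c.<pos><ref>><alt>\" are supported)"),
          notation)
  list(cds_pos = as.integer(m[2]), ref_base = m[3], alt_base = m[4])
}

#' Format a coding substitution in HGVS notation
#'
#' @param cds_pos,ref_base,alt_base fields as returned by
#'   [parse_hgvs_c()].
#' @return character scalar, e.g. `"c.233G>A"`.
#' @export
format_hgvs_c <- function(cds_pos, ref_base, alt_base) {
  sprintf("c.%d%s>%s", cds_pos, ref_base, alt_base)
}
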