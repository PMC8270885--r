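# Independent oracles and fixture builders used across the suite.

# Brute-force two-way within-subject ANOVA via explicit projection
# matrices on the raw observation vector (independent of the
# mean-decomposition route used by rm_anova_gg).
projection_rm_anova <- function(Y) {
  # Y: n x a x b array
  n <- dim(Y)[1]; a <- dim(Y)[2]; b <- dim(Y)[3]
  y <- as.vector(Y)  # varies fastest over subjects, then a, then b
  Jn <- matrix(1 / n, n, n); Ja <- matrix(1 / a, a, a); Jb <- matrix(1 / b, b, b)
  Cn <- diag(n) - Jn; Ca <- diag(a) - Ja; Cb <- diag(b) - Jb
  # as.vector(Y) ordering corresponds to kronecker(Mb, kronecker(Ma, Mn))
  P <- function(Mn, Ma, Mb) kronecker(Mb, kronecker(Ma, Mn))
  ss <- function(M) as.numeric(t(y) %*% M %*% y)
  SS_A <- ss(P(Jn, Ca, Jb));  SS_AS <- ss(P(Cn, Ca, Jb))
  SS_B <- ss(P(Jn, Ja, Cb));  SS_BS <- ss(P(Cn, Ja, Cb))
  SS_AB <- ss(P(Jn, Ca, Cb)); SS_ABS <- ss(P(Cn, Ca, Cb))
  F_A <- (SS_A / (a - 1)) / (SS_AS / ((a - 1) * (n - 1)))
  F_B <- (SS_B / (b - 1)) / (SS_BS / ((b - 1) * (n - 1)))
  F_AB <- (SS_AB / ((a - 1) * (b - 1))) /
    (SS_ABS / ((a - 1) * (b - 1) * (n - 1)))
  list(F = c(F_A, F_B, F_AB),
       p = c(pf(F_A, a - 1, (a - 1) * (n - 1), lower.tail = FALSE),
             pf(F_B, b - 1, (b - 1) * (n - 1), lower.tail = FALSE),
             pf(F_AB, (a - 1) * (b - 1), (a - 1) * (b - 1) * (n - 1),
                lower.tail = FALSE)))
}

# Exact two-sided Mann-Whitney p by full enumeration of group
# assignments (feasible for n1 + n2 <= 12).
enumerate_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(n1 + n2, n1)
  ws <- apply(sets, 2, function(i) sum(r[i]))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force maximal shared run: scan every window of consecutive
# markers containing the mutation marker and keep the widest fully
# concordant one.
scan_shared_segment <- function(genotypes, carriers, mutation_pos_bp) {
  ord <- order(genotypes$pos_bp)
  pos <- genotypes$pos_bp[ord]
  G <- as.matrix(genotypes[ord, carriers, drop = FALSE])
  conc <- apply(G, 1, function(a) all(a == a[1]))
  core <- which.min(abs(pos - mutation_pos_bp))
  best <- NULL
  for (i in seq_along(pos)) for (j in i:length(pos)) {
    if (i <= core && core <= j && all(conc[i:j])) {
      if (is.null(best) || (j - i) > (best[2] - best[1])) best <- c(i, j)
    }
  }
  c(start_bp = pos[best[1]], end_bp = pos[best[2]])
}

# Minimal hand-built image-summary object for aggregation tests.
fake_image_summary <- function(scene_id, n_cells, n_with_sg, n_sg_total = n_with_sg,
                               transfected = TRUE) {
  counts <- integer(n_cells)
  if (n_with_sg > 0) {
    counts[seq_len(n_with_sg)] <- 1L
    extra <- n_sg_total - n_with_sg
    if (extra > 0) counts[1] <- counts[1] + extra
  }
  per_cell <- data.frame(cell_id = seq_len(n_cells),
                         is_transfected = transfected,
                         n_sg = counts, n_enriched = 0L,
                         n_nonenriched = counts)
  structure(list(scene_id = scene_id, per_cell = per_cell),
            class = "sg_image_summary")
}

# A blank single-cell scene whose geometry is fully known: square
# nucleus and an annular cytoplasm, for hand-constructed photometry.
handmade_scene <- function(size = 96, bg = 10) {
  ch <- list(nuclei = matrix(bg, size, size), v5 = matrix(bg, size, size),
             tial1 = matrix(bg, size, size))
  ch$nuclei[44:52, 44:52] <- bg + 100
  structure(list(channels = ch, truth = NULL), class = "sg_scene")
}

# Write a small VCF fixture and return its path.
write_test_vcf <- function(path, rows) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=AF_GNOMAD,Number=1,Type=Float,Description=\"gnomAD allele frequency\">",
    "##INFO=<ID=AF_EXAC,Number=1,Type=Float,Description=\"ExAC allele frequency\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD score\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(header, rows), path)
  path
}
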