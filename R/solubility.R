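#' Normalize fractionation densitometry to loading and wild type
#'
#' Each band intensity is divided by its lane's total-protein loading,
#' then by the mean of the wild-type values of the same experiment and
#' fraction, so the wild-type per-experiment mean maps to 1 and
#' between-experiment detection gain cancels.
#'
#' @param table data frame with columns `construct`, `experiment`,
#'   `replicate`, `fraction`, `band_intensity`, `total_protein`
#'   (as produced by [simulate_densitometry()]).
#' @param wt label of the wild-type construct (default `"WT"`).
#' @return the table with a `normalized` column added.
#' @export
normalize_fractions <- function(table, wt = "WT") {
  need <- c("construct", "experiment", "fraction", "band_intensity",
            "total_protein")
  if (!all(need %in% names(table)))
    stopf("missing columns: %s", paste(setdiff(need, names(table)),
                                       collapse = ", "))
  if (any(table$total_protein <= 0)) stopf("total_protein must be > 0")
  loaded <- table$band_intensity / table$total_protein
  key <- interaction(table$experiment, table$fraction, drop = TRUE)
  for (k in levels(key)) {
    sel <- key == k
    wt_mean <- mean(loaded[sel & table$construct == wt])
    if (!is.finite(wt_mean) || wt_mean == 0)
      stopf("wild-type mean is zero or missing in experiment/fraction %s", k)
    loaded[sel] <- loaded[sel] / wt_mean
  }
  table$normalized <- loaded
  table
}

# Exact two-sided Mann-Whitney p-value via the distribution of the
# rank sum over all C(n1+n2, n1) group assignments, computed with a
# shift algorithm (dynamic program) on doubled midranks so ties are
# handled exactly.
mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))        # midranks
  w_obs <- sum(r[seq_len(n1)])
  ir <- as.integer(round(2 * r))  # doubled midranks are integers
  smax <- sum(ir)
  # counts[k+1, s+1] = number of size-k subsets with doubled-rank sum s
  counts <- matrix(0, n1 + 1L, smax + 1L)
  counts[1L, 1L] <- 1
  for (v in ir) {
    kmax <- n1
    for (k in kmax:1) {
      nz <- which(counts[k, ] > 0)
      if (length(nz))
        counts[k + 1L, nz + v] <- counts[k + 1L, nz + v] + counts[k, nz]
    }
  }
  dist <- counts[n1 + 1L, ]
  total <- sum(dist)
  w2 <- as.integer(round(2 * w_obs))
  p_le <- sum(dist[seq_len(w2 + 1L)]) / total
  p_ge <- sum(dist[(w2 + 1L):(smax + 1L)]) / total
  min(1, 2 * min(p_le, p_ge))
}

mw_normal <- function(x, y) {
  # normal approximation with tie correction
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 == 0) return(1)
  z <- (w - mu) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Two-sample Mann-Whitney U test (exact for small groups)
#'
#' Exact two-sided p-value by full permutation of the rank sum for
#' groups of up to `exact_max` observations each (ties handled
#' exactly); larger groups use the normal approximation with tie
#' correction.  Degenerate comparisons (all values tied across both
#' groups) give p = 1.
#'
#' @param x,y numeric samples.
#' @param exact_max largest per-group size for the exact branch
#'   (default 12).
#' @return list with `U` (statistic of the first sample), `p` and
#'   `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y, exact_max = 12L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stopf("both groups must be non-empty")
  U <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(c(x, y))) == 1L)
    return(list(U = U, p = 1, method = "degenerate"))
  if (max(n1, n2) <= exact_max)
    list(U = U, p = mw_exact(x, y), method = "exact")
  else
    list(U = U, p = mw_normal(x, y), method = "normal")
}

#' Compare constructs to wild type within each fraction
#'
#' Pools the normalized replicates of each construct across experiments
#' (three triplicate experiments give n = 9 per construct and fraction)
#' and tests each mutant against wild type with a two-tailed
#' Mann-Whitney U test, Bonferroni-corrected.  By default the
#' correction family is the set of mutants within one fraction
#' (supernatant and pellet annotated independently).
#'
#' @param table normalized table from [normalize_fractions()].
#' @param wt wild-type label (default `"WT"`).
#' @param n_comparisons Bonferroni multiplier `m`; default the number
#'   of mutant constructs (per fraction).
#' @param value_col column to test (default `"normalized"`).
#' @return object of class `solubility_result`: data frame with one row
#'   per construct x fraction: `construct`, `fraction`, `mean`, `sd`,
#'   `n`, and for mutants `U`, `p`, `p_bonferroni`
#'   (`min(1, m * p)`), `stars` (`"*"` p < 0.05, `"**"` p < 0.01,
#'   adjusted), `method`.
#' @export
compare_to_wt <- function(table, wt = "WT", n_comparisons = NULL,
                          value_col = "normalized") {
  if (!value_col %in% names(table))
    stopf("column `%s` not found - run normalize_fractions() first",
          value_col)
  constructs <- unique(table$construct)
  mutants <- setdiff(constructs, wt)
  if (length(mutants) == 0L) stopf("no constructs other than \"%s\"", wt)
  m <- if (is.null(n_comparisons)) length(mutants) else n_comparisons
  rows <- list()
  for (fr in unique(table$fraction)) {
    sub <- table[table$fraction == fr, ]
    wt_vals <- sub[[value_col]][sub$construct == wt]
    if (length(wt_vals) < 3L)
      stopf("need >= 3 wild-type replicates in fraction %s", fr)
    for (cn in constructs) {
      vals <- sub[[value_col]][sub$construct == cn]
      row <- data.frame(construct = cn, fraction = fr,
                        mean = mean(vals), sd = stats::sd(vals),
                        n = length(vals), U = NA_real_, p = NA_real_,
                        p_bonferroni = NA_real_, stars = "",
                        method = NA_character_,
                        stringsAsFactors = FALSE)
      if (cn != wt) {
        if (length(vals) < 3L)
          stopf("need >= 3 replicates for %s in fraction %s", cn, fr)
        tst <- mann_whitney(vals, wt_vals)
        row$U <- tst$U
        row$p <- tst$p
        row$p_bonferroni <- min(1, m * tst$p)
        row$stars <- if (row$p_bonferroni < 0.01) "**"
                     else if (row$p_bonferroni < 0.05) "*" else ""
        row$method <- tst$method
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_comparisons") <- m
  attr(out, "wt") <- wt
  class(out) <- c("solubility_result", "data.frame")
  out
}

#' @export
print.solubility_result <- function(x, digits = 4, ...) {
  cat(sprintf("Solubility vs %s (Mann-Whitney, Bonferroni m = %d per fraction)\n\n",
              attr(x, "wt"), attr(x, "n_comparisons")))
  df <- as.data.frame(x)
  for (cl in c("mean", "sd", "U", "p", "p_bonferroni"))
    df[[cl]] <- signif(df[[cl]], digits)
  print(df, row.names = FALSE)
  invisible(x)
}
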