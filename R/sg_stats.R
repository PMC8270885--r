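#' Aggregate per-image summaries to replicate-level well summaries
#'
#' Computes, for every (construct, treatment, replicate) design cell,
#' cell-weighted means across its images: the proportion of
#' SG-containing cells, mean granules per cell, and mean V5-enriched /
#' non-enriched granules per cell.  "Cell-weighted" means an image
#' contributes in proportion to the number of cells it holds, i.e. the
#' aggregate equals the statistic computed over the pooled cells of the
#' replicate.
#'
#' @param summaries list of `sg_image_summary` objects from
#'   [quantify_image()].
#' @param metadata data frame with `scene_id`, `construct`, `treatment`,
#'   `replicate`; matched to `summaries` by `scene_id`.
#' @param cells which cell population to summarise: `"transfected"`
#'   (default, the V5-positive cells), `"untransfected"`, or `"all"`.
#' @return data frame of class `well_summary` with one row per design
#'   cell: `construct`, `treatment`, `replicate`, `prop_sg_cells`,
#'   `mean_sg_per_cell`, `mean_enriched_sg_per_cell`,
#'   `mean_nonenriched_sg_per_cell`, `n_cells`.
#' @export
aggregate_wells <- function(summaries, metadata,
                            cells = c("transfected", "untransfected",
                                      "all")) {
  cells <- match.arg(cells)
  ids <- vapply(summaries, function(s) s$scene_id, character(1))
  if (!all(metadata$scene_id %in% ids))
    stopf("metadata rows without a matching image summary")
  per_image <- lapply(seq_len(nrow(metadata)), function(i) {
    s <- summaries[[match(metadata$scene_id[i], ids)]]
    pc <- s$per_cell
    sel <- switch(cells,
                  transfected = pc$is_transfected %in% TRUE,
                  untransfected = pc$is_transfected %in% FALSE,
                  all = rep(TRUE, nrow(pc)))
    pc <- pc[sel, , drop = FALSE]
    data.frame(construct = metadata$construct[i],
               treatment = metadata$treatment[i],
               replicate = metadata$replicate[i],
               n_cells = nrow(pc),
               sum_with_sg = sum(pc$n_sg > 0),
               sum_sg = sum(pc$n_sg),
               sum_enriched = sum(pc$n_enriched),
               sum_nonenriched = sum(pc$n_nonenriched))
  })
  pi <- do.call(rbind, per_image)
  key <- interaction(pi$construct, pi$treatment, pi$replicate, drop = TRUE)
  agg <- lapply(split(pi, key), function(d) {
    n <- sum(d$n_cells)
    data.frame(construct = d$construct[1], treatment = d$treatment[1],
               replicate = d$replicate[1],
               prop_sg_cells = if (n > 0) sum(d$sum_with_sg) / n else NA_real_,
               mean_sg_per_cell = if (n > 0) sum(d$sum_sg) / n else NA_real_,
               mean_enriched_sg_per_cell =
                 if (n > 0) sum(d$sum_enriched) / n else NA_real_,
               mean_nonenriched_sg_per_cell =
                 if (n > 0) sum(d$sum_nonenriched) / n else NA_real_,
               n_cells = n)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  class(out) <- c("well_summary", "data.frame")
  out
}

orthonormal_contrasts <- function(k) {
  q <- qr.Q(qr(cbind(1, stats::contr.helmert(k))))
  t(q[, -1, drop = FALSE])  # (k-1) x k rows, orthonormal, each sums to 0
}

gg_epsilon <- function(scores) {
  # scores: subjects x d matrix of orthonormal within-subject contrast
  # scores; Greenhouse-Geisser epsilon = tr(M)^2 / (d * tr(M^2))
  d <- ncol(scores)
  M <- stats::cov(scores)
  if (sum(M^2) == 0) return(1)  # degenerate (constant) scores
  eps <- sum(diag(M))^2 / (d * sum(M^2))
  min(max(eps, 1 / d), 1)
}

#' Two-way repeated-measures ANOVA with the Greenhouse-Geisser correction
#'
#' Both factors are within-subject; the subject is the independent
#' experiment (replicate).  The design must be complete and balanced
#' (every subject observed once in every factor-level combination);
#' incomplete subjects are reported in the error so they can be dropped
#' explicitly.  For each effect the Greenhouse-Geisser epsilon is
#' estimated from the sample covariance of the effect's orthonormal
#' within-subject contrast scores, and the corrected p-value uses
#' epsilon-scaled numerator and denominator degrees of freedom.
#'
#' @param data data frame in long format.
#' @param response name of the response column.
#' @param within length-2 character vector naming the two within-subject
#'   factor columns.
#' @param subject name of the subject (replicate) column.
#' @return object of class `sg_anova`: a data frame with one row per
#'   effect (`A`, `B`, `A:B`, named after the factors) holding `SS`,
#'   `df`, `error_SS`, `error_df`, `F`, `epsilon_GG`, `p_uncorrected`,
#'   `p_GG`.
#' @export
rm_anova_gg <- function(data, response, within = c("construct", "treatment"),
                        subject = "replicate") {
  stopifnot(length(within) == 2L)
  cols <- c(response, within, subject)
  if (!all(cols %in% names(data)))
    stopf("missing columns: %s", paste(setdiff(cols, names(data)),
                                       collapse = ", "))
  y <- data[[response]]
  fs <- factor(data[[subject]])
  fa <- factor(data[[within[1]]])
  fb <- factor(data[[within[2]]])
  n <- nlevels(fs); a <- nlevels(fa); b <- nlevels(fb)
  if (n < 2) stopf("need >= 2 subjects, got %d", n)
  if (a < 2 || b < 2)
    stopf("each within-subject factor needs >= 2 levels")
  counts <- table(fs, fa, fb)
  if (any(counts != 1L)) {
    bad <- apply(counts != 1L, 1, any)
    stopf(paste0("design is not complete/balanced (one observation per ",
                 "subject x cell required); offending subjects: %s - drop ",
                 "them or complete the design"),
          paste(levels(fs)[bad], collapse = ", "))
  }
  Y <- tapply(y, list(fs, fa, fb), mean)  # n x a x b

  grand <- mean(Y)
  m_s <- apply(Y, 1, mean); m_a <- apply(Y, 2, mean); m_b <- apply(Y, 3, mean)
  m_sa <- apply(Y, c(1, 2), mean); m_sb <- apply(Y, c(1, 3), mean)
  m_ab <- apply(Y, c(2, 3), mean)

  SS_A <- n * b * sum((m_a - grand)^2)
  SS_B <- n * a * sum((m_b - grand)^2)
  SS_AB <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + grand)^2)
  SS_AS <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + grand)^2)
  SS_BS <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + grand)^2)
  fit <- array(0, dim(Y))
  for (i in seq_len(n)) for (j in seq_len(a)) for (k in seq_len(b))
    fit[i, j, k] <- m_sa[i, j] + m_sb[i, k] + m_ab[j, k] -
      m_s[i] - m_a[j] - m_b[k] + grand
  SS_ABS <- sum((Y - fit)^2)

  CA <- orthonormal_contrasts(a)
  CB <- orthonormal_contrasts(b)
  eps_A <- gg_epsilon(m_sa %*% t(CA))
  eps_B <- gg_epsilon(m_sb %*% t(CB))
  inter <- vapply(seq_len(n), function(i)
    as.numeric(CA %*% Y[i, , ] %*% t(CB)), numeric((a - 1) * (b - 1)))
  inter <- if (is.matrix(inter)) t(inter) else matrix(inter, ncol = 1L)
  eps_AB <- gg_epsilon(inter)

  eff <- function(term, SS, df1, eSS, df2, eps) {
    Fv <- (SS / df1) / (eSS / df2)
    data.frame(term = term, SS = SS, df = df1, error_SS = eSS,
               error_df = df2, F = Fv, epsilon_GG = eps,
               p_uncorrected = stats::pf(Fv, df1, df2, lower.tail = FALSE),
               p_GG = stats::pf(Fv, eps * df1, eps * df2,
                                lower.tail = FALSE))
  }
  out <- rbind(
    eff(within[1], SS_A, a - 1, SS_AS, (a - 1) * (n - 1), eps_A),
    eff(within[2], SS_B, b - 1, SS_BS, (b - 1) * (n - 1), eps_B),
    eff(paste(within, collapse = ":"), SS_AB, (a - 1) * (b - 1),
        SS_ABS, (a - 1) * (b - 1) * (n - 1), eps_AB))
  rownames(out) <- NULL
  attr(out, "n_subjects") <- n
  class(out) <- c("sg_anova", "data.frame")
  out
}

#' @export
print.sg_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Two-way repeated-measures ANOVA (%d subjects), Greenhouse-Geisser corrected\n\n",
              attr(x, "n_subjects")))
  df <- as.data.frame(x)
  df$SS <- signif(df$SS, digits); df$error_SS <- signif(df$error_SS, digits)
  df$F <- signif(df$F, digits)
  df$epsilon_GG <- signif(df$epsilon_GG, digits)
  df$p_uncorrected <- signif(df$p_uncorrected, digits)
  df$p_GG <- signif(df$p_GG, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

# Monte-Carlo reference sample of max_g |T_g| for Dunnett many-to-one
# contrasts in a randomized block design (equicorrelation 1/2), cached
# per (m, df, n_mc).
dunnett_maxt_sample <- function(m, df, n_mc = 1e5L) {
  key <- sprintf("dunnett_%d_%d_%d", m, df, n_mc)
  if (!is.null(.sgfound_cache[[key]])) return(.sgfound_cache[[key]])
  sample <- with_seed(772681L, {
    Z <- matrix(stats::rnorm(n_mc * (m + 1L)), n_mc, m + 1L)
    denom <- sqrt(stats::rchisq(n_mc, df) / df)
    T <- (Z[, -1L, drop = FALSE] - Z[, 1L]) / sqrt(2) / denom
    sort(apply(abs(T), 1, max))
  })
  .sgfound_cache[[key]] <- sample
  sample
}

#' Dunnett many-to-one comparisons against a control construct
#'
#' Compares every non-control group with the control on per-replicate
#' paired differences: the design is treated as a randomized block with
#' the replicate (independent experiment) as block, the error variance
#' is the block-design residual mean square, and the contrasts follow a
#' multivariate t distribution with equicorrelation 1/2.  Adjusted
#' p-values and simultaneous confidence limits use a Monte-Carlo
#' reference sample of the maximum absolute contrast (1e5 draws, fixed
#' internal seed; p-value tolerance about +/- 0.002).
#'
#' @param data data frame with one observation per group x replicate
#'   (aggregate first with [aggregate_wells()] if needed).
#' @param response name of the response column.
#' @param group name of the grouping column (default `"construct"`).
#' @param subject name of the replicate/block column.
#' @param control control group label (default `"WT"`).
#' @param conf_level simultaneous confidence level (default 0.95).
#' @param n_mc Monte-Carlo draws for the reference distribution.
#' @return object of class `sg_dunnett`: data frame with one row per
#'   comparison (`comparison`, `mean_diff`, `se`, `t`, `ci_low`,
#'   `ci_high`, `p_adjusted`).
#' @export
dunnett_vs_control <- function(data, response, group = "construct",
                               subject = "replicate", control = "WT",
                               conf_level = 0.95, n_mc = 1e5L) {
  fg <- factor(data[[group]])
  if (!control %in% levels(fg))
    stopf("control group \"%s\" not present", control)
  fg <- stats::relevel(fg, ref = control)
  fs <- factor(data[[subject]])
  y <- data[[response]]
  g <- nlevels(fg); n <- nlevels(fs)
  if (g < 2) stopf("need >= 2 groups including the control")
  if (any(table(fs, fg) != 1L))
    stopf("need exactly one observation per group x replicate")
  Y <- tapply(y, list(fs, fg), mean)  # n x g, col 1 = control
  grand <- mean(Y)
  res <- Y - outer(rowMeans(Y), rep(1, g)) -
    outer(rep(1, n), colMeans(Y)) + grand
  df_err <- (g - 1) * (n - 1)
  MSE <- sum(res^2) / df_err
  se <- sqrt(2 * MSE / n)
  diffs <- colMeans(Y)[-1] - colMeans(Y)[1]
  # zero residual variance: a zero difference is no evidence (t = 0),
  # a non-zero one is unbounded evidence
  tval <- if (se == 0) ifelse(diffs == 0, 0, sign(diffs) * Inf)
          else diffs / se
  maxt <- dunnett_maxt_sample(g - 1L, df_err, as.integer(n_mc))
  p_adj <- vapply(abs(tval), function(t)
    mean(maxt >= t), numeric(1))
  crit <- stats::quantile(maxt, conf_level, names = FALSE)
  out <- data.frame(comparison = paste(levels(fg)[-1], "vs", control),
                    mean_diff = diffs, se = se, t = tval,
                    ci_low = diffs - crit * se,
                    ci_high = diffs + crit * se,
                    p_adjusted = pmin(p_adj, 1))
  rownames(out) <- NULL
  attr(out, "df_error") <- df_err
  attr(out, "critical_value") <- crit
  attr(out, "conf_level") <- conf_level
  class(out) <- c("sg_dunnett", "data.frame")
  out
}

#' @export
print.sg_dunnett <- function(x, ...) {
  cl <- attr(x, "conf_level") * 100
  cat(sprintf("Dunnett many-to-one comparisons (df = %d, %g%% simultaneous CIs)\n",
              attr(x, "df_error"), cl))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %s: p = %.4f; mean diff. %.4f; %g%% CI %.4f to %.4f\n",
                x$comparison[i], x$p_adjusted[i], x$mean_diff[i], cl,
                x$ci_low[i], x$ci_high[i]))
  invisible(x)
}
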