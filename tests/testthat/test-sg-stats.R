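test_that("well aggregation is cell-weighted", {
  summaries <- list(fake_image_summary("s1", n_cells = 50, n_with_sg = 10),
                    fake_image_summary("s2", n_cells = 150, n_with_sg = 60))
  metadata <- data.frame(scene_id = c("s1", "s2"), construct = "WT",
                         treatment = "NT", replicate = 1)
  w <- aggregate_wells(summaries, metadata)
  expect_equal(nrow(w), 1L)
  expect_equal(w$prop_sg_cells, 0.35)  # (10 + 60) / 200
  expect_equal(w$n_cells, 200L)

  # single image: the group mean is that image's value
  w1 <- aggregate_wells(summaries[1], metadata[1, ])
  expect_equal(w1$prop_sg_cells, 0.2)
})

test_that("a full synthetic experiment aggregates to one row per design cell", {
  design <- expand.grid(construct = c("WT", "S78N"), treatment = c("NT", "MG"),
                        replicate = 1:2, stringsAsFactors = FALSE)
  ex <- simulate_experiment(design, scene_config(n_cells = 6, seed = 14))
  summaries <- lapply(seq_along(ex$scenes), function(i)
    quantify_image(ex$scenes[[i]], scene_id = ex$metadata$scene_id[i]))
  w <- aggregate_wells(summaries, ex$metadata)
  expect_equal(nrow(w), 8L)
  expect_true(all(table(w$construct, w$treatment) == 2L))
})

test_that("two-level factors force epsilon = 1 and GG never lowers p", {
  set.seed(31)
  d <- expand.grid(replicate = 1:5, construct = c("a", "b"),
                   treatment = c("x", "y", "z"))
  d$y <- rnorm(nrow(d))
  res <- rm_anova_gg(d, "y")
  expect_identical(res$epsilon_GG[res$term == "construct"], 1)
  # epsilon <= 1 means the corrected p can only grow
  expect_true(all(res$p_GG >= res$p_uncorrected - 1e-12))
  expect_true(all(res$epsilon_GG >= 1 / res$df & res$epsilon_GG <= 1))
})

test_that("a 2 x 2 design has epsilon 1 for every term", {
  set.seed(19)
  d <- expand.grid(replicate = 1:4, construct = c("a", "b"),
                   treatment = c("x", "y"))
  d$y <- rnorm(nrow(d))
  res <- rm_anova_gg(d, "y")
  expect_equal(res$epsilon_GG, c(1, 1, 1))
  expect_false(any(is.na(res$p_GG)))
})

test_that("RM-ANOVA matches the projection-matrix oracle to 1e-10", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 4; a <- 2; b <- 3
    d <- expand.grid(replicate = 1:n, construct = letters[1:a],
                     treatment = LETTERS[1:b])
    d$y <- rnorm(nrow(d), sd = runif(1, 0.5, 2))
    res <- rm_anova_gg(d, "y")
    Y <- array(d$y, c(n, a, b))
    or <- projection_rm_anova(Y)
    expect_equal(res$F, or$F, tolerance = 1e-10)
    expect_equal(res$p_uncorrected, or$p, tolerance = 1e-10)
  }
})

test_that("RM-ANOVA rejects unusable designs with instructions", {
  d <- expand.grid(replicate = 1:4, construct = c("a", "b"),
                   treatment = c("x", "y"))
  d$y <- rnorm(nrow(d))
  expect_error(rm_anova_gg(d[-1, ], "y"), "drop")
  expect_error(rm_anova_gg(d[d$replicate == 1, ], "y"), "2 subjects")
  d1 <- d[d$treatment == "x", ]
  expect_error(rm_anova_gg(d1, "y"), ">= 2 levels")
})

test_that("a single Dunnett comparison reduces to the paired t-test", {
  set.seed(5)
  d <- expand.grid(replicate = 1:6, construct = c("WT", "MUT"))
  d$y <- rnorm(nrow(d)) + (d$construct == "MUT") * 0.8
  res <- dunnett_vs_control(d, "y")
  tt <- t.test(d$y[d$construct == "MUT"], d$y[d$construct == "WT"],
               paired = TRUE)
  expect_equal(res$mean_diff, unname(tt$estimate), tolerance = 1e-10)
  expect_equal(res$p_adjusted, tt$p.value, tolerance = 0.003)
})

test_that("identical groups give zero difference and p = 1", {
  d <- expand.grid(replicate = 1:4, construct = c("WT", "M1", "M2"))
  d$y <- rep(rnorm(4), 3)  # same values in every group
  res <- dunnett_vs_control(d, "y")
  expect_equal(res$mean_diff, c(0, 0))
  expect_equal(res$p_adjusted, c(1, 1))
  expect_equal(res$ci_low, -res$ci_high)
})

test_that("Dunnett adjusted p matches multcomp and dominates the raw t-test", {
  set.seed(8)
  d <- expand.grid(replicate = factor(1:4),
                   construct = c("WT", "A13V", "S78N", "P7T"))
  d$y <- rnorm(nrow(d)) + (d$construct == "P7T") * 1.5
  res <- dunnett_vs_control(d, "y")
  fit <- stats::lm(y ~ construct + replicate,
                   data = transform(d, construct = relevel(factor(construct),
                                                           "WT")))
  g <- multcomp::glht(fit, linfct = multcomp::mcp(construct = "Dunnett"))
  ref <- summary(g, test = multcomp::adjusted("single-step"))
  expect_equal(unname(res$p_adjusted),
               unname(as.numeric(ref$test$pvalues)), tolerance = 0.005)
  # adjusted p >= the unadjusted paired contrast p
  for (i in seq_len(nrow(res))) {
    praw <- 2 * pt(-abs(res$t[i]), attr(res, "df_error"))
    expect_gte(res$p_adjusted[i], praw - 0.003)
  }
  expect_error(dunnett_vs_control(d, "y", control = "absent"), "control")
})

test_that("planted well-summary differences are estimated without bias", {
  # planted shift of 0.15 in prop_sg_cells between mutant and WT
  set.seed(42)
  diffs <- replicate(400, {
    d <- expand.grid(replicate = 1:4, construct = c("WT", "MUT"))
    d$y <- 0.3 + (d$construct == "MUT") * 0.15 + rnorm(8, 0, 0.05)
    dunnett_vs_control(d, "y")$mean_diff
  })
  expect_lt(abs(mean(diffs) - 0.15), 0.01)
})
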