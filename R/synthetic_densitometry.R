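#' Configuration for synthetic solubility-fractionation densitometry
#'
#' Emulates band-intensity quantification of supernatant and pellet
#' fractions of a tagged protein expressed in cells, across several
#' independent experiments each with technical replicates.  Reduced
#' solubility of a construct is planted as `solubility_shift`: the
#' fraction of wild-type supernatant signal moved to the pellet, so the
#' expected supernatant + pellet total is identical for every construct
#' (the shift moves signal, it never creates it).
#'
#' @param constructs character vector; must include `"WT"`.
#' @param n_experiments number of independent experiments.
#' @param replicates_per_experiment technical replicates per experiment.
#' @param wt_sup_mean,wt_pel_mean expected wild-type band intensities.
#' @param solubility_shift named numeric vector in \[0, 1\] (one entry
#'   per construct; `WT` must be 0; unnamed scalar is recycled to all
#'   mutants).
#' @param noise_cv coefficient of variation of multiplicative noise on
#'   band intensities, and the log-scale SD of the per-experiment gain.
#'   With `noise_cv = 0` intensities equal their expected means exactly.
#' @param seed integer seed.
#' @return object of class `densitometry_config`.
#' @export
densitometry_config <- function(constructs = c("WT", "P7T", "A13V",
                                               "P27A", "S78N"),
                                n_experiments = 3,
                                replicates_per_experiment = 3,
                                wt_sup_mean = 100,
                                wt_pel_mean = 25,
                                solubility_shift = c(WT = 0, P7T = 0.6,
                                                     A13V = 0.5, P27A = 0.15,
                                                     S78N = 0.1),
                                noise_cv = 0.1,
                                seed = 1L) {
  if (!"WT" %in% constructs) stopf("`constructs` must include \"WT\"")
  if (n_experiments < 1 || replicates_per_experiment < 1)
    stopf("experiment and replicate counts must be >= 1")
  if (is.null(names(solubility_shift)))
    solubility_shift <- stats::setNames(
      ifelse(constructs == "WT", 0, rep_len(solubility_shift,
                                            length(constructs))),
      constructs)
  miss <- setdiff(constructs, names(solubility_shift))
  if (length(miss))
    stopf("`solubility_shift` missing entries for: %s",
          paste(miss, collapse = ", "))
  if (any(solubility_shift < 0 | solubility_shift > 1))
    stopf("`solubility_shift` entries must be in [0, 1]")
  check_number(noise_cv, "noise_cv", lower = 0)
  structure(list(constructs = constructs,
                 n_experiments = as.integer(n_experiments),
                 replicates_per_experiment =
                   as.integer(replicates_per_experiment),
                 wt_sup_mean = wt_sup_mean, wt_pel_mean = wt_pel_mean,
                 solubility_shift = solubility_shift, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "densitometry_config")
}

#' Simulate a supernatant/pellet densitometry table
#'
#' @param config a [densitometry_config()].
#' @return data frame with one row per
#'   (construct, experiment, replicate, fraction):
#'   `construct`, `experiment`, `replicate`,
#'   `fraction` (`"supernatant"`/`"pellet"`), `band_intensity`,
#'   `total_protein`.  Carries the config as attribute `"config"`.
#' @export
simulate_densitometry <- function(config) {
  stopifnot(inherits(config, "densitometry_config"))
  with_seed(config$seed, simulate_densitometry_impl(config))
}

simulate_densitometry_impl <- function(cfg) {
  shift <- cfg$solubility_shift[cfg$constructs]
  exp_sup <- cfg$wt_sup_mean * (1 - shift)
  exp_pel <- cfg$wt_pel_mean + cfg$wt_sup_mean * shift
  grid <- expand.grid(fraction = c("supernatant", "pellet"),
                      replicate = seq_len(cfg$replicates_per_experiment),
                      experiment = seq_len(cfg$n_experiments),
                      construct = cfg$constructs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # per-experiment detection gain (blot exposure); 1 when noise_cv = 0
  gain <- exp(stats::rnorm(cfg$n_experiments, 0, cfg$noise_cv))
  mu <- ifelse(grid$fraction == "supernatant",
               exp_sup[grid$construct], exp_pel[grid$construct])
  band <- mu * gain[grid$experiment] *
    pmax(1 + stats::rnorm(nrow(grid), 0, cfg$noise_cv), 0)
  out <- data.frame(construct = grid$construct,
                    experiment = grid$experiment,
                    replicate = grid$replicate,
                    fraction = grid$fraction,
                    band_intensity = band,
                    total_protein = 1,
                    stringsAsFactors = FALSE)
  attr(out, "config") <- cfg
  out
}
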