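# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  All generators and the Dunnett Monte-Carlo reference
# use this so that library code never perturbs the user's random stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stopf("`%s` must be a single number in [%s, %s]", name, lower, upper)
  x
}

check_proportion <- function(x, name) check_number(x, name, 0, 1)

# 1-D Otsu threshold on a numeric vector (256-bin histogram).  Returns a
# cut value; values strictly above it are foreground.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) stopf("cannot threshold: all values are equal")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  w <- cumsum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  m <- cumsum(h * mids)
  n <- w[n_bins]; mt <- m[n_bins]
  w1 <- w[-n_bins]; w2 <- n - w1
  valid <- w1 > 0 & w2 > 0
  between <- rep(-Inf, n_bins - 1L)
  between[valid] <- (mt * w1[valid] / n - m[-n_bins][valid])^2 /
    (w1[valid] / n * w2[valid] / n) # proportional to between-class variance
  breaks[which.max(between) + 1L]
}

# distance of every pixel in a logical matrix to the nearest TRUE pixel
# (0 on the TRUE set), via EBImage's distance map of the complement
dist_to_set <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  EBImage::distmap(1 - mask)
}

mad0 <- function(x) stats::mad(x, constant = 1.4826)
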