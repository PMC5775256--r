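#' Derive a reproducible substream seed
#'
#' All stochastic operations in the package draw from substreams derived
#' deterministically from a single master seed and a short string key, so a
#' whole simulated study is reproducible from one integer while independent
#' stages remain decoupled (re-running one stage does not perturb another).
#'
#' @param seed Master integer seed.
#' @param key Character scalar naming the substream (e.g. `"genome"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "genome")
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 97561
  # doubles are exact well past this range, so the arithmetic is portable
  as.integer((abs(seed) %% 2147483647 * 100003 + h) %% 2147483646)
}

with_substream <- function(seed, key, code) {
  withr::with_seed(substream_seed(seed, key), code)
}

# truncated Poisson, support >= 1
rtpois <- function(n, lambda) {
  stopifnot(lambda > 0)
  u <- runif(n, dpois(0, lambda), 1)
  pmax(1L, qpois(u, lambda))
}

# beta draw parameterised by mean and concentration, tolerating mean 0/1
rbeta_mean <- function(n, mean, concentration) {
  mean <- pmin(pmax(mean, 1e-6), 1 - 1e-6)
  rbeta(n, mean * concentration, (1 - mean) * concentration)
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

# pooled-count Clopper-Pearson interval
cp_interval <- function(x, n, conf = 0.95) {
  stopifnot(n > 0)
  as.numeric(binom.test(round(x), round(n), conf.level = conf)$conf.int)
}

is_allc <- function(x) {
  is.data.frame(x) &&
    all(c("chrom", "pos", "strand", "context", "mc", "cov") %in% names(x))
}

assert_allc <- function(x, name = "table") {
  if (!is_allc(x)) {
    abort(sprintf(
      "`%s` must be an allc-style data frame with columns chrom, pos, strand, context, mc, cov",
      name
    ))
  }
  invisible(x)
}

# collapse trinucleotide context to the CG/CA/CC/CT dinucleotide classes
context_class <- function(context) {
  cls <- substr(context, 1, 2)
  cls[!cls %in% c("CG", "CA", "CC", "CT")] <- NA_character_
  cls
}

# distance from a point to a set of 0-based half-open intervals on one
# chromosome (0 inside, gap in bp outside); intervals need not be sorted
point_interval_dist <- function(points, starts, ends) {
  if (length(starts) == 0L) return(rep(Inf, length(points)))
  o <- order(starts)
  starts <- starts[o]
  ends <- ends[o]
  # nearest interval is adjacent to the insertion position in sorted starts
  idx <- findInterval(points, starts)
  d <- rep(Inf, length(points))
  for (k in c(0L, 1L)) {
    i <- idx + 1L - k
    ok <- i >= 1L & i <= length(starts)
    if (!any(ok)) next
    di <- pmax(starts[i[ok]] - points[ok], points[ok] - ends[i[ok]], 0)
    d[ok] <- pmin(d[ok], di)
  }
  # running max of ends guards against contained intervals hiding a closer end
  cummax_end <- cummax(ends)
  ok <- idx >= 1L
  d[ok] <- pmin(d[ok], pmax(points[ok] - cummax_end[idx[ok]], 0))
  d
}
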