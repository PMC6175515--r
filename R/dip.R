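#' Hartigan's dip statistic of unimodality
#'
#' The dip of a sample is the smallest sup-norm distance between its empirical
#' CDF and any unimodal CDF (convex up to a mode, concave after). It is
#' computed here by the greatest-convex-minorant / least-concave-majorant
#' construction on the sorted sample: for every candidate mode position the
#' minimal fit error decomposes into a prefix convex-fit deviation and a
#' suffix concave-fit deviation, each read off the respective hull; the dip is
#' half the best achievable maximum of the two.
#'
#' The statistic is invariant under increasing affine transformations of the
#' data, and for a sample of \eqn{n \ge 2} distinct values satisfies
#' \eqn{1/(2n) \le D \le 1/4}.
#'
#' @param x Numeric vector, at least 2 values after removing \code{NA}s; all
#'   values must be finite. Larger values indicate stronger departure from
#'   unimodality.
#' @return The dip statistic \eqn{D}.
#' @references Hartigan, J. A. and Hartigan, P. M. (1985) The dip test of
#'   unimodality. \emph{Annals of Statistics} 13, 70--84.
#' @export
dip_statistic <- function(x) {
  x <- x[!is.na(x)]
  if (any(!is.finite(x))) stop("'x' must contain only finite values")
  if (length(x) < 2L) stop("need at least 2 non-missing values")
  .dip_stat_sorted(sort(as.numeric(x)))
}

#' Null distribution of the dip statistic
#'
#' Simulates dip statistics of uniform(0, 1) samples of size \code{n}. The
#' uniform is the least-favourable unimodal null, so p-values calibrated
#' against it are conservative for other unimodal distributions.
#'
#' @param n Sample size of each null draw.
#' @param n_null_samples Number of null replicates (default 10000).
#' @param seed Integer seed.
#' @return Sorted numeric vector of null dip statistics.
#' @export
dip_null_distribution <- function(n, n_null_samples = 10000L, seed = 1L) {
  stopifnot(n >= 2, n_null_samples >= 1)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  sort(vapply(seq_len(n_null_samples),
              function(i) .dip_stat_sorted(sort(stats::runif(n))),
              numeric(1)))
}

#' Dip test of unimodality
#'
#' Tests the null hypothesis that the sample comes from a unimodal
#' distribution. The p-value is the Monte Carlo fraction of uniform-null dip
#' statistics at the same sample size that reach or exceed the observed dip,
#' with add-one continuity: \eqn{p = (1 + \#\{D_0 \ge D\}) / (B + 1)}.
#'
#' @param x Numeric sample (n >= 4 recommended).
#' @param n_null_samples Number of null replicates \eqn{B} (>= 999
#'   recommended; default 10000).
#' @param seed Integer seed for the null simulation.
#' @param null_dips Optional precomputed vector from
#'   [dip_null_distribution()] for the same \code{length(x)}; when supplied,
#'   no new null simulation is run (useful when testing many samples of equal
#'   size).
#' @return An object of classes \code{"dip_test"} and \code{"htest"} with
#'   components \code{statistic} (D), \code{p.value}, \code{n_null_samples},
#'   \code{seed}.
#' @export
dip_test <- function(x, n_null_samples = 10000L, seed = 1L, null_dips = NULL) {
  d <- dip_statistic(x)
  n <- length(x[!is.na(x)])
  if (is.null(null_dips))
    null_dips <- dip_null_distribution(n, n_null_samples, seed)
  b <- length(null_dips)
  p <- (1 + sum(null_dips >= d)) / (b + 1)
  structure(list(statistic = c(D = d), p.value = p,
                 parameter = c(n = n),
                 n_null_samples = b, seed = seed,
                 method = "Hartigan dip test of unimodality (Monte Carlo)",
                 data.name = deparse1(substitute(x))),
            class = c("dip_test", "htest"))
}
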