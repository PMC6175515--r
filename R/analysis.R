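.check_records <- function(records, need = c("species", "flush_distance_m",
                                             "defence_category", "fate")) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "))
  invisible(records)
}

#' Proportional-odds regression of defence category
#'
#' Fits a maximum-likelihood proportional-odds logistic model of the ordinal
#' defence category (1--4) on species and flush distance, with phalarope as
#' the species reference level. Per-term chi-square tests are
#' likelihood-ratio by default (refitting without each term, df = 1 per term);
#' Wald tests are available by flag. Fitting is done by [MASS::polr()];
#' non-convergence and (quasi-)separation are reported, not silently ignored.
#'
#' @param records Nest-record data frame (see [generate_nests()] for the
#'   schema). Rows with missing flush distance or defence category are
#'   dropped with a warning.
#' @param chi_square \code{"lr"} (likelihood ratio, default) or \code{"wald"}.
#' @return An object of class \code{"ordinal_fit"}: \code{cutpoints} (3
#'   increasing latent thresholds), \code{coefficients} (speciessandpiper,
#'   flush_distance_m), \code{log_likelihood}, \code{term_tests} (data frame
#'   of term, chisq, df, p_value), \code{converged}, and the underlying
#'   \code{fit}.
#' @export
fit_defence_ordinal <- function(records, chi_square = c("lr", "wald")) {
  chi_square <- match.arg(chi_square)
  .check_records(records)
  keep <- !is.na(records$flush_distance_m) & !is.na(records$defence_category)
  if (any(!keep)) {
    warning(sum(!keep), " record(s) dropped: missing flush distance or category")
    records <- records[keep, , drop = FALSE]
  }
  if (length(unique(records$defence_category)) < 2L)
    stop("need at least 2 observed defence categories")
  dat <- data.frame(
    category = factor(records$defence_category, levels = 1:4, ordered = TRUE),
    species = factor(records$species, levels = c("phalarope", "sandpiper")),
    flush_distance_m = records$flush_distance_m)
  dat$category <- droplevels(dat$category)
  fit <- withCallingHandlers(
    MASS::polr(category ~ species + flush_distance_m, data = dat, Hess = TRUE),
    warning = function(w) invokeRestart("muffleWarning"))
  converged <- fit$convergence == 0
  se <- sqrt(diag(stats::vcov(fit)))[names(stats::coef(fit))]
  if (any(abs(stats::coef(fit)) > 30) || any(se > 100))
    warning("possible separation: extreme coefficient or standard error")
  ll_full <- as.numeric(stats::logLik(fit))
  terms_tested <- c("species", "flush_distance_m")
  if (chi_square == "lr") {
    tests <- lapply(terms_tested, function(tm) {
      f_red <- stats::as.formula(paste("category ~",
        setdiff(terms_tested, tm)))
      red <- withCallingHandlers(
        MASS::polr(f_red, data = dat, Hess = FALSE),
        warning = function(w) invokeRestart("muffleWarning"))
      chisq <- max(0, 2 * (ll_full - as.numeric(stats::logLik(red))))
      data.frame(term = tm, chisq = chisq, df = 1L,
                 p_value = stats::pchisq(chisq, 1L, lower.tail = FALSE))
    })
  } else {
    z <- stats::coef(fit) / se
    tests <- lapply(seq_along(terms_tested), function(i) {
      data.frame(term = terms_tested[i], chisq = z[i]^2, df = 1L,
                 p_value = stats::pchisq(z[i]^2, 1L, lower.tail = FALSE))
    })
  }
  structure(list(cutpoints = fit$zeta,
                 coefficients = stats::coef(fit),
                 log_likelihood = ll_full,
                 term_tests = do.call(rbind, tests),
                 chi_square = chi_square,
                 converged = converged,
                 n = nrow(dat),
                 fit = fit),
            class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat("Proportional-odds regression of defence category (reference: phalarope)\n")
  cat(sprintf("  n = %d, logLik = %.3f, converged: %s\n",
              x$n, x$log_likelihood, x$converged))
  cat("  cutpoints:", paste(sprintf("%.3f", x$cutpoints), collapse = ", "), "\n")
  cat("  coefficients:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  per-term %s chi-squares:\n", toupper(x$chi_square)))
  print(x$term_tests, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Quadratic logistic model of nest fate
#'
#' Construct a quadratic logistic fate model directly from coefficients on the
#' log-odds of hatching: \eqn{\mathrm{logit}\, P(\mathrm{hatch}) = \beta_0 +
#' \beta_1 d + \beta_2 d^2}. Used both as the return class of
#' [fit_fate_logistic()] and to evaluate externally reported coefficients.
#'
#' @param intercept,beta_flush,beta_flush_sq Coefficients on the log-odds of
#'   hatching.
#' @param standard_errors,wald_p_values Optional named numeric vectors.
#' @param converged Logical, default \code{TRUE}.
#' @param n Number of records behind the fit, if any.
#' @return An object of class \code{"fate_logistic"}.
#' @export
fate_logistic <- function(intercept, beta_flush, beta_flush_sq,
                          standard_errors = NULL, wald_p_values = NULL,
                          converged = TRUE, n = NA_integer_) {
  co <- c(intercept = intercept, beta_flush = beta_flush,
          beta_flush_sq = beta_flush_sq)
  stopifnot(all(is.finite(co)))
  if (!is.null(standard_errors) && converged && any(standard_errors <= 0))
    stop("standard errors must be positive for a converged fit")
  structure(list(coefficients = co, standard_errors = standard_errors,
                 wald_p_values = wald_p_values, converged = converged,
                 n = n, fit = NULL),
            class = "fate_logistic")
}

#' Fit the quadratic logistic regression of nest fate on flush distance
#'
#' Maximum-likelihood binomial logistic regression of hatching (1) versus
#' depredation (0) on flush distance and its square. Records with unknown
#' fate are excluded. Standard errors are Wald, from the observed information.
#' Separation and non-convergence are reported via \code{converged} and a
#' warning.
#'
#' @param records Nest-record data frame.
#' @return A [fate_logistic()] object with \code{standard_errors},
#'   \code{wald_p_values}, \code{converged}, \code{n}, and the underlying
#'   \code{glm} in \code{$fit}.
#' @export
fit_fate_logistic <- function(records) {
  .check_records(records, need = c("flush_distance_m", "fate"))
  dat <- records[records$fate %in% c("hatched", "depredated") &
                   !is.na(records$flush_distance_m), , drop = FALSE]
  y <- as.integer(dat$fate == "hatched")
  if (length(unique(y)) < 2L)
    stop("both fates (hatched and depredated) must be present")
  fit <- withCallingHandlers(
    stats::glm(y ~ flush_distance_m + I(flush_distance_m^2), data = dat,
               family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-9, maxit = 200)),
    warning = function(w) invokeRestart("muffleWarning"))
  sm <- summary(fit)$coefficients
  # in (quasi-)separation the ML estimates diverge and the Wald standard
  # errors blow up relative to the coefficient scale
  separated <- any(!is.finite(sm[, 2])) ||
    any(sm[, 2] > 100 * (1 + abs(sm[, 1])))
  converged <- fit$converged && !separated
  if (!converged)
    warning("fate regression did not converge cleanly",
            if (separated) " (separation suspected)" else "")
  out <- fate_logistic(intercept = sm[1, 1], beta_flush = sm[2, 1],
                       beta_flush_sq = sm[3, 1],
                       standard_errors = stats::setNames(sm[, 2],
                         c("intercept", "beta_flush", "beta_flush_sq")),
                       wald_p_values = stats::setNames(sm[, 4],
                         c("intercept", "beta_flush", "beta_flush_sq")),
                       converged = converged, n = nrow(dat))
  out$fit <- fit
  out
}

#' @export
print.fate_logistic <- function(x, ...) {
  cat("Quadratic logistic regression of nest fate (hatched = 1)\n")
  if (!is.na(x$n)) cat(sprintf("  n = %d, converged: %s\n", x$n, x$converged))
  co <- x$coefficients
  if (is.null(x$standard_errors)) {
    print(round(co, 4))
  } else {
    tab <- cbind(estimate = co, se = x$standard_errors, p = x$wald_p_values)
    print(round(tab, 4))
  }
  if (co[["beta_flush_sq"]] > 0)
    cat(sprintf("  predation risk maximal near %.2f m\n",
                -co[["beta_flush"]] / (2 * co[["beta_flush_sq"]])))
  invisible(x)
}

#' Predicted hatching curve and distance of maximum predation risk
#'
#' Evaluates the fitted quadratic logistic model on a distance grid and
#' reports the distance at which predicted hatching probability is lowest
#' (equivalently, predation risk highest) within a requested range. When the
#' quadratic coefficient is positive the minimiser is the vertex
#' \eqn{-\beta_1 / (2 \beta_2)}, clamped to the range; otherwise it is found
#' on the grid.
#'
#' @param fit A [fate_logistic()] object (fitted or built from coefficients).
#' @param distances Distance grid in metres.
#' @param range Length-2 numeric range (m) within which to locate the maximum
#'   predation risk. Defaults to the span of \code{distances}.
#' @return A list with \code{curve} (data frame \code{distance},
#'   \code{p_hatch}, \code{p_predation}) and \code{max_predation_distance}.
#' @export
predicted_fate_curve <- function(fit, distances = seq(0, 100, by = 0.25),
                                 range = base::range(distances)) {
  stopifnot(inherits(fit, "fate_logistic"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  co <- fit$coefficients
  eta <- co[["intercept"]] + co[["beta_flush"]] * distances +
    co[["beta_flush_sq"]] * distances^2
  p_hatch <- stats::plogis(eta)
  b1 <- co[["beta_flush"]]; b2 <- co[["beta_flush_sq"]]
  if (b2 > 0) {
    vertex <- -b1 / (2 * b2)
    dmax <- min(max(vertex, range[1]), range[2])
  } else {
    grid <- seq(range[1], range[2], length.out = 4096L)
    eg <- co[["intercept"]] + b1 * grid + b2 * grid^2
    dmax <- grid[which.min(eg)]
  }
  list(curve = data.frame(distance = distances, p_hatch = p_hatch,
                          p_predation = 1 - p_hatch),
       max_predation_distance = unname(dmax))
}

#' Two-sample t test of flush distance between species
#'
#' Pooled-variance Student's t by default (df = n1 + n2 - 2); the Welch
#' variant is available by flag. Two-sided p-value.
#'
#' @param records Nest-record data frame.
#' @param variant \code{"pooled"} (default) or \code{"welch"}.
#' @return An object of classes \code{"t_test_result"} and \code{"htest"}.
#' @export
flush_t_test <- function(records, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  .check_records(records, need = c("species", "flush_distance_m"))
  g1 <- records$flush_distance_m[records$species == "sandpiper"]
  g2 <- records$flush_distance_m[records$species == "phalarope"]
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each species needs at least 2 records")
  ht <- stats::t.test(g1, g2, var.equal = (variant == "pooled"))
  structure(list(statistic = ht$statistic,
                 parameter = ht$parameter,
                 p.value = ht$p.value,
                 variant = variant,
                 estimate = ht$estimate,
                 method = paste0(if (variant == "pooled") "Pooled " else "Welch ",
                                 "two-sample t test (sandpiper vs phalarope)"),
                 data.name = "flush_distance_m by species"),
            class = c("t_test_result", "htest"))
}

#' Ordinary least squares R-squared
#'
#' Coefficient of determination of a simple linear regression of \code{y} on
#' \code{x}, e.g. flush distance or defence category against nest age.
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs); \code{x} must
#'   vary.
#' @return R-squared in \eqn{[0, 1]}.
#' @export
linreg_r2 <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::var(x) == 0) stop("'x' has zero variance")
  summary(stats::lm(y ~ x))$r.squared
}

#' Descriptive summaries of a nest-record table
#'
#' Per-species sample size, mean and sample SD (n - 1 denominator) of flush
#' distance; per-species defence-category proportions; pooled proportions in
#' flush-distance bins; and apparent hatch success (hatched nests over all
#' nests, including unknown fates) per species. The default bins are
#' \eqn{[0, 5)}, \eqn{[5, 20]} and \eqn{(20, \infty)}; boundary membership at
#' 5 and 20 follows this convention and the cutoffs are configurable.
#'
#' @param records Nest-record data frame.
#' @param bin_breaks Two increasing cutoffs, default \code{c(5, 20)}.
#' @return An object of class \code{"nest_summary"}: \code{per_species} (data
#'   frame with n, mean, sd, hatch success), \code{category_proportions}
#'   (species x category matrix), \code{bin_proportions} (named vector),
#'   \code{bin_breaks}.
#' @export
summarize_nests <- function(records, bin_breaks = c(5, 20)) {
  .check_records(records)
  stopifnot(length(bin_breaks) == 2L, diff(bin_breaks) > 0)
  sp_levels <- c("sandpiper", "phalarope")
  per <- do.call(rbind, lapply(sp_levels, function(sp) {
    r <- records[records$species == sp, , drop = FALSE]
    d <- r$flush_distance_m[!is.na(r$flush_distance_m)]
    data.frame(species = sp, n = nrow(r),
               mean_flush = if (length(d)) mean(d) else NA_real_,
               sd_flush = if (length(d) > 1) stats::sd(d) else NA_real_,
               hatch_success = if (nrow(r)) mean(r$fate == "hatched") else NA_real_)
  }))
  cat_prop <- t(vapply(sp_levels, function(sp) {
    k <- records$defence_category[records$species == sp]
    tab <- tabulate(k[!is.na(k)], nbins = 4L)
    if (sum(tab) == 0) rep(NA_real_, 4) else tab / sum(tab)
  }, numeric(4)))
  colnames(cat_prop) <- paste0("category", 1:4)
  d <- records$flush_distance_m[!is.na(records$flush_distance_m)]
  bins <- c(mean(d < bin_breaks[1]),
            mean(d >= bin_breaks[1] & d <= bin_breaks[2]),
            mean(d > bin_breaks[2]))
  names(bins) <- c(sprintf("[0,%g)", bin_breaks[1]),
                   sprintf("[%g,%g]", bin_breaks[1], bin_breaks[2]),
                   sprintf("(%g,Inf)", bin_breaks[2]))
  structure(list(per_species = per, category_proportions = cat_prop,
                 bin_proportions = bins, bin_breaks = bin_breaks),
            class = "nest_summary")
}

#' @export
print.nest_summary <- function(x, ...) {
  cat("Nest-record summary\n")
  print(transform(x$per_species,
                  mean_flush = round(mean_flush, 2),
                  sd_flush = round(sd_flush, 2),
                  hatch_success = round(hatch_success, 3)),
        row.names = FALSE)
  cat("Defence-category proportions:\n")
  print(round(x$category_proportions, 3))
  cat("Pooled flush-distance bin proportions:\n")
  print(round(x$bin_proportions, 3))
  invisible(x)
}
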