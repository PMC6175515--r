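#' Monte Carlo predator-encounter configuration
#'
#' Settings for simulating single predator--nest encounters. Two predator
#' geometries are available:
#' \describe{
#'   \item{\code{stationary_uniform}}{the predator is placed area-uniformly in
#'     the disk of radius \code{arena_radius} centred on the nest (radial
#'     coordinate \eqn{R\sqrt{u}}). This is the geometry the analytic model's
#'     squared-law flush probability assumes, and is the default oracle.}
#'   \item{\code{transect}}{the predator walks a straight random chord of the
#'     arena, generated by a uniform random bearing and a uniform perpendicular
#'     offset in \eqn{(-R, R)}; the minimum approach distance to the nest is
#'     the absolute offset. This emulates a searcher walking through the area.}
#' }
#' In both geometries the bird flushes iff the predator comes within its
#' threshold distance, and a flushed bird's nest is detected with probability
#' \code{detection_probability(threshold)} -- detection is evaluated at the
#' instant the threshold circle is crossed.
#'
#' @param params A [risk_params()] object.
#' @param arena_radius Arena radius in metres; defaults to \code{params$r_ref}.
#' @param n_trials Number of independent encounter trials (>= 1).
#' @param seed Integer seed; identical configuration and seed reproduce
#'   identical trial tables.
#' @param predator_model \code{"stationary_uniform"} or \code{"transect"}.
#' @return An object of class \code{"encounter_config"}.
#' @export
encounter_config <- function(params = risk_params(),
                             arena_radius = params$r_ref,
                             n_trials = 10000L, seed = 1L,
                             predator_model = c("stationary_uniform", "transect")) {
  params <- as_risk_params(params)
  predator_model <- match.arg(predator_model)
  stopifnot(is.numeric(arena_radius), length(arena_radius) == 1L, arena_radius > 0,
            is.numeric(n_trials), length(n_trials) == 1L, n_trials >= 1,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(params = params, arena_radius = arena_radius,
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 predator_model = predator_model),
            class = "encounter_config")
}

#' @export
print.encounter_config <- function(x, ...) {
  cat(sprintf("Encounter configuration: %s model, arena %g m, %d trials, seed %d\n",
              x$predator_model, x$arena_radius, x$n_trials, x$seed))
  invisible(x)
}

#' A bird's nest-defence strategy
#'
#' @param flush_threshold Threshold flush distance in metres (>= 0).
#' @param deception_category Ordinal defence category 1--4 (1 = pure flush /
#'   passive deception, 4 = attention flights). Carried through population
#'   simulations; not used by the encounter geometry.
#' @return An object of class \code{"bird_strategy"}.
#' @export
bird_strategy <- function(flush_threshold, deception_category = NA_integer_) {
  stopifnot(is.numeric(flush_threshold), length(flush_threshold) == 1L,
            is.finite(flush_threshold), flush_threshold >= 0)
  if (!is.na(deception_category) && !deception_category %in% 1:4)
    stop("'deception_category' must be in 1..4")
  structure(list(flush_threshold = flush_threshold,
                 deception_category = as.integer(deception_category)),
            class = "bird_strategy")
}

#' Simulate predator--nest encounters for one flush strategy
#'
#' Runs \code{config$n_trials} independent encounters under the configured
#' predator geometry. Each trial records the predator's minimum approach (or
#' placement) distance, whether the bird flushed, and whether the flush led
#' the predator to the nest. \code{detected} implies \code{flushed} on every
#' trial.
#'
#' @param strategy A [bird_strategy()] object or a single non-negative number
#'   (the flush threshold in metres).
#' @param config An [encounter_config()] object.
#' @return A data frame with columns \code{predator_nest_distance},
#'   \code{flushed}, \code{detected} (one row per trial).
#' @export
simulate_encounters <- function(strategy, config = encounter_config()) {
  if (is.numeric(strategy)) strategy <- bird_strategy(strategy)
  stopifnot(inherits(strategy, "bird_strategy"),
            inherits(config, "encounter_config"))
  r <- strategy$flush_threshold
  R <- config$arena_radius
  n <- config$n_trials
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)
  dist <- switch(config$predator_model,
    stationary_uniform = R * sqrt(stats::runif(n)),
    transect = abs(stats::runif(n, -R, R)))
  flushed <- dist <= r
  p_det <- detection_probability(min(r, config$params$f_long), config$params)
  detected <- flushed & (stats::runif(n) < p_det)
  data.frame(predator_nest_distance = dist, flushed = flushed,
             detected = detected)
}

#' Monte Carlo estimate of the flush and detection probabilities
#'
#' Brute-force counterpart of the analytic risk model: for each threshold it
#' simulates encounters and reports the fraction of trials in which the bird
#' flushed and in which the nest was detected, with binomial standard errors
#' \eqn{\sqrt{p(1-p)/n}}. With the \code{stationary_uniform} geometry and
#' \code{arena_radius = r_ref}, the flush fraction estimates
#' [flush_probability()] and the detected fraction estimates [flush_risk()].
#' Trials should be numerous enough for the SE to be meaningful (>= 1e4
#' recommended).
#'
#' @param thresholds Non-empty numeric vector of flush thresholds (m).
#' @param config An [encounter_config()] object; each threshold uses a seed
#'   offset deterministically from \code{config$seed}.
#' @return A data frame with columns \code{threshold}, \code{p_flush},
#'   \code{se_flush}, \code{p_detect}, \code{se_detect}, \code{n_trials}.
#' @export
estimate_risk_curve <- function(thresholds, config = encounter_config()) {
  if (!is.numeric(thresholds) || length(thresholds) == 0L)
    stop("'thresholds' must be a non-empty numeric vector")
  rows <- lapply(seq_along(thresholds), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    tr <- simulate_encounters(thresholds[i], cfg_i)
    pf <- mean(tr$flushed); pd <- mean(tr$detected); n <- nrow(tr)
    data.frame(threshold = thresholds[i],
               p_flush = pf, se_flush = sqrt(pf * (1 - pf) / n),
               p_detect = pd, se_detect = sqrt(pd * (1 - pd) / n),
               n_trials = n)
  })
  do.call(rbind, rows)
}

#' Sampler specification for flush thresholds
#'
#' @param dist One of \code{"fixed"}, \code{"uniform"}, \code{"lognormal"},
#'   \code{"gamma"}.
#' @param ... Distribution parameters: \code{value} (fixed); \code{min},
#'   \code{max} (uniform); \code{meanlog}, \code{sdlog} (lognormal);
#'   \code{shape}, \code{rate} (gamma).
#' @return An object of class \code{"threshold_sampler"}.
#' @export
threshold_sampler <- function(dist = c("fixed", "uniform", "lognormal", "gamma"),
                              ...) {
  dist <- match.arg(dist)
  structure(list(dist = dist, args = list(...)), class = "threshold_sampler")
}

.draw_thresholds <- function(sampler, n) {
  stopifnot(inherits(sampler, "threshold_sampler"))
  a <- sampler$args
  switch(sampler$dist,
    fixed = rep(a$value, n),
    uniform = stats::runif(n, a$min, a$max),
    lognormal = stats::rlnorm(n, a$meanlog, a$sdlog),
    gamma = stats::rgamma(n, shape = a$shape, rate = a$rate),
    stop("unknown threshold distribution: ", sampler$dist))
}

#' Simulate nest fates for a population of flush strategies
#'
#' Each bird draws a flush threshold from \code{sampler}; its nest is
#' depredated if any of its encounters ends with the nest detected. The
#' default of one encounter per nest matches the per-encounter analytic model;
#' larger exposure is available through \code{encounters_per_nest}.
#'
#' @param n_birds Number of birds (>= 1).
#' @param sampler A [threshold_sampler()].
#' @param config An [encounter_config()]; its \code{n_trials} is ignored here
#'   (one stream of encounters per bird is drawn), its seed governs the run.
#' @param encounters_per_nest Encounters each nest is exposed to (>= 1).
#' @return A data frame with columns \code{nest_id}, \code{flush_threshold},
#'   \code{depredated} (logical).
#' @export
simulate_population <- function(n_birds, sampler, config = encounter_config(),
                                encounters_per_nest = 1L) {
  stopifnot(is.numeric(n_birds), n_birds >= 1,
            is.numeric(encounters_per_nest), encounters_per_nest >= 1)
  n_birds <- as.integer(n_birds)
  k <- as.integer(encounters_per_nest)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)
  thr <- .draw_thresholds(sampler, n_birds)
  R <- config$arena_radius
  p_det <- detection_probability(pmin(thr, config$params$f_long), config$params)
  depredated <- logical(n_birds)
  for (j in seq_len(k)) {
    dist <- switch(config$predator_model,
      stationary_uniform = R * sqrt(stats::runif(n_birds)),
      transect = abs(stats::runif(n_birds, -R, R)))
    flushed <- dist <= thr
    detected <- flushed & (stats::runif(n_birds) < p_det)
    depredated <- depredated | detected
  }
  data.frame(nest_id = sprintf("sim%05d", seq_len(n_birds)),
             flush_threshold = thr, depredated = depredated)
}

#' Emulate discovery bias of walking nest searchers
#'
#' Observers who find nests by walking and watching for flushes preferentially
#' discover nests whose birds flush at intermediate distances -- for the same
#' reason such distances are risky. Each nest is retained with probability
#' proportional to its flush-conditional discovery chance: the risk product at
#' its threshold, renormalised so the maximum retention probability is 1.
#'
#' @param population A data frame with a \code{flush_threshold} column, as
#'   returned by [simulate_population()].
#' @param params A [risk_params()] object describing observer conspicuousness.
#' @param seed Integer seed for the retention draws.
#' @return The retained subset of \code{population}, with a
#'   \code{retention_prob} column recording the probability used per nest.
#' @export
observer_discovery_filter <- function(population, params = risk_params(),
                                      seed = 1L) {
  stopifnot(is.data.frame(population), nrow(population) > 0,
            "flush_threshold" %in% names(population))
  params <- as_risk_params(params)
  rmax <- flush_risk(argmax_risk(params), params)
  p_keep <- flush_risk(pmin(population$flush_threshold, params$r_ref), params) / rmax
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  keep <- stats::runif(nrow(population)) < p_keep
  out <- population[keep, , drop = FALSE]
  out$retention_prob <- p_keep[keep]
  rownames(out) <- NULL
  out
}

# preserve the caller's RNG state around seeded simulations
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
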