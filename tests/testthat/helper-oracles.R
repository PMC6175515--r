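# Shared fixtures and independent oracles, built in code.

# Brute-force dip values from the LP formulation (minimise sup|F_n - G| over
# unimodal CDFs, one linear program per candidate mode), solved with scipy
# through the system python. Definition-level oracle, independent of the
# package's hull/bisection implementation.
dip_lp_oracle <- function(samples) {
  payload <- jsonlite::toJSON(list(samples = lapply(samples, as.numeric)),
                              digits = NA)
  tf <- tempfile(fileext = ".json")
  writeLines(payload, tf)
  on.exit(unlink(tf))
  out <- system2("python", shQuote(test_path("dip-lp-oracle.py")),
                 stdout = TRUE, stdin = tf)
  as.numeric(jsonlite::fromJSON(paste(out, collapse = "")))
}

# sample with exactly the requested mean and standard deviation
moment_matched <- function(n, mean, sd, seed) {
  set.seed(seed)
  z <- as.numeric(scale(rnorm(n)))
  mean + sd * z
}

# minimal valid nest-record table
make_records <- function(n = 10, species = rep(c("sandpiper", "phalarope"),
                                               length.out = n),
                         flush = seq(1, 30, length.out = n),
                         category = rep(1:4, length.out = n),
                         fate = rep(c("hatched", "depredated"), length.out = n)) {
  data.frame(nest_id = sprintf("n%03d", seq_len(n)), species = species,
             flush_distance_m = flush, defence_category = as.integer(category),
             fate = fate)
}

# proportional-odds log-likelihood (phalarope reference), for gradient checks
# at a fitted optimum -- written independently of MASS::polr
polr_loglik <- function(theta, records) {
  cuts <- theta[1:3]
  beta_sp <- theta[4]; beta_fl <- theta[5]
  eta <- beta_sp * (records$species == "sandpiper") +
    beta_fl * records$flush_distance_m
  cum <- cbind(0, plogis(outer(-eta, cuts, `+`)), 1)
  p <- cum[cbind(seq_len(nrow(records)), records$defence_category + 1L)] -
    cum[cbind(seq_len(nrow(records)), records$defence_category)]
  sum(log(pmax(p, 1e-300)))
}

num_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}
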