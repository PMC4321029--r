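# ---------------------------------------------------------------------------
# Generative model of the one-generation balancer-rescued outcross
#
# Conceived F1 zygotes are male or female with probability 1/2 (the X-linked
# Gal80 makes sex determine genotype deterministically). A female zygote is a
# rescued control and survives with probability min(1, f); a male zygote
# expresses the transgene and survives with probability min(1, v * m), where
# v is baseline relative male viability and m a multiplicative modifier
# effect (m = 1: none; m > 1: suppressor; m < 1: enhancer).
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' @param v Baseline male relative viability; the default is calibrated so an
#'   unmodified cross yields 22% F1 males in expectation
#'   ([calibrate_viability]`(0.22)`).
#' @param m Modifier effect multiplier on male viability (>= 0; 1 = none).
#' @param f Female relative viability (default 1: fully viable controls).
#' @param clutch_n Expected conceived F1 zygotes per cross. The default (240)
#'   reproduces the adult yield typical of the packaged screen: with the
#'   22% baseline a clutch of 240 zygotes leaves ~154 scored adults, the
#'   screen's median line size.
#' @param n_reps Monte-Carlo replicates for power computations.
#' @param seed Integer random seed.
#' @param poisson_clutch If `TRUE`, the clutch size of each cross is itself
#'   Poisson-distributed around `clutch_n`, mimicking natural variation in
#'   cross sizes; default `FALSE` (fixed clutch) for testability.
#' @return A `sim_config` object.
#' @export
sim_config <- function(v = calibrate_viability(0.22), m = 1, f = 1,
                       clutch_n = 240, n_reps = 1000, seed = 1,
                       poisson_clutch = FALSE) {
  stopifnot(v >= 0, m >= 0, f >= 0, n_reps >= 1)
  if (clutch_n < 1) stop("clutch_n must be a positive integer", call. = FALSE)
  structure(
    list(v = v, m = m, f = f, clutch_n = as.integer(clutch_n),
         n_reps = as.integer(n_reps), seed = as.integer(seed),
         poisson_clutch = isTRUE(poisson_clutch)),
    class = "sim_config"
  )
}

#' Expected F1 male fraction under the viability model
#'
#' Closed form: with male survival `s = min(1, v * m)` and female survival
#' `f' = min(1, f)`, the expected male fraction among surviving adults is
#' `s / (s + f')`. It equals the Mendelian 1/2 exactly when male and female
#' survivals are equal.
#'
#' @param v Baseline male relative viability.
#' @param m Modifier effect (default 1).
#' @param f Female relative viability (default 1).
#' @return Expected fraction of males among F1 adults.
#' @examples
#' expected_male_fraction(1, 1, 1)                       # 0.5
#' expected_male_fraction(calibrate_viability(0.22))     # 0.22
#' @export
expected_male_fraction <- function(v, m = 1, f = 1) {
  stopifnot(v >= 0, m >= 0, f >= 0)
  s <- min(1, v * m)
  ff <- min(1, f)
  if (s + ff == 0) stop("no survivors", call. = FALSE)
  s / (s + ff)
}

#' Calibrate baseline male viability from an observed male fraction
#'
#' Inverts the closed form at `m = 1`, `f = 1`: `v = p / (1 - p)` is the
#' unique viability for which an unmodified cross yields male fraction `p`.
#'
#' @param p Observed F1 male fraction, `0 <= p < 1`.
#' @return Baseline relative viability `v`.
#' @examples
#' calibrate_viability(0.22) # 0.28205...
#' @export
calibrate_viability <- function(p) {
  if (p < 0 || p >= 1) stop("male fraction must satisfy 0 <= p < 1",
                            call. = FALSE)
  p / (1 - p)
}

# vectorized tally engine; caller owns the RNG state
.sim_tallies <- function(n, config) {
  clutch <- if (config$poisson_clutch) {
    stats::rpois(n, config$clutch_n)
  } else {
    rep(config$clutch_n, n)
  }
  n_male <- stats::rbinom(n, clutch, 0.5)
  males <- stats::rbinom(n, n_male, min(1, config$v * config$m))
  females <- stats::rbinom(n, clutch - n_male, min(1, config$f))
  tibble::tibble(males = males, females = females)
}

#' Simulate one cross
#'
#' Zygote sex is binomial with probability 1/2; males then survive with
#' probability `min(1, v * m)` and females with `min(1, f)`. Identical
#' `(config, seed)` give identical tallies.
#'
#' @param config A [sim_config()].
#' @return A one-row tibble with `males` and `females` counts.
#' @export
simulate_cross <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .sim_tallies(1L, config))
}

#' Estimate a modifier effect from a tally
#'
#' Method of moments under full female viability: the male/female ratio
#' estimates `v * m`, so `m_hat = (males / females) / v`.
#'
#' @param males,females F1 adult counts (vectorized); `females >= 1`.
#' @param v Baseline male relative viability (> 0).
#' @return Estimated effect multiplier.
#' @examples
#' estimate_effect(314, 1123, calibrate_viability(0.22)) # ~0.99 (control)
#' @export
estimate_effect <- function(males, females, v) {
  if (v <= 0) stop("v must be positive", call. = FALSE)
  if (any(females < 1)) stop("zero females: effect not estimable",
                             call. = FALSE)
  (males / females) / v
}

#' Monte-Carlo detection power at a given effect size
#'
#' Simulates crosses at effect `m` and reports the proportion classified
#' (via [classify()]) into the class `m` implies: suppressor for `m > 1`,
#' enhancer for `m < 1`. The result carries its binomial standard error and
#' the implied class as attributes.
#'
#' @param m True modifier effect (not 1; see [false_positive_rate()]).
#' @param config A [sim_config()] (its `m` field is ignored in favor of `m`).
#' @param screen_config A [screen_config()].
#' @return Power as a numeric scalar with attributes `se` and `class`.
#' @export
detection_power <- function(m, config = sim_config(),
                            screen_config = f1screen::screen_config()) {
  if (m == 1) {
    stop("no true class at m = 1; use false_positive_rate()", call. = FALSE)
  }
  if (config$n_reps < 100) stop("n_reps must be >= 100", call. = FALSE)
  implied <- if (m > 1) "suppressor" else "enhancer"
  cfg <- config
  cfg$m <- m
  tallies <- withr::with_seed(config$seed, .sim_tallies(config$n_reps, cfg))
  scored <- tallies$males + tallies$females >= 1
  cls <- classify(pct_males(tallies$males[scored], tallies$females[scored]),
                  screen_config)
  power <- sum(cls == implied) / config$n_reps
  structure(power, se = sqrt(power * (1 - power) / config$n_reps),
            class_implied = implied)
}

#' Monte-Carlo false-positive rate under the null (m = 1)
#'
#' Proportion of unmodified simulated crosses misclassified as suppressor or
#' enhancer.
#'
#' @param config A [sim_config()] with `m` forced to 1.
#' @param screen_config A [screen_config()].
#' @return Rate as a numeric scalar with attribute `se`.
#' @export
false_positive_rate <- function(config = sim_config(),
                                screen_config = f1screen::screen_config()) {
  cfg <- config
  cfg$m <- 1
  tallies <- withr::with_seed(config$seed, .sim_tallies(config$n_reps, cfg))
  scored <- tallies$males + tallies$females >= 1
  cls <- classify(pct_males(tallies$males[scored], tallies$females[scored]),
                  screen_config)
  rate <- sum(cls != "nonmodifier") / config$n_reps
  structure(rate, se = sqrt(rate * (1 - rate) / config$n_reps))
}

# stable per-line substream seed: reordering or subsetting lines does not
# change any line's tally
.line_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(i)) %% 2147483647)
}

#' Generate a synthetic screen table
#'
#' Draws a true effect for every line from a discrete effect distribution
#' (point masses and mixtures), simulates each line's cross, and returns a
#' table in the screen TSV dialect so the whole scoring pipeline can run with
#' no external data.
#'
#' @param n_lines Number of deficiency-like lines to simulate.
#' @param effect_spec Either a single effect value (point mass) or a data
#'   frame / list with elements `m` (effect values) and `prob` (mixture
#'   weights, normalized internally).
#' @param config A [sim_config()]; `seed` governs both the effect draws and
#'   the per-line tallies (each line uses a counter-derived substream).
#' @return A tibble with `line_id`, `true_m`, `males`, `females`, carrying
#'   the configuration in attribute `sim_config`.
#' @export
generate_screen_table <- function(n_lines, effect_spec = 1,
                                  config = sim_config()) {
  stopifnot(n_lines >= 1)
  spec <- .normalize_effect_spec(effect_spec)
  true_m <- withr::with_seed(config$seed, {
    sample(spec$m, n_lines, replace = TRUE, prob = spec$prob)
  })
  males <- integer(n_lines)
  females <- integer(n_lines)
  for (i in seq_len(n_lines)) {
    cfg <- config
    cfg$m <- true_m[i]
    tal <- withr::with_seed(.line_seed(config$seed, i), .sim_tallies(1L, cfg))
    males[i] <- tal$males
    females[i] <- tal$females
  }
  out <- tibble::tibble(
    line_id = sprintf("sim%04d", seq_len(n_lines)),
    true_m = true_m,
    males = males,
    females = females
  )
  attr(out, "sim_config") <- config
  out
}

.normalize_effect_spec <- function(effect_spec) {
  if (is.numeric(effect_spec) && is.null(dim(effect_spec)) &&
      length(effect_spec) == 1L) {
    return(list(m = effect_spec, prob = 1))
  }
  if (is.list(effect_spec) && all(c("m", "prob") %in% names(effect_spec))) {
    m <- effect_spec$m
    prob <- effect_spec$prob
    if (length(m) != length(prob) || any(prob < 0) || sum(prob) <= 0 ||
        any(m < 0)) {
      stop("invalid effect distribution spec", call. = FALSE)
    }
    return(list(m = m, prob = prob / sum(prob)))
  }
  stop("invalid effect distribution spec", call. = FALSE)
}
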