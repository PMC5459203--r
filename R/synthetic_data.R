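# Seeded generators for every input the analysis consumes: Langmuir
# depletion isotherms, single-exponential fluorescence-quench traces with a
# pre-addition baseline, and lognormal TEM size samples. All generators are
# pure functions of (parameters, seed): the global RNG state is saved and
# restored around each call.

#' Measurement-noise model
#'
#' The instrument path is emulated as multiplicative lamp/detector noise
#' (applied before the lamp-reference division and divided out imperfectly,
#' leaving a residual multiplicative sd) followed by additive detector
#' noise.
#'
#' @param multiplicative_sd residual multiplicative noise, as a fraction.
#' @param additive_sd additive noise, in signal units.
#' @param seed integer seed; identical seed gives identical output.
#' @return A `mof_noise_model` list.
#' @export
noise_model <- function(multiplicative_sd = 0, additive_sd = 0, seed = 1L) {
  if (multiplicative_sd < 0 || additive_sd < 0)
    stop_input("noise standard deviations must be >= 0")
  structure(list(multiplicative_sd = multiplicative_sd,
                 additive_sd = additive_sd, seed = as.integer(seed)),
            class = "mof_noise_model")
}

# evaluate expr under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic depletion isotherm
#'
#' Langmuir values at the design concentrations, perturbed by the noise
#' model; with `replicates > 1` each point is the mean of independently
#' perturbed replicates and a per-point sd column is attached, mirroring
#' triplicate bench measurements.
#'
#' @param p_max,k_d generating Langmuir parameters (ug/mg, ug/mL).
#' @param design external concentrations, ug/mL (non-empty).
#' @param noise a [noise_model()].
#' @param replicates independent replicates per design point.
#' @return A `mof_isotherm` dataset (see [isotherm_dataset()]).
#' @export
#' @examples
#' gen_isotherm(649.4, 4.4, design = c(20, 50, 150, 400, 1000, 1500),
#'              noise = noise_model(0.05, 0, seed = 7), replicates = 3)
gen_isotherm <- function(p_max, k_d, design, noise = noise_model(),
                         replicates = 1L) {
  if (length(design) == 0) stop_input("design must be non-empty")
  truth <- langmuir_eval(design, p_max, k_d)
  with_seed(noise$seed, {
    reps <- replicate(replicates, {
      y <- truth * (1 + stats::rnorm(length(truth), 0, noise$multiplicative_sd))
      y <- y + stats::rnorm(length(truth), 0, noise$additive_sd)
      pmax(y, 0)
    })
    reps <- matrix(reps, nrow = length(truth))
    isotherm_dataset(design, rowMeans(reps),
                     replicate_sd = if (replicates > 1L)
                       apply(reps, 1, stats::sd))
  })
}

#' Generate a synthetic fluorescence-quench trace
#'
#' A unit baseline for `baseline_s` seconds before particle addition, then
#' `offset + (1 - offset) * exp(-rate * t)`, sampled at `dt` and perturbed
#' by the noise model. `rate = 0` produces the flat trace seen when no
#' loading occurs (the high-pH analogue).
#'
#' @param rate first-order loading rate, 1/s (>= 0).
#' @param offset normalized plateau level in (0, 1].
#' @param baseline_s pre-addition recording time, s.
#' @param duration_s post-addition recording time, s (>= 100).
#' @param noise a [noise_model()].
#' @param dt sampling interval, s.
#' @param ph,solvent optional metadata.
#' @return A `mof_trace` (not yet baseline-normalized: the baseline carries
#'   noise like any real recording).
#' @export
#' @examples
#' gen_trace(rate = 0.013, offset = 0.2, baseline_s = 60, duration_s = 500,
#'           noise = noise_model(0.01, 0, seed = 3))
gen_trace <- function(rate, offset = 0.2, baseline_s = 60, duration_s = 500,
                      noise = noise_model(), dt = 1, ph = NA_real_,
                      solvent = NA_character_) {
  if (rate < 0) stop_input("rate must be >= 0")
  if (offset <= 0 || offset > 1) stop_input("offset must be in (0, 1]")
  if (duration_s < 100) stop_input("duration_s must be >= 100 s")
  t <- seq(-baseline_s, duration_s, by = dt)
  truth <- ifelse(t < 0, 1,
                  if (rate == 0) 1 else offset + (1 - offset) * exp(-rate * t))
  with_seed(noise$seed, {
    y <- truth * (1 + stats::rnorm(length(t), 0, noise$multiplicative_sd))
    y <- y + stats::rnorm(length(t), 0, noise$additive_sd)
    fluorescence_trace(t, pmax(y, 1e-9), ph = ph, solvent = solvent)
  })
}

#' Generate lognormal TEM diameters
#'
#' Right-skewed, strictly positive diameters, the shape TEM size histograms
#' of nanoparticle batches typically show. `sigma_log = 0` degenerates to
#' all values equal to the median.
#'
#' @param median_nm median diameter, nm.
#' @param sigma_log log-scale standard deviation.
#' @param n sample size (>= 1).
#' @param seed integer seed.
#' @return Numeric vector of diameters, nm.
#' @export
#' @examples
#' summarize_sizes(gen_sizes(52, 0.31, n = 10000, seed = 42))
gen_sizes <- function(median_nm, sigma_log, n, seed = 1L) {
  if (n < 1) stop_input("n must be >= 1")
  if (median_nm <= 0 || sigma_log < 0)
    stop_input("median_nm must be > 0 and sigma_log >= 0")
  with_seed(seed, median_nm * exp(stats::rnorm(n, 0, sigma_log)))
}
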