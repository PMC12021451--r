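# Synthetic assay-data generators: shake-flask partitioning (equal-volume
# two-phase mass balance, bidirectional start) and the whole-blood
# depletion assay, both with multiplicative lognormal measurement noise.

#' Simulation configuration for the synthetic assay generators
#'
#' The defaults mirror the wet-lab study design: triplicates per
#' equilibration direction for the shake flask, six replicates for the
#' depletion assay at a primary concentration of 1000 ng/mL, hematocrit
#' 0.45. `noise_cv` is the fractional coefficient of variation of the
#' multiplicative lognormal peak-area noise (so `noise_cv` is
#' approximately the relative SD of a measured area).
#'
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param noise_cv Fractional CV of measurement noise (>= 0).
#' @param n_per_direction Shake-flask replicates per direction.
#' @param n_replicates Depletion-assay replicates per concentration.
#' @param concentrations Depletion-assay spike concentrations (ng/mL).
#' @param matrix_effect_ratio Octanol vs water LC-MS response-factor
#'   ratio (> 0); 1 means both phases respond identically.
#' @param equilibration_fraction Fraction of the distance from the
#'   all-in-start-phase state to two-phase equilibrium that is covered,
#'   in (0, 1\]; 1 means full equilibration.
#' @param hct Hematocrit used by the depletion simulator's physical
#'   floor check.
#'
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = NULL, noise_cv = 0.05,
                              n_per_direction = 3, n_replicates = 6,
                              concentrations = 1000,
                              matrix_effect_ratio = 1,
                              equilibration_fraction = 1, hct = 0.45) {
  if (!is.null(seed)) {
    stopifnot(is_scalar_number(seed))
    seed <- as.integer(seed)
  }
  stopifnot(is_scalar_number(noise_cv), noise_cv >= 0,
            is_scalar_number(n_per_direction), n_per_direction >= 1,
            is_scalar_number(n_replicates), n_replicates >= 1,
            is.numeric(concentrations), length(concentrations) >= 1,
            all(is.finite(concentrations) & concentrations > 0),
            is_scalar_number(matrix_effect_ratio), matrix_effect_ratio > 0,
            is_scalar_number(equilibration_fraction),
            equilibration_fraction > 0, equilibration_fraction <= 1,
            is_scalar_number(hct), hct > 0, hct < 1)
  structure(list(seed = seed, noise_cv = noise_cv,
                 n_per_direction = as.integer(n_per_direction),
                 n_replicates = as.integer(n_replicates),
                 concentrations = concentrations,
                 matrix_effect_ratio = matrix_effect_ratio,
                 equilibration_fraction = equilibration_fraction,
                 hct = hct),
            class = "simulation_config")
}

# multiplicative lognormal noise with E[log eps] = 0 and CV ~ noise_cv
noise_factor <- function(n, noise_cv) {
  if (noise_cv == 0) return(rep(1, n))
  exp(rnorm(n, mean = 0, sd = sqrt(log(1 + noise_cv^2))))
}

#' Simulate shake-flask partitioning measurements
#'
#' Equal-volume two-phase mass balance: with partition coefficient
#' \eqn{P = 10^{\log P}}, the equilibrium mass fractions are
#' \eqn{P/(1+P)} in octanol and \eqn{1/(1+P)} in water. Replicates start
#' with all compound in one phase (both directions are generated) and
#' cover `equilibration_fraction` of the distance to equilibrium, so
#' mass is conserved exactly for every fraction. Peak areas are
#' proportional to the phase concentrations with multiplicative
#' lognormal noise; the octanol response is additionally scaled by
#' `matrix_effect_ratio`.
#'
#' @param true_logp True log10 partition coefficient.
#' @param cfg A [simulation_config()].
#' @param compound Compound label for the output records.
#'
#' @return Tibble of replicate measurements in the schema consumed by
#'   [estimate_logp()].
#' @export
simulate_shake_flask <- function(true_logp, cfg = simulation_config(),
                                 compound = "synthetic") {
  stopifnot(inherits(cfg, "simulation_config"), is_scalar_number(true_logp))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  p <- 10^true_logp
  f <- cfg$equilibration_fraction
  # mass fractions (total mass 1) by starting phase
  states <- list(
    from_organic = c(oct = 1 - f / (1 + p), wat = f / (1 + p)),
    from_aqueous = c(oct = f * p / (1 + p), wat = 1 - f * p / (1 + p))
  )
  response <- 1000  # arbitrary instrument response per unit concentration
  rows <- lapply(names(states), function(dir) {
    st <- states[[dir]]
    n <- cfg$n_per_direction
    tibble(
      compound = compound, direction = dir, replicate_id = seq_len(n),
      area_octanol = response * cfg$matrix_effect_ratio * st[["oct"]] *
        noise_factor(n, cfg$noise_cv),
      area_water = response * st[["wat"]] * noise_factor(n, cfg$noise_cv)
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate depletion-assay measurements
#'
#' For each spike concentration \eqn{C_0}, the reference plasma holds
#' \eqn{C_0} and the plasma equilibrated with red blood cells holds
#' \eqn{C_0 / R_b}; peak areas are proportional with multiplicative
#' lognormal noise. `true_rb` below the physical floor `1 - hct` (which
#' would require negative erythrocyte content) is rejected.
#'
#' @param true_rb True blood-to-plasma concentration ratio.
#' @inheritParams simulate_shake_flask
#'
#' @return Tibble of replicate measurements in the schema consumed by
#'   [estimate_rb()].
#' @export
simulate_depletion <- function(true_rb, cfg = simulation_config(),
                               compound = "synthetic") {
  stopifnot(inherits(cfg, "simulation_config"), is_scalar_number(true_rb))
  if (true_rb < 1 - cfg$hct) {
    pa_error(sprintf(
      "true_rb = %g is below the physical floor 1 - hct = %g",
      true_rb, 1 - cfg$hct), "papartition_parameter_error")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  response <- 1000
  rows <- lapply(cfg$concentrations, function(c0) {
    n <- cfg$n_replicates
    tibble(
      compound = compound, concentration = c0, replicate_id = seq_len(n),
      area_reference_plasma = response * c0 * noise_factor(n, cfg$noise_cv),
      area_equilibrated_plasma = response * (c0 / true_rb) *
        noise_factor(n, cfg$noise_cv)
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate a determined-vs-literature method-validation panel
#'
#' Stands in for a reference-substance panel: for each compound the true
#' value plays the role of the literature value, synthetic replicate
#' data are generated and run through the corresponding estimator, and
#' the resulting determined-vs-literature pairs feed
#' [validate_logp_method()] / [validate_rb_method()]. Each compound uses
#' seed `cfg$seed + index` so replicate noise is independent across the
#' panel yet reproducible.
#'
#' @param truths Named numeric vector of true values (names = compound
#'   labels); at least 3 entries for downstream validation.
#' @param cfg A [simulation_config()].
#' @param assay `"logp"` (shake flask) or `"rb"` (depletion).
#'
#' @return List with `determined` (tibble of estimator summaries) and
#'   `literature` (the input truths), ready for the validators.
#' @export
simulate_validation_panel <- function(truths, cfg = simulation_config(),
                                      assay = c("logp", "rb")) {
  assay <- match.arg(assay)
  stopifnot(is.numeric(truths), !is.null(names(truths)))
  base_seed <- if (is.null(cfg$seed)) NULL else cfg$seed
  determined <- dplyr::bind_rows(lapply(seq_along(truths), function(i) {
    cfg_i <- cfg
    if (!is.null(base_seed)) cfg_i$seed <- base_seed + i
    if (assay == "logp") {
      estimate_logp(simulate_shake_flask(truths[[i]], cfg_i,
                                         compound = names(truths)[i]))
    } else {
      estimate_rb(simulate_depletion(truths[[i]], cfg_i,
                                     compound = names(truths)[i]))
    }
  }))
  list(determined = determined, literature = truths)
}
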