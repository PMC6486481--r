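# Synthetic scenarios: ground-truth Golgi models plus replicate "observed"
# profiles, so fitting, diagnostics and flux analysis are testable without
# experimental data.  Replicate noise comes solely from finite-n SSA
# sampling, the model's own noise source.

.SCENARIO_RATES <- list(
  # 3-cisterna model dominated by oligomannose output (>90%): slow first
  # antenna, appreciable quench.
  `oligomannose-3c` = list(
    cisternae = 3L,
    input = c(Man8 = 0.80, Man9 = 0.15, Man9Glc = 0.05),
    rates = rbind(
      MAN1     = c(0.080, 0.120, 0.040),
      EndoMan  = c(0.300, 0.020, 0.010),
      MGAT1    = c(0.002, 0.006, 0.003),
      MAN2     = c(0.050, 0.100, 0.100),
      MGAT2    = c(0.020, 0.050, 0.080),
      MGAT4    = c(0.010, 0.020, 0.040),
      MGAT5    = c(0.010, 0.020, 0.040),
      GalT     = c(0.005, 0.050, 0.150),
      SiaT     = c(0.002, 0.020, 0.120),
      FUT8     = c(0.010, 0.040, 0.060),
      antFUT   = c(0.002, 0.010, 0.030),
      OMquench = c(0.020, 0.030, 0.050)),
    home = c(MAN1 = 2L, EndoMan = 1L, MGAT1 = 2L, MAN2 = 2L, MGAT2 = 3L,
             MGAT4 = 3L, MGAT5 = 3L, GalT = 3L, SiaT = 3L, FUT8 = 3L,
             antFUT = 3L, OMquench = 3L)),
  # 4-cisterna model with a substantial complex-glycan output, including
  # tri-/tetra-antennary species.
  `complex-4c` = list(
    cisternae = 4L,
    input = c(Man8 = 0.80, Man9 = 0.15, Man9Glc = 0.05),
    rates = rbind(
      MAN1     = c(0.250, 0.350, 0.100, 0.050),
      EndoMan  = c(0.400, 0.050, 0.010, 0.010),
      MGAT1    = c(0.050, 0.250, 0.100, 0.020),
      MAN2     = c(0.050, 0.300, 0.150, 0.050),
      MGAT2    = c(0.020, 0.150, 0.250, 0.050),
      MGAT4    = c(0.005, 0.050, 0.120, 0.050),
      MGAT5    = c(0.005, 0.050, 0.120, 0.050),
      GalT     = c(0.005, 0.050, 0.200, 0.300),
      SiaT     = c(0.002, 0.020, 0.100, 0.300),
      FUT8     = c(0.010, 0.100, 0.150, 0.050),
      antFUT   = c(0.002, 0.010, 0.050, 0.100),
      OMquench = c(0.010, 0.020, 0.030, 0.030)),
    home = c(MAN1 = 2L, EndoMan = 1L, MGAT1 = 2L, MAN2 = 2L, MGAT2 = 3L,
             MGAT4 = 3L, MGAT5 = 3L, GalT = 4L, SiaT = 4L, FUT8 = 3L,
             antFUT = 4L, OMquench = 3L)),
  # Reduced 3-cisterna, 5-enzyme pathway used for parameter-recovery
  # studies; the truth follows the 80%-in-home-cisterna layout the priors
  # encode.
  `recovery-3c5e` = list(
    cisternae = 3L,
    input = c(Man8 = 0.85, Man9 = 0.15),
    rates = rbind(
      MAN1     = c(0.400, 0.050, 0.050),
      MGAT1    = c(0.020, 0.160, 0.020),
      MAN2     = c(0.030, 0.240, 0.030),
      GalT     = c(0.040, 0.040, 0.320),
      OMquench = c(0.010, 0.010, 0.080)),
    home = c(MAN1 = 1L, MGAT1 = 2L, MAN2 = 2L, GalT = 3L, OMquench = 3L))
)

.SCENARIO_PERTURB <- list(
  `man2-null` = list(base = "complex-4c", multipliers = c(MAN2 = 0)),
  `cog4ko-like` = list(base = "complex-4c",
                       multipliers = c(MGAT1 = 0.5, MGAT5 = 0.4,
                                       MAN2 = 0.6, GalT = 0.5))
)

#' Available synthetic scenario presets
#' @return Character vector of preset names.
#' @export
scenario_presets <- function() {
  c(names(.SCENARIO_RATES), names(.SCENARIO_PERTURB))
}

#' Build a synthetic scenario
#'
#' A scenario bundles a ground-truth [golgi_model()], replicate settings
#' and an optional enzyme perturbation (0 = knockout-like, <1 =
#' knockdown-like).  Presets: `"oligomannose-3c"` (3 cisternae, >90%
#' oligomannose output), `"complex-4c"` (4 cisternae, complex-rich),
#' `"recovery-3c5e"` (reduced 5-enzyme pathway for recovery studies),
#' `"man2-null"` (complex-4c with MAN2 removed, the mannosidase-II
#' inhibition limit) and `"cog4ko-like"` (complex-4c with reduced MGAT1,
#' MGAT5, MAN2 and GalT).  Scenario construction is a pure function of
#' (preset, seed).
#'
#' @param preset preset name (see [scenario_presets()]).
#' @param seed seed stored in the scenario and used by [synth_observed()].
#' @param n_glycans glycans per replicate (default 10000).
#' @param n_replicates replicates for the observed profile (default 3).
#' @return An object of class `"golgi_scenario"`.
#' @export
make_scenario <- function(preset, seed = 1L, n_glycans = 10000L,
                          n_replicates = 3L) {
  if (preset %in% names(.SCENARIO_PERTURB)) {
    spec <- .SCENARIO_PERTURB[[preset]]
    sc <- make_scenario(spec$base, seed, n_glycans, n_replicates)
    sc$preset <- preset
    return(perturb(sc, spec$multipliers))
  }
  if (!preset %in% names(.SCENARIO_RATES))
    stop("unknown preset: ", preset)
  spec <- .SCENARIO_RATES[[preset]]
  model <- golgi_model(spec$rates, residence_time = 10,
                       input_distribution = spec$input)
  structure(list(preset = preset, ground_truth = model, home = spec$home,
                 perturbation = NULL, n_glycans = n_glycans,
                 n_replicates = n_replicates, seed = seed),
            class = "golgi_scenario")
}

#' @export
print.golgi_scenario <- function(x, ...) {
  cat("<golgi_scenario> preset '", x$preset, "', seed ", x$seed, "\n", sep = "")
  if (!is.null(x$perturbation))
    cat("  perturbation:", paste0(names(x$perturbation), "x",
                                  x$perturbation, collapse = ", "), "\n")
  print(scenario_model(x))
  invisible(x)
}

#' Apply an enzyme perturbation to a scenario
#'
#' Scales the named enzymes' rates across all cisternae; everything else
#' is unchanged.  Perturbations compose multiplicatively.
#'
#' @param scenario a `"golgi_scenario"`.
#' @param multipliers named non-negative multipliers.
#' @return The perturbed scenario.
#' @export
perturb <- function(scenario, multipliers) {
  unknown <- setdiff(names(multipliers),
                     rownames(scenario$ground_truth$rates))
  if (length(unknown))
    stop("unknown enzyme(s): ", paste(unknown, collapse = ", "))
  if (any(multipliers < 0)) stop("multipliers must be >= 0")
  p <- scenario$perturbation
  if (is.null(p)) p <- setNames(numeric(0), character(0))
  for (e in names(multipliers))
    p[e] <- if (e %in% names(p)) p[[e]] * multipliers[[e]] else multipliers[[e]]
  scenario$perturbation <- p
  scenario
}

#' Effective model of a scenario (ground truth + perturbation)
#' @param scenario a `"golgi_scenario"`.
#' @return A [golgi_model()].
#' @export
scenario_model <- function(scenario) {
  m <- scenario$ground_truth
  if (!is.null(scenario$perturbation) && length(scenario$perturbation))
    m <- scale_enzymes(m, scenario$perturbation)
  m
}

#' Synthetic observed profile for a scenario
#'
#' Replicate-simulates the scenario's effective model and returns the mean
#' profile with SEMs, in the same format as a real observed-profile input.
#'
#' @param scenario a `"golgi_scenario"`.
#' @param ruleset rule set (default mammalian rules, restricted
#'   automatically to the scenario's enzymes).
#' @return A [glycan_profile()] with SEMs.
#' @export
synth_observed <- function(scenario, ruleset = scenario_ruleset(scenario)) {
  replicate_profile(scenario_model(scenario),
                    n_glycans = scenario$n_glycans,
                    n_replicates = scenario$n_replicates,
                    seed = scenario$seed, ruleset = ruleset)
}

#' Rule set restricted to a scenario's enzymes
#'
#' Drops rules whose enzyme has no rate row in the scenario's model, so
#' reduced scenarios compile reduced reaction networks.
#'
#' @param scenario a `"golgi_scenario"`.
#' @param base full rule set to restrict.
#' @return `list(rules, scales)`.
#' @export
scenario_ruleset <- function(scenario, base = default_mammalian_rules()) {
  enz <- rownames(scenario$ground_truth$rates)
  base$rules <- Filter(function(r) r$enzyme %in% enz, base$rules)
  base
}

#' Localization priors matching a scenario's layout
#'
#' Priors built from the scenario's documented enzyme homes and total
#' rates via [localization_priors()]; this encodes the same knowledge the
#' ground truth was built from, without using the fitted values
#' themselves beyond the stated per-enzyme totals.
#'
#' @param scenario a `"golgi_scenario"`.
#' @param home_frac,sdlog passed to [localization_priors()].
#' @return A [prior_spec()].
#' @export
scenario_priors <- function(scenario, home_frac = 0.8, sdlog = 0.8) {
  m <- scenario$ground_truth
  localization_priors(m, scenario$home,
                      total_rate = rowSums(m$rates),
                      home_frac = home_frac, sdlog = sdlog)
}
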