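#' Specify a simulated flupentixol condition
#'
#' Flupentixol, a non-specific dopamine receptor antagonist, is modelled as
#' two dose-proportional transforms: (1) attenuation of the reward
#' prediction errors consumed by Model-Free-type learners (the learning
#' effect of blocking phasic dopamine) and (2) elevation of the softmax
#' selection temperature (the expression effect of reduced tonic dopamine
#' signalling, pushing choice toward exploration). Systemic administration
#' activates both transforms; local administration in the nucleus accumbens
#' core activates only the RPE transform, on the hypothesis that the feature
#' learner, but not the action-selection stage, resides there. The
#' Model-Based planner is never affected: it learns from observed
#' transitions, not from dopamine-like prediction errors.
#'
#' @param dose nonnegative dose in arbitrary units.
#' @param site `"none"`, `"systemic"` or `"local_NAcc"`.
#' @param k_rpe dose-to-RPE-attenuation coefficient (eta_rpe = k_rpe * dose).
#' @param k_temp dose-to-temperature-elevation coefficient
#'   (eta_temp = k_temp * dose; systemic only).
#' @return list of class `drug_condition` with resolved `eta_rpe` and
#'   `eta_temp` magnitudes.
#' @export
drug_condition <- function(dose = 0, site = c("none", "systemic", "local_NAcc"),
                           k_rpe = 0.1, k_temp = 1) {
  site <- match.arg(site)
  stopifnot(dose >= 0, k_rpe >= 0, k_temp >= 0)
  structure(list(
    dose = dose, site = site,
    eta_rpe = if (site == "none") 0 else k_rpe * dose,
    eta_temp = if (site == "systemic") k_temp * dose else 0),
    class = "drug_condition")
}

#' Attenuate a reward prediction error under flupentixol
#'
#' Positive errors are reduced additively and clamped at zero:
#' delta' = max(0, delta - eta_rpe). A dose can therefore at most block
#' positive learning, never turn it into negative learning. Negative errors
#' pass unchanged: receptor blockade silences the burst signal, while the
#' pause signalling a negative error is still read out. (A multiplicative
#' attenuation would only slow learning down without ever disrupting the
#' values that sustain an acquired response; the additive clamp is what lets
#' an acquired sign-tracking response relax under the drug, because
#' unattenuated negative revisions are no longer balanced by the attenuated
#' positive ones.)
#'
#' @param delta RPE (vectorised).
#' @param cond a [drug_condition()].
#' @return the transformed RPE(s); identity when `cond$site == "none"`.
#' @export
attenuate_rpe <- function(delta, cond) {
  eta <- cond$eta_rpe
  if (eta <= 0) return(delta)
  ifelse(delta > 0, pmax(0, delta - eta), delta)
}

#' Elevate the softmax temperature under systemic flupentixol
#'
#' beta' = beta * (1 + eta_temp) under systemic administration; identity
#' otherwise. At dose zero the transform is exactly the identity, and the
#' effect scales with the baseline temperature.
#'
#' @param beta baseline selection temperature (> 0).
#' @param cond a [drug_condition()].
#' @return the effective temperature.
#' @export
elevate_temperature <- function(beta, cond) {
  stopifnot(beta > 0)
  beta * (1 + cond$eta_temp)
}
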