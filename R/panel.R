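#' Default characterization of the four-metabolite plasma panel
#'
#' Published bench characterization of the platform for total L-amino acids
#' (LAA), glutamate, choline, and sarcosine measured in human plasma with
#' oxidase/peroxidase colorimetric assays. Each row carries the
#' Michaelis-Menten calibration (`v_max` mV/s, `k_m` uM, offset `c` mV/s), the
#' linear-model sensitivity inside the linear range (`sens` mV/s per mM, with
#' `baseline` mV/s and range bounds in uM), the average relative replicate
#' standard deviation observed in the linear range (`noise_rel`, fraction),
#' and the standard-addition spike levels used in the clinical protocol
#' (`spike_a` uM; the second spike is `2 * spike_a`).
#'
#' In `"dried"` reagent mode (reagents pre-deposited and dried in the
#' channels for simultaneous multi-metabolite measurements) the sensitivities
#' are rescaled to their dried-mode values and sarcosine is dropped; the
#' elevated dried-mode negative-control statistics are available from
#' [negative_control_defaults()].
#'
#' @param mode `"liquid"` (off-chip mixed reagents, default) or `"dried"`.
#' @return A data.frame, one row per metabolite.
#' @export
panel_assays <- function(mode = c("liquid", "dried")) {
  mode <- match.arg(mode)
  tab <- data.frame(
    metabolite = c("LAA", "glutamate", "choline", "sarcosine"),
    v_max   = c(3.63, 5.28, 11.34, 11.03),
    k_m     = c(2866, 529.7, 1382, 1209),
    c       = c(-0.032, -0.087, 0.082, 0.027),
    sens    = c(0.83, 6.06, 9.98, 7.84),
    baseline = c(0.020, 0.003, 0.019, 0.050),
    lin_lo  = c(0, 0, 0, 0),
    lin_hi  = c(1500, 320, 120, 120),
    test_hi = c(5400, 1500, 600, 600),
    noise_rel = c(0.183, 0.172, 0.164, 0.192),
    spike_a = c(500, 100, 100, 100),
    stringsAsFactors = FALSE
  )
  if (mode == "dried") {
    dried_sens <- c(LAA = 0.72, glutamate = 6.14, choline = 7.78)
    tab <- tab[tab$metabolite %in% names(dried_sens), , drop = FALSE]
    scale <- dried_sens[tab$metabolite] / tab$sens
    tab$sens <- unname(dried_sens[tab$metabolite])
    # dried-mode MM curve rescaled proportionally to the sensitivity change
    tab$v_max <- tab$v_max * unname(scale)
    tab$noise_rel <- c(LAA = 0.157, glutamate = 0.180, choline = 0.177)[tab$metabolite]
    rownames(tab) <- NULL
  }
  tab$spike_b <- 2 * tab$spike_a
  tab
}

#' Michaelis-Menten parameters for one panel metabolite
#'
#' @param metabolite One of `"LAA"`, `"glutamate"`, `"choline"`, `"sarcosine"`.
#' @param mode Reagent mode passed to [panel_assays()].
#' @return An [mm_params()] object.
#' @export
panel_mm_params <- function(metabolite, mode = "liquid") {
  tab <- panel_assays(mode)
  row <- tab[tab$metabolite == metabolite, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown metabolite for mode '", mode, "': ", metabolite)
  mm_params(v_max = row$v_max, k_m = row$k_m, c = row$c)
}

#' Default negative-control rate statistics
#'
#' Mean and standard deviation of the initial reaction rate of negative
#' controls (assay run without the substrate-specific oxidase), common to all
#' four assays: 5.0 +/- 2.7 uV/s with liquid reagents (n = 24) and
#' 23.0 +/- 12.5 uV/s in dried-reagent mode.
#'
#' @param mode `"liquid"` or `"dried"`.
#' @return A [negative_control_stats()] object (rates in uV/s).
#' @export
negative_control_defaults <- function(mode = c("liquid", "dried")) {
  mode <- match.arg(mode)
  if (mode == "liquid") negative_control_stats(mu_c = 5.0, delta_c = 2.7, n = 24)
  else negative_control_stats(mu_c = 23.0, delta_c = 12.5, n = 24)
}

#' Default clinical cohort group specifications
#'
#' Group-level concentration means and standard deviations (uM) for the
#' non-cancer control group (n = 10) and the prostate-cancer group (n = 16)
#' of the preliminary clinical study, for LAA, glutamate, choline and
#' sarcosine. Used by [simulate_cohort()] to draw synthetic cohorts with the
#' published group statistics.
#'
#' @return A list of two [group_spec()] objects named `"non-PCa"` and `"PCa"`.
#' @export
cohort_group_defaults <- function() {
  mets <- c("LAA", "glutamate", "choline", "sarcosine")
  list(
    "non-PCa" = group_spec(
      label = "non-PCa", n = 10,
      mean = stats::setNames(c(1984, 40.2, 10.0, 11.5), mets),
      sd   = stats::setNames(c(527, 11.2, 4.1, 4.3), mets)),
    "PCa" = group_spec(
      label = "PCa", n = 16,
      mean = stats::setNames(c(2694, 62.2, 13.4, 10.0), mets),
      sd   = stats::setNames(c(1052, 29.5, 7.9, 6.9), mets))
  )
}

#' Published PSA reference operating characteristics
#'
#' Literature sensitivity/specificity of prostate-specific antigen at the
#' 3.1 ng/mL threshold and its ROC AUC, used as the comparator for the
#' metabolite-panel classifier.
#'
#' @return A list with `sensitivity`, `specificity`, and `auc`.
#' @export
psa_reference <- function() {
  list(sensitivity = 0.32, specificity = 0.87, auc = 0.68)
}
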