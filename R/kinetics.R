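#' Kinetic parameters for the single-compartment PCASL signal model
#'
#' Physical constants entering the expected label/control difference:
#' blood T1 (all label decay is assumed to occur at blood T1, appropriate
#' for the long transit times of white matter where little label has
#' exchanged by readout), labeling efficiency, the combined efficiency
#' penalty of the background-suppression inversions, the blood-brain
#' partition coefficient, and the equilibrium magnetization scale.
#'
#' @param t1_blood Longitudinal relaxation time of arterial blood, ms
#'   (default 1650 at 3 T).
#' @param labeling_efficiency PCASL inversion efficiency, in (0, 1].
#' @param bs_efficiency Combined background-suppression efficiency
#'   multiplier, in (0, 1].
#' @param blood_brain_partition Blood-brain partition coefficient
#'   lambda, mL/g.
#' @param equilibrium_magnetization Equilibrium magnetization M0 in
#'   arbitrary signal units; sets the output scale.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(t1_blood = 1650,
                           labeling_efficiency = 0.85,
                           bs_efficiency = 0.75,
                           blood_brain_partition = 0.9,
                           equilibrium_magnetization = 1) {
  if (t1_blood <= 0) stop("'t1_blood' must be positive", call. = FALSE)
  if (labeling_efficiency <= 0 || labeling_efficiency > 1 ||
      bs_efficiency <= 0 || bs_efficiency > 1)
    stop("efficiencies must lie in (0, 1]", call. = FALSE)
  if (blood_brain_partition <= 0)
    stop("'blood_brain_partition' must be positive", call. = FALSE)
  structure(list(t1_blood = t1_blood,
                 labeling_efficiency = labeling_efficiency,
                 bs_efficiency = bs_efficiency,
                 blood_brain_partition = blood_brain_partition,
                 equilibrium_magnetization = equilibrium_magnetization),
            class = "kinetic_params")
}

#' Expected ASL difference signal (single-compartment PCASL model)
#'
#' Closed-form expected control-minus-label difference for continuous
#' labeling of duration tau = LD, read out at t = LD + PLD after the
#' start of labeling, for a voxel with perfusion `cbf` (f) and arterial
#' transit time `transit_time` (delta).  With epsilon = labeling
#' efficiency x BS efficiency, lambda the partition coefficient and T1b
#' blood T1, the model is piecewise in t:
#' \deqn{\Delta M = 0, \quad t \le \delta}
#' \deqn{\Delta M = 2\epsilon M_0 \frac{f}{\lambda}\frac{T_{1b}}{60000}
#'   e^{-\delta/T_{1b}} (1 - e^{-(t-\delta)/T_{1b}}),
#'   \quad \delta < t \le \delta+\tau}
#' \deqn{\Delta M = 2\epsilon M_0 \frac{f}{\lambda}\frac{T_{1b}}{60000}
#'   e^{-\delta/T_{1b}} (1 - e^{-\tau/T_{1b}}) e^{-(t-\delta-\tau)/T_{1b}},
#'   \quad t > \delta+\tau}
#' (the factor 60000 converts CBF from mL/100g/min with f in those units
#' to per-ms flow; continuous and nonnegative in t).
#'
#' @param cbf Perfusion in mL/100g/min; vectorized.
#' @param transit_time Arterial transit time delta in ms; vectorized
#'   (recycled against `cbf`).
#' @param protocol An `asl_protocol` supplying LD and PLD.
#' @param kp A `kinetic_params` object.
#' @return Expected difference signal in the units of
#'   `equilibrium_magnetization`.
#' @examples
#' p <- protocol_preset("exp3")
#' kinetic_delta_m(60, 1000, p, kinetic_params())
#' kinetic_delta_m(20, 1600, p, kinetic_params())  # typical WM voxel
#' @export
kinetic_delta_m <- function(cbf, transit_time, protocol, kp) {
  stopifnot(inherits(protocol, "asl_protocol"), inherits(kp, "kinetic_params"))
  if (any(!is.finite(cbf)) || any(!is.finite(transit_time)))
    stop("'cbf' and 'transit_time' must be finite", call. = FALSE)
  if (any(cbf < 0)) stop("'cbf' must be nonnegative", call. = FALSE)
  if (any(transit_time < 0))
    stop("'transit_time' must be nonnegative", call. = FALSE)
  n <- max(length(cbf), length(transit_time))
  cbf <- rep_len(cbf, n)
  delta <- rep_len(transit_time, n)

  tau <- protocol$label_duration
  t <- protocol$label_duration + protocol$post_label_delay
  t1b <- kp$t1_blood
  eps <- kp$labeling_efficiency * kp$bs_efficiency
  scale <- 2 * eps * kp$equilibrium_magnetization * (cbf /
    kp$blood_brain_partition) * (t1b / 60000) * exp(-delta / t1b)

  dm <- numeric(n)
  during <- t > delta & t <= delta + tau
  after <- t > delta + tau
  dm[during] <- scale[during] * (1 - exp(-(t - delta[during]) / t1b))
  dm[after] <- scale[after] * (1 - exp(-tau / t1b)) *
    exp(-(t - delta[after] - tau) / t1b)
  dm
}
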