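#' Resistivity conversion parameters
#'
#' Constants of the intensity-to-resistivity law
#' `R(v) = K (1 - v)^E + D` (ohm cm): `K` sets the dynamic range between
#' water-free and water-saturated tissue, `E` the sharpness of the rise at
#' low water content, and `D` the floor reached by fully water-saturated
#' tissue (CSF-like, 65 ohm cm).
#'
#' @param K range constant (> 0), default 16000.
#' @param E exponent (> 0), default 4.
#' @param D offset (> 0), default 65.
#' @return a list of class `resistivity_params`.
#' @export
resistivity_params <- function(K = 16000, E = 4, D = 65) {
  if (!(K > 0 && E > 0 && D > 0)) stop("K, E, D must all be > 0")
  structure(list(K = K, E = E, D = D), class = "resistivity_params")
}

#' Combine T1/T2/PD channels into a normalized water-intensity volume
#'
#' Each channel is brought back to the water-fraction scale by inverting its
#' monotone forward map: PD and T2 gains are recovered from the channel
#' maximum (attained in CSF, water fraction 1), the T1 gain by least-squares
#' regression of T1 against `1 - v_pd` over head voxels. The three estimates
#' are averaged with the given weights and clamped to `[0, 1]`; background
#' (air) voxels are set to 0. With noiseless phantom triplets the result
#' equals the ground-truth water fraction to machine precision.
#'
#' @param triplet an [simulate_mri_triplet()] result (or any list with
#'   arrays `t1`, `t2`, `pd` on a shared grid).
#' @param weights channel weights `c(pd, t2, t1)`, renormalized to sum 1.
#' @param background_tau background threshold: voxels below this fraction
#'   of the recovered gain in both PD and T1 are treated as air (`v = 0`).
#' @return a double array `v` in `[0, 1]` of class `normalized_intensity`.
#' @export
combine_mri <- function(triplet, weights = c(pd = 0.5, t2 = 0.25,
                                             t1 = 0.25),
                        background_tau = 0.02) {
  d <- dim(triplet$pd)
  if (!identical(d, dim(triplet$t1)) || !identical(d, dim(triplet$t2)))
    stop("T1/T2/PD grids differ in shape")
  if (length(weights) != 3L || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be three non-negative values")
  wts <- weights / sum(weights)
  zero <- array(0, d)

  a_pd <- max(triplet$pd)
  v_pd <- if (a_pd > 0) triplet$pd / a_pd else zero
  a_t2 <- max(triplet$t2)
  v_t2 <- if (a_t2 > 0) (triplet$t2 / a_t2)^2 else zero
  a_t1m <- max(triplet$t1)
  # head support: water signal (PD) or bone-bright T1 separates tissue
  # from air, which is ~0 in all three channels
  headm <- v_pd > background_tau |
    (a_t1m > 0 & triplet$t1 / max(a_t1m, 1e-12) > background_tau)
  v_t1 <- zero
  if (a_t1m > 0 && any(headm)) {
    resid <- (1 - v_pd)[headm]
    denom <- sum(resid^2)
    a_t1 <- if (denom > 0) sum(triplet$t1[headm] * resid) / denom else a_t1m
    v_t1 <- 1 - triplet$t1 / a_t1
  }
  v <- wts[1] * v_pd + wts[2] * v_t2 + wts[3] * v_t1
  v[v < 0] <- 0
  v[v > 1] <- 1
  v[!headm] <- 0
  structure(v, class = "normalized_intensity")
}

#' Convert normalized intensity to resistivity
#'
#' Applies `R(v) = K (1 - v)^E + D` elementwise; `v = 1` (pure water)
#' gives `R = D`, `v = 0` gives `R = K + D`.
#'
#' @param v normalized intensity array (or scalar/vector) in `[0, 1]`.
#' @param params a [resistivity_params()].
#' @return resistivity in ohm cm, same shape as `v`, class
#'   `resistivity_volume` with the parameters attached.
#' @export
resistivity_from_intensity <- function(v, params = resistivity_params()) {
  stopifnot(inherits(params, "resistivity_params"))
  vv <- unclass(v)
  if (any(vv < 0 | vv > 1)) stop("normalized intensity outside [0, 1]")
  R <- params$K * (1 - vv)^params$E + params$D
  structure(R, class = "resistivity_volume", params = params)
}

#' Convert resistivity to conductivity and mask out air
#'
#' @param R resistivity array (ohm cm).
#' @param labels tissue label array; air voxels (`0`) are excluded from the
#'   conduction domain (`sigma = 0`, mask `FALSE`).
#' @return object of class `conductivity_volume`: list with `sigma`
#'   (S/cm array, 0 on air) and logical `mask` (TRUE on conducting voxels).
#' @export
conductivity_from_resistivity <- function(R, labels) {
  R <- unclass(R)
  if (!identical(dim(R), dim(labels)))
    stop("resistivity and label grids differ in shape")
  if (any(R <= 0)) stop("resistivity must be positive")
  sigma <- 1 / R
  mask <- labels != TISSUE_CODES[["air"]]
  sigma[!mask] <- 0
  structure(list(sigma = sigma, mask = mask), class = "conductivity_volume")
}

#' Phantom water fraction straight to conductivity
#'
#' Convenience chain used by the pipeline when the MRI simulation step is
#' bypassed: water fraction -> Eq. `R(v)` -> `1/R` with air masked.
#' @param phantom a `head_phantom`.
#' @param params a [resistivity_params()].
#' @return a `conductivity_volume`.
#' @export
phantom_conductivity <- function(phantom, params = resistivity_params()) {
  R <- resistivity_from_intensity(phantom$water, params)
  conductivity_from_resistivity(R, phantom$label)
}
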