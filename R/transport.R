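# Particle transport for the vial tally.  Electrons follow straight-line
# continuous-slowing-down (CSDA) tracks; photons are treated in the
# first-collision kerma approximation.  Both are deliberately simple: the
# vial is small compared to the photon mean free path and large compared
# to most electron ranges, so the neglected second-order physics (multiple
# scattering detours, in-vial photon scatter) moves the blood S-value by
# far less than its Monte Carlo uncertainty.

ELECTRON_CUTOFF_KEV <- 10
PHOTON_CUTOFF_KEV <- 10
TABLE_MAX_KEV <- 1000

#' Transport electrons through the vial
#'
#' Straight-line CSDA transport: an electron deposits, in each region, the
#' energy lost over its in-region path according to the water stopping
#' power (density-scaled for the polypropylene wall).  Electrons at or
#' below the 10 keV cutoff deposit locally.  Energy that survives past the
#' wall is counted as escaped (the air path is ignorable at these
#' energies).
#'
#' @param energy_keV vector of initial kinetic energies, keV.
#' @param points,directions emission points (in blood) and unit
#'   directions, as from [sample_emission_points()].
#' @param geom a [vial_geometry()].
#' @return data.frame with per-history `deposit_blood`, `deposit_wall`,
#'   `escaped` (keV); the three always sum to `energy_keV`.
#' @export
transport_electron <- function(energy_keV, points, directions, geom) {
  stopifnot(inherits(geom, "vial_geometry"))
  if (any(energy_keV > TABLE_MAX_KEV))
    stop("electron energy above stopping-power table range (1 MeV)")
  points <- rbind(points); directions <- rbind(directions)
  n <- length(energy_keV)
  dep_blood <- numeric(n); dep_wall <- numeric(n); escaped <- numeric(n)

  local <- energy_keV <= ELECTRON_CUTOFF_KEV
  dep_blood[local] <- energy_keV[local]
  if (all(local))
    return(data.frame(deposit_blood = dep_blood, deposit_wall = dep_wall,
                      escaped = escaped))

  idx <- which(!local)
  paths <- region_path_lengths(points[idx, , drop = FALSE],
                               directions[idx, , drop = FALSE], geom)
  rho_b <- geom$densities$blood
  rho_w <- geom$densities$wall
  e0 <- energy_keV[idx]
  r0 <- csda_range(e0)                       # g/cm^2
  mass_path_blood <- paths$blood * rho_b
  stops_in_blood <- r0 <= mass_path_blood
  # residual energy where the track crosses into the wall
  resid <- pmax(r0 - mass_path_blood, 0)
  e_at_wall <- ifelse(stops_in_blood, 0, electron_energy_at_range(resid))
  dep_blood[idx] <- e0 - e_at_wall
  mass_path_wall <- paths$wall * rho_w
  resid_wall <- pmax(resid - mass_path_wall, 0)
  e_after_wall <- ifelse(e_at_wall > 0 & resid_wall > 0,
                         electron_energy_at_range(resid_wall), 0)
  dep_wall[idx] <- e_at_wall - e_after_wall
  escaped[idx] <- e_after_wall
  data.frame(deposit_blood = dep_blood, deposit_wall = dep_wall,
             escaped = escaped)
}

#' Transport photons through the vial
#'
#' Samples the free path from exponential attenuation with the
#' material-specific total attenuation coefficients along the
#' blood/wall/air layers.  At the first collision the collision-kerma
#' fraction `muen/mu` of the photon energy is deposited locally; the
#' scattered remainder and uncollided photons are counted as escaped.
#' Photons at or below 10 keV deposit fully at the emission point.
#'
#' @inheritParams transport_electron
#' @return data.frame with per-history `deposit_blood`, `deposit_wall`,
#'   `deposit_air`, `escaped` (keV), summing to `energy_keV`.
#' @export
transport_photon <- function(energy_keV, points, directions, geom) {
  stopifnot(inherits(geom, "vial_geometry"))
  if (any(energy_keV > TABLE_MAX_KEV))
    stop("photon energy above attenuation table range (1 MeV)")
  points <- rbind(points); directions <- rbind(directions)
  n <- length(energy_keV)
  dep_blood <- numeric(n); dep_wall <- numeric(n)
  dep_air <- numeric(n); escaped <- numeric(n)

  local <- energy_keV <= PHOTON_CUTOFF_KEV
  dep_blood[local] <- energy_keV[local]
  idx <- which(!local)
  if (length(idx)) {
    e0 <- energy_keV[idx]
    paths <- region_path_lengths(points[idx, , drop = FALSE],
                                 directions[idx, , drop = FALSE], geom)
    cb <- photon_coefficients(e0, "water")
    cw <- photon_coefficients(e0, "polypropylene")
    ca <- photon_coefficients(e0, "air")
    tau_b <- cb$mu_rho * geom$densities$blood * paths$blood
    tau_w <- cw$mu_rho * geom$densities$wall * paths$wall
    tau_a <- ca$mu_rho * geom$densities$air * paths$air
    tau <- stats::rexp(length(idx))
    in_blood <- tau < tau_b
    in_wall <- !in_blood & tau < tau_b + tau_w
    in_air <- !in_blood & !in_wall & tau < tau_b + tau_w + tau_a
    kerma <- function(co) co$muen_rho / co$mu_rho
    dep_blood[idx[in_blood]] <- (e0 * kerma(cb))[in_blood]
    dep_wall[idx[in_wall]] <- (e0 * kerma(cw))[in_wall]
    dep_air[idx[in_air]] <- (e0 * kerma(ca))[in_air]
    escaped[idx] <- e0 - dep_blood[idx] - dep_wall[idx] - dep_air[idx]
  }
  data.frame(deposit_blood = dep_blood, deposit_wall = dep_wall,
             deposit_air = dep_air, escaped = escaped)
}
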