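# Vial geometry: a blood cylinder inside a polypropylene tube surrounded by
# air, modelled after the 5 ml round-bottom tube used for in-vitro blood
# irradiation (internal radius 0.48 cm, internal height 7.49 cm, 1 mm wall,
# 5 cm of air on every side).

#' Construct the irradiation-vial geometry
#'
#' The blood region is the cylinder `0 <= z <= inner_height_cm`,
#' `x^2 + y^2 <= inner_radius_cm^2`, filled with soft-tissue-equivalent
#' blood (density 1.0 g/cm^3), wrapped in a polypropylene wall (0.9
#' g/cm^3) and dry air (1.2e-3 g/cm^3).
#'
#' @param inner_radius_cm internal radius of the tube, cm.  The default
#'   0.48 cm makes the blood volume (about 5.4 ml) consistent with a 5 ml
#'   tube holding a 4.5 ml blood/activity mixture.
#' @param inner_height_cm internal height, cm.
#' @param wall_thickness_cm polypropylene wall and cap thickness, cm.
#' @param air_margin_cm thickness of the surrounding air shell, cm.
#' @param fill_volume_ml nominal liquid fill (3.5 ml blood + 1 ml activity
#'   solution); kept for dose/activity bookkeeping and sensitivity checks.
#' @param densities named list with `blood`, `wall`, `air` in g/cm^3.
#' @return object of class `vial_geometry`.
#' @export
vial_geometry <- function(inner_radius_cm = 0.48,
                          inner_height_cm = 7.49,
                          wall_thickness_cm = 0.10,
                          air_margin_cm = 5.0,
                          fill_volume_ml = 4.5,
                          densities = list(blood = 1.0, wall = 0.9,
                                           air = 1.2e-3)) {
  stopifnot(inner_radius_cm > 0, inner_height_cm > 0,
            wall_thickness_cm > 0, air_margin_cm > 0, fill_volume_ml > 0,
            densities$blood > 0, densities$wall > 0, densities$air > 0)
  blood_volume <- pi * inner_radius_cm^2 * inner_height_cm
  if (blood_volume < fill_volume_ml)
    stop(sprintf("blood cylinder volume %.3f ml smaller than fill volume %.3f ml",
                 blood_volume, fill_volume_ml))
  structure(list(inner_radius = inner_radius_cm,
                 inner_height = inner_height_cm,
                 wall_thickness = wall_thickness_cm,
                 air_margin = air_margin_cm,
                 fill_volume = fill_volume_ml,
                 blood_volume = blood_volume,
                 densities = densities),
            class = "vial_geometry")
}

#' @export
print.vial_geometry <- function(x, ...) {
  cat(sprintf("<vial_geometry>  r = %.3f cm, h = %.2f cm, wall %.2f cm, air %.1f cm\n",
              x$inner_radius, x$inner_height, x$wall_thickness, x$air_margin))
  cat(sprintf("  blood cylinder %.2f ml (nominal fill %.2f ml)\n",
              x$blood_volume, x$fill_volume))
  invisible(x)
}

#' Sample uniform emission points and isotropic directions
#'
#' Decays occur in a homogeneous blood/radionuclide mixture, so emission
#' points are uniform in the blood cylinder and directions isotropic.
#'
#' @param geom a [vial_geometry()].
#' @param n number of samples.
#' @return list with `points` (n x 3 matrix, cm) and `directions`
#'   (n x 3 unit vectors), drawn from the current RNG state.
#' @export
sample_emission_points <- function(geom, n) {
  stopifnot(inherits(geom, "vial_geometry"), n >= 1)
  r <- geom$inner_radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  z <- stats::runif(n, 0, geom$inner_height)
  cz <- stats::runif(n, -1, 1)           # isotropic: cos(theta) uniform
  ph <- stats::runif(n, 0, 2 * pi)
  sz <- sqrt(pmax(0, 1 - cz^2))
  list(points = cbind(x = r * cos(th), y = r * sin(th), z = z),
       directions = cbind(x = sz * cos(ph), y = sz * sin(ph), z = cz))
}

# distance from interior points to the surface of the cylinder
# r <= radius, z0 <= z <= z1, along unit directions; vectorised
cylinder_exit <- function(points, directions, radius, z0, z1) {
  x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  dx <- directions[, 1]; dy <- directions[, 2]; dz <- directions[, 3]
  t_cap <- ifelse(dz > 0, (z1 - z) / dz, ifelse(dz < 0, (z0 - z) / dz, Inf))
  a <- dx^2 + dy^2
  b <- x * dx + y * dy
  c0 <- x^2 + y^2 - radius^2
  disc <- pmax(b^2 - a * c0, 0)
  t_side <- ifelse(a > 0, (-b + sqrt(disc)) / a, Inf)
  dist <- pmin(t_cap, t_side)
  surface <- ifelse(t_side <= t_cap, "side",
                    ifelse(dz > 0, "cap_top", "cap_bottom"))
  list(distance = dist, surface = surface)
}

#' Distance from a point in blood to the blood-region boundary
#'
#' Ray/cylinder intersection: the smallest positive path length from
#' `points` along `directions` to the surface of the blood cylinder,
#' with a label for the surface crossed (side wall vs caps).
#'
#' @param points n x 3 matrix of positions inside the blood region, cm.
#' @param directions n x 3 matrix of unit direction vectors.
#' @param geom a [vial_geometry()].
#' @return data.frame with `distance` (cm) and `surface` (one of
#'   `"side"`, `"cap_top"`, `"cap_bottom"`).
#' @export
distance_to_boundary <- function(points, directions, geom) {
  stopifnot(inherits(geom, "vial_geometry"))
  points <- rbind(points); directions <- rbind(directions)
  eps <- 1e-12
  inside <- points[, 1]^2 + points[, 2]^2 <= geom$inner_radius^2 + eps &
    points[, 3] >= -eps & points[, 3] <= geom$inner_height + eps
  if (!all(inside)) stop("point outside the blood region")
  res <- cylinder_exit(points, directions, geom$inner_radius,
                       0, geom$inner_height)
  data.frame(distance = res$distance, surface = res$surface)
}

# geometric path lengths (cm) through blood, wall and air along each ray,
# used by the transport routines; nested coaxial cylinders are convex, so
# each ray crosses blood, then wall, then air, exactly once
region_path_lengths <- function(points, directions, geom) {
  d_blood <- cylinder_exit(points, directions, geom$inner_radius,
                           0, geom$inner_height)$distance
  tw <- geom$wall_thickness
  d_wall_out <- cylinder_exit(points, directions, geom$inner_radius + tw,
                              -tw, geom$inner_height + tw)$distance
  am <- geom$air_margin
  d_air_out <- cylinder_exit(points, directions,
                             geom$inner_radius + tw + am,
                             -tw - am, geom$inner_height + tw + am)$distance
  list(blood = d_blood,
       wall = pmax(d_wall_out - d_blood, 0),
       air = pmax(d_air_out - d_wall_out, 0))
}
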