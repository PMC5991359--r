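# Phantom-based density calibration and subchondral sampling.
#
# HU -> hydroxyapatite-equivalent density via the linear two-point phantom
# calibration
#     rho_HA = (CT_bone - CT_H2O) / (CT_HA - CT_H2O) * rho_phantom ,
# then apparent density and elastic modulus via the empirical power law
#     rho_app = rho_HA / 0.626 ,   E = 2017.3 * rho_app^2.46  [MPa].
# Subchondral bone is sampled along the inward surface normal to 5 mm depth,
# the approximate depth at which subchondral plate porosity increases in
# mature racehorses.

#' Calibration parameters estimated from a scan
#'
#' @param volume an `mc3_volume`
#' @param phantom_region region descriptor or "phantom" (default: the
#'   volume's descriptor)
#' @param water_region likewise for the water/background reference
#' @param rho_phantom nominal phantom density, mg cm^-3 HA
#' @return `mc3_calibration`: `ct_ha`, `ct_h2o` (mean HU over the regions),
#'   `rho_phantom`
#' @export
estimate_calibration <- function(volume, phantom_region = "phantom",
                                 water_region = "water",
                                 rho_phantom = volume$phantom_density) {
  mp <- region_mask(volume, phantom_region)
  mw <- region_mask(volume, water_region)
  if (!any(mp) || !any(mw)) stop("empty calibration region")
  ct_ha <- mean(volume$hu[mp])
  ct_h2o <- mean(volume$hu[mw])
  if (abs(ct_ha - ct_h2o) < 1e-9)
    stop("degenerate calibration: phantom and water mean HU are equal")
  if (rho_phantom <= 0) stop("rho_phantom must be positive")
  structure(list(ct_ha = ct_ha, ct_h2o = ct_h2o, rho_phantom = rho_phantom),
            class = "mc3_calibration")
}

#' @export
print.mc3_calibration <- function(x, ...) {
  cat(sprintf("mc3_calibration: CT_HA %.1f HU, CT_H2O %.1f HU, rho_phantom %g mg cm^-3\n",
              x$ct_ha, x$ct_h2o, x$rho_phantom))
  invisible(x)
}

#' Convert mean HU to hydroxyapatite-equivalent density
#'
#' Linear phantom calibration. Negative outputs (HU below water, e.g. fat
#' near the surface) are preserved, not clamped; exclusion is left to
#' reporting stages.
#'
#' @param mean_hu numeric vector of HU values
#' @param calib an `mc3_calibration`
#' @param units output units, `"g.cm3"` (default) or `"mg.cm3"`
#' @return density in the requested units
#' @export
hu_to_rho_ha <- function(mean_hu, calib, units = c("g.cm3", "mg.cm3")) {
  units <- match.arg(units)
  rho_mg <- (mean_hu - calib$ct_h2o) / (calib$ct_ha - calib$ct_h2o) *
    calib$rho_phantom
  if (units == "mg.cm3") rho_mg else rho_mg / 1000
}

#' Apparent density and elastic modulus from HA-equivalent density
#'
#' @param rho_ha HA-equivalent density, g cm^-3 (must be non-negative;
#'   callers clamp or exclude negative calibrated values first)
#' @return list with `rho_app` (g cm^-3) and `modulus` (MPa)
#' @export
rho_ha_to_modulus <- function(rho_ha) {
  if (any(rho_ha < 0)) stop("negative rho_ha; clamp or exclude before converting")
  rho_app <- rho_ha / 0.626
  list(rho_app = rho_app, modulus = 2017.3 * rho_app^2.46)
}

#' Mean subchondral HU along inward normals
#'
#' At every node the unit inward normal (from the parametric patch, with the
#' template's outward winding negated) is followed to `depth` mm; the volume
#' is sampled by trilinear interpolation at uniform steps including both
#' endpoints, and the arithmetic mean is assigned to the node. Nodes whose
#' ray leaves the volume are flagged and get NA.
#'
#' @param mesh a fitted `mc3_mesh` lying inside the volume
#' @param volume an `mc3_volume`
#' @param depth sampling depth, mm (default 5)
#' @param step sampling step, mm (default 0.25, below in-plane voxel size)
#' @return list with `mean_hu` (length n, NA where flagged) and `flagged`
#'   (logical)
#' @export
sample_subchondral <- function(mesh, volume, depth = 5, step = 0.25) {
  if (depth <= 0 || step <= 0) stop("depth and step must be positive")
  nrm <- node_normals(mesh)
  s <- seq(0, depth, by = step)
  if (abs(s[length(s)] - depth) > 1e-9) s <- c(s, depth)
  n <- nrow(mesh$nodes)
  acc <- matrix(0, n, length(s))
  for (j in seq_along(s))
    acc[, j] <- trilinear_sample(volume, mesh$nodes - s[j] * nrm)
  flagged <- apply(acc, 1, anyNA)
  if (any(flagged))
    message(sum(flagged), " node ray(s) left the volume; flagged and excluded")
  mean_hu <- rowMeans(acc)
  mean_hu[flagged] <- NA_real_
  list(mean_hu = mean_hu, flagged = flagged)
}

#' Per-node density field: HU, densities, modulus
#'
#' Runs [sample_subchondral()], applies the phantom calibration and the
#' density-modulus law. Negative calibrated densities are kept but flagged.
#'
#' @param mesh a fitted `mc3_mesh`
#' @param volume an `mc3_volume`
#' @param calib an `mc3_calibration` (default: estimated from the volume)
#' @param depth,step see [sample_subchondral()]
#' @return data.frame with one row per node: `node`, `x`, `y`, `z`,
#'   `mean_hu`, `rho_ha`, `rho_app`, `modulus`, `flagged`
#' @export
node_density_field <- function(mesh, volume,
                               calib = estimate_calibration(volume),
                               depth = 5, step = 0.25) {
  ss <- sample_subchondral(mesh, volume, depth, step)
  rho <- hu_to_rho_ha(ss$mean_hu, calib)
  neg <- !is.na(rho) & rho < 0
  rho_pos <- ifelse(is.na(rho) | neg, NA_real_, rho)
  mod <- rep(NA_real_, length(rho))
  ok <- !is.na(rho_pos)
  if (any(ok)) {
    m <- rho_ha_to_modulus(rho_pos[ok])
    mod[ok] <- m$modulus
  }
  data.frame(node = seq_len(nrow(mesh$nodes)),
             x = mesh$nodes[, 1], y = mesh$nodes[, 2], z = mesh$nodes[, 3],
             mean_hu = ss$mean_hu, rho_ha = rho,
             rho_app = rho / 0.626, modulus = mod,
             flagged = ss$flagged | neg)
}

#' Export a node density field as CSV (or PLY with a scalar channel)
#' @param field data.frame from [node_density_field()]
#' @param path output path
#' @export
write_density_csv <- function(field, path) {
  utils::write.csv(field, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_density_csv
#' @param mesh the mesh the field belongs to
#' @param channel column exported as the PLY scalar
#' @export
write_density_ply <- function(field, mesh, path, channel = "rho_app") {
  write_ply(mesh$nodes, path, scalar = field[[channel]])
  invisible(path)
}
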