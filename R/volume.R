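# Calibrated CT-like image volumes.
#
# An mc3_volume holds a 3-D array of Hounsfield units with voxel spacing and
# origin (world mm coordinates of the center of voxel [1,1,1]), plus
# descriptors for the calibration phantom cylinder and a water/background
# reference box. voxelize() rasterizes a synthetic specimen into such a
# volume so that the density-mapping stage can be validated by round trip.

#' Construct an image volume
#' @param hu 3-D numeric array of Hounsfield units
#' @param spacing voxel spacing, mm (length 3)
#' @param origin world position of the center of voxel `[1,1,1]`, mm
#' @param phantom_region phantom cylinder descriptor (list: `center` xy,
#'   `radius`, `zlim`)
#' @param water_region background box descriptor (list: `lo`, `hi` voxel
#'   index corners)
#' @param phantom_density nominal phantom density, mg cm^-3 HA
#' @return `mc3_volume`
#' @export
new_mc3_volume <- function(hu, spacing, origin, phantom_region = NULL,
                           water_region = NULL, phantom_density = 800) {
  structure(list(hu = hu, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 phantom_region = phantom_region,
                 water_region = water_region,
                 phantom_density = phantom_density),
            class = "mc3_volume")
}

#' @export
print.mc3_volume <- function(x, ...) {
  cat("mc3_volume:", paste(dim(x$hu), collapse = " x "),
      "voxels, spacing", paste(x$spacing, collapse = "/"), "mm\n")
  invisible(x)
}

#' Logical mask for a named region of a volume
#' @param volume an `mc3_volume`
#' @param region "phantom" or "water", or an explicit descriptor list
#' @return logical array matching the volume
#' @export
region_mask <- function(volume, region) {
  if (is.character(region))
    region <- switch(region, phantom = volume$phantom_region,
                     water = volume$water_region,
                     stop("unknown region '", region, "'"))
  if (is.null(region)) stop("region descriptor missing")
  dm <- dim(volume$hu)
  if (!is.null(region$radius)) {           # cylinder along z
    xs <- volume$origin[1] + (seq_len(dm[1]) - 1) * volume$spacing[1]
    ys <- volume$origin[2] + (seq_len(dm[2]) - 1) * volume$spacing[2]
    zs <- volume$origin[3] + (seq_len(dm[3]) - 1) * volume$spacing[3]
    inxy <- outer((xs - region$center[1])^2, (ys - region$center[2])^2, "+") <=
      region$radius^2
    inz <- zs >= region$zlim[1] & zs <= region$zlim[2]
    array(outer(inxy, inz, "&"), dm)
  } else {                                  # index box
    m <- array(FALSE, dm)
    m[region$lo[1]:region$hi[1], region$lo[2]:region$hi[2],
      region$lo[3]:region$hi[3]] <- TRUE
    m
  }
}

#' Trilinear interpolation of a volume at world points
#' @param volume an `mc3_volume`
#' @param pts m x 3 world coordinates (mm)
#' @return numeric vector (NA where the 8-voxel support leaves the volume)
#' @export
trilinear_sample <- function(volume, pts) {
  pts <- as.matrix(pts)
  dm <- dim(volume$hu)
  g <- sweep(sweep(pts, 2, volume$origin), 2, volume$spacing, "/") + 1
  i0 <- floor(g)
  f <- g - i0
  ok <- i0[, 1] >= 1 & i0[, 2] >= 1 & i0[, 3] >= 1 &
        i0[, 1] + 1 <= dm[1] & i0[, 2] + 1 <= dm[2] & i0[, 3] + 1 <= dm[3]
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]; f <- f[ok, , drop = FALSE]
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    acc <- acc + w * volume$hu[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  out[ok] <- acc
  out
}

# HU of a density (g cm^-3) under the linear phantom calibration model
density_to_hu <- function(rho_g, ct_ha, ct_h2o, phantom_density_mg) {
  ct_h2o + (1000 * rho_g / phantom_density_mg) * (ct_ha - ct_h2o)
}

#' Rasterize a synthetic specimen into a CT-like volume
#'
#' Bone voxels within an 8 mm subchondral shell take HU values consistent
#' with the specimen's node densities inverted through the linear phantom
#' calibration; deeper voxels take the baseline-density HU. A uniform
#' phantom cylinder and a water background complete the scene. The bone
#' boundary is rasterized with a one-voxel outward pad so that surface
#' samples interpolate pure bone HU (an idealization: no partial-volume
#' blur). Inside/outside is resolved by a star-shaped radial lookup from the
#' interior anchor over a dense direction-binned surface table.
#'
#' @param specimen an `mc3_specimen`
#' @param spec the synthetic spec (voxel spacing, phantom and HU parameters)
#' @param fov optional list(origin, dims): explicit field of view; an error
#'   is raised if the specimen does not fit
#' @param seed seed for optional HU noise
#' @return `mc3_volume`
#' @export
voxelize <- function(specimen, spec = default_synthetic_spec(), fov = NULL,
                     seed = NULL) {
  spec <- validate_synthetic_spec(spec)
  mesh <- mesh_from_specimen(specimen)
  dens <- specimen$node_density
  sp <- spec$voxel_spacing
  margin <- 7
  lo <- apply(mesh$nodes, 2, min) - margin
  hi <- apply(mesh$nodes, 2, max) + margin
  # phantom cylinder beside the bone (+x)
  ph_r <- 8
  ph_center <- c(hi[1] + 4 + ph_r, (lo[2] + hi[2]) / 2)
  ph_zlim <- c(lo[3] + 0.35 * (hi[3] - lo[3]), lo[3] + 0.65 * (hi[3] - lo[3]))
  hi[1] <- ph_center[1] + ph_r + 4
  if (!is.null(fov)) {
    if (any(lo < fov$origin - 1e-9) ||
        any(hi > fov$origin + (fov$dims - 1) * sp + 1e-9))
      stop("specimen (plus margins) extends outside the requested field of view")
    origin <- fov$origin; dims <- fov$dims
  } else {
    origin <- lo
    dims <- ceiling((hi - lo) / sp) + 1
  }
  ct_ha <- spec$ct_ha; ct_h2o <- spec$ct_h2o
  hu_of <- function(rho) density_to_hu(rho, ct_ha, ct_h2o, spec$phantom_density)

  # dense surface samples with density and normals
  gq <- 12L
  ds <- dense_surface_samples(mesh, grid = gq)
  B <- sparse_basis(mesh$topology, ds$patch, ds$u, ds$v)
  s_dens <- as.vector(B %*% dens)
  su <- eval_points(mesh, ds$patch, ds$u, ds$v, du = 1L)
  sv <- eval_points(mesh, ds$patch, ds$u, ds$v, dv = 1L)
  s_nrm <- cbind(su[, 2] * sv[, 3] - su[, 3] * sv[, 2],
                 su[, 3] * sv[, 1] - su[, 1] * sv[, 3],
                 su[, 1] * sv[, 2] - su[, 2] * sv[, 1])
  s_nrm <- s_nrm / pmax(sqrt(rowSums(s_nrm^2)), 1e-12)
  s_pts <- ds$points
  # proximal cut cap, padded 1 mm past the cut so boundary interpolation
  # stays inside bone
  topo <- mesh$topology
  ring <- node_id(N_ROWS, seq_len(N_THETA))
  ring_pts <- mesh$nodes[ring, ]
  ring_c <- colMeans(ring_pts)
  zdir <- specimen$rigid_pose$R %*% c(0, 0, 1)
  rr <- seq(0, 1, length.out = 12L)
  thg <- seq(0, 2 * pi, length.out = 49L)[-49L]
  cap <- do.call(rbind, lapply(rr, function(f)
    sweep(sweep(ring_pts[rep(seq_len(N_THETA), length.out = N_THETA), ,
                         drop = FALSE], 2, ring_c, "-") * f, 2, -ring_c)))
  cap <- sweep(cap, 2, -as.vector(zdir) * 1)  # pad 1 mm past the cut
  cap_n <- matrix(as.vector(zdir), nrow(cap), 3, byrow = TRUE)
  all_pts <- rbind(s_pts, cap)
  all_nrm <- rbind(s_nrm, cap_n)
  all_den <- c(s_dens, rep(spec$density_base, nrow(cap)))

  # star-shaped direction-binned surface table around the interior anchor
  anchor <- colMeans(mesh$nodes)
  dvec <- sweep(all_pts, 2, anchor)
  r <- sqrt(rowSums(dvec^2))
  az <- atan2(dvec[, 2], dvec[, 1])
  el <- asin(pmin(pmax(dvec[, 3] / pmax(r, 1e-12), -1), 1))
  n_az <- 180L; n_el <- 90L
  ia <- pmin(floor((az + pi) / (2 * pi) * n_az) + 1L, n_az)
  ie <- pmin(floor((el + pi / 2) / pi * n_el) + 1L, n_el)
  key <- (ie - 1L) * n_az + ia
  dir_u <- dvec / pmax(r, 1e-12)
  cosf <- pmax(abs(rowSums(all_nrm * dir_u)), 0.2)
  r_tab <- rho_tab <- cos_tab <- matrix(NA_real_, n_az, n_el)
  agg_max <- tapply(r, key, max)
  agg_rho <- tapply(all_den, key, mean)
  agg_cos <- tapply(cosf, key, mean)
  kk <- as.integer(names(agg_max))
  r_tab[kk] <- agg_max; rho_tab[kk] <- agg_rho; cos_tab[kk] <- agg_cos
  # fill empty bins by repeated neighbor averaging (az wraps)
  fill <- function(tab) {
    while (anyNA(tab)) {
      up <- tab[, c(1, seq_len(n_el - 1))]; dn <- tab[, c(2:n_el, n_el)]
      lf <- tab[c(n_az, seq_len(n_az - 1)), ]; rt <- tab[c(2:n_az, 1), ]
      est <- array(rowMeans(cbind(as.vector(up), as.vector(dn),
                                  as.vector(lf), as.vector(rt)),
                            na.rm = TRUE), dim(tab))
      tab[is.na(tab)] <- est[is.na(tab)]
    }
    tab
  }
  r_tab <- fill(r_tab); rho_tab <- fill(rho_tab); cos_tab <- fill(cos_tab)

  hu <- array(ct_h2o, dims)
  shell_d <- 8
  xs <- origin[1] + (seq_len(dims[1]) - 1) * sp[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * sp[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * sp[3]
  hu_core <- hu_of(spec$density_base)
  for (k in seq_len(dims[3])) {
    dx <- rep(xs - anchor[1], times = dims[2])
    dy <- rep(ys - anchor[2], each = dims[1])
    dz <- zs[k] - anchor[3]
    rv <- sqrt(dx^2 + dy^2 + dz^2)
    azv <- atan2(dy, dx)
    elv <- asin(pmin(pmax(dz / pmax(rv, 1e-12), -1), 1))
    iav <- pmin(floor((azv + pi) / (2 * pi) * n_az) + 1L, n_az)
    iev <- pmin(floor((elv + pi / 2) / pi * n_el) + 1L, n_el)
    kyv <- (iev - 1L) * n_az + iav
    depth <- (r_tab[kyv] - rv) * cos_tab[kyv]
    slab <- rep(ct_h2o, length(rv))
    in_shell <- depth >= -1 & depth <= shell_d
    slab[in_shell] <- hu_of(rho_tab[kyv[in_shell]])
    slab[depth > shell_d] <- hu_core
    hu[, , k] <- slab
  }
  # subchondral refinement: the radial table blurs the boundary where the
  # line of sight grazes the surface, so the shell around every node's
  # inward-normal ray is rasterized explicitly (tube of radius 1 mm, from
  # 1 mm outside to 8 mm inside) with the node's density
  nrm <- node_normals(mesh)
  tang1 <- cbind(-nrm[, 2], nrm[, 1], 0)          # n x ez
  tl <- sqrt(rowSums(tang1^2))
  bad <- which(tl < 1e-6)                          # normal ~ parallel to ez
  if (length(bad))
    tang1[bad, ] <- cbind(nrm[bad, 3], 0, -nrm[bad, 1])  # n x ey
  tang1 <- tang1 / sqrt(rowSums(tang1^2))
  tang2 <- cbind(nrm[, 2] * tang1[, 3] - nrm[, 3] * tang1[, 2],
                 nrm[, 3] * tang1[, 1] - nrm[, 1] * tang1[, 3],
                 nrm[, 1] * tang1[, 2] - nrm[, 2] * tang1[, 1])
  # full-support writes cover a 2-voxel cube per point, so a 0.5 mm paint
  # lattice still tiles the tube without holes
  og <- expand.grid(a = seq(-1, 1, by = 0.5), b = seq(-1, 1, by = 0.5))
  og <- og[og$a^2 + og$b^2 <= 1.3^2 + 1e-9, ]
  dsq <- seq(-1, shell_d, by = 0.5)
  n_nodes <- nrow(mesh$nodes)
  paint <- function(offsets) {
    for (j in seq_len(nrow(offsets))) {
      centers <- mesh$nodes + offsets$a[j] * tang1 + offsets$b[j] * tang2
      P <- centers[rep(seq_len(n_nodes), each = length(dsq)), ] -
        outer(rep(dsq, n_nodes), c(1, 1, 1)) *
        nrm[rep(seq_len(n_nodes), each = length(dsq)), ]
      # write the full 8-voxel trilinear support of every paint point:
      # rounding to one voxel aliases against the paint lattice and leaves
      # pinholes that trilinear sampling would read
      idx0 <- floor(sweep(sweep(P, 2, origin), 2, sp, "/")) + 1
      vals <- hu_of(dens[rep(seq_len(n_nodes), each = length(dsq))])
      for (dd in 0:7) {
        idx <- idx0 + rep(c(dd %% 2, dd %/% 2 %% 2, dd %/% 4), each = nrow(idx0))
        okv <- idx[, 1] >= 1 & idx[, 2] >= 1 & idx[, 3] >= 1 &
          idx[, 1] <= dims[1] & idx[, 2] <= dims[2] & idx[, 3] <= dims[3]
        hu[idx[okv, , drop = FALSE]] <<- vals[okv]
      }
    }
  }
  paint(og)
  # second pass: re-paint the narrow core of every ray so that where tubes
  # of adjacent nodes overlap (converging rays under crests and near the
  # pole) the ray still reads its own node's density; voxels claimed by
  # several cores (crossing rays) get the mean of the claimants
  core <- og[og$a^2 + og$b^2 <= 0.75^2 + 1e-9, ]
  nd <- length(dsq)
  rep_n <- rep(seq_len(n_nodes), each = nd)
  lin_all <- integer(0); val_all <- numeric(0)
  for (j in seq_len(nrow(core))) {
    centers <- mesh$nodes + core$a[j] * tang1 + core$b[j] * tang2
    P <- centers[rep_n, ] - outer(rep(dsq, n_nodes), c(1, 1, 1)) * nrm[rep_n, ]
    idx0 <- floor(sweep(sweep(P, 2, origin), 2, sp, "/")) + 1
    val0 <- hu_of(dens[rep_n])
    for (dd in 0:7) {
      idx <- idx0 + rep(c(dd %% 2, dd %/% 2 %% 2, dd %/% 4), each = nrow(idx0))
      okv <- idx[, 1] >= 1 & idx[, 2] >= 1 & idx[, 3] >= 1 &
        idx[, 1] <= dims[1] & idx[, 2] <= dims[2] & idx[, 3] <= dims[3]
      lin <- (idx[okv, 3] - 1L) * dims[1] * dims[2] +
        (idx[okv, 2] - 1L) * dims[1] + idx[okv, 1]
      # one claim per (voxel, node): keep the per-node duplicates out
      key <- as.numeric(lin) * n_nodes + rep_n[okv]
      dup <- duplicated(key)
      lin_all <- c(lin_all, lin[!dup]); val_all <- c(val_all, val0[okv][!dup])
    }
  }
  dupg <- duplicated(paste(lin_all, val_all))
  lin_all <- lin_all[!dupg]; val_all <- val_all[!dupg]
  agg <- rowsum(val_all, lin_all)
  cnt <- rowsum(rep(1, length(lin_all)), lin_all)
  hu[as.integer(rownames(agg))] <- agg / cnt
  # phantom cylinder (uniform CT_HA)
  inxy <- outer((xs - ph_center[1])^2, (ys - ph_center[2])^2, "+") <= ph_r^2
  kz <- which(zs >= ph_zlim[1] & zs <= ph_zlim[2])
  for (k in kz) hu[, , k][inxy] <- ct_ha
  if (spec$hu_noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    hu <- hu + array(rnorm(length(hu), 0, spec$hu_noise_sd), dim(hu))
  }
  wr <- list(lo = c(1L, 1L, 1L), hi = pmin(dims, 10L))
  new_mc3_volume(hu, sp, origin,
                 phantom_region = list(center = ph_center, radius = ph_r * 0.8,
                                       zlim = ph_zlim + c(2, -2)),
                 water_region = wr,
                 phantom_density = spec$phantom_density)
}

#' Write / read a volume as NIfTI-1 (plus a JSON sidecar for regions)
#'
#' @param volume an `mc3_volume`
#' @param path output path (`.nii` or `.nii.gz`); the sidecar is
#'   `paste0(path, ".json")`
#' @export
write_volume_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$hu, pixdim = volume$spacing)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(origin = volume$origin,
                            phantom_region = volume$phantom_region,
                            water_region = volume$water_region,
                            phantom_density = volume$phantom_density),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pr <- meta$phantom_region
  new_mc3_volume(array(as.numeric(img), dim(img)),
                 spacing = RNifti::pixdim(img)[1:3],
                 origin = as.numeric(meta$origin),
                 phantom_region = list(center = as.numeric(pr$center),
                                       radius = pr$radius,
                                       zlim = as.numeric(pr$zlim)),
                 water_region = lapply(meta$water_region, as.integer),
                 phantom_density = meta$phantom_density)
}

#' Write / read a volume as flat binary + JSON header (DICOM-free fallback)
#' @param volume an `mc3_volume`
#' @param path base path; writes `<path>.raw` and `<path>.json`
#' @export
write_volume_raw <- function(volume, path) {
  con <- file(paste0(path, ".raw"), "wb")
  writeBin(as.vector(volume$hu), con, size = 4L, endian = "little")
  close(con)
  jsonlite::write_json(list(dims = dim(volume$hu), spacing = volume$spacing,
                            origin = volume$origin,
                            phantom_region = volume$phantom_region,
                            water_region = volume$water_region,
                            phantom_density = volume$phantom_density),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume_raw
#' @export
read_volume_raw <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  con <- file(paste0(path, ".raw"), "rb")
  v <- readBin(con, "numeric", n = prod(dims), size = 4L, endian = "little")
  close(con)
  pr <- meta$phantom_region
  new_mc3_volume(array(v, dims), as.numeric(meta$spacing),
                 as.numeric(meta$origin),
                 phantom_region = list(center = as.numeric(pr$center),
                                       radius = pr$radius,
                                       zlim = as.numeric(pr$zlim)),
                 water_region = lapply(meta$water_region, as.integer),
                 phantom_density = meta$phantom_density)
}
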