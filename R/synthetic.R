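# Synthetic MC3-like populations with known latent structure.
#
# Specimens are drawn from a linear generative model on the template nodes:
#   coords_i  = base + sum_k w_ik * sigma_k * shape_field_k  + noise
#   density_i = base_density + sum_k w_ik * sigma_dk * density_loading_k + noise
# with standard-normal mode scores w_ik, unit-norm orthogonal fields, and
# sigma_k chosen so mode k contributes its variance_fraction of the total
# generative variance. A random rigid pose is applied before export, so the
# fitting and alignment stages are genuinely exercised. Ground truth (node
# coordinates, densities, scores, pose) is kept for validation only; the
# pipeline proper never reads it.

#' Default generative modes for the synthetic population
#'
#' Three latent modes emulating the dominant variation reported for distal
#' MC3 epiphyses: (1) overall size coupled to globally higher subchondral
#' density, (2) sagittal-ridge prominence coupled to dorso-proximal density,
#' (3) lateral/medial condyle asymmetry coupled to lower palmar condylar
#' density. Shape fields are unit-norm and orthogonalized in sequence, as are
#' density loadings, so variance bookkeeping is exact.
#'
#' @param base an `mc3_mesh` from [make_base_shape()]
#' @param variance_fractions per-mode fractions of total generative variance
#' @return list of modes, each with `variance_fraction`, `shape_field`
#'   (n x 3, unit Frobenius norm) and `density_loading` (length n, unit norm)
#' @export
default_generative_modes <- function(base,
                                     variance_fractions = c(0.50, 0.30, 0.15)) {
  topo <- base$topology
  th <- topo$node_theta; tt <- topo$node_t
  capw <- cap_weight(tt)
  n <- topo$n_nodes
  nrm <- node_normals(base)
  th0 <- ifelse(is.na(th), 0, th)

  # Shape fields are *surface-normal* offset fields (periosteal-apposition-
  # like growth) and spatially broad: tangential displacement cannot be
  # observed from surface data, and concentrating a large variance fraction
  # in a narrow bump would imply implausible multi-mm local spikes at 2 SD.
  w1 <- 0.6 + 0.4 * capw                      # overall size (epiphysis-weighted)
  d1 <- nrm * w1
  w2 <- (vm_bump(th0, pi / 2, 2) + 0.6 * vm_bump(th0, -pi / 2, 2)) * capw
  w2[is.na(th)] <- 0                          # sagittal ridge prominence
  d2 <- nrm * w2
  w3 <- cos(th0) * capw
  w3[is.na(th)] <- 0                          # lateral/medial asymmetry
  d3 <- nrm * w3

  u1 <- 0.2 + capw
  u2 <- vm_bump(th0, pi / 2, 3) * capw
  u2[is.na(th)] <- 0
  u3 <- -(vm_bump(th0, -pi / 4, 2) + vm_bump(th0, -3 * pi / 4, 2)) * capw
  u3[is.na(th)] <- 0

  # shape fields must be orthogonal to the rigid-motion subspace (3
  # translations + 3 infinitesimal rotations): any rigid component would be
  # removed again by the Procrustes alignment, distorting the variance
  # fractions the modes are supposed to carry
  cen <- colMeans(base$nodes)
  X0 <- sweep(base$nodes, 2, cen)
  rigid <- cbind(
    flatten_coords(matrix(rep(c(1, 0, 0), n), n, 3, byrow = TRUE)),
    flatten_coords(matrix(rep(c(0, 1, 0), n), n, 3, byrow = TRUE)),
    flatten_coords(matrix(rep(c(0, 0, 1), n), n, 3, byrow = TRUE)),
    flatten_coords(cbind(0, -X0[, 3], X0[, 2])),
    flatten_coords(cbind(X0[, 3], 0, -X0[, 1])),
    flatten_coords(cbind(-X0[, 2], X0[, 1], 0)))
  Q <- qr.Q(qr(rigid))
  orth <- function(fields, deflate = NULL) {
    out <- list()
    for (f in fields) {
      v <- as.vector(f)
      if (!is.null(deflate)) v <- v - deflate %*% crossprod(deflate, v)
      for (o in out) v <- v - sum(v * o) * o
      out[[length(out) + 1L]] <- as.vector(v) / sqrt(sum(v^2))
    }
    out
  }
  sf <- lapply(orth(list(flatten_coords(d1), flatten_coords(d2),
                         flatten_coords(d3)), deflate = Q),
               unflatten_coords)
  df <- orth(list(u1, u2, u3))
  lapply(seq_along(variance_fractions), function(k) {
    list(variance_fraction = variance_fractions[k],
         shape_field = matrix(sf[[k]], n, 3),
         density_loading = df[[k]])
  })
}

#' Default synthetic-population specification
#'
#' The packaged defaults describe a population of 40 specimens with three
#' latent modes (variance fractions 0.50/0.30/0.15), 1 mm per-coordinate
#' generative RMS shape variation, 0.08 g cm^-3 density variation around a
#' 0.7 g cm^-3 subchondral baseline, 0.15 mm segmentation jitter, poses
#' within +/-30 degrees and +/-20 mm, CT voxels of 0.3 x 0.3 x 0.6 mm and an
#' 800 mg cm^-3 hydroxyapatite phantom.
#'
#' @param n_specimens number of specimens
#' @param seed integer seed driving every random draw of the generator
#' @return a `SyntheticSpec`-style list, validated
#' @export
default_synthetic_spec <- function(n_specimens = 40L, seed = 20260101L) {
  spec <- list(
    n_specimens = as.integer(n_specimens),
    base_shape_params = default_shape_params(),
    variance_fractions = c(0.50, 0.30, 0.15),
    shape_rms_mm = 1.0,        # per-coordinate generative RMS over modes
    density_rms = 0.08,        # g cm^-3, generative RMS over modes
    point_noise_sd = 0.15,     # mm, isotropic segmentation jitter
    node_noise_sd = NULL,      # mm; NULL = absorb the unassigned variance
                               # fraction (shape_rms * sqrt(1 - sum(vf)))
    density_base = 0.7,        # g cm^-3 HA-equivalent baseline
    density_noise_sd = NULL,   # g cm^-3; NULL as above
    cloud_density = 0.25,      # points per mm^2
    voxel_spacing = c(0.3, 0.3, 0.6),  # mm
    phantom_density = 800,     # mg cm^-3 HA
    ct_ha = 1600,              # HU of the phantom insert
    ct_h2o = 0,                # HU of water/background
    hu_noise_sd = 0,           # HU
    pose_rot_deg = 30,
    pose_trans_mm = 20,
    seed = as.integer(seed)
  )
  validate_synthetic_spec(spec)
}

#' @rdname default_synthetic_spec
#' @param spec candidate specification list
#' @export
validate_synthetic_spec <- function(spec) {
  if (spec$n_specimens < 2L) stop("n_specimens must be >= 2")
  validate_shape_params(spec$base_shape_params)
  vf <- spec$variance_fractions
  if (any(vf <= 0) || any(vf > 1) || sum(vf) > 1 + 1e-12)
    stop("variance fractions must lie in (0,1] and sum to <= 1")
  if (any(spec$voxel_spacing <= 0)) stop("voxel spacing must be positive")
  for (nm in c("shape_rms_mm", "density_rms", "density_base"))
    if (spec[[nm]] < 0) stop(nm, " must be non-negative")
  # unassigned variance defaults into iid node noise so the variance budget
  # is complete and mode fractions are fractions of the total
  if (is.null(spec$node_noise_sd))
    spec$node_noise_sd <- spec$shape_rms_mm * sqrt(max(1 - sum(vf), 0))
  if (is.null(spec$density_noise_sd))
    spec$density_noise_sd <- spec$density_rms * sqrt(max(1 - sum(vf), 0))
  invisible(spec)
}

#' Draw a synthetic population of ground-truth specimens
#'
#' @param spec a specification from [default_synthetic_spec()]
#' @return `mc3_population`: list of specimens, each carrying posed and
#'   unposed node coordinates, node densities, mode scores and the rigid
#'   pose; the base mesh, modes, and spec are attached
#' @export
sample_population <- function(spec = default_synthetic_spec()) {
  spec <- validate_synthetic_spec(spec)
  base <- make_base_shape(spec$base_shape_params)
  modes <- default_generative_modes(base, spec$variance_fractions)
  topo <- base$topology
  n <- topo$n_nodes
  nm <- length(modes)
  # sigma_k so that mode k contributes variance_fraction_k of the total
  # generative variance (fields are unit-norm)
  tot_shape <- spec$shape_rms_mm^2 * 3 * n
  tot_dens <- spec$density_rms^2 * n
  sig_s <- sqrt(vapply(modes, `[[`, 0, "variance_fraction") * tot_shape)
  sig_d <- sqrt(vapply(modes, `[[`, 0, "variance_fraction") * tot_dens)

  set.seed(spec$seed)
  N <- spec$n_specimens
  scores <- matrix(rnorm(N * nm), N, nm)
  specimens <- vector("list", N)
  for (i in seq_len(N)) {
    coords <- base$nodes
    dens <- rep(spec$density_base, n)
    for (k in seq_len(nm)) {
      coords <- coords + scores[i, k] * sig_s[k] * modes[[k]]$shape_field
      dens <- dens + scores[i, k] * sig_d[k] * modes[[k]]$density_loading
    }
    coords <- coords + matrix(rnorm(3 * n, 0, spec$node_noise_sd), n, 3)
    dens <- pmax(dens + rnorm(n, 0, spec$density_noise_sd), 0)
    ang <- runif(3, -spec$pose_rot_deg, spec$pose_rot_deg) * pi / 180
    R <- euler_rotation(ang[1], ang[2], ang[3])
    tr <- runif(3, -spec$pose_trans_mm, spec$pose_trans_mm)
    specimens[[i]] <- structure(
      list(id = i,
           node_coords = apply_rigid(coords, R, tr),
           node_coords_local = coords,
           node_density = dens,
           mode_scores = scores[i, ],
           rigid_pose = list(R = R, t = tr),
           point_noise_sd = spec$point_noise_sd),
      class = "mc3_specimen")
  }
  structure(list(specimens = specimens, base = base, modes = modes,
                 spec = spec),
            class = "mc3_population")
}

#' @export
print.mc3_population <- function(x, ...) {
  cat("mc3_population:", length(x$specimens), "specimens,",
      length(x$modes), "generative modes (seed", x$spec$seed, ")\n")
  invisible(x)
}

#' Mesh view of a ground-truth specimen
#'
#' @param specimen an `mc3_specimen`
#' @param posed use the exported (posed) coordinates or the unposed frame?
#' @return `mc3_mesh` with node densities attached
#' @export
mesh_from_specimen <- function(specimen, posed = TRUE) {
  new_mc3_mesh(if (posed) specimen$node_coords else specimen$node_coords_local,
               densities = specimen$node_density)
}

#' Export a segmented-surface-like point cloud from a specimen
#'
#' Points are drawn per patch with Poisson counts proportional to patch area,
#' placed uniformly in the patch chart and jittered with isotropic Gaussian
#' noise. No correspondence information is exported.
#'
#' @param specimen an `mc3_specimen` (or any `mc3_mesh`)
#' @param density target points per mm^2 of surface
#' @param point_noise_sd mm; defaults to the specimen's generating value
#' @param seed integer seed
#' @return m x 3 matrix of points (mm)
#' @export
export_point_cloud <- function(specimen, density = 0.25,
                               point_noise_sd = NULL, seed = 1L) {
  if (density <= 0) stop("density must be positive")
  mesh <- if (inherits(specimen, "mc3_mesh")) specimen
          else mesh_from_specimen(specimen)
  if (is.null(point_noise_sd))
    point_noise_sd <- if (!is.null(specimen$point_noise_sd))
      specimen$point_noise_sd else 0
  topo <- mesh$topology
  np <- nrow(topo$patches)
  areas <- vapply(seq_len(np), function(p) patch_area(mesh, p), 0)
  set.seed(seed)
  counts <- stats::rpois(np, density * areas)
  patch <- rep(seq_len(np), counts)
  m <- length(patch)
  pts <- eval_points(mesh, patch, runif(m), runif(m))
  if (point_noise_sd > 0)
    pts <- pts + matrix(rnorm(3 * m, 0, point_noise_sd), m, 3)
  pts
}

#' Write / read point clouds as CSV (x,y,z in mm)
#' @param pts m x 3 matrix
#' @param path file path
#' @export
write_cloud_csv <- function(pts, path) {
  df <- as.data.frame(as.matrix(pts))
  names(df) <- c("x", "y", "z")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cloud_csv
#' @export
read_cloud_csv <- function(path) {
  as.matrix(utils::read.csv(path)[, c("x", "y", "z")])
}

#' Ground-truth sidecar archive for one specimen (testing only)
#'
#' @param specimen an `mc3_specimen`
#' @param path file path (JSON)
#' @export
write_specimen_json <- function(specimen, path) {
  jsonlite::write_json(
    list(format = "mc3ssm-specimen", version = 1L, id = specimen$id,
         node_coords = specimen$node_coords,
         node_coords_local = specimen$node_coords_local,
         node_density = specimen$node_density,
         mode_scores = specimen$mode_scores,
         rigid_pose = specimen$rigid_pose,
         point_noise_sd = specimen$point_noise_sd),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_specimen_json
#' @export
read_specimen_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "mc3ssm-specimen")) stop("not a specimen archive")
  structure(list(id = x$id,
                 node_coords = as.matrix(x$node_coords),
                 node_coords_local = as.matrix(x$node_coords_local),
                 node_density = as.numeric(x$node_density),
                 mode_scores = as.numeric(x$mode_scores),
                 rigid_pose = list(R = as.matrix(x$rigid_pose$R),
                                   t = as.numeric(x$rigid_pose$t)),
                 point_noise_sd = x$point_noise_sd),
            class = "mc3_specimen")
}

# ---- flattening between node matrices and model vectors --------------------

#' Flatten / unflatten node coordinate matrices
#'
#' Model vectors interleave coordinates per node (x1,y1,z1,x2,...), matching
#' the N x 3n training-matrix convention.
#' @param mat n x 3 node matrix
#' @return numeric vector of length 3n
#' @export
flatten_coords <- function(mat) as.vector(t(as.matrix(mat)))

#' @rdname flatten_coords
#' @param vec length-3n vector
#' @export
unflatten_coords <- function(vec) matrix(vec, ncol = 3, byrow = TRUE)

#' Population coordinate matrix (N x 3n)
#' @param population an `mc3_population` (or list of meshes/specimens)
#' @param posed use posed coordinates?
#' @return N x 3n matrix
#' @export
population_coord_matrix <- function(population, posed = FALSE) {
  sp <- if (inherits(population, "mc3_population")) population$specimens
        else population
  do.call(rbind, lapply(sp, function(s) {
    m <- if (inherits(s, "mc3_mesh")) s$nodes
         else if (posed) s$node_coords else s$node_coords_local
    flatten_coords(m)
  }))
}

#' Population density matrix (N x n)
#' @param population an `mc3_population`
#' @return N x n matrix of node densities
#' @export
population_density_matrix <- function(population) {
  do.call(rbind, lapply(population$specimens, function(s) s$node_density))
}
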