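# Template topology and the analytic MC3-like base surface.
#
# The template is a fixed quadrilateral-patch layout over a (theta, t)
# parameter chart: theta runs around the shaft axis (24 node columns, 8 cubic
# patches, periodic), t runs along a meridian from the distal pole (t = 0)
# to the proximal cut ring (t = 1; 15 node rows above the pole, 5 cubic
# patches).  Row 0 collapses to a single pole node, which closes the distal
# end; the proximal end stays open.  Every specimen in a study shares this
# topology, so node indices are corresponding points by construction.

N_THETA <- 24L   # node columns around the shaft (periodic)
N_ROWS  <- 15L   # node rows above the pole
N_PATCH_U <- 8L  # patches around
N_PATCH_V <- 5L  # patches along the meridian
T_CAP <- 0.6     # meridian fraction occupied by the distal cap

#' Node id for a (row, column) grid position
#'
#' Row 0 is the distal pole (a single shared node); rows 1..15 hold 24 nodes
#' each. Columns wrap periodically.
#' @param i_t meridian row index, 0..15
#' @param i_th angular column index (any integer; wrapped mod 24)
#' @return integer node id in 1..361
#' @keywords internal
node_id <- function(i_t, i_th) {
  n <- max(length(i_t), length(i_th))
  i_t <- rep_len(as.integer(i_t), n); i_th <- rep_len(as.integer(i_th), n)
  out <- 1L + (i_t - 1L) * N_THETA + ((i_th - 1L) %% N_THETA) + 1L
  out[i_t == 0L] <- 1L
  out
}

#' Template patch/topology description
#'
#' @return list with `n_nodes`, a `patches` integer matrix (one row per patch,
#'   16 node ids in v-major order: v-row 1 u-cols 1..4, then v-row 2, ...),
#'   patch parameter offsets, and per-node `(theta, t)` chart coordinates
#'   (theta is `NA` for the pole node).
#' @export
mc3_topology <- function() {
  n_nodes <- 1L + N_ROWS * N_THETA
  n_patch <- N_PATCH_U * N_PATCH_V
  patches <- matrix(0L, n_patch, 16L)
  pr_of <- integer(n_patch); pc_of <- integer(n_patch)
  p <- 0L
  for (pr in seq_len(N_PATCH_V)) {
    for (pc in seq_len(N_PATCH_U)) {
      p <- p + 1L
      ids <- integer(16L)
      for (i in 1:4) {            # v (t) direction
        i_t <- 3L * (pr - 1L) + (i - 1L)
        for (j in 1:4) {          # u (theta) direction
          i_th <- 3L * (pc - 1L) + j
          ids[(i - 1L) * 4L + j] <- node_id(i_t, i_th)
        }
      }
      patches[p, ] <- ids
      pr_of[p] <- pr; pc_of[p] <- pc
    }
  }
  theta <- rep(NA_real_, n_nodes)
  tpar  <- numeric(n_nodes)
  for (i_t in seq_len(N_ROWS)) {
    for (i_th in seq_len(N_THETA)) {
      id <- node_id(i_t, i_th)
      theta[id] <- 2 * pi * (i_th - 1L) / N_THETA
      tpar[id]  <- i_t / N_ROWS
    }
  }
  tpar[1L] <- 0
  list(n_nodes = n_nodes, patches = patches,
       patch_row = pr_of, patch_col = pc_of,
       theta0 = 2 * pi * 3 * (pc_of - 1L) / N_THETA,
       dtheta = 2 * pi * 3 / N_THETA,
       t0 = 3 * (pr_of - 1L) / N_ROWS,
       dt = 3 / N_ROWS,
       node_theta = theta, node_t = tpar)
}

# ---- cubic Lagrange basis on [0,1], nodes at 0, 1/3, 2/3, 1 -----------------

#' Cubic Lagrange basis values
#' @param u numeric vector in `[0,1]`
#' @return length(u) x 4 matrix of basis values
#' @keywords internal
lag3 <- function(u) {
  cbind(-4.5 * (u - 1/3) * (u - 2/3) * (u - 1),
        13.5 * u * (u - 2/3) * (u - 1),
        -13.5 * u * (u - 1/3) * (u - 1),
        4.5 * u * (u - 1/3) * (u - 2/3))
}

#' @rdname lag3
#' @keywords internal
dlag3 <- function(u) {
  cbind(-4.5 * ((u - 2/3) * (u - 1) + (u - 1/3) * (u - 1) + (u - 1/3) * (u - 2/3)),
        13.5 * ((u - 2/3) * (u - 1) + u * (u - 1) + u * (u - 2/3)),
        -13.5 * ((u - 1/3) * (u - 1) + u * (u - 1) + u * (u - 1/3)),
        4.5 * ((u - 1/3) * (u - 2/3) + u * (u - 2/3) + u * (u - 1/3)))
}

#' @rdname lag3
#' @keywords internal
d2lag3 <- function(u) {
  cbind(-4.5 * 2 * ((u - 1/3) + (u - 2/3) + (u - 1)),
        13.5 * 2 * (u + (u - 2/3) + (u - 1)),
        -13.5 * 2 * (u + (u - 1/3) + (u - 1)),
        4.5 * 2 * (u + (u - 1/3) + (u - 2/3)))
}

# ---- analytic base surface --------------------------------------------------

#' Default base-shape parameters (mm unless noted)
#'
#' An analytic loft of superelliptical cross-sections with two condylar lobes
#' and a raised central sagittal ridge flanked by parasagittal grooves. The
#' medial condyle and the dorsal ridge are slightly larger than their
#' counterparts by default, which breaks the mirror symmetries and makes the
#' principal axes of the shape sign-identifiable during pre-alignment.
#'
#' @return named list of parameters: `ml_halfwidth` (mm, medio-lateral
#'   superellipse half-width), `dp_halfwidth_dorsal`/`dp_halfwidth_palmar`
#'   (mm, dorsal and palmar half-depths of the egg-shaped cross-section),
#'   `se_exponent` (dimensionless roundedness), `condyle_radius_lat`,
#'   `condyle_radius_med`, `ridge_height`, `groove_depth` (mm bump
#'   amplitudes), `ridge_palmar_frac` (dimensionless palmar/dorsal ridge
#'   ratio), `epiphysis_length` (mm, distal-cap depth), `proximal_cutoff`
#'   (mm, axial length from the most distal point to the cut), and the
#'   dimensionless bump concentrations `kappa_condyle`, `kappa_ridge`.
#' @export
default_shape_params <- function() {
  list(ml_halfwidth = 28, dp_halfwidth_dorsal = 17, dp_halfwidth_palmar = 25,
       se_exponent = 2.5,
       condyle_radius_lat = 4.5, condyle_radius_med = 6,
       ridge_height = 3, ridge_palmar_frac = 0.6, groove_depth = 1.5,
       epiphysis_length = 26, proximal_cutoff = 45,
       kappa_condyle = 8, kappa_ridge = 20)
}

validate_shape_params <- function(p) {
  need <- c("ml_halfwidth", "dp_halfwidth_dorsal", "dp_halfwidth_palmar",
            "se_exponent",
            "condyle_radius_lat", "condyle_radius_med", "ridge_height",
            "ridge_palmar_frac", "groove_depth", "epiphysis_length",
            "proximal_cutoff", "kappa_condyle", "kappa_ridge")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing base-shape parameters: ", paste(miss, collapse = ", "))
  pos <- c("ml_halfwidth", "dp_halfwidth_dorsal", "dp_halfwidth_palmar",
           "se_exponent",
           "condyle_radius_lat", "condyle_radius_med", "ridge_height",
           "epiphysis_length", "proximal_cutoff")
  for (nm in pos) if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
    stop("base-shape parameter '", nm, "' must be positive")
  if (p$groove_depth < 0) stop("groove_depth must be >= 0")
  if (p$proximal_cutoff <= p$epiphysis_length)
    stop("proximal_cutoff must exceed epiphysis_length")
  invisible(p)
}

# von Mises-style angular bump, 1 at theta = mu
vm_bump <- function(theta, mu, kappa) exp(kappa * (cos(theta - mu) - 1))

#' In-plane radius of the base cross-section
#'
#' Superellipse radius plus the angular condyle/ridge/groove modulation scaled
#' by the meridian cap weight.
#' @param theta angle around the shaft axis (0 = lateral, pi/2 = dorsal)
#' @param t meridian coordinate in `[0,1]`
#' @param params base-shape parameters
#' @return radius in mm (same length as theta/t after recycling)
#' @export
base_radius <- function(theta, t, params = default_shape_params()) {
  p <- params
  # egg-shaped cross-section: palmar half deeper than dorsal, blended smoothly
  b <- p$dp_halfwidth_dorsal * (1 + sin(theta)) / 2 +
       p$dp_halfwidth_palmar * (1 - sin(theta)) / 2
  rse <- (abs(cos(theta))^p$se_exponent / p$ml_halfwidth^p$se_exponent +
          abs(sin(theta))^p$se_exponent / b^p$se_exponent)^(-1 / p$se_exponent)
  m <- p$condyle_radius_lat * vm_bump(theta, 0, p$kappa_condyle) +
       p$condyle_radius_med * vm_bump(theta, pi, p$kappa_condyle) +
       p$ridge_height * vm_bump(theta, pi / 2, p$kappa_ridge) +
       p$ridge_palmar_frac * p$ridge_height * vm_bump(theta, -pi / 2, p$kappa_ridge) -
       p$groove_depth * (vm_bump(theta, pi / 4, p$kappa_ridge) +
                         vm_bump(theta, 3 * pi / 4, p$kappa_ridge) +
                         vm_bump(theta, -pi / 4, p$kappa_ridge) +
                         vm_bump(theta, -3 * pi / 4, p$kappa_ridge))
  rse + cap_weight(t) * m
}

#' Meridian weighting of the condylar/ridge modulation
#'
#' 0 at the distal pole, rising to 1 at the cap/shaft junction (t = 0.6) and
#' decaying smoothly to 0 by t = 0.8 so the proximal shaft is a plain
#' superelliptical tube.
#' @param t meridian coordinate
#' @keywords internal
cap_weight <- function(t) {
  w <- numeric(length(t))
  cap <- t <= T_CAP
  w[cap] <- sin(pi / 2 * t[cap] / T_CAP)^2
  mid <- t > T_CAP & t <= 0.8
  w[mid] <- cos((t[mid] - T_CAP) / 0.2 * pi / 2)^2
  w
}

#' Evaluate the analytic base surface
#'
#' @param theta,t chart coordinates (vectors, recycled)
#' @param params base-shape parameters
#' @return matrix of xyz positions in mm; x is medio-lateral (+x lateral),
#'   y dorso-palmar (+y dorsal), z axial (+z proximal, most distal point at 0)
#' @export
base_surface_point <- function(theta, t, params = default_shape_params()) {
  n <- max(length(theta), length(t))
  theta <- rep_len(theta, n); t <- rep_len(t, n)
  R <- base_radius(theta, t, params)
  e <- params$epiphysis_length; L <- params$proximal_cutoff
  out <- matrix(0, n, 3)
  cap <- t <= T_CAP
  phi <- pi / 2 * t[cap] / T_CAP
  out[cap, 1] <- R[cap] * sin(phi) * cos(theta[cap])
  out[cap, 2] <- R[cap] * sin(phi) * sin(theta[cap])
  out[cap, 3] <- e * (1 - cos(phi))
  sh <- !cap
  out[sh, 1] <- R[sh] * cos(theta[sh])
  out[sh, 2] <- R[sh] * sin(theta[sh])
  out[sh, 3] <- e + (L - e) * (t[sh] - T_CAP) / (1 - T_CAP)
  out
}

# ---- landmark and region manifest ------------------------------------------

#' Landmark and region manifest of the packaged template
#'
#' Landmark node ids are fixed in the template topology (grid positions given
#' as meridian row, angular column at 15 degree steps). Regions give the node
#' and patch subsets used for regional BMD means and condylar areas. The
#' palmar/dorsal BMD node subsets are approximations of the anatomical regions
#' and are labelled as such.
#'
#' @return list with `landmarks` (named node ids), `rings` (named ordered node
#'   id vectors), `node_regions` and `patch_regions` (named id vectors)
#' @export
mc3_landmarks <- function() {
  lm <- c(
    distal_pole              = node_id(0L, 1L),
    lateral_edge             = node_id(9L, 1L),    # theta =   0, junction ring
    medial_edge              = node_id(9L, 13L),   # theta = 180
    lateral_groove_dorsal    = node_id(9L, 4L),    # theta =  45
    medial_groove_dorsal     = node_id(9L, 10L),   # theta = 135
    ridge_flank_lateral      = node_id(8L, 6L),    # theta =  75
    ridge_flank_medial       = node_id(8L, 8L),    # theta = 105
    sagittal_ridge_crest     = node_id(8L, 7L)     # theta =  90
  )
  metaphysis_ring <- node_id(N_ROWS, seq_len(N_THETA))
  rows_bmd <- 5:9
  dorsal_cols <- c(2:4, 10:12)    # 15..45 and 135..165 degrees
  palmar_cols <- c(14:16, 22:24)  # 195..225 and 315..345 degrees
  grid_ids <- function(rows, cols)
    as.integer(outer(rows, cols, function(r, c) node_id(r, c)))
  topo <- mc3_topology()
  patch_ids <- function(pr, pc) which(topo$patch_row %in% pr & topo$patch_col %in% pc)
  list(
    landmarks = lm,
    rings = list(metaphysis_ring = metaphysis_ring),
    node_regions = list(
      dorsal_condylar = grid_ids(rows_bmd, dorsal_cols),
      palmar_condylar = grid_ids(rows_bmd, palmar_cols)
    ),
    patch_regions = list(
      lateral_condyle = patch_ids(2:3, c(1L, 8L)),
      medial_condyle  = patch_ids(2:3, 4:5),
      all = seq_len(nrow(topo$patches))
    ),
    measurements = list(
      medio_lateral_width   = c("lateral_edge", "medial_edge"),
      lateral_condylar_width = c("lateral_edge", "lateral_groove_dorsal"),
      medial_condylar_width  = c("medial_edge", "medial_groove_dorsal"),
      sagittal_ridge_width   = c("ridge_flank_lateral", "ridge_flank_medial")
    )
  )
}

#' Build the ground-truth base mesh on the template topology
#'
#' Samples the analytic base surface at the template's node chart positions.
#' Deterministic for fixed parameters.
#'
#' @param params base-shape parameters (see [default_shape_params()])
#' @return an `mc3_mesh`: list with `nodes` (n x 3 mm), `topology`,
#'   `manifest`, `params`
#' @export
make_base_shape <- function(params = default_shape_params()) {
  validate_shape_params(params)
  topo <- mc3_topology()
  nodes <- matrix(0, topo$n_nodes, 3)
  nodes[1, ] <- base_surface_point(0, 0, params)  # pole
  for (i_t in seq_len(N_ROWS)) {
    ids <- node_id(i_t, seq_len(N_THETA))
    nodes[ids, ] <- base_surface_point(2 * pi * (seq_len(N_THETA) - 1L) / N_THETA,
                                       i_t / N_ROWS, params)
  }
  new_mc3_mesh(nodes, topo, mc3_landmarks(), params)
}
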