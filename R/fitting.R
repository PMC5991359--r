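# Registration of the template surface to a segmented point cloud:
#   1. similarity pre-alignment (centroid/scale + rigid ICP),
#   2. coarse host-mesh fit: the template is embedded in a tricubic Bernstein
#      free-form deformation lattice and the lattice control points are
#      optimized, which regularizes the deformation to smooth, global change;
#   3. fine fit: per-node least squares with a bending (second-derivative)
#      penalty on the displacement from the initial surface.
# Both fits alternate closest-point correspondence with a linear solve
# (Gauss-Newton / iterated closest point).

#' Least-squares rigid (optionally similarity) transform between point sets
#'
#' Closed-form orthogonal Procrustes (Kabsch/Umeyama): finds `R`, `t` (and
#' optionally scale `s`) minimizing `sum |s R a_i + t - b_i|^2` over proper
#' rotations.
#'
#' @param A,B m x 3 matrices of corresponding points
#' @param scale estimate an isotropic scale as well?
#' @return list with `R`, `t`, `s` and the residual RMS
#' @export
kabsch <- function(A, B, scale = FALSE) {
  A <- as.matrix(A); B <- as.matrix(B)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(A0, B0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- if (scale) sum(sv$d * diag(D)) / sum(A0^2) else 1
  t <- cb - s * as.vector(R %*% ca)
  fit <- sweep(s * A %*% t(R), 2, -t)
  list(R = R, t = t, s = s, rms = sqrt(mean(rowSums((fit - B)^2))))
}

#' Similarity pre-alignment of the template to a cloud
#'
#' Centroid + RMS-radius initialization followed by a few rounds of rigid+
#' scale ICP on a subsample of the cloud. Intended for poses within roughly
#' +/- 45 degrees of the template frame.
#'
#' @param template an `mc3_mesh`
#' @param cloud m x 3 point matrix
#' @param icp_rounds ICP iterations
#' @param subsample max cloud points used
#' @return list with the transform (`R`, `t`, `s`) and the transformed mesh
#' @export
prealign_template <- function(template, cloud, icp_rounds = 25L, subsample = 600L,
                              point_weight = 0.1) {
  cloud <- as.matrix(cloud)
  idx <- if (nrow(cloud) > subsample)
    round(seq(1, nrow(cloud), length.out = subsample)) else seq_len(nrow(cloud))
  sub <- cloud[idx, , drop = FALSE]
  X <- template$nodes
  ct <- colMeans(X); cc <- colMeans(sub)
  s0 <- sqrt(mean(rowSums(sweep(sub, 2, cc)^2)) /
             mean(rowSums(sweep(X, 2, ct)^2)))
  R <- diag(3); t <- cc - s0 * ct; s <- s0
  # a few closed-form point-to-point rounds to get into the basin
  for (i in 1:4) {
    cur <- new_mc3_mesh(sweep(s * X %*% t(R), 2, -t), template$topology,
                        template$manifest)
    cp <- closest_point(cur, sub, grid = c(32L, 9L), n_start = 2L, iters = 6L)
    foot_template <- sweep(cp$point, 2, t) %*% R / s
    k <- kabsch(foot_template, sub, scale = TRUE)
    R <- k$R; t <- k$t; s <- k$s
  }
  # linearized point-to-plane rigid + scale Gauss-Newton (fast tangential
  # convergence); a weak point-to-point term keeps the pose locked
  for (i in seq_len(icp_rounds)) {
    cur <- new_mc3_mesh(sweep(s * X %*% t(R), 2, -t), template$topology,
                        template$manifest)
    cp <- closest_point(cur, sub, grid = c(32L, 9L), n_start = 2L, iters = 6L)
    x <- cp$point
    nrm <- foot_normals(cur, cp)
    r <- rowSums(nrm * (x - sub))
    cxn <- cbind(x[, 2] * nrm[, 3] - x[, 3] * nrm[, 2],
                 x[, 3] * nrm[, 1] - x[, 1] * nrm[, 3],
                 x[, 1] * nrm[, 2] - x[, 2] * nrm[, 1])
    J <- cbind(cxn, nrm, rowSums(nrm * x))            # d r / d(omega, dt, ds)
    rp <- x - sub
    m <- nrow(x)
    # point-to-point rows, one per coordinate
    Z <- matrix(0, 3 * m, 7)
    Z[seq_len(m), 2] <-  x[, 3]; Z[seq_len(m), 3] <- -x[, 2]
    Z[m + seq_len(m), 1] <- -x[, 3]; Z[m + seq_len(m), 3] <- x[, 1]
    Z[2 * m + seq_len(m), 1] <- x[, 2]; Z[2 * m + seq_len(m), 2] <- -x[, 1]
    Z[seq_len(m), 4] <- 1; Z[m + seq_len(m), 5] <- 1; Z[2 * m + seq_len(m), 6] <- 1
    Z[, 7] <- as.vector(x)
    A <- crossprod(J) + point_weight * crossprod(Z)
    b <- -(crossprod(J, r) + point_weight * crossprod(Z, as.vector(rp)))
    delta <- tryCatch(solve(A, b), error = function(e) rep(0, 7))
    w <- delta[1:3]; dt <- delta[4:6]; dsc <- delta[7]
    ang <- sqrt(sum(w^2))
    Rw <- if (ang < 1e-12) diag(3) else {
      k_ <- w / ang
      K <- matrix(c(0, k_[3], -k_[2], -k_[3], 0, k_[1], k_[2], -k_[1], 0), 3, 3)
      diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    }
    sc <- exp(min(max(dsc, -0.2), 0.2))
    # compose the increment y -> sc * Rw y + dt with the current transform
    R <- Rw %*% R
    t <- sc * as.vector(Rw %*% t) + dt
    s <- sc * s
    if (ang < 1e-7 && sqrt(sum(dt^2)) < 1e-7 && abs(dsc) < 1e-9) break
  }
  nodes <- sweep(s * X %*% t(R), 2, -t)
  list(R = R, t = t, s = s,
       mesh = new_mc3_mesh(nodes, template$topology, template$manifest))
}

# ---- free-form deformation lattice -----------------------------------------

bernstein <- function(s, d) {
  k <- 0:d
  outer(s, k, function(x, kk) choose(d, kk) * x^kk * (1 - x)^(d - kk))
}

#' Build a Bernstein FFD lattice around a set of points
#'
#' @param pts points the lattice must enclose
#' @param shape control points per axis (default 4 x 4 x 4, tricubic)
#' @param margin fractional bounding-box margin
#' @return `mc3_lattice`: box, shape, identity control points
#' @export
make_host_lattice <- function(pts, shape = c(4L, 4L, 4L), margin = 0.15) {
  pts <- as.matrix(pts)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  pad <- margin * (hi - lo)
  lo <- lo - pad; hi <- hi + pad
  d <- shape - 1L
  grid <- expand.grid(i = 0:d[1], j = 0:d[2], k = 0:d[3])
  P0 <- cbind(lo[1] + grid$i / d[1] * (hi[1] - lo[1]),
              lo[2] + grid$j / d[2] * (hi[2] - lo[2]),
              lo[3] + grid$k / d[3] * (hi[3] - lo[3]))
  structure(list(lo = lo, hi = hi, shape = as.integer(shape), P0 = P0),
            class = "mc3_lattice")
}

#' Embedding matrix of points in an FFD lattice
#'
#' Rows map lattice control points to embedded point positions: `x = H P`.
#' The identity lattice (`P = P0`) reproduces the points exactly (Bernstein
#' linear precision).
#'
#' @param lattice an `mc3_lattice`
#' @param pts m x 3 points inside the lattice box
#' @return m x prod(shape) dense matrix
#' @export
lattice_embed <- function(lattice, pts) {
  pts <- as.matrix(pts)
  s <- sweep(sweep(pts, 2, lattice$lo), 2, lattice$hi - lattice$lo, "/")
  if (any(s < -1e-9 | s > 1 + 1e-9))
    stop("points outside the lattice box")
  s <- pmin(pmax(s, 0), 1)
  d <- lattice$shape - 1L
  Bx <- bernstein(s[, 1], d[1]); By <- bernstein(s[, 2], d[2]); Bz <- bernstein(s[, 3], d[3])
  H <- matrix(0, nrow(pts), prod(lattice$shape))
  col <- 0L
  for (k in seq_len(lattice$shape[3])) for (j in seq_len(lattice$shape[2]))
    for (i in seq_len(lattice$shape[1])) {
      col <- col + 1L
      H[, col] <- Bx[, i] * By[, j] * Bz[, k]
    }
  H
}

# unit surface normals at closest-point footpoints
foot_normals <- function(mesh, cp) {
  su <- eval_points(mesh, cp$patch, cp$u, cp$v, du = 1L)
  sv <- eval_points(mesh, cp$patch, cp$u, cp$v, dv = 1L)
  nrm <- cbind(su[, 2] * sv[, 3] - su[, 3] * sv[, 2],
               su[, 3] * sv[, 1] - su[, 1] * sv[, 3],
               su[, 1] * sv[, 2] - su[, 2] * sv[, 1])
  nrm / pmax(sqrt(rowSums(nrm^2)), 1e-12)
}

# second-difference smoothness operator on the control grid (zero on affine
# deformations, so rigid/affine motion is never penalized)
lattice_smoother <- function(lattice) {
  sh <- lattice$shape
  idx <- array(seq_len(prod(sh)), dim = sh)
  ri <- integer(0); ci <- integer(0); xv <- numeric(0); row <- 0L
  add <- function(cols, vals) {
    row <<- row + 1L
    ri <<- c(ri, rep(row, length(cols))); ci <<- c(ci, cols); xv <<- c(xv, vals)
  }
  for (k in seq_len(sh[3])) for (j in seq_len(sh[2])) for (i in seq_len(sh[1])) {
    # pure second differences
    if (i > 1 && i < sh[1])
      add(c(idx[i - 1, j, k], idx[i, j, k], idx[i + 1, j, k]), c(1, -2, 1))
    if (j > 1 && j < sh[2])
      add(c(idx[i, j - 1, k], idx[i, j, k], idx[i, j + 1, k]), c(1, -2, 1))
    if (k > 1 && k < sh[3])
      add(c(idx[i, j, k - 1], idx[i, j, k], idx[i, j, k + 1]), c(1, -2, 1))
    # mixed second differences (penalize twist/shear gradients, which are
    # invisible to the single-axis terms); weight sqrt(2) per thin-plate form
    w <- sqrt(2)
    if (i < sh[1] && j < sh[2])
      add(c(idx[i, j, k], idx[i + 1, j, k], idx[i, j + 1, k], idx[i + 1, j + 1, k]),
          w * c(1, -1, -1, 1))
    if (i < sh[1] && k < sh[3])
      add(c(idx[i, j, k], idx[i + 1, j, k], idx[i, j, k + 1], idx[i + 1, j, k + 1]),
          w * c(1, -1, -1, 1))
    if (j < sh[2] && k < sh[3])
      add(c(idx[i, j, k], idx[i, j + 1, k], idx[i, j, k + 1], idx[i, j + 1, k + 1]),
          w * c(1, -1, -1, 1))
  }
  Matrix::sparseMatrix(i = ri, j = ci, x = xv,
                       dims = c(row, prod(lattice$shape)))
}

#' Coarse host-mesh (free-form deformation) fit of the template to a cloud
#'
#' The template nodes are embedded in a Bernstein lattice; iterated closest
#' point alternates cloud-to-surface correspondence with a linear solve for
#' the lattice control points under a second-difference smoothness penalty
#' (affine deformations are unpenalized). The similarity pre-alignment is
#' applied first unless the template is already posed.
#'
#' @param template an `mc3_mesh` (the packaged template)
#' @param cloud m x 3 segmented surface points (mm)
#' @param lattice_shape control points per axis
#' @param regularization_weight smoothness penalty weight
#' @param max_iter,tol iteration cap and the minimum RMS improvement (mm)
#'   counted as progress; iteration stops after 5 iterations without it
#' @param prealign run the similarity pre-alignment first?
#' @param point_weight weight of the point-to-point term relative to the
#'   point-to-plane term
#' @param subsample cloud points used during optimization (the reported RMS
#'   is always over the full cloud)
#' @return `mc3_fit`: `mesh` (fitted `mc3_mesh`), `rms` (mm, cloud to
#'   surface), `iterations`, `converged`, and the pre-alignment transform
#' @export
host_mesh_fit <- function(template, cloud, lattice_shape = c(6L, 6L, 6L),
                          regularization_weight = 3e-6, max_iter = 50L,
                          tol = 1e-3, prealign = TRUE, point_weight = 0.1,
                          subsample = 800L) {
  cloud <- as.matrix(cloud)
  if (nrow(cloud) == 0) stop("empty cloud")
  full_cloud <- cloud
  if (nrow(cloud) > subsample)
    cloud <- cloud[round(seq(1, nrow(cloud), length.out = subsample)), ,
                   drop = FALSE]
  pre <- NULL
  mesh0 <- template
  if (prealign) {
    pre <- prealign_template(template, cloud)
    mesh0 <- pre$mesh
  }
  lattice <- make_host_lattice(mesh0$nodes, lattice_shape)
  H <- lattice_embed(lattice, mesh0$nodes)
  DtD <- as.matrix(Matrix::crossprod(lattice_smoother(lattice)))
  P <- lattice$P0
  nc <- nrow(P)
  best <- list(rms = Inf, nodes = mesh0$nodes, iter = 0L)
  patience <- 5L
  converged <- FALSE; it <- 0L
  topo <- template$topology
  mm <- nrow(cloud)
  while (it < max_iter) {
    it <- it + 1L
    nodes <- H %*% P
    cur <- new_mc3_mesh(nodes, topo, template$manifest)
    cp <- closest_point(cur, cloud, grid = c(48L, 13L), n_start = 2L, iters = 8L)
    rms <- sqrt(mean(cp$distance^2))
    if (rms < best$rms - tol) best <- list(rms = rms, nodes = nodes, iter = it)
    else if (rms < best$rms) best[c("rms", "nodes")] <- list(rms, nodes)
    if (it - best$iter >= patience) { converged <- TRUE; break }
    # combined point-to-plane + point-to-point Gauss-Newton step for the
    # lattice control points (plane term removes tangential ICP lag)
    B <- sparse_basis(topo, cp$patch, cp$u, cp$v)
    M <- as.matrix(B %*% H)
    nrm <- foot_normals(cur, cp)
    d <- rowSums(nrm * cloud)
    MtM <- crossprod(M)
    A <- matrix(0, 3L * nc, 3L * nc); b <- numeric(3L * nc)
    for (c1 in 1:3) {
      for (c2 in 1:3) {
        blk <- crossprod(M, nrm[, c1] * nrm[, c2] * M)
        if (c1 == c2)
          blk <- blk + point_weight * MtM + regularization_weight * mm * DtD
        A[(c1 - 1L) * nc + seq_len(nc), (c2 - 1L) * nc + seq_len(nc)] <- blk
      }
      b[(c1 - 1L) * nc + seq_len(nc)] <-
        crossprod(M, nrm[, c1] * d) + point_weight * crossprod(M, cloud[, c1])
    }
    Pv <- solve(A, b)
    P <- matrix(Pv, nc, 3)
  }
  mesh_out <- new_mc3_mesh(best$nodes, topo, template$manifest)
  rms_out <- if (nrow(full_cloud) > nrow(cloud))
    cloud_rms(mesh_out, full_cloud) else best$rms
  structure(list(mesh = mesh_out, rms = rms_out, iterations = it,
                 converged = converged, prealign = pre[c("R", "t", "s")]),
            class = "mc3_fit")
}

#' @export
print.mc3_fit <- function(x, ...) {
  cat(sprintf("mc3_fit: RMS %.4f mm after %d iterations (%s)\n",
              x$rms, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# bending (second parametric derivative) penalty matrix over nodes; computed
# once per topology with 4 x 4 Gauss quadrature per patch and normalized so
# smoothing weights are comparable across mesh sizes
bending_penalty <- local({
  cache <- NULL
  function(topology) {
    if (!is.null(cache)) return(cache)
    gq <- gauss4()
    uv <- expand.grid(u = gq$x, v = gq$x)
    wq <- as.vector(outer(gq$w, gq$w))
    np <- nrow(topology$patches)
    p <- rep(seq_len(np), each = nrow(uv))
    u <- rep(uv$u, np); v <- rep(uv$v, np)
    w <- rep(wq, np)
    Buu <- sparse_basis(topology, p, u, v, du = 2L)
    Buv <- sparse_basis(topology, p, u, v, du = 1L, dv = 1L)
    Bvv <- sparse_basis(topology, p, u, v, dv = 2L)
    W <- Matrix::Diagonal(x = w)
    K <- Matrix::crossprod(Buu, W %*% Buu) +
      2 * Matrix::crossprod(Buv, W %*% Buv) +
      Matrix::crossprod(Bvv, W %*% Bvv)
    K <- K / mean(Matrix::diag(K))
    cache <<- K
    K
  }
})

#' Fine per-node surface fit
#'
#' Iterated closest point with a per-node linear solve: squared cloud-point to
#' surface distances plus a Sobolev-type bending penalty on the displacement
#' from the initial surface (so an infinite smoothing weight returns the
#' initial nodes). The reported fit never has larger RMS than the initial
#' surface: the best iterate is kept.
#'
#' @param initial an `mc3_fit` or `mc3_mesh` giving the starting surface
#' @param cloud m x 3 point matrix
#' @param smoothing_weight bending penalty weight
#' @param max_iter,tol iteration cap and the minimum RMS improvement (mm)
#'   counted as progress; iteration stops after 4 iterations without it
#' @return `mc3_fit`
#' @export
fine_fit <- function(initial, cloud, smoothing_weight = 1e-3,
                     max_iter = 30L, tol = 1e-4, point_weight = 0.2) {
  mesh0 <- if (inherits(initial, "mc3_fit")) initial$mesh else initial
  cloud <- as.matrix(cloud)
  if (nrow(cloud) == 0) stop("empty cloud")
  topo <- mesh0$topology
  n <- topo$n_nodes
  K <- bending_penalty(topo)
  reg <- smoothing_weight * (K + 1e-3 * Matrix::Diagonal(n))
  X0 <- mesh0$nodes
  X <- X0
  best <- list(rms = Inf, nodes = X0, iter = 0L)
  patience <- 4L
  converged <- FALSE; it <- 0L
  mm <- nrow(cloud)
  while (it < max_iter) {
    it <- it + 1L
    cur <- new_mc3_mesh(X, topo, mesh0$manifest)
    cp <- closest_point(cur, cloud, grid = c(48L, 13L), n_start = 2L, iters = 8L)
    rms <- sqrt(mean(cp$distance^2))
    if (rms < best$rms - tol) best <- list(rms = rms, nodes = X, iter = it)
    else if (rms < best$rms) best[c("rms", "nodes")] <- list(rms, X)
    if (it - best$iter >= patience) { converged <- TRUE; break }
    # point-to-plane + anchored point-to-point step for the node positions,
    # with the bending penalty applied to the displacement from the initial
    # surface (penalty -> infinity returns the initial nodes)
    B <- sparse_basis(topo, cp$patch, cp$u, cp$v)
    nrm <- foot_normals(cur, cp)
    d <- rowSums(nrm * cloud)
    BtB <- Matrix::crossprod(B)
    blocks <- vector("list", 9L)
    bvec <- numeric(3L * n)
    for (c1 in 1:3) {
      for (c2 in 1:3) {
        blk <- Matrix::crossprod(B, nrm[, c1] * nrm[, c2] * B) / mm
        if (c1 == c2) blk <- blk + point_weight * BtB / mm + reg
        blocks[[(c1 - 1L) * 3L + c2]] <- blk
      }
      bvec[(c1 - 1L) * n + seq_len(n)] <-
        as.vector(Matrix::crossprod(B, nrm[, c1] * d) / mm +
                  point_weight * Matrix::crossprod(B, cloud[, c1]) / mm +
                  reg %*% X0[, c1])
    }
    A <- rbind(cbind(blocks[[1]], blocks[[2]], blocks[[3]]),
               cbind(blocks[[4]], blocks[[5]], blocks[[6]]),
               cbind(blocks[[7]], blocks[[8]], blocks[[9]]))
    X <- matrix(as.vector(Matrix::solve(A, bvec)), n, 3)
  }
  structure(list(mesh = new_mc3_mesh(best$nodes, topo, mesh0$manifest),
                 rms = best$rms, iterations = it, converged = converged,
                 prealign = if (inherits(initial, "mc3_fit")) initial$prealign),
            class = "mc3_fit")
}
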