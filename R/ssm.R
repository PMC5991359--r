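# Principal-component models of shape, density, and combined shape-density
# variation. Shapes enter as N x 3n matrices (x,y,z per node); the combined
# model uses N x 4n with the density channel interleaved per node (x,y,z,I)
# and per-variable standardization (correlation PCA), since the channels
# carry mixed units.

#' Interleave coordinate and density blocks into a combined training matrix
#'
#' @param coord_matrix N x 3n matrix (x,y,z per node)
#' @param density_matrix N x n matrix
#' @return N x 4n matrix with per-node (x,y,z,I) ordering
#' @export
build_combined_matrix <- function(coord_matrix, density_matrix) {
  N <- nrow(coord_matrix); n <- ncol(density_matrix)
  if (ncol(coord_matrix) != 3 * n || nrow(density_matrix) != N)
    stop("coordinate and density matrices do not match")
  out <- matrix(0, N, 4 * n)
  out[, combined_coord_idx(n)] <- coord_matrix
  out[, combined_density_idx(n)] <- density_matrix
  out
}

#' @rdname build_combined_matrix
#' @param n number of nodes
#' @export
combined_coord_idx <- function(n) {
  as.vector(vapply(seq_len(n), function(i) 4L * (i - 1L) + 1:3,
                   integer(3)))
}

#' @rdname build_combined_matrix
#' @export
combined_density_idx <- function(n) 4L * seq_len(n)

#' Train a principal-component model
#'
#' Mean-centers the training matrix (per-variable standardization for the
#' combined flavor: correlation-based PCA), decomposes it by economy SVD,
#' and retains the smallest number of components whose cumulative variance
#' reaches `variance_target`. Component signs follow a fixed convention:
#' positive inner product of the shape loading with the outward radial
#' directions of the mean shape (first nonzero entry positive when there is
#' no shape block).
#'
#' @param training_matrix N x p matrix (rows are specimens)
#' @param flavor "shape" (N x 3n, covariance PCA), "density" (N x n,
#'   covariance PCA), or "combined" (N x 4n, correlation PCA)
#' @param variance_target cumulative variance fraction retained
#' @return `mc3_ssm`: mean vector, orthonormal components (p x m), score
#'   standard deviations, variance fractions, standardization scales,
#'   `n_retained`
#' @export
ssm_train <- function(training_matrix, flavor = c("shape", "density", "combined"),
                      variance_target = 0.80) {
  flavor <- match.arg(flavor)
  X <- as.matrix(training_matrix)
  N <- nrow(X); p <- ncol(X)
  if (N < 2) stop("need at least two specimens to train a model")
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    node <- switch(flavor, shape = (bad[2] - 1L) %/% 3L + 1L,
                   density = bad[2], combined = (bad[2] - 1L) %/% 4L + 1L)
    stop("NaN in training matrix: specimen ", bad[1], ", variable ", bad[2],
         " (node ", node, ")")
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  scales <- rep(1, p)
  if (flavor == "combined") {
    s <- apply(Xc, 2, stats::sd)
    s[s < 1e-12 * max(s, 1e-300)] <- 1
    scales <- s
  }
  Z <- sweep(Xc, 2, scales, "/") / sqrt(N - 1)
  sv <- svd(Z, nu = 0)
  keep <- sv$d^2 > 1e-12 * sv$d[1]^2
  if (!any(keep)) keep[1] <- TRUE   # degenerate: identical specimens
  d <- sv$d[keep]; V <- sv$v[, keep, drop = FALSE]
  vf <- if (sum(d^2) > 0) d^2 / sum(d^2) else rep(1, length(d))
  # sign convention
  ref <- sign_reference(flavor, mu, p)
  for (j in seq_len(ncol(V))) {
    dt <- sum(V[, j] * ref)
    if (abs(dt) > 1e-12) {
      if (dt < 0) V[, j] <- -V[, j]
    } else {
      nz <- which(abs(V[, j]) > 1e-8)[1]
      if (!is.na(nz) && V[nz, j] < 0) V[, j] <- -V[, j]
    }
  }
  n_ret <- which(cumsum(vf) >= variance_target - 1e-12)[1]
  structure(list(flavor = flavor, mean = mu, components = V, sdev = d,
                 variance_fractions = vf, scales = scales,
                 n_retained = n_ret, n_train = N,
                 variance_target = variance_target),
            class = "mc3_ssm")
}

# outward-radial reference field of the mean shape in variable space
sign_reference <- function(flavor, mu, p) {
  if (flavor == "density") return(rep(0, p))
  n <- if (flavor == "shape") p / 3L else p / 4L
  nodes <- if (flavor == "shape") unflatten_coords(mu)
           else unflatten_coords(mu[combined_coord_idx(n)])
  dirs <- sweep(nodes, 2, colMeans(nodes))
  dirs <- dirs / pmax(sqrt(rowSums(dirs^2)), 1e-12)
  if (flavor == "shape") return(flatten_coords(dirs))
  out <- numeric(p)
  out[combined_coord_idx(n)] <- flatten_coords(dirs)
  out
}

#' @export
print.mc3_ssm <- function(x, ...) {
  cat(sprintf("mc3_ssm (%s): %d training specimens, %d retained of %d modes (%.0f%% variance)\n",
              x$flavor, x$n_train, x$n_retained, length(x$sdev),
              100 * x$variance_target))
  cat("  leading variance fractions:",
      paste(sprintf("%.3f", utils::head(x$variance_fractions, 5)), collapse = " "),
      "\n")
  invisible(x)
}

#' Reconstruct a specimen vector from mode weights
#'
#' Weights are in standard-deviation units: weight w on mode i displaces the
#' mean by `w * sdev_i` along the (scale-restored) component, matching the
#' usual "+/- 2 SD" usage.
#'
#' @param model an `mc3_ssm`
#' @param weights numeric vector, one weight per leading mode (at most
#'   `n_retained` unless `limit = FALSE`)
#' @param limit enforce the retained-mode limit?
#' @return specimen vector in original units
#' @export
ssm_reconstruct <- function(model, weights = numeric(0), limit = TRUE) {
  k <- length(weights)
  kmax <- if (limit) model$n_retained else length(model$sdev)
  if (k > kmax)
    stop("weight count (", k, ") exceeds available modes (", kmax, ")")
  x <- model$mean
  if (k > 0) {
    delta <- model$components[, seq_len(k), drop = FALSE] %*%
      (weights * model$sdev[seq_len(k)])
    x <- x + model$scales * as.vector(delta)
  }
  x
}

#' Project a specimen vector onto the leading modes
#'
#' Least-squares coefficients in the k-mode subspace after centering and
#' standardization; exact by orthonormality of the components.
#'
#' @param model an `mc3_ssm`
#' @param x specimen vector (original units)
#' @param k number of modes (default: all retained)
#' @return list with `weights` (SD units), `residual_rms` (original units,
#'   per variable) and `residual_norm` (standardized space)
#' @export
ssm_project <- function(model, x, k = model$n_retained) {
  if (length(x) != length(model$mean)) stop("vector length mismatch")
  if (k > length(model$sdev)) k <- length(model$sdev)
  z <- (x - model$mean) / model$scales
  V <- model$components[, seq_len(k), drop = FALSE]
  a <- as.vector(crossprod(V, z))
  w <- a / model$sdev[seq_len(k)]
  resid <- z - as.vector(V %*% a)
  xr <- model$mean + model$scales * as.vector(V %*% a)
  list(weights = w,
       residual_rms = sqrt(mean((x - xr)^2)),
       residual_norm = sqrt(sum(resid^2)))
}

# geometric (per-node Euclidean) RMS between two stacked coordinate vectors
geometric_rms <- function(x, y) {
  d <- unflatten_coords(x) - unflatten_coords(y)
  sqrt(mean(rowSums(d^2)))
}

#' Leave-one-out reconstruction analysis
#'
#' For every specimen: train on the remainder, project the held-out specimen
#' onto the leading k components for k = 0..max_components, and record the
#' geometric RMS (mm, per node) and density RMS (g cm^-3, original units).
#' Curves are averaged over specimens.
#'
#' @param coord_matrix N x 3n aligned coordinate matrix (NULL for
#'   density-only models)
#' @param density_matrix N x n density matrix (NULL for shape-only models)
#' @param flavor model flavor
#' @param max_components largest k evaluated (truncated with a warning to the
#'   LOO rank limit N - 2)
#' @return data.frame with columns `k`, `geometric_rms`, `density_rms` (NA
#'   where the flavor lacks the channel)
#' @export
loo_analysis <- function(coord_matrix = NULL, density_matrix = NULL,
                         flavor = c("shape", "density", "combined"),
                         max_components = 10L) {
  flavor <- match.arg(flavor)
  X <- switch(flavor,
              shape = as.matrix(coord_matrix),
              density = as.matrix(density_matrix),
              combined = build_combined_matrix(as.matrix(coord_matrix),
                                               as.matrix(density_matrix)))
  N <- nrow(X)
  if (N < 3) stop("leave-one-out needs at least 3 specimens")
  if (max_components >= N - 1) {
    warning("max_components >= N - 1; truncating to ", N - 2L)
    max_components <- N - 2L
  }
  n <- switch(flavor, shape = ncol(X) / 3L, density = ncol(X),
              combined = ncol(X) / 4L)
  geo <- matrix(NA_real_, N, max_components + 1L)
  den <- matrix(NA_real_, N, max_components + 1L)
  for (i in seq_len(N)) {
    mod <- ssm_train(X[-i, , drop = FALSE], flavor, variance_target = 1)
    z <- (X[i, ] - mod$mean) / mod$scales
    a_full <- as.vector(crossprod(mod$components, z))
    for (k in 0:max_components) {
      kk <- min(k, length(mod$sdev))
      a <- a_full
      if (kk < length(a)) a[(kk + 1):length(a)] <- 0
      xr <- mod$mean + mod$scales *
        as.vector(mod$components %*% a)
      if (flavor == "shape") {
        geo[i, k + 1L] <- geometric_rms(X[i, ], xr)
      } else if (flavor == "density") {
        den[i, k + 1L] <- sqrt(mean((X[i, ] - xr)^2))
      } else {
        ci <- combined_coord_idx(n); di <- combined_density_idx(n)
        geo[i, k + 1L] <- geometric_rms(X[i, ci], xr[ci])
        den[i, k + 1L] <- sqrt(mean((X[i, di] - xr[di])^2))
      }
    }
  }
  data.frame(k = 0:max_components,
             geometric_rms = colMeans(geo),
             density_rms = colMeans(den))
}

#' Variance table across model flavors
#'
#' One row per component and flavor with absolute and cumulative explained
#' variance (percent).
#'
#' @param ... named `mc3_ssm` models
#' @return data.frame with `flavor`, `component`, `variance_pct`,
#'   `cumulative_pct`
#' @export
variance_table <- function(...) {
  models <- list(...)
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- vapply(models, `[[`, "", "flavor")
  do.call(rbind, lapply(names(models), function(nm) {
    vf <- models[[nm]]$variance_fractions
    data.frame(flavor = nm, component = seq_along(vf),
               variance_pct = 100 * vf,
               cumulative_pct = 100 * cumsum(vf))
  }))
}

#' Write / read a trained model as a JSON archive
#' @param model an `mc3_ssm`
#' @param path file path
#' @export
write_ssm_json <- function(model, path) {
  jsonlite::write_json(
    list(format = "mc3ssm-model", version = 1L,
         flavor = model$flavor, mean = model$mean,
         components = model$components, sdev = model$sdev,
         variance_fractions = model$variance_fractions,
         scales = model$scales, n_retained = model$n_retained,
         n_train = model$n_train, variance_target = model$variance_target),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ssm_json
#' @export
read_ssm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "mc3ssm-model")) stop("not an mc3ssm model archive")
  structure(list(flavor = x$flavor, mean = as.numeric(x$mean),
                 components = as.matrix(x$components),
                 sdev = as.numeric(x$sdev),
                 variance_fractions = as.numeric(x$variance_fractions),
                 scales = as.numeric(x$scales),
                 n_retained = as.integer(x$n_retained),
                 n_train = as.integer(x$n_train),
                 variance_target = x$variance_target),
            class = "mc3_ssm")
}
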