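# Population correspondence: generalized Procrustes alignment (rigid, no
# scaling -- size must stay in the model) and the iterative loop that
# alternates shape-model training with model-constrained refitting until the
# population RMS stabilizes.

as_node_matrix <- function(x) {
  if (inherits(x, "mc3_fit")) x$mesh$nodes
  else if (inherits(x, "mc3_mesh")) x$nodes
  else as.matrix(x)
}

#' Generalized Procrustes alignment (rigid, no scaling)
#'
#' Iteratively aligns every mesh to the evolving mean by closed-form
#' orthogonal Procrustes (proper rotations only), until the mean stops moving.
#' Size is deliberately left in the data: overall scale is a real biological
#' mode and must reach the shape model.
#'
#' @param meshes list of `mc3_mesh`/`mc3_fit` objects or n x 3 matrices with
#'   identical topology
#' @param tol mean-movement convergence tolerance (mm)
#' @param max_iter iteration cap
#' @return `mc3_aligned`: aligned coordinate list and N x 3n matrix, the
#'   per-specimen rigid transforms, and the final mean matrix
#' @export
rigid_align <- function(meshes, tol = 1e-6, max_iter = 200L) {
  X <- lapply(meshes, as_node_matrix)
  if (length(X) < 2) stop("need at least two meshes to align")
  n <- nrow(X[[1]])
  for (x in X) if (nrow(x) != n || ncol(x) != 3)
    stop("topology mismatch: all meshes must share the node count")
  C <- X
  M <- Reduce(`+`, C) / length(C)
  for (it in seq_len(max_iter)) {
    for (i in seq_along(C)) {
      k <- kabsch(C[[i]], M)
      C[[i]] <- sweep(C[[i]] %*% t(k$R), 2, -k$t)
    }
    M2 <- Reduce(`+`, C) / length(C)
    moved <- sqrt(mean((M2 - M)^2))
    M <- M2
    if (moved < tol) break
  }
  transforms <- lapply(seq_along(X), function(i) kabsch(X[[i]], C[[i]])[c("R", "t")])
  structure(list(coords = C,
                 matrix = do.call(rbind, lapply(C, flatten_coords)),
                 transforms = transforms, mean = M, iterations = it),
            class = "mc3_aligned")
}

#' @export
print.mc3_aligned <- function(x, ...) {
  cat("mc3_aligned:", length(x$coords), "specimens,",
      nrow(x$coords[[1]]), "nodes (", x$iterations, "GPA iterations )\n")
  invisible(x)
}

#' Fit the template to every cloud (coarse + fine)
#'
#' Convenience wrapper running [host_mesh_fit()] then [fine_fit()] per cloud.
#'
#' @param template an `mc3_mesh`
#' @param clouds list of point matrices
#' @param ... passed to [host_mesh_fit()]
#' @param smoothing_weight passed to [fine_fit()]
#' @param verbose print per-specimen RMS?
#' @return list of `mc3_fit`
#' @export
fit_population <- function(template, clouds, ..., smoothing_weight = 1e-3,
                           verbose = FALSE) {
  lapply(seq_along(clouds), function(i) {
    coarse <- host_mesh_fit(template, clouds[[i]], ...)
    fine <- fine_fit(coarse, clouds[[i]], smoothing_weight = smoothing_weight)
    if (verbose)
      message(sprintf("specimen %d: coarse %.3f mm, fine %.3f mm",
                      i, coarse$rms, fine$rms))
    fine
  })
}

#' Iterative shape-model-constrained correspondence refinement
#'
#' Rounds of: rigid alignment, shape-PCA training, projection of every fitted
#' mesh onto the subspace covering `variance_keep` of the variance (which
#' regularizes node sliding and propagates correspondence), mapping back to
#' the specimen frame, and an unconstrained fine refit to the cloud. Stops
#' when the population mean RMS falls below `rms_target` or stops improving.
#'
#' @param template an `mc3_mesh`
#' @param clouds list of point matrices
#' @param initial_fits list of `mc3_fit` from [fit_population()]
#' @param rms_target mm (default 0.3)
#' @param min_rounds constrained-refit rounds always executed (default 1:
#'   the model constraint is the point of the loop, so it runs at least once
#'   even when the initial fits already beat the target)
#' @param max_rounds round cap
#' @param variance_keep variance fraction retained by the model constraint
#' @param improve_tol minimum mean-RMS improvement to continue (mm)
#' @param smoothing_weight fine-fit smoothing
#' @param verbose print per-round RMS?
#' @return `mc3_training_set`: final fits, aligned N x 3n matrix and
#'   transforms, per-round RMS history, convergence flag
#' @export
correspondence_loop <- function(template, clouds, initial_fits,
                                rms_target = 0.3, min_rounds = 1L,
                                max_rounds = 10L,
                                variance_keep = 0.98, improve_tol = 1e-3,
                                smoothing_weight = 1e-3, verbose = FALSE) {
  N <- length(clouds)
  if (length(initial_fits) != N) stop("one initial fit per cloud required")
  fits <- initial_fits
  rms_now <- vapply(fits, `[[`, 0, "rms")
  rms_history <- list(rms_now)
  converged <- FALSE
  round <- 0L
  while (round < max_rounds) {
    round <- round + 1L
    aligned <- rigid_align(lapply(fits, function(f) f$mesh$nodes))
    model <- ssm_train(aligned$matrix, "shape", variance_target = variance_keep)
    for (i in seq_len(N)) {
      proj <- ssm_project(model, aligned$matrix[i, ], k = model$n_retained)
      xr <- ssm_reconstruct(model, proj$weights)
      tr <- aligned$transforms[[i]]
      # back to the specimen frame: aligned = R x + t
      nodes <- sweep(unflatten_coords(xr), 2, tr$t) %*% tr$R
      start <- new_mc3_mesh(nodes, template$topology, template$manifest)
      fits[[i]] <- fine_fit(start, clouds[[i]],
                            smoothing_weight = smoothing_weight)
    }
    rms_prev <- rms_now
    rms_now <- vapply(fits, `[[`, 0, "rms")
    rms_history[[length(rms_history) + 1L]] <- rms_now
    if (verbose)
      message(sprintf("round %d: mean RMS %.4f mm", round, mean(rms_now)))
    if (mean(rms_now) < rms_target && round >= min_rounds) {
      converged <- TRUE; break
    }
    if (round >= min_rounds &&
        mean(rms_prev) - mean(rms_now) < improve_tol) break
  }
  aligned <- rigid_align(lapply(fits, function(f) f$mesh$nodes))
  structure(list(fits = fits, aligned = aligned,
                 rms = rms_now, mean_rms = mean(rms_now),
                 rms_history = do.call(rbind, rms_history),
                 rounds = round, converged = converged,
                 rms_target = rms_target),
            class = "mc3_training_set")
}

#' @export
print.mc3_training_set <- function(x, ...) {
  cat(sprintf("mc3_training_set: %d specimens, mean RMS %.4f mm after %d rounds (%s)\n",
              length(x$fits), x$mean_rms, x$rounds,
              if (x$converged) "target met" else "target not met"))
  invisible(x)
}
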