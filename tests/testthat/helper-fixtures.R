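# Shared fixtures, built once per test run. Everything is generated in code;
# nothing is read from disk.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env))
    assign(name, builder(), envir = fixture_env)
  get(name, envir = fixture_env)
}

base_mesh <- function() fixture("base", function() make_base_shape())

# a small synthetic population (shared across tests that only read it)
small_population <- function() fixture("pop6", function()
  sample_population(default_synthetic_spec(n_specimens = 6, seed = 424242)))

# noiseless uniform surface cloud from a mesh, in code (independent of the
# package's Poisson exporter)
surface_cloud <- function(mesh, n = 1500, sd = 0, seed = 1) {
  set.seed(seed)
  np <- nrow(mesh$topology$patches)
  p <- sample.int(np, n, replace = TRUE)
  pts <- evaluate_surface(mesh, p, runif(n), runif(n))
  if (sd > 0) pts <- pts + matrix(rnorm(3 * n, 0, sd), n, 3)
  pts
}

rotation_angle_deg <- function(R1, R2 = diag(3)) {
  R <- R1 %*% t(R2)
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}

# uniform-HU volume covering a mesh with the given margins (hand-built)
uniform_volume <- function(mesh, hu = 500, margin = 8, spacing = c(1, 1, 1)) {
  lo <- apply(mesh$nodes, 2, min) - margin
  hi <- apply(mesh$nodes, 2, max) + margin
  dims <- ceiling((hi - lo) / spacing) + 1
  new_mc3_volume(array(hu, dims), spacing, lo,
                 water_region = list(lo = c(1L, 1L, 1L), hi = c(3L, 3L, 3L)))
}
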