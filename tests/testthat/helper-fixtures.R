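# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# unit right tetrahedron (volume 1/6)
unit_tet <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1L), region = 1L)
}

# coarse proxy shared across tests (a few thousand tets)
coarse_proxy <- function() {
  cached("coarse_proxy",
         function() generate_proxy(proxy_params(edge_length = 2.5,
                                                seed = 7L)))
}

# default-resolution proxy for the acceptance checks
default_proxy <- function() {
  cached("default_proxy", function() generate_proxy(proxy_params(seed = 1L)))
}

# default-resolution field pair / frames, computed once
default_fields <- function(use_virtual = TRUE) {
  key <- paste0("fields_", use_virtual)
  cached(key, function()
    suppressMessages(solve_field_pair(default_proxy(),
                                      use_virtual = use_virtual)))
}

default_frames <- function(use_virtual = TRUE) {
  key <- paste0("frames_", use_virtual)
  cached(key, function() {
    mesh <- default_proxy()
    f <- default_fields(use_virtual)
    bone <- c(1L, 2L)
    long_regions <- if (use_virtual) c(bone, 9L) else bone
    gl <- element_gradients(mesh, f$phi_long, long_regions)
    gr <- element_gradients(mesh, f$phi_rad, bone)
    ref <- centerline_tangent(attr(mesh, "proxy_params"),
                              element_centroids(mesh))
    build_frames(mesh, gl, gr, bone_regions = bone, reference = ref)
  })
}

# full three-model comparison on the default proxy, computed once
default_run <- function() {
  cached("default_run",
         function() suppressMessages(run_comparison(default_run_config(seed = 1L))))
}

# uniform isotropic stiffness array for a mesh
uniform_stiffness <- function(mesh, constants) {
  C <- stiffness_from_compliance(compliance_from_constants(constants))
  arr <- array(NA_real_, c(nrow(mesh$tets), 6L, 6L))
  for (e in seq_len(nrow(mesh$tets))) arr[e, , ] <- C
  arr
}

# random rotation matrix (uniform via QR of Gaussian)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# random admissible orthotropic constants (rejection sampling)
random_ortho <- function() {
  repeat {
    E <- runif(3, 0.5, 30)
    G <- runif(3, 0.2, 10)
    nu <- runif(3, 0.05, 0.4)
    c <- ortho_constants(E[1], E[2], E[3], G[1], G[2], G[3],
                         nu[1], nu[2], nu[3])
    ok <- tryCatch({
      compliance_from_constants(c)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(c)
  }
}
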