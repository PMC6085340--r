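# shared fixtures and independent closed-form oracles; heavyweight objects
# (factorized diffusion operators) are memoized for the whole test run

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, builder(), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# homogeneous optical properties used by the solver oracle checks
oracle_mua <- 0.01
oracle_musp <- 1.0

uniform_optics <- function(mu_a = oracle_mua, mu_sp = oracle_musp) {
  o <- default_tissue_optics()
  o$mu_a[o$class != "air"] <- mu_a
  o$mu_s_prime[o$class != "air"] <- mu_sp
  o
}

# small homogeneous slab (gray throughout) + factorized operator
test_slab <- function() memo("slab", function() {
  build_layered_phantom(c(gray = 23), grid_shape = c(40, 40, 24),
                        voxel_size = 1, optics = uniform_optics())
})
test_slab_op <- function() memo("slab_op", function() {
  diffusion_operator(test_slab(), 805)
})

# small layered (skull/CSF/gray/white) phantom
test_phantom <- function() memo("phantom", function() {
  macaque_phantom(grid_shape = c(44, 44, 24))
})

## independent closed-form semi-infinite CW diffusion oracles -------------

oracle_afactor <- function(n = 1.4) {
  rd <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  (1 + rd) / (1 - rd)
}

# extrapolated-boundary point-source fluence, unit power, source depth 1/musp
oracle_fluence <- function(rho, z, mu_a = oracle_mua, mu_sp = oracle_musp) {
  D <- 1 / (3 * (mu_a + mu_sp))
  mueff <- sqrt(mu_a / D)
  z0 <- 1 / mu_sp
  zb <- 2 * oracle_afactor() * D
  r1 <- sqrt(rho^2 + (z - z0)^2)
  r2 <- sqrt(rho^2 + (z + z0 + 2 * zb)^2)
  (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * D)
}

# diffuse reflectance (partial-current form) at lateral distance rho
oracle_reflectance <- function(rho, mu_a = oracle_mua, mu_sp = oracle_musp) {
  D <- 1 / (3 * (mu_a + mu_sp))
  mueff <- sqrt(mu_a / D)
  z0 <- 1 / mu_sp
  zb <- 2 * oracle_afactor() * D
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
   (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2) / (4 * pi)
}

## small synthetic sessions -------------------------------------------------

quick_config <- function(n_trials = 16, ...) {
  sim_config(n_trials = n_trials, ...)
}

quick_session <- function(seed = 11, ...) {
  memo(paste0("session_", seed), function() {
    simulate_session(quick_config(...), seed = seed)
  })
}

paper_channels <- function() memo("paper_channels", function() {
  dplyr::select(
    assign_regions(enumerate_channels(paper_layout()), paper_region_table()),
    channel, region, side)
})
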