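# Lazily-built shared fixtures: expensive Monte Carlo runs happen at most
# once per test session, on first use.
shared_cache <- new.env(parent = emptyenv())

shared <- function(name, builder) {
  if (!exists(name, envir = shared_cache)) {
    assign(name, builder(), envir = shared_cache)
  }
  get(name, envir = shared_cache)
}

head4 <- function() shared("head4", four_layer_head)
grid224 <- function() shared("grid224", tau_grid)
brain_layer <- function() head4()$layers[[4]]

# four-layer tallies used across fitting / metric / acceptance tests
tallies4 <- function() shared("tallies4", function()
  run_mc(head4(), mc_config(n_photons = 1.5e6, seed = 424242)))

# homogeneous brain slab (MC <-> diffusion comparisons)
brain_model <- function() shared("brain_model", function()
  head_model(list(brain_layer()), name = "homogeneous brain"))
tallies_hom <- function() shared("tallies_hom", function()
  run_mc(brain_model(), mc_config(n_photons = 1e6, seed = 777)))

# clean four-layer g2 at one detector index, optionally with perturbed DBs
clean_curve <- function(detector, levels = 6e-6, perturb_layer = 4) {
  generate_dataset(head4(), tau = grid224()$tau, perturb_layer = perturb_layer,
                   levels = levels, detectors = detector,
                   tallies = tallies4())
}

# analytical (inverse-crime) g2 for a reduction at given flows
crime_curve <- function(reduction, rho, dbs, beta = 0.5) {
  g2_curve(rho, grid224()$tau,
           dcsfit:::ml_g2_eval(reduction, rho, grid224()$tau, dbs, beta,
                               knots = 0),
           beta = beta, provenance = "analytical:crime")
}
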