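# Shared small fixtures, built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, fixture_env)) assign(name, build(), fixture_env)
  get(name, fixture_env)
}

# tiny straight vessel (unstented), ~3k agents
tiny_vessel_spec <- function(curvature = Inf) {
  vessel_spec(lumen_radius = 0.18, segment_length = 0.7,
              curvature_radius = curvature,
              agent_nominal_radius = 0.018,
              wall_layers = data.frame(kind = c("IEL_SMC", "SMC", "EEL_SMC"),
                                       n = c(1L, 2L, 1L)))
}

tiny_vessel <- function() fixture("tiny_vessel", function() {
  build_vessel(tiny_vessel_spec())
})

tiny_curved_vessel <- function() fixture("tiny_curved_vessel", function() {
  build_vessel(tiny_vessel_spec(curvature = 5))
})

# small stented deployment shared across deploy/biology/metrics tests
small_deployment <- function() fixture("small_deployment", function() {
  set.seed(421)
  vs <- vessel_spec(lumen_radius = 0.2, segment_length = 0.9,
                    agent_nominal_radius = 0.018,
                    wall_layers = data.frame(
                      kind = c("IEL_SMC", "SMC", "EEL_SMC"),
                      n = c(1L, 2L, 1L)))
  v <- build_vessel(vs)
  sp <- stent_spec(n_rings = 2, struts_per_ring = 6, strut_length = 0.28,
                   ring_spacing = 0.38, target_radius = 0.26,
                   strut_width = 0.08, strut_thickness = 0.06,
                   voxel_edge = 0.03)
  st <- generate_parametric_stent(sp, segment_length = 0.9)
  dep <- deploy(v, st$agents)
  dep$vessel_spec <- vs
  dep$stent_spec <- sp
  dep$state <- initialize_phenotypes(dep$state, voxel_edge = 0.03)
  dep
})

# small solved tube for flow-dependent tests
small_tube <- function() fixture("small_tube", function() {
  lat <- tube_lattice(0.3, 0.9, 0.03)
  solve_flow(lat, flow_params())
})

expect_equal_tol <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol)
}
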