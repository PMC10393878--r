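# shared fixtures: geometries and (memoised) flow solutions used across
# test files; everything is generated in code, deterministically

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(make), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

cylinder_spec <- function(d = 3, length = 30)
  stenosis_spec(reference_diameter = d, stenosis_pct = 0, lesion_length = 10,
                lesion_center = length / 2, vessel_length = length)

lesion_spec <- function(pct, d = 3, length = 30)
  stenosis_spec(reference_diameter = d, stenosis_pct = pct,
                lesion_length = 10, lesion_center = length / 2,
                vessel_length = length)

# small cylinder solution at low Reynolds number (viscous validation cases)
cyl_solution <- function(flow = 0.234, budget = c(300, 3000), pct_fid = 100) {
  key <- sprintf("cyl_%g_%d_%d", flow, budget[2], pct_fid)
  fixture(key, {
    geom <- make_stenosed_vessel(cylinder_spec(), 64, 32)
    mesh <- build_mesh(geom, pct_fid, n_min = budget[1], n_max = budget[2])
    solve_steady(mesh, fluid_properties(), boundary_conditions(flow))
  })
}

# paired-flow solutions on a stenosed vessel (shared across tests)
stenosis_pair <- function(pct = 60, budget = c(200, 2000)) {
  key <- sprintf("sten_%d_%d", pct, budget[2])
  fixture(key, {
    geom <- make_stenosed_vessel(lesion_spec(pct), 96, 32)
    mesh <- build_mesh(geom, 100, n_min = budget[1], n_max = budget[2])
    fl <- fluid_properties()
    list(geom = geom, mesh = mesh,
         s1 = solve_steady(mesh, fl, boundary_conditions(1)),
         s3 = solve_steady(mesh, fl, boundary_conditions(3)))
  })
}

# exhaustive sign-enumeration oracle for the signed-rank test (n <= 12);
# average ranks for ties, two-sided p doubled from the attained tail
signrank_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-12)
  p_ge <- mean(v_all >= v_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}
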