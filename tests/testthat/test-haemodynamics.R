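test_that("Carreau-Yasuda viscosity hits both plateaus and the midpoint", {
  p <- rheology_params()
  expect_equal(carreau_yasuda_viscosity(0, p), 0.022)
  expect_equal(carreau_yasuda_viscosity(1e12, p), 0.0022, tolerance = 1e-4)
  # direct formula evaluation at gamma = 1/lambda
  gd <- 1 / 0.11
  mu_direct <- 0.0022 + (0.022 - 0.0022) * (1 + 1)^((0.392 - 1) / 0.644)
  expect_equal(carreau_yasuda_viscosity(gd, p), mu_direct, tolerance = 1e-12)
  expect_equal(mu_direct, 0.01249, tolerance = 1e-3)
  expect_error(carreau_yasuda_viscosity(-1, p), "non-negative")
})

test_that("Carreau-Yasuda viscosity is strictly decreasing and bounded", {
  p <- rheology_params()
  gd <- 10^seq(-3, 6, length.out = 50)
  mu <- carreau_yasuda_viscosity(gd, p)
  expect_true(all(diff(mu) < 0))
  expect_true(all(mu > p$eta_inf & mu <= p$eta_0))
})

test_that("poiseuille_wss matches the closed form and scales as D^-3", {
  expect_equal(poiseuille_wss(0, 4, 0.0035), 0)
  expect_equal(poiseuille_wss(300, 4, 0.0035),
               32 * 0.0035 * (300e-6 / 60) / (pi * 0.004^3), tolerance = 1e-12)
  expect_equal(poiseuille_wss(300, 4, 0.0035), 2.785, tolerance = 1e-3)
  expect_equal(poiseuille_wss(300, 8, 0.0035),
               poiseuille_wss(300, 4, 0.0035) / 8, tolerance = 1e-12)
  expect_error(poiseuille_wss(300, 0, 0.0035), "positive")
})

test_that("grid convergence index reproduces hand arithmetic and threshold", {
  g0 <- gci(1.0, 1.0, 2, 2)
  expect_equal(g0$gci, 0)
  expect_true(g0$pass)
  g <- gci(1.0, 1.02, r = 2, p_order = 2, safety_factor = 1.25)
  expect_equal(g$gci, 1.25 * 0.02 / 3, tolerance = 1e-12)
  expect_equal(g$gci, 0.008333, tolerance = 1e-4)
  expect_true(g$pass)
  # bracketing the 3% acceptance criterion
  expect_true(gci(1, 1 + 0.029 * 3 / 1.25, 2, 2)$pass)
  expect_false(gci(1, 1 + 0.031 * 3 / 1.25, 2, 2)$pass)
  expect_error(gci(0, 1, 2, 2), "non-zero")
  expect_error(gci(1, 1.1, 1, 2), "exceed 1")
})

test_that("Newtonian solver matches the Poiseuille closed form on a tube", {
  net <- tube_network(length_mm = 100, diameter_mm = 4)
  q <- const_wave(300, n = 16)
  spl <- build_outlet_splits(net, list(LICA = q), region_table(c(left_middle = 1)))
  sol <- solve_network(net, list(LICA = q), spl, newtonian_params(0.0035),
                       solver_config(n_phase = 16))
  dp_true <- 128 * 0.0035 * 0.1 * (300e-6 / 60) / (pi * 0.004^4)
  dp <- sol$pressure[match("A", sol$node_names), ] -
    sol$pressure[match("B", sol$node_names), ]
  expect_equal(max(abs(dp - dp_true)) / dp_true, 0, tolerance = 1e-9)
  expect_equal(sol$flow[1, 1], 300, tolerance = 1e-9)
  v_true <- (300e-6 / 60) / (pi * 0.002^2) * 100
  expect_equal(sol$v_mean[1, 1], v_true, tolerance = 1e-9)
  expect_equal(sol$v_max[1, 1], 2 * v_true, tolerance = 1e-9)
  expect_equal(sol$wss[1, 1], 32 * 0.0035 * (300e-6 / 60) / (pi * 0.004^3),
               tolerance = 1e-9)
})

test_that("Newtonian solver matches the resistance ladder on a series chain", {
  # three segments in series: same flow, pressure drops add
  seg <- data.frame(id = c("S1", "S2", "S3"),
                    from = c("A", "B", "C"), to = c("B", "C", "D"),
                    length_mm = c(40, 25, 60), diameter_mm = c(4, 3.2, 2.5),
                    name = c("s1", "s2", "s3"))
  net <- vascular_network(seg, inlets = c(A = "LICA"),
                          outlets = c(D = "left_middle"))
  q <- const_wave(200, n = 16)
  spl <- build_outlet_splits(net, list(LICA = q), region_table(c(left_middle = 1)))
  mu <- 0.004
  sol <- solve_network(net, list(LICA = q), spl, newtonian_params(mu),
                       solver_config(n_phase = 16))
  Q <- 200e-6 / 60
  R <- 128 * mu * seg$length_mm * 1e-3 / (pi * (seg$diameter_mm * 1e-3)^4)
  dp_true <- Q * sum(R)
  dp <- sol$pressure[match("A", sol$node_names), 1] -
    sol$pressure[match("D", sol$node_names), 1]
  expect_equal(dp, dp_true, tolerance = 1e-9)
  expect_equal(unname(sol$flow[, 1]), rep(200, 3), tolerance = 1e-9)
})

test_that("symmetric Y gives equal daughter flows and pressures", {
  net <- y_network(d_parent = 4, d_daughter = 2.8)
  q <- pulsatile_wave(400, n = 16)
  tab <- region_table(c(left_middle = 0.5, right_middle = 0.5))
  spl <- build_outlet_splits(net, list(LICA = q), tab)
  sol <- solve_network(net, list(LICA = q), spl, rheology_params(),
                       solver_config(n_phase = 16))
  i1 <- match("D1", sol$segments$id); i2 <- match("D2", sol$segments$id)
  expect_equal(sol$flow[i1, ], sol$flow[i2, ], tolerance = 1e-9)
  expect_equal(sol$pressure[match("C1", sol$node_names), ],
               sol$pressure[match("C2", sol$node_names), ], tolerance = 1e-9)
})

test_that("converged solutions conserve mass nodally with bounded viscosity", {
  for (k in 1:8) {
    net <- random_network(seed = 200 + k, n_nodes = sample(6:9, 1),
                          loops = sample(0:2, 1))
    if (is.null(net)) next
    tab <- table_for_network(net, seed = k)
    inflow <- pulsatile_wave(stats::runif(1, 150, 800), n = 16)
    spl <- build_outlet_splits(net, list(LICA = inflow), tab)
    sol <- solve_network(net, list(LICA = inflow), spl, rheology_params(),
                         solver_config(n_phase = 16))
    expect_lt(nodal_residual(sol, net, list(LICA = inflow), spl), 1e-9)
    expect_true(all(sol$mu >= rheology_params()$eta_inf - 1e-15))
    expect_true(all(sol$mu <= rheology_params()$eta_0 + 1e-15))
    expect_equal(sol$v_max, 2 * sol$v_mean)
  }
})

test_that("pressures shift but flows are invariant under reference-node choice", {
  net <- y_network()
  q <- pulsatile_wave(350, n = 16)
  tab <- region_table(c(left_middle = 0.5, right_middle = 0.5))
  spl <- build_outlet_splits(net, list(LICA = q), tab)
  s1 <- solve_network(net, list(LICA = q), spl, rheology_params(),
                      solver_config(n_phase = 16, reference_node = "A"))
  s2 <- solve_network(net, list(LICA = q), spl, rheology_params(),
                      solver_config(n_phase = 16, reference_node = "C2"))
  expect_equal(s1$flow, s2$flow, tolerance = 1e-8)
  shift <- s1$pressure - s2$pressure
  expect_lt(max(abs(sweep(shift, 2, shift[1, ]))), 1e-6 * max(abs(s1$pressure)))
})

test_that("raising inflow never raises effective viscosity (shear thinning)", {
  net <- y_network()
  tab <- region_table(c(left_middle = 0.5, right_middle = 0.5))
  mus <- sapply(c(200, 400, 800), function(f) {
    q <- const_wave(f, n = 16)
    spl <- build_outlet_splits(net, list(LICA = q), tab)
    sol <- solve_network(net, list(LICA = q), spl, rheology_params(),
                         solver_config(n_phase = 16))
    sol$mu[, 1]
  })
  expect_true(all(diff(t(mus)) <= 1e-12))
})

test_that("the quasi-steady solution is phase-local", {
  net <- y_network()
  tab <- region_table(c(left_middle = 0.5, right_middle = 0.5))
  ph <- seq(0, 1, length.out = 17)[-17]
  vals <- 300 + 150 * sin(2 * pi * ph)
  perm <- c(9:16, 1:8)
  q1 <- sampled_waveform(vals, 1, "mL/min")
  q2 <- sampled_waveform(vals[perm], 1, "mL/min")
  run <- function(q) {
    spl <- build_outlet_splits(net, list(LICA = q), tab)
    solve_network(net, list(LICA = q), spl, rheology_params(),
                  solver_config(n_phase = 16))
  }
  s1 <- run(q1); s2 <- run(q2)
  expect_equal(s2$flow, s1$flow[, perm], tolerance = 1e-7)
  expect_equal(s2$v_max, s1$v_max[, perm], tolerance = 1e-7)
})

test_that("solver rejects non-conservative boundary flows", {
  net <- y_network()
  tab <- region_table(c(left_middle = 0.5, right_middle = 0.5))
  q <- const_wave(400, n = 16)
  spl <- build_outlet_splits(net, list(LICA = q), tab)
  expect_error(
    solve_network(net, list(LICA = const_wave(500, n = 16)), spl,
                  rheology_params(), solver_config(n_phase = 16)),
    "conserve mass")
})
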