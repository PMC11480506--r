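test_that("concentration and ion bookkeeping match the published setup", {
  # 33 chains in a 30 nm box is the 2 mM working concentration
  expect_equal(round(concentration(33, 30)), 2)
  expect_equal(concentration(33, 30), 2.0295, tolerance = 1e-4)
  expect_equal(concentration(0, 30), 0)
  # linearity
  expect_equal(concentration(16, 30) * 2, concentration(32, 30))
  # 16 + 16 two-species setup
  expect_equal(concentration(32, 30), 1.968, tolerance = 1e-3)

  # 0.150 mol/L x N_A x 2.7e-20 L = 2439, verified by hand
  expect_equal(ion_counts(30, 150, 0), list(n_na = 2439L, n_cl = 2439L))
  expect_equal(ion_counts(30, 0, 2), list(n_na = 0L, n_cl = 2L))
  expect_equal(ion_counts(30, 0, -3), list(n_na = 3L, n_cl = 0L))
  expect_error(concentration(33, -1), "box_edge")
})

test_that("build_system packs self-avoiding chains reproducibly", {
  cfg <- system_config(list(DR1 = region_topology("DR1")), copies = 6L,
                       box_edge = 12, seed = 7L)
  fr1 <- build_system(cfg)
  fr2 <- build_system(cfg)
  expect_identical(fr1$coords, fr2$coords)  # determinism

  expect_true(all(fr1$coords >= 0 & fr1$coords < 12))
  expect_equal(nrow(fr1$coords), 6L * 22L)

  # no two non-bonded beads closer than sigma (minimum image)
  sigma <- cfg$params$sigma
  pairs <- oracle_contacts(fr1, contact_params(cutoff = sigma,
                                               exclusion = 2L))
  expect_equal(nrow(pairs), 0L)

  expect_equal(attr(fr1, "concentration_mM"), concentration(6, 12))
  expect_type(attr(fr1, "ions")$n_na, "integer")

  # an impossible packing fails with advice rather than hanging
  tiny <- system_config(list(DR2 = region_topology("DR2")), copies = 20L,
                        box_edge = 3, seed = 1L)
  expect_error(build_system(tiny, max_attempts = 2L), "larger box")
})

test_that("simulate_system conserves bookkeeping and is seed-deterministic", {
  cfg <- system_config(list(DR1 = region_topology("DR1")), copies = 4L,
                       box_edge = 10, seed = 3L,
                       params = sim_params(chi = 1))
  start <- build_system(cfg)

  t0 <- simulate_system(start, cfg, n_steps = 0L)
  expect_equal(n_frames(t0), 1L)
  expect_identical(t0$frames[[1]], start$coords)

  tr1 <- simulate_system(start, cfg, n_steps = 400L, save_every = 100L)
  tr2 <- simulate_system(start, cfg, n_steps = 400L, save_every = 100L)
  expect_identical(tr1$frames, tr2$frames)
  expect_false(identical(
    tr1$frames,
    simulate_system(start, cfg, n_steps = 400L, save_every = 100L,
                    seed = 99L)$frames))

  expect_equal(n_frames(tr1), 5L)
  expect_true(all(diff(tr1$times) > 0))
  expect_true(all(vapply(tr1$frames, nrow, 1L) == nrow(start$coords)))
  expect_true(all(vapply(tr1$frames, function(m) all(m >= 0 & m < 10), TRUE)))
  expect_true(all(is.finite(tr1$provenance$energies)))

  # bonds stay intact: bonded beads never drift far from b0
  last <- tr1$frames[[5]]
  bonds <- drcluster:::system_bonds(cfg)
  d <- vapply(seq_len(nrow(bonds)), function(r)
    sqrt(min_image_dist2(last[bonds[r, 1], ], last[bonds[r, 2], ], 10)), 0)
  expect_true(all(d > 0.1 & d < 0.9))
})

test_that("unstable or too-coarse integration settings are rejected", {
  cfg <- system_config(list(DR1 = region_topology("DR1")), copies = 2L,
                       box_edge = 10,
                       params = sim_params(dt = 0.01))
  start <- build_system(cfg)
  expect_error(simulate_system(start, cfg, 10L), "sigma/4")

  cfg2 <- system_config(list(DR1 = region_topology("DR1")), copies = 2L,
                        box_edge = 10,
                        params = sim_params(dt = 0.004, eps_rep = 300))
  start2 <- build_system(cfg2)
  expect_error(simulate_system(start2, cfg2, 10L), "stiffness")
})

test_that("chi schedules are honoured and validated", {
  cfg <- system_config(list(DR1 = region_topology("DR1")), copies = 3L,
                       box_edge = 10, params = sim_params(chi = 2))
  start <- build_system(cfg)
  tr <- simulate_system(start, cfg, n_steps = 100L, save_every = 50L,
                        schedule = function(t) if (t < 0.1) 2 else 0)
  expect_equal(n_frames(tr), 3L)
  expect_error(simulate_system(start, cfg, 100L, schedule = rep(1, 5)),
               "length n_steps")
  expect_error(simulate_system(start, cfg, 100L,
                               schedule = rep(-1, 100)), "chi")
})

test_that("planted clusters are recovered exactly, including across the box edge", {
  cfg <- system_config(list(DR1 = region_topology("DR1")), copies = 6L,
                       box_edge = 30, seed = 11L)
  partition <- list(c(1L, 2L, 3L), 4L, c(5L, 6L))
  fr <- plant_clusters(cfg, partition)
  expect_equal(attr(fr, "planted_partition"), partition)
  got <- find_clusters(interaction_graph(fr))
  expect_equal(got, partition)

  # singleton-only partition: no cluster of size >= 2
  fr1 <- plant_clusters(cfg, as.list(1:6))
  got1 <- find_clusters(interaction_graph(fr1))
  expect_true(all(lengths(got1) == 1L))

  # a pair straddling the periodic boundary is still one cluster
  fr2 <- plant_clusters(cfg, list(c(1L, 2L), 3L, 4L, 5L, 6L),
                        straddle_boundary = TRUE)
  expect_true(any(fr2$coords[fr2$beads$chain <= 2, 1] > 25) &&
              any(fr2$coords[fr2$beads$chain <= 2, 1] < 5))
  got2 <- find_clusters(interaction_graph(fr2))
  expect_equal(got2[[1]], c(1L, 2L))

  expect_error(plant_clusters(cfg, list(1:5)), "exactly once")
  small <- system_config(list(DR1 = region_topology("DR1")), copies = 6L,
                         box_edge = 8)
  expect_error(plant_clusters(small, as.list(1:6)), "enlarge the box")
})

test_that("synthetic FRAP traces round-trip their ground truth", {
  tr <- synth_frap(0.82, 169, frame_interval_s = 5, n_frames = 122,
                   bleach_frame = 3, noise_sd = 0)
  curve <- process_frap(tr)
  expect_equal(curve$value[1], 0)
  fit <- fit_one_phase(curve)
  expect_equal(fit$mobile_fraction, 0.82, tolerance = 1e-6)
  expect_equal(fit$t_half_s, 169, tolerance = 1e-6)

  # immobile sample: flat at zero after bleach
  tr0 <- synth_frap(0, 100, n_frames = 30, noise_sd = 0)
  expect_true(all(abs(process_frap(tr0)$value) < 1e-12))

  # determinism and noise
  a <- synth_frap(0.5, 60, n_frames = 50, noise_sd = 5, seed = 4)
  b <- synth_frap(0.5, 60, n_frames = 50, noise_sd = 5, seed = 4)
  expect_identical(a$traces, b$traces)
  expect_error(synth_frap(1.2, 10), "mobile_fraction")
  expect_error(synth_frap(0.5, -1), "t_half")
})

test_that("synthetic mass samples hit their moments and stay deterministic", {
  s <- synth_masses(list(c(135, 67, 1)), 5000, seed = 42)
  se <- 67 / sqrt(5000)
  expect_lt(abs(mean(s$masses) - 135), 3 * se)
  expect_identical(s$masses, synth_masses(list(c(135, 67, 1)), 5000,
                                          seed = 42)$masses)
  # weight 1 on one component -> all events from it
  s2 <- synth_masses(list(c(100, 1, 1), c(500, 1, 0)), 200, seed = 1)
  expect_true(all(abs(s2$masses - 100) < 10))
  expect_error(synth_masses(list(c(100, 0, 1)), 10), "SDs")
  expect_error(synth_masses(list(c(100, 1, 0.5)), 10), "sum to 1")
})

test_that("synthetic binding curves encode single-site saturation", {
  grid <- c(0.05, 0.2, 0.8, 2, 3, 12, 50)
  b <- synth_binding(2, r0 = 0.05, r_max = 0.25, conc_grid = grid)
  # half saturation at L = Kd
  expect_equal(b$data$anisotropy[grid == 2], (0.05 + 0.25) / 2)
  expect_warning(synth_binding(2, conc_grid = c(100, 200, 400)),
                 "bracket")
  expect_error(synth_binding(-1, conc_grid = grid), "kd_uM")
  expect_error(synth_binding(2, conc_grid = c(1, 1, 2)), "distinct")
})

test_that("periodic wrapping leaves analysis results unchanged", {
  cfg <- system_config(list(DR1 = region_topology("DR1")), copies = 5L,
                       box_edge = 9, seed = 5L)
  fr <- build_system(cfg)
  shift <- c(3.7, -11.2, 9 * 4)  # arbitrary, includes whole multiples
  fr2 <- fr
  fr2$coords <- drcluster:::wrap_coords(sweep(fr$coords, 2, shift, `+`), 9)
  p <- contact_params()
  c1 <- bead_contacts(fr, p); c2 <- bead_contacts(fr2, p)
  expect_equal(c1[order(c1$i, c1$j), ], c2[order(c2$i, c2$j), ])
})
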