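# Integrator correctness, initial conformations, protocol plumbing.

test_that("rosette conformations have uniform spacing and sit on the box axis", {
  r <- init_rosette(300, 15)
  d <- sqrt(rowSums(diff(r$pos)^2))
  expect_true(all(d >= 0.9 & d <= 1.3))
  expect_equal(colMeans(r$pos)[1:2], c(0, 0), tolerance = 1e-9)
  expect_true(max(abs(r$pos[, 1:2])) < 15 / 2)
  # degenerate size still yields a valid partial rosette
  r10 <- init_rosette(10, 12)
  d10 <- sqrt(rowSums(diff(r10$pos)^2))
  expect_true(all(d10 >= 0.9 & d10 <= 1.3))
  expect_error(init_rosette(300, 2), "box too small")
})

test_that("box sizing reproduces the chromatin density target", {
  # worked example: 2 Mbp at 6.5 Mbp/um^3 with 25 nm beads
  expect_equal(box_from_density(2000, 6.5, 25), 27.0, tolerance = 0.05)
  # exact round trip
  for (kbp in c(100, 1000, 3000))
    expect_equal(density_from_box(kbp, box_from_density(kbp, 6.5, 25), 25),
                 6.5, tolerance = 1e-9)
  # scaling law: doubling the fragment multiplies L by 2^(1/3)
  expect_equal(box_from_density(2000) / box_from_density(1000), 2^(1/3),
               tolerance = 1e-12)
})

test_that("protein population splits 1/4:1/8:5/8 with remainder to HP1", {
  tf <- tf_population(1000)
  expect_equal(tf$total, 100)
  expect_equal(unname(tf$counts["active"]), 25)
  expect_equal(unname(tf$counts["polycomb"]), 12)
  expect_equal(unname(tf$counts["hp1"]), 63)   # 62 floored + remainder 1
  expect_equal(sum(tf$counts), tf$total)
  expect_equal(tf$ksw, 1e-3)
})

test_that("protein state switching is frozen at ksw = 0 and balances at 1/2", {
  set.seed(1)
  b <- rep(c(TRUE, FALSE), 50)
  expect_identical(switch_tf_states(b, 0, 1), b)
  states <- logical(200)
  frac <- replicate(4000, {
    states <<- switch_tf_states(states, ksw = 0.05, dt = 1)
    mean(states)
  })
  expect_equal(mean(frac[2000:4000]), 0.5, tolerance = 0.02)
})

test_that("NVE integration conserves energy (no secular drift)", {
  expect_lt(nve_drift(), 1e-4)
})

test_that("zero forces and zero noise give uniform motion", {
  v <- rbind(c(0.1, -0.2, 0.3), c(0, 0.5, 0))
  st <- md_state(pos = rbind(c(0, 0, 0), c(5, 0, 0)), vel = v,
                 box = c(50, 50, 50), nb_mode = "off")
  st2 <- integrate_md(st, 1000, thermostat = FALSE, seed = 1)
  expect_equal(st2$pos, st$pos + v * 10, tolerance = 1e-10)
  expect_equal(st2$vel, v, tolerance = 1e-12)
})

test_that("the thermostat equilibrates kinetic energy to 3/2 kBT per bead", {
  set.seed(2)
  n <- 400
  st <- md_state(pos = matrix(stats::runif(n * 3, 0, 10), ncol = 3),
                 box = c(10, 10, 10), nb_mode = "off")
  st <- integrate_md(st, 2000, seed = 11)
  ke <- numeric(400)
  for (k in seq_along(ke)) {
    st <- integrate_md(st, 25, seed = 100 + k)
    ke[k] <- total_energy(st)$kinetic / n
  }
  expect_equal(mean(ke), 1.5, tolerance = 0.02)
})

test_that("integration is deterministic under a fixed seed", {
  st <- phantom_state(50, seed = 4)
  a <- integrate_md(st, 2000, seed = 123)
  b <- integrate_md(st, 2000, seed = 123)
  expect_identical(a$pos, b$pos)
  expect_identical(a$vel, b$vel)
  c2 <- integrate_md(st, 2000, seed = 124)
  expect_false(identical(a$pos, c2$pos))
})

test_that("phantom-chain bond correlations decay at the discrete Kratky-Porod rate", {
  # the discrete chain with stiffness K has <cos theta> = coth(K) - 1/K
  # exactly; the fitted decay length is -1/ln of that (about K - 1/2)
  L <- 1 / tanh(4) - 1 / 4
  st <- phantom_state(300, seed = 5)
  st <- integrate_md(st, 10000, seed = 6)
  m <- bond_correlations(st, frames = 200, steps_per_frame = 500, smax = 4,
                         seed = 7)
  expect_equal(m[1], L, tolerance = 0.01)
  expect_equal(decay_length(m), -1 / log(L), tolerance = 0.25)
})

test_that("crumple springs are laid on (i, i+2) and omitted across acetylated beads", {
  ac <- rep(FALSE, 12); ac[6] <- TRUE   # bead 5 (0-based) acetylated
  b <- chromotopos:::.crumple_bonds(ac, force_field_params())
  expect_true(all(b$j - b$i == 2))
  # springs (3,5), (4,6), (5,7) touch bead 5 and must be absent
  expect_false(any(b$i %in% 3:5))
  expect_equal(b$k[1], 200)
  expect_equal(b$r0[1], 1.1)
})

test_that("heteromorphic fiber: crumpled regions have tighter (i, i+2) spacing", {
  gaps <- heteromorphic_gaps(seed = 9)
  expect_lt(gaps["crumpled"], gaps["open"])
  expect_equal(unname(gaps["crumpled"]), 1.1, tolerance = 0.1)
})

test_that("protocol schedule scales every duration by the desk factor", {
  s <- protocol_schedule(0.01)
  expect_equal(s$production, 3000)
  expect_equal(s$rosette_relax, 6)
  expect_equal(s$chromatin_attr_on, 100)
  expect_equal(s$tf_attr_on, 500)
  expect_equal(s$sample_every, 20)
  expect_equal(s$retain_at, c(2000, 3000))
  expect_equal(s$soft_max, 500)          # amplitudes are not durations
  expect_error(protocol_schedule(0), "desk_scale")
})

test_that("the staged protocol runs, samples and keeps bonds intact under wrap", {
  dir <- tempfile()
  files <- synth_epigenome(synthetic_locus(), dir)
  track <- annotate_locus(files, files$fragment)
  ens <- run_protocol(track, seed = 3, desk_scale = 0.002, n_production = 2)
  # two production runs branch from one relaxed state
  expect_equal(sort(unique(ens$frame_meta$production_run)), c(1, 2))
  expect_true(all(table(ens$frame_meta$production_run) >= 2))
  expect_equal(ncol(ens$frames[[1]]), 3)
  expect_equal(nrow(ens$frames[[1]]), 100)
  # retained structures flagged at the documented times
  expect_true(any(ens$frame_meta$retained))
  # backbone bonds all below the FENE maximum in every sampled frame
  for (f in ens$frames) {
    bl <- sqrt(rowSums(diff(f)^2))
    expect_true(all(bl < force_field_params()$fene_r0))
  }
  # full determinism of the pipeline under one seed
  ens2 <- run_protocol(track, seed = 3, desk_scale = 0.002, n_production = 2)
  expect_identical(ens$frames, ens2$frames)
})
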