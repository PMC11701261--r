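# Loop-extruder loading, translocation, CTCF halting, turnover.

single_extruder <- function(left, right) {
  structure(data.frame(id = 1L, left = as.integer(left),
                       right = as.integer(right),
                       left_block = "none", right_block = "none",
                       stringsAsFactors = FALSE),
            class = c("extruder_set", "data.frame"))
}
no_boundaries <- data.frame(bead = integer(), orientation = character())

test_that("extruder counts follow the density rule and anchors load at (i, i+3)", {
  set.seed(1)
  ex <- seed_extruders(2000, extrusion_params(density = 10))
  expect_equal(nrow(ex), 20)
  expect_true(all(ex$right - ex$left == 3))
  ex2 <- seed_extruders(2000, extrusion_params(density = 7.5))
  expect_equal(nrow(ex2), 15)
  # no shared anchor beads
  expect_false(any(duplicated(c(ex$left, ex$right))))
  expect_error(seed_extruders(30, n = 10), "too small")
  expect_equal(extrusion_params()$processivity_kbp, 160)
})

test_that("ends halt at opposing CTCF boundaries and pass aligned ones", {
  # backward-oriented boundary at 60 blocks a right-moving end (anchor rests
  # at 59); forward at 40 blocks the left-moving end (anchor at 41)
  bd <- data.frame(bead = c(40L, 60L), orientation = c("forward", "backward"))
  set.seed(2)
  ex <- single_extruder(49, 52)
  for (s in 1:200) ex <- attempt_translocation(ex, bd, 100, dt = 250)
  expect_equal(ex$left, 41)
  expect_equal(ex$right, 59)
  expect_equal(ex$left_block, "ctcf")
  expect_equal(ex$right_block, "ctcf")

  # aligned orientations let both ends pass; chain ends stop them instead
  bd_pass <- data.frame(bead = c(40L, 60L), orientation = c("backward", "forward"))
  ex <- single_extruder(49, 52)
  for (s in 1:400) ex <- attempt_translocation(ex, bd_pass, 100, dt = 250)
  expect_equal(ex$left, 0)               # runs to the chain end
  expect_equal(ex$right, 99)
  expect_equal(ex$left_block, "chain_end")

  # bidirectional blocks both travel directions
  bd_bi <- data.frame(bead = 60L, orientation = "bidirectional")
  ex <- single_extruder(55, 58)
  for (s in 1:200) ex <- attempt_translocation(ex, bd_bi, 100, dt = 250)
  expect_equal(ex$right, 59)
})

test_that("a blocked end never blocks the other end", {
  bd <- data.frame(bead = 52L, orientation = "bidirectional")
  set.seed(3)
  # the boundary sits just below the left anchor, so only that end halts
  ex <- single_extruder(53, 56)
  for (s in 1:200) ex <- attempt_translocation(ex, bd, 100, dt = 250)
  expect_equal(ex$left, 53)             # wants 52, blocked
  expect_equal(ex$left_block, "ctcf")
  expect_gt(ex$right, 60)               # right end kept extruding
})

test_that("anchors never cross or share beads, and collisions re-test", {
  set.seed(4)
  p <- extrusion_params(density = 40)   # crowded to force collisions
  r <- run_extrusion(1000, 2000, p, dt = 100, seed = 9)
  expect_true(all(r$extruders$right > r$extruders$left))
  expect_false(any(duplicated(c(r$extruders$left, r$extruders$right))))
  expect_true(any(r$extruders$left_block == "collision" |
                    r$extruders$right_block == "collision") ||
                r$mean_loop_kbp < 25)   # crowded chain -> short loops
})

test_that("turnover keeps the extruder count constant and is off at k_off = 0", {
  set.seed(5)
  ex <- seed_extruders(500, extrusion_params(density = 10))
  frozen <- attempt_unbind_rebind(ex, 500, extrusion_params(k_off = 0), dt = 100)
  expect_identical(frozen$extruders, ex)
  expect_equal(frozen$n_unbound, 0L)
  p <- extrusion_params(k_off = 0.002)
  n_before <- nrow(ex)
  for (s in 1:200) {
    out <- attempt_unbind_rebind(ex, 500, p, dt = 100)
    ex <- out$extruders
    expect_equal(nrow(ex), n_before)
  }
  expect_false(any(duplicated(c(ex$left, ex$right))))
})

test_that("extruder bond lists track the current anchors", {
  expect_equal(nrow(extruder_bonds(single_extruder(10, 13)[0, ])), 0)
  ex <- single_extruder(10, 13)
  expect_equal(extruder_bonds(ex), data.frame(i = 10L, j = 13L))
  bd <- no_boundaries
  set.seed(6)
  ex2 <- attempt_translocation(ex, bd, 100, dt = 250)  # p = 1 per end
  expect_equal(extruder_bonds(ex2), data.frame(i = 9L, j = 14L))
})

test_that("extrusion trajectories are bit-identical under a fixed seed", {
  p <- extrusion_params()
  a <- run_extrusion(800, 500, p, dt = 100, seed = 77, log_every = 50)
  b <- run_extrusion(800, 500, p, dt = 100, seed = 77, log_every = 50)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$extruders, b$extruders)
  log <- tempfile()
  write_extruder_log(a$trajectory, log)
  expect_true(file.exists(log))
})

test_that("convergent boundary capture frequency increases with activation probability", {
  capture_rate <- function(p, nrep = 120) {
    hits <- 0
    for (k in seq_len(nrep)) {
      bd <- if (stats::runif(1) < p)
        data.frame(bead = c(40L, 60L), orientation = c("forward", "backward"))
      else no_boundaries
      ex <- single_extruder(49, 52)
      for (s in 1:150) ex <- attempt_translocation(ex, bd, 100, dt = 100)
      hits <- hits + (ex$left == 41 && ex$right == 59)
    }
    hits / nrep
  }
  set.seed(8)
  rates <- vapply(c(0.25, 0.5, 1.0), capture_rate, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_gt(rates[3], 0.9)
})
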