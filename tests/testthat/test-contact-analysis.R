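# Read sampling, binning, ICE balancing, Pearson and directionality scores.

# translation-invariant exponential-decay map used by several tests
decay_map <- function(n = 80, bin = 10, scale = 10) {
  contact_map(exp(-abs(outer(1:n, 1:n, "-")) / scale), bin_kbp = bin)
}

test_that("read acceptance follows exp(-r/rt)", {
  # two beads at separation rt: acceptance must be 1/e
  two <- structure_ensemble(list(rbind(c(0, 0, 0), c(3.5, 0, 0))))
  m <- sample_reads(two, 3e4, rt = 3.5, seed = 1)
  expect_equal(attr(m, "acceptance_rate"), exp(-1), tolerance = 0.01)
  expect_equal(m$total_reads, 3e4)
  expect_true(isSymmetric(m$counts))
  # zero separation accepts every trial
  zero <- structure_ensemble(list(rbind(c(0, 0, 0), c(1e-12, 0, 0))))
  mz <- sample_reads(zero, 5e3, rt = 3.5, seed = 2)
  expect_equal(attr(mz, "acceptance_rate"), 1, tolerance = 1e-6)
})

test_that("read sampling is unbiased: counts proportional to exp(-r/rt)", {
  # 5 beads on a line; expected pair weights known in closed form
  pos <- cbind(c(0, 1, 2, 4, 7), 0, 0)
  ens <- structure_ensemble(list(pos))
  m <- sample_reads(ens, 4e4, rt = 3.5, seed = 3)
  idx <- which(upper.tri(m$counts), arr.ind = TRUE)
  d <- abs(pos[idx[, 1], 1] - pos[idx[, 2], 1])
  w <- exp(-d / 3.5)
  obs <- m$counts[idx]
  chi <- stats::chisq.test(obs, p = w / sum(w))
  expect_gt(chi$p.value, 0.01)
})

test_that("binning conserves totals exactly and places reads correctly", {
  set.seed(4)
  x <- matrix(rpois(900, 3), 30); x <- x + t(x)
  m <- contact_map(x, bin_kbp = 1)
  b <- bin_map(m, 10)
  expect_equal(sum(b$counts), sum(m$counts))
  expect_equal(dim(b$counts), c(3, 3))
  expect_identical(bin_map(m, 1)$counts, m$counts)
  # a single off-diagonal read at (3 kbp, 27 kbp) lands in 10-kbp bins (0, 2)
  y <- matrix(0, 30, 30); y[4, 28] <- 1; y[28, 4] <- 1
  b2 <- bin_map(contact_map(y), 10)
  expect_equal(b2$counts[1, 3], 1)
  expect_equal(b2$counts[3, 1], 1)
  expect_equal(sum(b2$counts), 2)
  expect_error(bin_map(b, 25), "multiple")
})

test_that("ICE balancing equalizes marginals and masks empty bins", {
  # all-equal matrix is already balanced
  flat <- contact_map(matrix(1, 4, 4))
  expect_equal(ice_normalize(flat)$counts / ice_normalize(flat)$counts[1, 1],
               matrix(1, 4, 4))
  set.seed(5)
  x <- matrix(rpois(400, 5) + 1, 20); x <- x + t(x)
  iced <- ice_normalize(contact_map(x))
  rs <- rowSums(iced$counts)
  expect_lt(stats::sd(rs) / mean(rs), 1e-6)
  expect_equal(iced$normalization, "ICE")
  # a zero row is masked and left untouched
  x2 <- x; x2[7, ] <- 0; x2[, 7] <- 0
  iced2 <- ice_normalize(contact_map(x2))
  expect_true(iced2$mask[7])
  rs2 <- rowSums(iced2$counts)[-7]
  expect_lt(stats::sd(rs2) / mean(rs2), 1e-6)
})

test_that("map correlation behaves at the identity, anti-pattern and null", {
  m <- decay_map()
  expect_equal(map_correlation(m, m)$r, 1)
  anti <- contact_map(max(m$counts) - m$counts + 0.01, bin_kbp = m$bin_kbp)
  expect_lt(map_correlation(m, anti)$r, 0)
  set.seed(6)
  a <- matrix(rpois(2500, 4), 50); a <- a + t(a)
  b <- matrix(rpois(2500, 4), 50); b <- b + t(b)
  null <- map_correlation(contact_map(a), contact_map(b))
  expect_lt(abs(null$r), 0.1)
  tiny <- contact_map(matrix(1, 2, 2))
  expect_error(map_correlation(tiny, tiny), "3 paired bins")
})

test_that("directionality score vanishes on translation-invariant maps", {
  D <- directionality_score(decay_map(), lower = 20, upper = 200)
  expect_true(all(abs(D[!attr(D, "edge")]) < 1e-10))
  expect_error(directionality_score(decay_map(n = 3), lower = 20, upper = 200),
               "shorter")
})

test_that("directionality sign convention: domain edges bias D left and right", {
  n <- 60
  x <- matrix(0.01, n, n)
  x[20:36, 20:36] <- 5          # one dense self-interacting domain
  m <- contact_map((x + t(x)) / 2, bin_kbp = 10)
  D <- directionality_score(m, lower = 20, upper = 200)
  # bins near the right edge of the domain see their contacts on the left
  expect_true(all(D[30:36] > 0))
  # bins near the left edge see them on the right
  expect_true(all(D[20:26] < 0))
})

test_that("directionality is antisymmetric under map reflection", {
  set.seed(7)
  n <- 60
  x <- matrix(rpois(n * n, 3), n); x <- x + t(x)
  m <- contact_map(x, bin_kbp = 10)
  rev_m <- contact_map(x[n:1, n:1], bin_kbp = 10)
  D <- directionality_score(m, 20, 200)
  Dr <- directionality_score(rev_m, 20, 200)
  expect_equal(as.numeric(D), -rev(as.numeric(Dr)), tolerance = 1e-12)
  # D-profile correlation: 1 against itself; against the mirror it equals
  # -cor(D, rev(D)) by the reflection identity above
  expect_equal(directionality_correlation(m, m, 20, 200)$r, 1)
  keep <- !attr(D, "edge")
  expect_equal(directionality_correlation(m, rev_m, 20, 200)$r,
               -stats::cor(as.numeric(D)[keep], rev(as.numeric(D))[keep]),
               tolerance = 1e-12)
  # independent random maps give near-zero D correlation
  y <- matrix(rpois(n * n, 3), n); y <- y + t(y)
  expect_lt(abs(directionality_correlation(m, contact_map(y, bin_kbp = 10),
                                           20, 200)$r), 0.5)
})

test_that("contact maps round-trip through the dense TSV format", {
  m <- decay_map(n = 12)
  f <- tempfile(fileext = ".tsv")
  write_contact_map(m, f)
  m2 <- read_contact_map(f)
  expect_equal(m2$counts, m$counts, tolerance = 1e-12)
  expect_equal(m2$bin_kbp, m$bin_kbp)
  expect_equal(m2$normalization, m$normalization)
})
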