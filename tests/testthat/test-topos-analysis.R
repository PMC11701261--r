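# Partner/influential calling, topos extents, network catalogs, diversity.

plan_matrix <- function(n_structures, candidates, setter) {
  m <- matrix(FALSE, n_structures, length(candidates),
              dimnames = list(NULL, as.character(candidates)))
  setter(m)
}

test_that("contact frequencies are exact on planned ensembles and monotone in threshold", {
  cm <- plan_matrix(600, c(12, 30), function(m) {
    m[1:60, 1] <- TRUE; m[1:300, 2] <- TRUE; m
  })
  ens <- toy_ensemble(50, promoter_bead = 20, contact_matrix = cm)
  f <- contact_frequency(ens, 20, c(12, 30))
  expect_equal(unname(f), c(0.10, 0.50))
  f_wide <- contact_frequency(ens, 20, c(12, 30), threshold = 20)
  expect_true(all(f_wide >= f))
  expect_error(contact_frequency(structure_ensemble(list()), 1, 2), "empty")
})

test_that("partner and influential thresholds are inclusive at the boundary", {
  f <- c(`5` = 60 / 600, `6` = 59 / 600, `7` = 300 / 600, `8` = 299 / 600)
  expect_equal(call_partners(f), c(5, 7, 8))        # 0.0983 excluded
  expect_equal(call_influential(f), 7)              # exactly 50% included
  expect_length(call_partners(numeric()), 0)
  # influential is always a subset of partners
  expect_true(all(call_influential(f) %in% call_partners(f)))
})

test_that("topos extents span promoter and partners inclusively", {
  fr <- genome_fragment("chrT", 0, 400000)
  e <- topos_extent(200, c(100, 300), fr)
  expect_equal(e$size_kbp, 201)
  expect_equal(e$start, 100000)
  expect_equal(e$end, 301000)
  expect_equal(topos_extent(200, c(300, 100), fr)$size_kbp, 201)  # order-free
  expect_equal(topos_extent(200, integer(), fr)$size_kbp, 1)      # degenerate
})

test_that("network catalogs match a brute-force recount and respect 2^q", {
  set.seed(1)
  cand <- c(3, 9, 15)
  cm <- plan_matrix(20, cand, function(m) { m[] <- runif(60) < 0.4; m })
  ens <- toy_ensemble(25, 12, cm)
  catalog <- enumerate_networks(ens, 12, cand)
  # independent oracle: recount subsets directly from the raw coordinates
  brute <- brute_force_networks(ens, 12, cand)
  expect_catalog_matches_brute(catalog, brute)
  expect_lte(nrow(catalog), 2^3)
  expect_equal(sum(catalog$fraction), 1)
  # all structures identical -> a single network
  cm_const <- plan_matrix(10, cand, function(m) { m[, 1] <- TRUE; m })
  expect_equal(nrow(enumerate_networks(toy_ensemble(25, 12, cm_const), 12, cand)), 1)
})

test_that("diversity is the (q+1)-normalized Shannon entropy with exact worked values", {
  one <- data.frame(network = "a", count = 10, fraction = 1)
  expect_equal(diversity_score(one, q = 2), 0)
  expect_equal(diversity_score(one, q = 0), 0)      # well-defined at q = 0
  four <- data.frame(network = letters[1:4], count = 25, fraction = 0.25)
  expect_equal(diversity_score(four, q = 3), log(4) / 4, tolerance = 1e-12)
  bad <- data.frame(network = "a", count = 1, fraction = 0.7)
  expect_error(diversity_score(bad, q = 1), "sum to 1")
})

test_that("uniform occupancy of all 2^q subsets gives entropy q ln 2", {
  for (q in 1:3) {
    n <- 2^q
    cat_q <- data.frame(network = as.character(seq_len(n)), count = 1,
                        fraction = 1 / n)
    s <- diversity_score(cat_q, q) * (q + 1)
    expect_equal(s, q * log(2), tolerance = 1e-12)
    # upper bound: H <= ln(min(2^q, n_structures)) / (q+1), attained only here
    expect_lte(diversity_score(cat_q, q), log(n) / (q + 1) + 1e-12)
    skew <- data.frame(network = as.character(seq_len(n)), count = 1,
                       fraction = c(1 - 0.1 * (n - 1), rep(0.1, n - 1)))
    if (n > 1) expect_lt(diversity_score(skew, q), log(n) / (q + 1))
  }
})

test_that("per-promoter reports assemble frequencies, sets, extent and diversity", {
  fr <- genome_fragment("chrT", 0, 50000)
  track <- make_track(50, atac_kbp = c(10, 20, 30, 40))
  track$promoter[21] <- TRUE                 # bead 20, also an ATAC bead
  cm <- plan_matrix(100, c(10, 30, 40), function(m) {
    m[1:80, 1] <- TRUE; m[1:30, 2] <- TRUE; m[1:5, 3] <- TRUE; m
  })
  ens <- toy_ensemble(50, 20, cm, track = track)
  rep1 <- topos_report(ens, 20, gene = "G")
  expect_equal(sort(rep1$partners), c(10, 30))
  expect_equal(rep1$influential, 10)
  expect_equal(rep1$q, 2)
  expect_equal(rep1$extent$size_kbp, 21)     # beads 10..30
  expect_true(all(rep1$influential %in% rep1$partners))
  expect_equal(sum(rep1$catalog$fraction), 1)
  out <- export_topos_reports(list(rep1), fr, tempfile())
  expect_true(file.exists(out))
})

test_that("diversity correlates with the influential share when planted", {
  set.seed(2)
  fake_report <- function(H, q, n_inf, gene)
    structure(list(gene = gene, q = q, influential = seq_len(n_inf),
                   diversity = H), class = "topos_report")
  n <- 40
  pct <- stats::runif(n, 10, 90)
  q <- sample(4:10, n, replace = TRUE)
  n_inf <- pmax(1, pmin(q - 1, round(q * pct / 100)))
  H <- 0.004 * (100 * n_inf / q) + stats::rnorm(n, sd = 0.03)
  reports <- lapply(seq_len(n), function(i)
    fake_report(H[i], q[i], n_inf[i], paste0("g", i)))
  res <- diversity_vs_influential(reports)
  expect_gt(res$overall$rho, 0)
  expect_lt(res$overall$p, 0.05)
  # permuting H destroys the association
  perm <- lapply(seq_len(n), function(i)
    fake_report(sample(H)[i], q[i], n_inf[i], paste0("g", i)))
  res_p <- diversity_vs_influential(perm)
  expect_lt(abs(res_p$overall$rho), 0.45)
  # degenerate (constant H) flagged rather than crashing
  const <- lapply(seq_len(n), function(i)
    fake_report(0.5, q[i], n_inf[i], paste0("g", i)))
  expect_true(diversity_vs_influential(const)$overall$degenerate)
  expect_error(diversity_vs_influential(reports[1:3]), "fewer than 10")
})
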