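# Shared builders for the test suite. Everything is generated in code; no
# stored fixtures.

# peak data.frame in the parse_peak_file output shape
peaks_df <- function(chrom, start, end, score = 0, strand = ".") {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = start, end = end,
             score = rep_len(score, n), strand = rep_len(strand, n),
             stringsAsFactors = FALSE)
}

# a small annotated track built through the public annotation API
make_track <- function(n_kbp = 60, atac_kbp = integer(), h3k27ac_kbp = integer(),
                       h3k27me3_kbp = integer(), h3k9me3_kbp = integer()) {
  fr <- genome_fragment("chrT", 0, n_kbp * 1000)
  mk <- function(kbp) if (length(kbp))
    peaks_df("chrT", kbp * 1000, (kbp + 1) * 1000) else
      peaks_df(character(), numeric(), numeric())
  annotate_marks(fr, list(atac = mk(atac_kbp), h3k27ac = mk(h3k27ac_kbp),
                          h3k27me3 = mk(h3k27me3_kbp),
                          h3k9me3 = mk(h3k9me3_kbp)))
}

# equilibrated phantom chain state (connectivity + bending only)
phantom_state <- function(n, seed = 1) {
  set.seed(seed)
  md_state(sample_kp_chain(n), box = rep(4 * n, 3), periodic = TRUE,
           nb_mode = "off", bonded_wca = TRUE,
           fene_bonds = cbind(0:(n - 2), 1:(n - 1)),
           angles = cbind(0:(n - 3), 1:(n - 2), 2:(n - 1)))
}

# mean bond-vector correlations over sampled frames
bond_correlations <- function(state, frames, steps_per_frame, smax,
                              seed = 99) {
  cors <- matrix(0, frames, smax)
  for (k in seq_len(frames)) {
    state <- integrate_md(state, steps_per_frame, seed = seed * 1e4 + k)
    b <- diff(state$pos)
    b <- b / sqrt(rowSums(b^2))
    cors[k, ] <- vapply(1:smax, function(s)
      mean(rowSums(b[1:(nrow(b) - s), , drop = FALSE] *
                     b[(1 + s):nrow(b), , drop = FALSE])), numeric(1))
  }
  colMeans(cors)
}

decay_length <- function(m) {
  s <- seq_along(m)
  -1 / unname(stats::coef(stats::lm(log(m) ~ s))[2])
}

# independent subset recount used against enumerate_networks
brute_force_networks <- function(ens, promoter_bead, candidates) {
  table(vapply(ens$frames, function(p) {
    d <- sqrt(rowSums(sweep(p[candidates + 1, , drop = FALSE], 2,
                            p[promoter_bead + 1, ])^2))
    paste(candidates[d < 3.5], collapse = ",")
  }, character(1)))
}

expect_catalog_matches_brute <- function(catalog, brute) {
  bn <- names(brute)
  testthat::expect_setequal(catalog$network, bn)
  ord_c <- order(catalog$network)
  ord_b <- order(bn)
  testthat::expect_equal(catalog$count[ord_c], as.integer(brute)[ord_b])
}

# mean count of active proteins within `cutoff` of a 20-bead block, with or
# without ATAC marks on the block; used by the bridging-induced attraction
# tests
bridging_block_count <- function(marked, seed, n = 60, ntf = 20,
                                 equil_steps = 15000, n_samples = 20) {
  set.seed(seed)
  track <- make_track(n, atac_kbp = if (marked) 20:39 else integer())
  ts <- chromotopos:::.build_type_system(track)
  L <- box_from_density(n)
  pos <- sample_kp_chain(n, bond = 0.97)
  pos <- pos - matrix(colMeans(pos), n, 3, byrow = TRUE)
  tfpos <- matrix((stats::runif(ntf * 3) - 0.5) * L, ncol = 3)
  type <- c(ts$chrom_type, rep(ts$protein_type("active", TRUE), ntf))
  st <- md_state(rbind(pos, tfpos), box = c(L, L, L), type = type,
                 eps = chromotopos:::.eps_variant(ts, TRUE, TRUE),
                 fene_bonds = cbind(0:(n - 2), 1:(n - 1)),
                 angles = cbind(0:(n - 3), 1:(n - 2), 2:(n - 1)),
                 nb_mode = "soft", soft_a = 10, n_chromatin = n)
  for (a in c(50, 150, 300, 500)) {  # push-off before switching on WCA/LJ
    st$soft_a <- a
    st <- integrate_md(st, 400, seed = seed * 17 + a)
  }
  st$nb_mode <- "lj"
  st <- integrate_md(st, equil_steps, seed = seed + 3)
  total <- 0
  for (k in seq_len(n_samples)) {
    st <- integrate_md(st, 1000, seed = seed * 1000 + k)
    block <- st$pos[21:40, , drop = FALSE]
    tfp <- st$pos[(n + 1):(n + ntf), , drop = FALSE]
    for (t in seq_len(ntf)) {
      d <- sweep(block, 2, tfp[t, ])
      for (kk in 1:3) d[, kk] <- d[, kk] - L * round(d[, kk] / L)
      if (min(sqrt(rowSums(d^2))) < 2) total <- total + 1
    }
  }
  total / n_samples
}

# secular energy drift of an NVE FENE dimer, normalized to a 1e4-step
# horizon; the linear fit over many samples separates true drift from the
# bounded O(dt^2) oscillation of the velocity-Verlet shadow energy
nve_drift <- function(n_samples = 300, steps_per = 100) {
  st <- md_state(pos = rbind(c(0, 0, 0), c(1.1, 0, 0)),
                 vel = rbind(c(0.3, 0.2, 0), c(-0.3, -0.2, 0.1)),
                 box = c(20, 20, 20), nb_mode = "off", fene_bonds = cbind(0, 1))
  es <- numeric(n_samples)
  for (k in seq_len(n_samples)) {
    st <- integrate_md(st, steps_per, thermostat = FALSE, seed = k)
    es[k] <- total_energy(st)$total
  }
  slope <- stats::coef(stats::lm(es ~ seq_along(es)))[2]
  abs(slope * (1e4 / steps_per)) / abs(mean(es))
}

# relaxes a half-crumpled chain and returns the mean (i, i+2) spacing in the
# crumpled and the acetylated (open) halves; the crumple springs are ramped
# in during the soft push-off so the quench cannot overstretch the backbone
heteromorphic_gaps <- function(seed = 9, n = 60) {
  set.seed(seed)
  track <- make_track(n, h3k27ac_kbp = (n / 2):(n - 1))
  ff <- force_field_params()
  crumple <- chromotopos:::.crumple_bonds(track$h3k27ac, ff)
  st <- md_state(init_rosette(n, 10)$pos, box = c(12, 12, 12),
                 fene_bonds = cbind(0:(n - 2), 1:(n - 1)),
                 angles = cbind(0:(n - 3), 1:(n - 2), 2:(n - 1)),
                 nb_mode = "soft", soft_a = 20)
  for (frac in seq(0.1, 1, by = 0.1)) {   # joint push-off + crumple ramp
    ramped <- crumple
    ramped$k <- frac * ff$crumple_k
    st$harm_bonds <- ramped
    st$soft_a <- 300 * frac
    st <- integrate_md(st, 300, seed = seed * 31 + round(100 * frac))
  }
  st$nb_mode <- "lj"
  st <- integrate_md(st, 10000, seed = seed + 1)
  crumpled <- c(); open <- c()
  for (k in 1:20) {
    st <- integrate_md(st, 500, seed = seed * 100 + k)
    d2 <- sqrt(rowSums((st$pos[3:n, ] - st$pos[1:(n - 2), ])^2))
    crumpled <- c(crumpled, d2[1:(n / 2 - 4)])
    open <- c(open, d2[(n / 2 + 1):(n - 2)])
  }
  c(crumpled = mean(crumpled), open = mean(open))
}

# synth -> annotate -> simulate at desk scale; returns the ensemble
toy_pipeline_ensemble <- function(seed, desk_scale = 0.01, dir = tempfile()) {
  files <- synth_epigenome(synthetic_locus(seed = seed), dir)
  track <- annotate_locus(files, files$fragment)
  run_protocol(track, seed = seed, desk_scale = desk_scale)
}
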