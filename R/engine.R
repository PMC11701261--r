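#' Periodic box side from a chromatin density target
#'
#' The fragment is simulated in a periodic cube of side `L` such that the
#' chromatin density matches a nuclear value (default 6.5 Mbp per cubic
#' micron, i.e. ~6.5 Gbp in a ~10 um diploid nucleus). The physical bead
#' size enters only here and in FISH conversions.
#'
#' @param kbp fragment length in kbp.
#' @param density_mbp_um3 target density in Mbp per cubic micron.
#' @param sigma_nm physical bead size in nm.
#' @return cube side in sigma.
#' @export
box_from_density <- function(kbp, density_mbp_um3 = 6.5, sigma_nm = 25) {
  stopifnot(kbp > 0, density_mbp_um3 > 0, sigma_nm > 0)
  sigma_um <- sigma_nm * 1e-3
  (kbp / (density_mbp_um3 * sigma_um^3 * 1e3))^(1 / 3)
}

#' Chromatin density implied by a box
#' @param kbp fragment length in kbp.
#' @param box_sigma cube side in sigma.
#' @param sigma_nm physical bead size in nm.
#' @return density in Mbp per cubic micron.
#' @export
density_from_box <- function(kbp, box_sigma, sigma_nm = 25) {
  sigma_um <- sigma_nm * 1e-3
  (kbp * 1e-3) / (box_sigma * sigma_um)^3
}

#' Multivalent protein population
#'
#' The total protein count is 10% of the chromatin bead count, split
#' between species in the ratio active : polycomb : HP1 = 1/4 : 1/8 : 5/8.
#' Counts are floored per species with the remainder assigned to HP1 (the
#' largest share). Each protein switches between a binding and a
#' non-binding state at rate `ksw`.
#'
#' @param n_chromatin number of chromatin beads.
#' @param fraction protein beads as a fraction of chromatin beads.
#' @param ratio named species ratio (must sum to 1).
#' @param ksw switching rate in 1/tau.
#' @return object of class `tf_population` with per-species counts.
#' @export
tf_population <- function(n_chromatin, fraction = 0.10,
                          ratio = c(active = 1/4, polycomb = 1/8, hp1 = 5/8),
                          ksw = 1e-3) {
  stopifnot(abs(sum(ratio) - 1) < 1e-9, all(names(ratio) %in% protein_species()))
  total <- round(fraction * n_chromatin)
  counts <- floor(ratio * total)
  counts["hp1"] <- counts["hp1"] + (total - sum(counts))
  structure(list(counts = counts, total = total, ksw = ksw,
                 fraction = fraction, ratio = ratio),
            class = "tf_population")
}

#' Flip protein binding states stochastically
#'
#' Each protein flips between binding and non-binding with probability
#' `ksw * dt` per sweep (symmetric rates, so the stationary bound fraction
#' is 1/2).
#'
#' @param binding logical vector of current states.
#' @param ksw switching rate (1/tau).
#' @param dt sweep interval (tau); `ksw * dt` must be << 1.
#' @return updated logical vector.
#' @export
switch_tf_states <- function(binding, ksw, dt) {
  flip <- stats::runif(length(binding)) < ksw * dt
  xor(binding, flip)
}

#' Mitotic-like rosette initial conformation
#'
#' Builds the chain as a stack of rosettes around the z axis of the box: a
#' parametric petal curve (radial lobes with a slowly rotating petal
#' direction and a constant axial rise) resampled to uniform bead spacing.
#' The conformation is self-overlap tolerant (it is relaxed under a soft
#' potential) and fits a parallelepiped with equal x and y sides and a
#' longer height.
#'
#' @param n_beads chain length.
#' @param box_xy side of the box in x and y (sigma).
#' @param spacing target consecutive-bead spacing (sigma).
#' @param petals_per_turn how many petals per full rotation of the petal
#'   direction.
#' @return list with `pos` (n x 3 matrix, centred on the box axis) and
#'   `height` (required z extent in sigma).
#' @export
init_rosette <- function(n_beads, box_xy, spacing = 1.1, petals_per_turn = 8) {
  if (n_beads < 10) stop("need at least 10 beads")
  radius <- 0.35 * box_xy
  if (radius < 1) stop("box too small for a rosette of this chain")
  contour <- n_beads * spacing
  # one petal: rho = R sin(pi u), u in [0,1]; measure its length numerically
  petal_len <- function(rise) {
    u <- seq(0, 1, length.out = 201)
    p <- .rosette_point(u, radius, petals_per_turn, rise)
    sum(sqrt(rowSums(diff(p)^2)))
  }
  rise <- 1.0
  n_pet <- max(1, 1.5 * contour / petal_len(rise))
  u <- seq(0, n_pet, length.out = max(2000, ceiling(100 * contour)))
  fine <- .rosette_point(u, radius, petals_per_turn, rise)
  # greedy chord-length resampling: petals pass through the axis, where
  # arc-length spacing would give short chords on the doubled-back path
  pos <- matrix(NA_real_, n_beads, 3)
  pos[1, ] <- fine[1, ]
  k <- 1L
  for (b in 2:n_beads) {
    if (k >= nrow(fine)) stop("box too small for a rosette of this chain")
    win <- (k + 1):min(k + 5000, nrow(fine))
    d2 <- (fine[win, 1] - pos[b - 1, 1])^2 + (fine[win, 2] - pos[b - 1, 2])^2 +
      (fine[win, 3] - pos[b - 1, 3])^2
    nxt <- which(d2 >= spacing^2)
    if (!length(nxt)) stop("box too small for a rosette of this chain")
    k <- win[nxt[1]]
    pos[b, ] <- fine[k, ]
  }
  pos[, 1] <- pos[, 1] - mean(pos[, 1])
  pos[, 2] <- pos[, 2] - mean(pos[, 2])
  pos[, 3] <- pos[, 3] - mean(pos[, 3])
  list(pos = pos, height = diff(range(pos[, 3])) + 2)
}

#' Equilibrium conformation of a Kratky-Porod phantom chain
#'
#' Draws a chain directly from the bending-energy Boltzmann distribution:
#' each successive bond direction is tilted from the previous one by an
#' angle with density proportional to \eqn{\sin\theta\,e^{K\cos\theta}}
#' (K = lp/sigma), with uniform azimuth, using inverse-CDF sampling of
#' cos(theta). Used to initialize phantom-chain runs at equilibrium so
#' dynamics only needs to decorrelate, not to relax a global conformation.
#'
#' @param n_beads chain length.
#' @param lp bending stiffness parameter in sigma.
#' @param bond bond length in sigma.
#' @return n x 3 position matrix.
#' @export
sample_kp_chain <- function(n_beads, lp = 4, bond = 0.97) {
  u <- stats::runif(n_beads - 2)
  # inverse CDF of cos(theta) ~ exp(K cos) on [-1, 1]
  cos_t <- log(exp(-lp) + u * (exp(lp) - exp(-lp))) / lp
  sin_t <- sqrt(pmax(0, 1 - cos_t^2))
  phi <- stats::runif(n_beads - 2, 0, 2 * pi)
  dirs <- matrix(0, n_beads - 1, 3)
  dirs[1, ] <- c(0, 0, 1)
  for (b in 2:(n_beads - 1)) {
    d <- dirs[b - 1, ]
    # orthonormal frame around d
    a <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- a - sum(a * d) * d; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3],
            d[1] * e1[2] - d[2] * e1[1])
    dirs[b, ] <- cos_t[b - 1] * d +
      sin_t[b - 1] * (cos(phi[b - 1]) * e1 + sin(phi[b - 1]) * e2)
  }
  pos <- rbind(c(0, 0, 0), apply(dirs * bond, 2, cumsum))
  pos
}

.rosette_point <- function(u, radius, petals_per_turn, rise) {
  rho <- radius * abs(sin(pi * (u %% 1)))
  theta <- 2 * pi * floor(u) / petals_per_turn + 0.35 * pi * (u %% 1)
  cbind(rho * cos(theta), rho * sin(theta), rise * u)
}

#' Build a molecular-dynamics system state
#'
#' Positions are unwrapped (never folded into the box); the minimum-image
#' convention is applied to nonbonded pair vectors during integration, so
#' bonds, angles and centre-of-mass measurements always use real-space
#' coordinates. All bead indices in bond/angle tables are 0-based, matching
#' the bead grid of [annotate_marks()].
#'
#' @param pos n x 3 position matrix (sigma).
#' @param vel n x 3 velocity matrix; `NULL` draws Maxwell-Boltzmann
#'   velocities at `temperature`.
#' @param box length-3 box dimensions (sigma).
#' @param periodic logical; when `FALSE`, soft repulsive walls confine the
#'   system if `walls = TRUE`.
#' @param type integer type index per bead (0-based row of `eps`).
#' @param eps symmetric type-by-type well-depth matrix (kBT); 0 entries are
#'   purely steric (WCA), positive entries attract via the truncated-shifted
#'   Lennard-Jones potential.
#' @param fene_bonds two-column matrix/data.frame of 0-based bead pairs.
#' @param harm_bonds data.frame `(i, j, k, r0)` of harmonic bonds.
#' @param angles three-column matrix/data.frame of 0-based bead triplets.
#' @param nb_mode `"lj"` (eps matrix), `"soft"` (bounded push-off), or
#'   `"off"`.
#' @param soft_a soft-potential amplitude (kBT) when `nb_mode = "soft"`.
#' @param bonded_wca apply the excluded-volume (WCA) term to FENE-bonded
#'   pairs even when `nb_mode = "off"` (used for phantom chains, where
#'   non-neighbour excluded volume is dropped but the bond keeps its
#'   standard repulsive core).
#' @param walls,wall_a soft-wall switch and amplitude for non-periodic runs.
#' @param units a [simulation_units()].
#' @param ff a [force_field_params()].
#' @param n_chromatin how many leading beads are chromatin (the rest are
#'   proteins).
#' @param temperature thermostat temperature in kBT.
#' @return an object of class `md_state`.
#' @export
md_state <- function(pos, vel = NULL, box, periodic = TRUE,
                     type = integer(nrow(pos)),
                     eps = matrix(0, max(type) + 1, max(type) + 1),
                     fene_bonds = NULL, harm_bonds = NULL, angles = NULL,
                     nb_mode = c("lj", "soft", "off"), soft_a = 0,
                     bonded_wca = FALSE, walls = FALSE, wall_a = 50,
                     units = simulation_units(), ff = force_field_params(),
                     n_chromatin = nrow(pos), temperature = 1) {
  nb_mode <- match.arg(nb_mode)
  pos <- as.matrix(pos)
  stopifnot(ncol(pos) == 3, length(box) == 3, length(type) == nrow(pos))
  if (is.null(vel))
    vel <- matrix(stats::rnorm(3 * nrow(pos),
                               sd = sqrt(temperature / units$mass)), ncol = 3)
  structure(list(pos = pos, vel = as.matrix(vel), box = as.numeric(box),
                 periodic = periodic, type = as.integer(type), eps = eps,
                 fene_bonds = .as_bond_matrix(fene_bonds, 2),
                 harm_bonds = .as_harm(harm_bonds),
                 angles = .as_bond_matrix(angles, 3),
                 nb_mode = nb_mode, soft_a = soft_a, bonded_wca = bonded_wca,
                 walls = walls, wall_a = wall_a,
                 units = units, ff = ff, n_chromatin = n_chromatin,
                 temperature = temperature, clock = 0),
            class = "md_state")
}

.as_bond_matrix <- function(x, k) {
  if (is.null(x) || !NROW(x)) return(matrix(integer(), 0, k))
  m <- as.matrix(as.data.frame(x)[, 1:k])
  storage.mode(m) <- "integer"
  m
}
.as_harm <- function(x) {
  if (is.null(x) || !NROW(x))
    return(data.frame(i = integer(), j = integer(), k = numeric(),
                      r0 = numeric()))
  as.data.frame(x)[, c("i", "j", "k", "r0")]
}

#' @export
print.md_state <- function(x, ...) {
  cat(sprintf(paste0("md_state: %d beads (%d chromatin) in %s box ",
                     "%.1f x %.1f x %.1f sigma, clock %.1f tau\n"),
              nrow(x$pos), x$n_chromatin,
              if (x$periodic) "periodic" else "walled",
              x$box[1], x$box[2], x$box[3], x$clock))
  invisible(x)
}

#' Advance the system by Langevin (or NVE) dynamics
#'
#' Velocity-Verlet-based BAOAB integration of the Langevin equation at time
#' step `dt`; with `thermostat = FALSE` (and hence no friction or noise) the
#' scheme is plain velocity Verlet and conserves energy, which is the
#' validation mode. Deterministic under a fixed seed. A FENE bond reaching
#' its maximum extension or a non-finite force aborts with a diagnostic
#' carrying the step number.
#'
#' @param state an [md_state()].
#' @param n_steps number of MD steps (`dt` from `state$units$timestep`).
#' @param thermostat logical.
#' @param seed integer seed for the thermostat noise; `NULL` draws one from
#'   the R session RNG.
#' @return the advanced `md_state`.
#' @export
integrate_md <- function(state, n_steps, thermostat = TRUE, seed = NULL) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  u <- state$units
  nbm <- match(state$nb_mode, c("off", "soft", "lj")) - 1L
  ljn <- if (nbm == 2L) lj_normalization(state$ff$tf_cutoff) else 1
  out <- md_run_cpp(state$pos, state$vel, state$box, state$periodic,
                    state$type, state$eps, state$ff$tf_cutoff, ljn,
                    nbm, state$soft_a, state$walls, state$wall_a,
                    isTRUE(state$bonded_wca),
                    state$fene_bonds, state$ff$fene_k, state$ff$fene_r0,
                    .as_bond_matrix(state$harm_bonds, 2),
                    state$harm_bonds$k, state$harm_bonds$r0,
                    state$angles, state$ff$bend_lp,
                    as.integer(n_steps), u$timestep, u$mass,
                    if (thermostat) u$gamma else 0,
                    state$temperature, thermostat, as.numeric(seed))
  state$pos <- out$pos
  state$vel <- out$vel
  state$clock <- state$clock + n_steps * u$timestep
  state
}

#' Total energy of a system state
#' @param state an [md_state()].
#' @return list with `kinetic`, `potential` and `total` energy in kBT.
#' @export
total_energy <- function(state) {
  nbm <- match(state$nb_mode, c("off", "soft", "lj")) - 1L
  ljn <- if (nbm == 2L) lj_normalization(state$ff$tf_cutoff) else 1
  md_energy_cpp(state$pos, state$vel, state$box, state$periodic,
                state$type, state$eps, state$ff$tf_cutoff, ljn,
                nbm, state$soft_a, state$walls, state$wall_a,
                isTRUE(state$bonded_wca),
                state$fene_bonds, state$ff$fene_k, state$ff$fene_r0,
                .as_bond_matrix(state$harm_bonds, 2),
                state$harm_bonds$k, state$harm_bonds$r0,
                state$angles, state$ff$bend_lp, state$units$mass)
}

# ---- type system: map bead marks and protein species to eps-matrix rows ----

# chromatin types = distinct mark combinations present on the fragment;
# protein types = (species, binding state) pairs appended after them.
.build_type_system <- function(track, affinities = affinity_table(),
                               ff = force_field_params()) {
  marks <- as.matrix(as.data.frame(track)[, chromatin_marks()])
  key <- apply(marks, 1, function(r) paste(as.integer(r), collapse = ""))
  combos <- unique(key)
  chrom_type <- match(key, combos) - 1L
  combo_marks <- lapply(combos, function(k)
    chromatin_marks()[strsplit(k, "")[[1]] == "1"])
  species <- protein_species()
  n_ct <- length(combos)
  ntype <- n_ct + 2L * length(species)
  eps <- matrix(0, ntype, ntype)
  for (a in seq_len(n_ct)) for (b in seq_len(n_ct))
    eps[a, b] <- pair_affinity("chromatin", marks = combo_marks[[a]],
                               partner_marks = combo_marks[[b]],
                               table = affinities, params = ff)
  for (s in seq_along(species)) {
    row_on <- n_ct + 2L * (s - 1L) + 1L
    for (a in seq_len(n_ct)) {
      e <- pair_affinity(species[s], TRUE, combo_marks[[a]], affinities, ff)
      eps[row_on, a] <- e
      eps[a, row_on] <- e
    }
  }
  protein_type <- function(s, binding)
    n_ct + 2L * (match(s, species) - 1L) + ifelse(binding, 0L, 1L)  # 0-based
  list(chrom_type = chrom_type, n_chrom_types = n_ct,
       combo_marks = combo_marks, eps_full = eps,
       protein_type = protein_type)
}

# stage-specific eps matrices derived from the full one
.eps_variant <- function(ts, chromatin_attraction = TRUE, tf_attraction = TRUE) {
  eps <- ts$eps_full
  ct <- seq_len(ts$n_chrom_types)
  if (!chromatin_attraction) eps[ct, ct] <- 0
  if (!tf_attraction) {
    pr <- setdiff(seq_len(nrow(eps)), ct)
    eps[pr, ] <- 0; eps[, pr] <- 0
  }
  eps
}

#' Staged initialization and production schedule
#'
#' Durations in tau for each stage of the equilibration/production
#' protocol, all multiplied by one desk-scale factor: rosette relaxation
#' under a ramped soft potential (600, ramp 0-500 kBT, harmonic backbone
#' k = 100 kBT/sigma^2, r0 = 1.1 sigma), slow z compression of the box to a
#' cube (1e4), relaxation with fixed boundaries (5e3) then periodic
#' boundaries (2.5e4), boundary-free loop extrusion to erase the rosette
#' memory (2e4, density 7.5/Mbp), crumple-spring relaxation (1e4), protein
#' equilibration with steric-only interactions (1e3), and production (3e5;
#' chromatin-chromatin attraction on at 1e4, protein-chromatin attraction
#' at 5e4; sampling every 2e3 during the final 1e5; structures retained at
#' 2e5 and 3e5).
#'
#' @param desk_scale scalar multiplying every duration (and the sampling
#'   cadence) proportionally.
#' @return object of class `protocol_schedule`.
#' @export
protocol_schedule <- function(desk_scale = 1) {
  stopifnot(desk_scale > 0)
  s <- list(rosette_relax = 600, soft_max = 500,
            rosette_backbone_k = 100, rosette_backbone_r0 = 1.1,
            box_compression = 1e4, fixed_relax = 5e3, periodic_relax = 2.5e4,
            ctcf_free_extrusion = 2e4, ctcf_free_density = 7.5,
            crumple_relax = 1e4, tf_equilibration = 1e3,
            production = 3e5, chromatin_attr_on = 1e4, tf_attr_on = 5e4,
            sample_every = 2e3, sample_window = 1e5, retain_at = c(2e5, 3e5))
  scale_keys <- c("rosette_relax", "box_compression", "fixed_relax",
                  "periodic_relax", "ctcf_free_extrusion", "crumple_relax",
                  "tf_equilibration", "production", "chromatin_attr_on",
                  "tf_attr_on", "sample_every", "sample_window", "retain_at")
  for (k in scale_keys) s[[k]] <- s[[k]] * desk_scale
  s$desk_scale <- desk_scale
  structure(s, class = "protocol_schedule")
}

# integrate `tau` time units in event-sized chunks, running extrusion/TF
# sweeps and an optional per-chunk callback between chunks
.run_stage <- function(env, tau, extrude = FALSE, switch_tf = FALSE,
                       callback = NULL, sample_from = Inf) {
  dt <- env$state$units$timestep
  chunk_steps <- env$extr$event_interval
  total_steps <- max(1L, round(tau / dt))
  done <- 0L
  t0 <- env$state$clock
  while (done < total_steps) {
    n <- min(chunk_steps, total_steps - done)
    env$state <- integrate_md(env$state, n, thermostat = TRUE,
                              seed = sample.int(.Machine$integer.max, 1))
    done <- done + n
    sweep_dt <- n * dt
    if (extrude && !is.null(env$extruders) && nrow(env$extruders)) {
      env$extruders <- attempt_translocation(env$extruders, env$boundaries,
                                             env$n_beads, env$extr, sweep_dt)
      env$extruders <- attempt_unbind_rebind(env$extruders, env$n_beads,
                                             env$extr, sweep_dt)$extruders
      .sync_extruder_bonds(env)
    }
    if (switch_tf && length(env$tf_binding)) {
      new_binding <- switch_tf_states(env$tf_binding, env$tf$ksw, sweep_dt)
      if (any(new_binding != env$tf_binding)) {
        env$tf_binding <- new_binding
        .sync_tf_types(env)
      }
    }
    if (!is.null(callback)) callback(done / total_steps)
    el <- env$state$clock - t0
    if (is.finite(sample_from) && el >= sample_from) {
      if (is.null(env$next_sample) || env$state$clock >= env$next_sample - 1e-9) {
        env$frames[[length(env$frames) + 1]] <-
          env$state$pos[seq_len(env$n_beads), , drop = FALSE]
        env$frame_times <- c(env$frame_times, env$state$clock)
        env$next_sample <- env$state$clock + env$sched$sample_every
      }
    }
  }
  invisible(NULL)
}

.sync_extruder_bonds <- function(env) {
  hb <- env$harm_static
  if (!is.null(env$extruders) && nrow(env$extruders)) {
    eb <- extruder_bonds(env$extruders)
    hb <- rbind(hb, data.frame(i = eb$i, j = eb$j, k = env$state$ff$extruder_k,
                               r0 = env$state$ff$extruder_r0))
  }
  env$state$harm_bonds <- hb
}

.sync_tf_types <- function(env) {
  if (!length(env$tf_binding)) return(invisible(NULL))
  sp <- env$tf_species
  env$state$type[env$n_beads + seq_along(sp)] <-
    vapply(seq_along(sp), function(i)
      env$ts$protein_type(sp[i], env$tf_binding[i]), integer(1))
  invisible(NULL)
}

#' Run the full staged simulation protocol
#'
#' Executes the heteromorphic-polymer protocol end to end on an annotated
#' fragment: rosette initialization and soft-potential relaxation, box
#' compression, fixed- and periodic-boundary relaxation, boundary-free loop
#' extrusion, crumple-spring relaxation, protein equilibration, then the
#' production run with attraction switch-ons and conformational sampling.
#' Supports the two-tier scheme (`n_relax` relaxed states, each seeding
#' `n_production` production runs with fresh seeds).
#'
#' @param track an annotated [annotate_marks()] bead track (with CTCF and
#'   promoter records if available).
#' @param seed integer master seed; all stage randomness derives from it.
#' @param desk_scale scalar shrinking all stage durations proportionally
#'   (1 = the cluster-scale protocol; everyday desk use is 0.01-0.1).
#' @param n_relax,n_production the two-tier replication counts.
#' @param units,ff,affinities,extr model parameter objects.
#' @param tf a [tf_population()] or `NULL` for the default 10% population.
#' @param schedule a [protocol_schedule()]; its desk scale must match
#'   `desk_scale` (pass either).
#' @param target_density,sigma_nm chromatin density rule for the box.
#' @param verbose print stage progress.
#' @return an object of class `structure_ensemble`: a list of sampled
#'   chromatin conformations (n_beads x 3 matrices, unwrapped coordinates)
#'   with frame metadata, the bead track, box and parameter echo.
#' @export
run_protocol <- function(track, seed = 1, desk_scale = 1,
                         n_relax = 1, n_production = 1,
                         units = simulation_units(),
                         ff = force_field_params(),
                         affinities = affinity_table(),
                         extr = extrusion_params(),
                         tf = NULL,
                         schedule = protocol_schedule(desk_scale),
                         target_density = 6.5, sigma_nm = 25,
                         verbose = FALSE) {
  fragment <- attr(track, "fragment")
  n_beads <- fragment$n_beads
  if (is.null(tf)) tf <- tf_population(n_beads)
  ts <- .build_type_system(track, affinities, ff)
  sched <- schedule
  say <- function(...) if (verbose) message(sprintf(...))

  cube <- box_from_density(n_beads, target_density, sigma_nm)
  all_frames <- list()
  meta <- list()
  set.seed(seed)
  relax_seeds <- sample.int(2^30, n_relax)
  for (r in seq_len(n_relax)) {
    set.seed(relax_seeds[r])
    env <- .relax_tier(track, ts, cube, units, ff, extr, tf, sched, say)
    prod_seeds <- sample.int(2^30, n_production)
    for (p in seq_len(n_production)) {
      set.seed(prod_seeds[p])
      penv <- .clone_env(env)
      .production_tier(penv, track, ts, sched, say)
      all_frames <- c(all_frames, penv$frames)
      if (length(penv$frames))
        meta[[length(meta) + 1]] <- data.frame(
          relax_run = r, production_run = p, time_tau = penv$frame_times,
          retained = vapply(penv$frame_times, function(tt)
            any(abs((tt - penv$prod_start) - sched$retain_at) <
                  sched$sample_every / 2), logical(1)))
    }
  }
  structure_ensemble(all_frames, do.call(rbind, meta), track,
                     box = c(cube, cube, cube),
                     params = list(units = units, ff = ff, extr = extr,
                                   tf = tf, schedule = sched, seed = seed))
}

.clone_env <- function(env) {
  e <- new.env(parent = emptyenv())
  for (nm in ls(env)) assign(nm, get(nm, envir = env), envir = e)
  e
}

# stages 1-8: rosette through end-of-setup; returns the stage environment
.relax_tier <- function(track, ts, cube, units, ff, extr, tf, sched, say) {
  fragment <- attr(track, "fragment")
  n_beads <- fragment$n_beads
  env <- new.env(parent = emptyenv())
  env$n_beads <- n_beads
  env$extr <- extr
  env$tf <- tf
  env$ts <- ts
  env$sched <- sched
  env$frames <- list(); env$frame_times <- numeric()
  env$next_sample <- NULL
  env$extruders <- NULL
  env$boundaries <- data.frame(bead = integer(), orientation = character())
  env$tf_binding <- logical(); env$tf_species <- character()

  ros <- init_rosette(n_beads, cube)
  box0 <- c(cube, cube, max(ros$height, cube))
  backbone <- data.frame(i = 0:(n_beads - 2), j = 1:(n_beads - 1))
  angles <- cbind(0:(n_beads - 3), 1:(n_beads - 2), 2:(n_beads - 1))

  say("stage: rosette relaxation (%g tau)", sched$rosette_relax)
  env$harm_static <- data.frame(i = backbone$i, j = backbone$j,
                                k = sched$rosette_backbone_k,
                                r0 = sched$rosette_backbone_r0)
  env$state <- md_state(ros$pos, box = box0, periodic = FALSE,
                        type = ts$chrom_type, eps = .eps_variant(ts, FALSE, FALSE),
                        harm_bonds = env$harm_static, angles = angles,
                        nb_mode = "soft", soft_a = 0, walls = TRUE,
                        units = units, ff = ff, n_chromatin = n_beads)
  n_ramp <- 10
  for (k in seq_len(n_ramp)) {
    env$state$soft_a <- sched$soft_max * k / n_ramp
    .run_stage(env, sched$rosette_relax / n_ramp)
  }

  say("stage: box compression to cube (%g tau)", sched$box_compression)
  env$harm_static <- .as_harm(NULL)
  env$state$harm_bonds <- env$harm_static
  env$state$fene_bonds <- .as_bond_matrix(backbone, 2)
  env$state$nb_mode <- "lj"            # all-zero eps => pure WCA
  n_cmp <- 50
  z_path <- seq(box0[3], cube, length.out = n_cmp + 1)[-1]
  for (k in seq_len(n_cmp)) {
    scalef <- z_path[k] / env$state$box[3]
    env$state$box[3] <- z_path[k]
    env$state$pos[, 3] <- env$state$pos[, 3] * scalef
    .run_stage(env, sched$box_compression / n_cmp)
  }

  say("stage: fixed-boundary relaxation (%g tau)", sched$fixed_relax)
  .run_stage(env, sched$fixed_relax)

  say("stage: periodic relaxation (%g tau)", sched$periodic_relax)
  env$state$periodic <- TRUE
  env$state$walls <- FALSE
  .run_stage(env, sched$periodic_relax)

  say("stage: boundary-free extrusion (%g tau)", sched$ctcf_free_extrusion)
  pre_extr <- extrusion_params(density = sched$ctcf_free_density,
                               v_extr = extr$v_extr, k_off = extr$k_off,
                               event_interval = extr$event_interval)
  env$extruders <- seed_extruders(n_beads, pre_extr)
  .sync_extruder_bonds(env)
  .run_stage(env, sched$ctcf_free_extrusion, extrude = TRUE)

  say("stage: crumple relaxation (%g tau)", sched$crumple_relax)
  # top up extruders to the production density and activate CTCF boundaries
  n_target <- round(extr$density * n_beads / 1000)
  while (nrow(env$extruders) < n_target) {
    occ <- .anchor_beads(env$extruders)
    pos <- .load_position(n_beads, occ)
    env$extruders <- rbind(env$extruders,
                           data.frame(id = nrow(env$extruders) + 1,
                                      left = pos, right = pos + 3L,
                                      left_block = "none", right_block = "none"))
  }
  env$boundaries <- sample_ctcf_activation(track)
  # crumple the whole fiber; the spring constant is ramped in over the first
  # half of the stage so the quench does not overstretch backbone bonds
  full_crumple <- .crumple_bonds(rep(FALSE, n_beads), ff)
  n_ramp <- 10
  for (step in seq_len(n_ramp)) {
    ramped <- full_crumple
    ramped$k <- (step / n_ramp) * ff$crumple_k
    env$harm_static <- ramped
    .sync_extruder_bonds(env)
    .run_stage(env, sched$crumple_relax / (2 * n_ramp), extrude = TRUE)
  }
  env$harm_static <- full_crumple
  .sync_extruder_bonds(env)
  .run_stage(env, sched$crumple_relax / 2, extrude = TRUE)

  say("stage: protein equilibration (%g tau)", sched$tf_equilibration)
  .insert_tfs(env, tf, ts)
  env$state$eps <- .eps_variant(ts, FALSE, FALSE)   # steric only
  .run_stage(env, sched$tf_equilibration, extrude = TRUE, switch_tf = TRUE)

  # end of setup: open acetylated regions
  env$harm_static <- .crumple_bonds(track$h3k27ac, ff)
  .sync_extruder_bonds(env)
  env
}

# crumple springs on (i, i+2) kept only where none of i, i+1, i+2 is acetylated
.crumple_bonds <- function(h3k27ac, ff) {
  n <- length(h3k27ac)
  i <- 0:(n - 3)
  keep <- !(h3k27ac[i + 1] | h3k27ac[i + 2] | h3k27ac[i + 3])
  data.frame(i = i[keep], j = i[keep] + 2L, k = ff$crumple_k,
             r0 = ff$crumple_r0)
}

# proteins placed uniformly in the box, rejecting overlaps below 0.9 sigma
.insert_tfs <- function(env, tf, ts) {
  counts <- tf$counts
  species <- rep(names(counts), counts)
  if (!length(species)) return(invisible(NULL))
  box <- env$state$box
  old <- env$state$pos
  new_pos <- matrix(NA_real_, length(species), 3)
  placed <- 0
  tries <- 0
  while (placed < length(species)) {
    tries <- tries + 1
    if (tries > 10000 * length(species)) stop("could not place protein beads")
    cand <- (stats::runif(3) - 0.5) * box
    d2 <- .min_image_d2(rbind(old, new_pos[seq_len(placed), , drop = FALSE]),
                        cand, box)
    if (min(d2) > 0.81) {
      placed <- placed + 1
      new_pos[placed, ] <- cand
    }
  }
  binding <- stats::runif(length(species)) < 0.5
  env$tf_species <- species
  env$tf_binding <- binding
  env$state$pos <- rbind(env$state$pos, new_pos)
  env$state$vel <- rbind(env$state$vel,
                         matrix(stats::rnorm(3 * length(species),
                                             sd = sqrt(env$state$temperature /
                                                       env$state$units$mass)),
                                ncol = 3))
  env$state$type <- c(env$state$type,
                      vapply(seq_along(species), function(i)
                        ts$protein_type(species[i], binding[i]), integer(1)))
  invisible(NULL)
}

.min_image_d2 <- function(mat, p, box) {
  d <- sweep(mat, 2, p)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  rowSums(d * d)
}

# stage 9: production with attraction switch-ons and sampling
.production_tier <- function(env, track, ts, sched, say) {
  say("stage: production (%g tau)", sched$production)
  env$prod_start <- env$state$clock
  # cell-to-cell CTCF variability: each production run resamples its boundaries
  env$boundaries <- sample_ctcf_activation(track)
  P <- sched$production
  t1 <- min(sched$chromatin_attr_on, P)
  t2 <- min(sched$tf_attr_on, P)
  sample_from <- P - sched$sample_window
  env$next_sample <- NULL
  .production_segment(env, ts, 0, t1, FALSE, FALSE, sample_from)
  .production_segment(env, ts, t1, t2, TRUE, FALSE, sample_from)
  .production_segment(env, ts, t2, P, TRUE, TRUE, sample_from)
  invisible(NULL)
}

.production_segment <- function(env, ts, from, to, chrom_on, tf_on,
                                sample_from) {
  if (to <= from) return(invisible(NULL))
  env$state$eps <- .eps_variant(ts, chrom_on, tf_on)
  # sampling begins once production elapsed time passes sample_from
  .run_stage(env, to - from, extrude = TRUE, switch_tf = TRUE,
             sample_from = max(0, sample_from - from))
  invisible(NULL)
}

#' Structure ensemble container
#'
#' @param frames list of n_beads x 3 chromatin conformations (sigma,
#'   unwrapped coordinates).
#' @param frame_meta data.frame of per-frame metadata (or `NULL`).
#' @param track the annotated bead track the ensemble was simulated from.
#' @param box length-3 periodic box.
#' @param params parameter echo list.
#' @return object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(frames, frame_meta = NULL, track = NULL,
                               box = NULL, params = list()) {
  stopifnot(is.list(frames))
  structure(list(frames = frames, frame_meta = frame_meta, track = track,
                 box = box, params = params),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("structure ensemble: %d conformation(s) of %d beads\n",
              length(x$frames),
              if (length(x$frames)) nrow(x$frames[[1]]) else 0))
  invisible(x)
}

#' @export
length.structure_ensemble <- function(x) length(x$frames)
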