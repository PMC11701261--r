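#' Loop-extrusion parameters
#'
#' Defaults follow the model's standard kinetics: 10 extruders per Mbp
#' (7.5/Mbp during the boundary-free pre-relaxation stage), translocation
#' speed `v_extr` = 4e-3 kbp/tau per end, and unbinding rate `k_off` =
#' 2.5e-5 /tau, giving a processivity lambda = v_extr/k_off = 160 kbp.
#' Extrusion events are swept every `event_interval` MD steps.
#'
#' @param density extruders per Mbp.
#' @param v_extr translocation speed in kbp/tau.
#' @param k_off unbinding rate in 1/tau.
#' @param event_interval MD steps between extrusion-event sweeps.
#' @return an object of class `extrusion_params`.
#' @export
extrusion_params <- function(density = 10, v_extr = 4e-3, k_off = 2.5e-5,
                             event_interval = 100) {
  stopifnot(density > 0, v_extr > 0, k_off >= 0, event_interval >= 1)
  structure(list(density = density, v_extr = v_extr, k_off = k_off,
                 event_interval = as.integer(event_interval),
                 processivity_kbp = if (k_off > 0) v_extr / k_off else Inf),
            class = "extrusion_params")
}

# internal representation: data.frame(id, left, right (0-based beads),
#   left_block, right_block in {"none","ctcf","collision","chain_end"})
.new_extruder_set <- function(left, right) {
  structure(data.frame(id = seq_along(left), left = as.integer(left),
                       right = as.integer(right),
                       left_block = rep("none", length(left)),
                       right_block = rep("none", length(left)),
                       stringsAsFactors = FALSE),
            class = c("extruder_set", "data.frame"))
}

#' @export
print.extruder_set <- function(x, ...) {
  cat(sprintf("%d loop extruder(s); mean loop %.1f kbp\n", nrow(x),
              if (nrow(x)) mean(x$right - x$left) else 0))
  invisible(x)
}

.anchor_beads <- function(ex) c(ex$left, ex$right)

# one fresh uniformly random loading position (i, i+3) avoiding occupied anchors
.load_position <- function(n_beads, occupied) {
  cand <- 0:(n_beads - 4)
  ok <- !(cand %in% occupied) & !((cand + 3L) %in% occupied)
  cand <- cand[ok]
  if (!length(cand)) stop("no free loading position for extruder")
  cand[sample.int(length(cand), 1)]
}

#' Seed loop extruders on a naked chain
#'
#' Loads `round(density * fragment length in Mbp)` extruders (or an explicit
#' `n`), each as a spring over beads `(i, i+3)` at uniformly random `i`, with
#' no two extruders sharing an anchor bead.
#'
#' @param n_beads number of chromatin beads (1 bead = 1 kbp).
#' @param params an [extrusion_params()].
#' @param n optional explicit extruder count overriding the density rule.
#' @return an `extruder_set`.
#' @export
seed_extruders <- function(n_beads, params = extrusion_params(), n = NULL) {
  if (n_beads <= 4) stop("chain too short for extruders")
  if (is.null(n)) n <- round(params$density * n_beads / 1000)
  if (n * 2 > n_beads / 2) stop("fragment too small for requested extruder count")
  left <- integer(n)
  occupied <- integer()
  for (k in seq_len(n)) {
    left[k] <- .load_position(n_beads, occupied)
    occupied <- c(occupied, left[k], left[k] + 3L)
  }
  .new_extruder_set(left, left + 3L)
}

# is bead `b` a blocking boundary for an end moving in `dir` (+1 right, -1 left)?
# Orientation convention: a forward-motif boundary blocks leftward-travelling
# ends, a backward-motif boundary blocks rightward-travelling ends, so a
# forward...backward pair captures a convergent loop between them.
.blocks <- function(boundaries, b, dir) {
  hit <- boundaries$bead == b
  if (!any(hit)) return(FALSE)
  o <- boundaries$orientation[hit]
  any(o == "bidirectional" | (dir > 0 & o == "backward") |
        (dir < 0 & o == "forward"))
}

#' One translocation sweep over an extruder set
#'
#' Each unblocked end independently advances one bead outward with
#' probability `v_extr * dt` (at most one bead per sweep per end). An end
#' halts when the next bead is an active CTCF boundary opposing its travel
#' direction (or bidirectional), is occupied by another extruder's anchor,
#' or is the chain end. CTCF and chain-end blocks persist until rebind;
#' collision blocks are re-tested every sweep. A blocked end never blocks
#' the other end of the same extruder.
#'
#' @param extruders an `extruder_set`.
#' @param boundaries active boundary set from [sample_ctcf_activation()]
#'   (data.frame `bead`, `orientation`).
#' @param n_beads chain length in beads.
#' @param params an [extrusion_params()].
#' @param dt sweep interval in tau; `v_extr * dt` must be <= 1 kbp.
#' @return the updated `extruder_set`.
#' @export
attempt_translocation <- function(extruders, boundaries, n_beads,
                                  params = extrusion_params(),
                                  dt = params$event_interval * 0.01) {
  p_step <- params$v_extr * dt
  if (p_step > 1) stop("v_extr * dt exceeds one bead per sweep")
  ex <- extruders
  if (!nrow(ex)) return(ex)
  # ends in random order so no extruder systematically wins collisions
  ends <- data.frame(row = rep(seq_len(nrow(ex)), 2),
                     side = rep(c("left", "right"), each = nrow(ex)))
  ends <- ends[sample.int(nrow(ends)), , drop = FALSE]
  for (e in seq_len(nrow(ends))) {
    i <- ends$row[e]; side <- ends$side[e]
    blocked <- ex[[paste0(side, "_block")]][i]
    if (blocked %in% c("ctcf", "chain_end")) next
    if (stats::runif(1) >= p_step) next
    dir <- if (side == "left") -1L else 1L
    nxt <- ex[[side]][i] + dir
    if (nxt < 0 || nxt >= n_beads) {
      ex[[paste0(side, "_block")]][i] <- "chain_end"
    } else if (.blocks(boundaries, nxt, dir)) {
      ex[[paste0(side, "_block")]][i] <- "ctcf"
    } else if (nxt %in% .anchor_beads(ex)) {
      ex[[paste0(side, "_block")]][i] <- "collision"
    } else {
      ex[[side]][i] <- nxt
      ex[[paste0(side, "_block")]][i] <- "none"
    }
  }
  ex
}

#' One unbind/instant-rebind sweep
#'
#' Each extruder unbinds with probability `k_off * dt`; an unbound extruder
#' is immediately re-seeded at a fresh uniformly random position (anchors
#' `(i, i+3)`, excluding beads occupied by other anchors), so the number of
#' extruders on chromatin stays constant.
#'
#' @inheritParams attempt_translocation
#' @return list with the updated `extruder_set` and `n_unbound`, the number
#'   of turnover events this sweep.
#' @export
attempt_unbind_rebind <- function(extruders, n_beads,
                                  params = extrusion_params(),
                                  dt = params$event_interval * 0.01) {
  ex <- extruders
  if (!nrow(ex)) return(list(extruders = ex, n_unbound = 0L))
  unbind <- stats::runif(nrow(ex)) < params$k_off * dt
  for (i in which(unbind)) {
    occupied <- .anchor_beads(ex[-i, , drop = FALSE])
    pos <- .load_position(n_beads, occupied)
    ex$left[i] <- pos; ex$right[i] <- pos + 3L
    ex$left_block[i] <- "none"; ex$right_block[i] <- "none"
  }
  list(extruders = ex, n_unbound = sum(unbind), which_unbound = which(unbind))
}

#' Bond list realizing an extruder set in the force field
#'
#' One extruder spring (harmonic + short-range WCA) per extruder between its
#' current anchors; regenerated after every extrusion sweep.
#'
#' @param extruders an `extruder_set`.
#' @return data.frame `(i, j)` of 0-based anchor bead pairs.
#' @export
extruder_bonds <- function(extruders) {
  data.frame(i = extruders$left, j = extruders$right)
}

#' Run the 1D extrusion kinetics alone
#'
#' Sweeps translocation and turnover on a chain without any 3D dynamics,
#' optionally logging a trajectory. Useful for kinetic calibration (mean
#' extruder lifetime, steady-state loop length) and for tests.
#'
#' @param n_beads chain length.
#' @param n_sweeps number of event sweeps.
#' @param params an [extrusion_params()].
#' @param boundaries active boundary data.frame (default none).
#' @param dt sweep interval in tau.
#' @param n explicit extruder count (default from density).
#' @param seed RNG seed.
#' @param log_every if > 0, record anchor positions every so many sweeps.
#' @return list with the final `extruder_set`, `mean_loop_kbp`
#'   (time-averaged over all sweeps and extruders), `n_unbound` (total
#'   turnover events), `lifetimes_tau` (completed residence times), and
#'   optional `trajectory` data.frame.
#' @export
run_extrusion <- function(n_beads, n_sweeps, params = extrusion_params(),
                          boundaries = NULL, dt = params$event_interval * 0.01,
                          n = NULL, seed = NULL, log_every = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(boundaries))
    boundaries <- data.frame(bead = integer(), orientation = character())
  ex <- seed_extruders(n_beads, params, n = n)
  born <- rep(0, nrow(ex))
  lifetimes <- numeric()
  loop_sum <- 0; loop_n <- 0; n_unbound <- 0L
  traj <- if (log_every > 0) vector("list", n_sweeps %/% log_every) else NULL
  for (s in seq_len(n_sweeps)) {
    ex <- attempt_translocation(ex, boundaries, n_beads, params, dt)
    ub <- attempt_unbind_rebind(ex, n_beads, params, dt)
    for (i in ub$which_unbound) {
      lifetimes <- c(lifetimes, (s - born[i]) * dt)
      born[i] <- s
    }
    ex <- ub$extruders
    loop_sum <- loop_sum + sum(ex$right - ex$left)
    loop_n <- loop_n + nrow(ex)
    n_unbound <- n_unbound + ub$n_unbound
    if (log_every > 0 && s %% log_every == 0)
      traj[[s %/% log_every]] <- cbind(sweep = s, ex)
  }
  list(extruders = ex,
       mean_loop_kbp = loop_sum / loop_n,
       n_unbound = n_unbound,
       lifetimes_tau = lifetimes,
       trajectory = if (!is.null(traj)) do.call(rbind, traj) else NULL)
}

#' Write an extruder trajectory log as TSV
#' @param trajectory the `trajectory` element of [run_extrusion()].
#' @param path output file.
#' @export
write_extruder_log <- function(trajectory, path) {
  utils::write.table(trajectory, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
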