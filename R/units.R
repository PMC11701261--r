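#' Simulation units
#'
#' The model works in reduced units: the bead diameter \eqn{\sigma} (one bead =
#' 1 kbp of chromatin) is the length unit, \eqn{k_BT} the energy unit, and
#' \eqn{\tau = \sigma\sqrt{m/k_BT}} the time unit. The physical size of
#' \eqn{\sigma} in nm is deliberately left free at simulation time and only
#' fixed a posteriori by fitting to FISH distance distributions (typically
#' 20-30 nm); it enters only density and FISH conversions.
#'
#' @param sigma_length bead diameter in simulation length units (always 1).
#' @param energy_unit thermal energy kBT (always 1).
#' @param time_unit tau in reduced units (always 1).
#' @param timestep integration time step dt, in tau.
#' @param mass bead mass m (same for all beads).
#' @param gamma friction coefficient; gamma = 2 gives a Brownian time
#'   tau_B = 2 tau, i.e. an overdamped but still tractable regime.
#' @param physical_sigma_nm optional physical bead size in nm, used only for
#'   FISH and density conversions. When set it must lie in a plausible
#'   15-40 nm window.
#' @return an object of class `simulation_units`.
#' @export
simulation_units <- function(sigma_length = 1, energy_unit = 1, time_unit = 1,
                             timestep = 0.01, mass = 1, gamma = 2,
                             physical_sigma_nm = NULL) {
  if (!is.numeric(timestep) || timestep <= 0)
    stop("timestep must be > 0")
  if (!is.null(physical_sigma_nm)) {
    if (physical_sigma_nm < 15 || physical_sigma_nm > 40)
      stop("physical_sigma_nm outside the plausible 15-40 nm window")
  }
  structure(list(sigma_length = sigma_length, energy_unit = energy_unit,
                 time_unit = time_unit, timestep = timestep, mass = mass,
                 gamma = gamma, physical_sigma_nm = physical_sigma_nm),
            class = "simulation_units")
}

#' Force-field parameters
#'
#' Defaults are the model's standard parameterization, all in reduced units
#' (energies in kBT, lengths in sigma):
#' FENE backbone Kf = 30, R0 = 1.6; bending stiffness lp = 4 (Kratky-Porod);
#' protein-chromatin attraction cutoff rc = 1.8; extruder spring kextr = 40
#' with rest length 1.5; crumple springs kh = 200 with rest length 1.1;
#' and a weak 0.4 kBT chromatin-chromatin attraction between beads that do
#' not carry the H3K27ac mark.
#'
#' @param fene_k,fene_r0 FENE spring constant (kBT/sigma^2) and maximum bond
#'   extension (sigma).
#' @param bend_lp bending persistence parameter (sigma).
#' @param tf_cutoff attraction cutoff rc (sigma); must exceed 2^(1/6).
#' @param extruder_k,extruder_r0 extruder harmonic spring constant and rest
#'   length.
#' @param crumple_k,crumple_r0 next-to-nearest-neighbour crumple spring
#'   constant and rest length.
#' @param chromatin_self_eps well depth for the non-acetylated
#'   chromatin-chromatin attraction (kBT).
#' @return an object of class `force_field_params`.
#' @export
force_field_params <- function(fene_k = 30, fene_r0 = 1.6, bend_lp = 4,
                               tf_cutoff = 1.8, extruder_k = 40,
                               extruder_r0 = 1.5, crumple_k = 200,
                               crumple_r0 = 1.1, chromatin_self_eps = 0.4) {
  p <- list(fene_k = fene_k, fene_r0 = fene_r0, bend_lp = bend_lp,
            tf_cutoff = tf_cutoff, extruder_k = extruder_k,
            extruder_r0 = extruder_r0, crumple_k = crumple_k,
            crumple_r0 = crumple_r0, chromatin_self_eps = chromatin_self_eps)
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1 || x <= 0,
                 logical(1))))
    stop("all force-field parameters must be positive scalars")
  if (extruder_r0 >= fene_r0 * 2)  # sanity: rest length far below blow-up scale
    stop("extruder_r0 implausibly large")
  if (tf_cutoff <= 2^(1/6))
    stop("tf_cutoff must exceed 2^(1/6) sigma for an attractive well to exist")
  structure(p, class = "force_field_params")
}

#' Protein-chromatin affinity table
#'
#' Well depths (kBT) for the attraction between each multivalent protein
#' species in its binding state and each chromatin mark. Defaults: active
#' factors bind accessible (ATAC) beads at 7 kBT and H3K27ac beads at 3 kBT;
#' polycomb-like factors bind H3K27me3 at 7 kBT; HP1-like factors bind
#' H3K9me3 at 3 kBT. Unlisted pairs are purely steric (0).
#'
#' @param entries a data.frame with columns `species`, `mark`, `eps`.
#' @return an object of class `affinity_table`.
#' @export
affinity_table <- function(entries = NULL) {
  if (is.null(entries)) {
    entries <- data.frame(
      species = c("active", "active", "polycomb", "hp1"),
      mark    = c("atac", "h3k27ac", "h3k27me3", "h3k9me3"),
      eps     = c(7, 3, 7, 3),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(entries),
            all(c("species", "mark", "eps") %in% names(entries)))
  if (!all(entries$species %in% protein_species()))
    stop("unknown protein species in affinity table")
  if (!all(entries$mark %in% chromatin_marks()))
    stop("unknown chromatin mark in affinity table")
  if (any(entries$eps < 0)) stop("affinity well depths must be >= 0")
  structure(entries, class = c("affinity_table", "data.frame"))
}

#' @export
print.affinity_table <- function(x, ...) {
  cat("Protein-chromatin affinities (kBT):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# Known labels; shared by annotation and the force field.
chromatin_marks <- function() c("atac", "h3k27ac", "h3k27me3", "h3k9me3")
protein_species <- function() c("active", "polycomb", "hp1")

#' Pair affinity between a protein (or chromatin bead) and a chromatin bead
#'
#' Implements the mark-to-affinity rules: a protein in the non-binding state
#' is purely steric (0); a binding protein sees the maximum well depth over
#' the marks the bead carries for that species (a bead with several marks
#' presents each, and a single pairwise potential takes the strongest);
#' chromatin-chromatin pairs where neither bead carries H3K27ac attract
#' weakly at `chromatin_self_eps`.
#'
#' @param species one of `"active"`, `"polycomb"`, `"hp1"`, or `"chromatin"`.
#' @param binding logical; protein binding state (ignored for chromatin).
#' @param marks character vector of marks on the partner chromatin bead
#'   (possibly empty).
#' @param table an [affinity_table()].
#' @param params a [force_field_params()] (for `chromatin_self_eps`).
#' @param partner_marks for chromatin-chromatin pairs, the marks of the first
#'   bead (default none).
#' @return well depth in kBT.
#' @export
pair_affinity <- function(species, binding = TRUE, marks = character(),
                          table = affinity_table(),
                          params = force_field_params(),
                          partner_marks = character()) {
  if (length(marks) && !all(marks %in% chromatin_marks()))
    stop("unknown mark label: ", paste(setdiff(marks, chromatin_marks()), collapse = ", "))
  if (identical(species, "chromatin")) {
    if (!("h3k27ac" %in% marks) && !("h3k27ac" %in% partner_marks))
      return(params$chromatin_self_eps)
    return(0)
  }
  if (!species %in% protein_species())
    stop("unknown protein species: ", species)
  if (!isTRUE(binding)) return(0)
  hit <- table$species == species & table$mark %in% marks
  if (!any(hit)) return(0)
  max(table$eps[hit])
}
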