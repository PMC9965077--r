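#' Simulation configuration for the coarse-grained ensemble generator
#'
#' Parameters of the bead-per-residue Metropolis Monte Carlo model used to
#' generate replica conformational ensembles. Each residue is one bead;
#' consecutive beads are joined by rigid virtual bonds of `bond_length`
#' (3.8 Angstrom, the canonical CA-CA distance); non-bonded beads interact
#' through a hard core of radius `excluded_volume_radius`; phenylalanine
#' beads of FG-family motifs additionally attract each other through a
#' square well of depth `cohesion_epsilon` (in kT) within
#' `cohesion_cutoff`. A point variant is modelled as a local weakening of
#' that cohesion: pairs involving F sites within `variant_range` residues of
#' `variant_position` have their well depth multiplied by `variant_penalty`
#' (1 = no effect); optionally the variant bead itself repels F beads with a
#' square shoulder of height `variant_repulsion` kT.
#'
#' The nominal time mapping is 0.005 ns per Monte Carlo sweep, so the
#' default 25000 sweeps span a nominal 125 ns and frames recorded every
#' 0.005 ns give the conventional analysis stride (0.01 ns) as an integer
#' multiple. The mapping is a labelling convention for window logic only.
#'
#' Replica sub-seeds are derived by a counter-based rule
#' (`master seed + replica_id * 2654435769 mod 2^32`, further scrambled by
#' splitmix64 in the sampler), so adding replicas never changes existing
#' ones.
#'
#' @param n_replicas number of independent replicas (default 20).
#' @param n_sweeps Monte Carlo sweeps per replica (default 25000, i.e. a
#'   nominal 125 ns).
#' @param record_interval_ns frame recording interval, nominal ns; must be a
#'   multiple of 0.005 (default 0.005).
#' @param bond_length virtual bond length, Angstrom.
#' @param excluded_volume_radius hard-core bead radius, Angstrom.
#' @param cohesion_epsilon F-F square-well depth, kT.
#' @param cohesion_cutoff F-F square-well range, Angstrom; must be at least
#'   the hard-core diameter.
#' @param variant_position residue number of the point variant, or NULL.
#' @param variant_penalty multiplicative weakening (0..1) of cohesion for F
#'   sites within `variant_range` of the variant.
#' @param variant_range neighbourhood half-width in residues (default 10).
#' @param variant_repulsion square-shoulder height, kT, between the variant
#'   bead and F beads (default 0 = weakening only).
#' @param seed master integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_replicas = 20L, n_sweeps = 25000L,
                       record_interval_ns = 0.005, bond_length = 3.8,
                       excluded_volume_radius = 1.9, cohesion_epsilon = 3.0,
                       cohesion_cutoff = 9.0, variant_position = NULL,
                       variant_penalty = 0.3, variant_range = 10L,
                       variant_repulsion = 0.0, seed = 1L) {
  stopifnot(n_replicas >= 1, n_sweeps >= 1, bond_length > 0,
            excluded_volume_radius > 0, cohesion_epsilon >= 0,
            variant_penalty >= 0, variant_penalty <= 1,
            variant_repulsion >= 0)
  if (cohesion_cutoff < 2 * excluded_volume_radius)
    stop("cohesion_cutoff must be >= the excluded-volume diameter (",
         2 * excluded_volume_radius, " Angstrom)")
  ns_per_sweep <- 0.005
  rec <- record_interval_ns / ns_per_sweep
  if (abs(rec - round(rec)) > 1e-9 || round(rec) < 1)
    stop("record_interval_ns must be a positive multiple of ", ns_per_sweep)
  structure(
    list(n_replicas = as.integer(n_replicas), n_sweeps = as.integer(n_sweeps),
         record_interval_ns = record_interval_ns,
         ns_per_sweep = ns_per_sweep, bond_length = bond_length,
         excluded_volume_radius = excluded_volume_radius,
         cohesion_epsilon = cohesion_epsilon,
         cohesion_cutoff = cohesion_cutoff,
         variant_position = if (is.null(variant_position)) NULL
                            else as.integer(variant_position),
         variant_penalty = variant_penalty,
         variant_range = as.integer(variant_range),
         variant_repulsion = variant_repulsion,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d replicas x %d sweeps (nominal %.1f ns), eps=%.2f kT, cutoff=%.1f A\n",
    x$n_replicas, x$n_sweeps, x$n_sweeps * x$ns_per_sweep,
    x$cohesion_epsilon, x$cohesion_cutoff))
  if (!is.null(x$variant_position))
    cat(sprintf("  variant at %d: penalty %.2f within +/-%d residues, repulsion %.2f kT\n",
                x$variant_position, x$variant_penalty, x$variant_range,
                x$variant_repulsion))
  invisible(x)
}

#' Build a fully extended bead chain
#'
#' Places one bead per residue on a straight line along the x axis at the
#' given bond length — the fully extended starting conformation from which
#' every replica is launched.
#'
#' @param seq an [fg_sequence()].
#' @param bond_length consecutive-bead distance, Angstrom.
#' @return An N x 3 coordinate matrix (Angstrom).
#' @export
build_extended_chain <- function(seq, bond_length = 3.8) {
  stopifnot(bond_length > 0)
  n <- length(seq$residues)
  cbind(x = (seq_len(n) - 1) * bond_length, y = numeric(n), z = numeric(n))
}

## interaction sites and per-pair well depths for a config
## returns list(idx0 = 0-based bead indices, eps = symmetric depth matrix)
interaction_sites <- function(seq, config) {
  phe <- phenylalanine_sites(seq)
  off <- seq$numbering_offset
  site_scale <- rep(1, length(phe))
  if (!is.null(config$variant_position) &&
      (config$variant_penalty < 1 || config$variant_repulsion > 0)) {
    near <- abs(phe - config$variant_position) <= config$variant_range
    site_scale[near] <- config$variant_penalty
  }
  nf <- length(phe)
  eps <- matrix(0, nf, nf)
  if (nf > 1) {
    for (a in seq_len(nf - 1)) for (b in (a + 1):nf) {
      s <- if (site_scale[a] < 1 || site_scale[b] < 1) config$variant_penalty else 1
      eps[a, b] <- eps[b, a] <- config$cohesion_epsilon * s
    }
  }
  idx0 <- phe - off          # 0-based bead indices
  if (!is.null(config$variant_position) && config$variant_repulsion > 0) {
    vb <- config$variant_position - off
    if (vb >= 0 && vb < length(seq$residues) && !(vb %in% idx0)) {
      idx0 <- c(idx0, vb)
      eps <- rbind(cbind(eps, -config$variant_repulsion),
                   c(rep(-config$variant_repulsion, nf), 0))
    }
  }
  list(idx0 = as.integer(idx0), eps = eps, phe = phe)
}

replica_subseed <- function(master, replica_id) {
  lo <- (as.numeric(master) + 2654435769 * as.numeric(replica_id)) %% 2^32
  c(lo = lo, hi = as.numeric(replica_id) %% 2^32)
}

#' Simulate one replica trajectory
#'
#' Runs Metropolis Monte Carlo from the fully extended chain using pivot,
#' crankshaft and end-bead rotation moves (all preserve bond lengths
#' exactly). The energy is a hard-core excluded volume plus a square-well
#' attraction between phenylalanine beads of FG-family motifs (see
#' [sim_config()]). Identical `(seed, replica_id)` give a bit-identical
#' trajectory.
#'
#' @param seq an [fg_sequence()].
#' @param config a [sim_config()].
#' @param replica_id integer replica label (1-based).
#' @return An object of class `replica_trajectory`: `replica_id`, `times_ns`,
#'   `coords` (frames x beads x 3 array, Angstrom), `topology` (the
#'   sequence) and `diagnostics` (energies, acceptance).
#' @export
simulate_replica <- function(seq, config, replica_id) {
  stopifnot(inherits(seq, "fg_sequence"), inherits(config, "sim_config"))
  x0 <- build_extended_chain(seq, config$bond_length)
  sites <- interaction_sites(seq, config)
  ss <- replica_subseed(config$seed, replica_id)
  record_every <- as.integer(round(config$record_interval_ns /
                                   config$ns_per_sweep))
  res <- mc_simulate_cpp(x0, sites$idx0, sites$eps,
                         2 * config$excluded_volume_radius,
                         config$cohesion_cutoff, config$n_sweeps,
                         record_every, config$ns_per_sweep,
                         ss["lo"], ss["hi"])
  nfr <- nrow(res$frames)
  nb <- nrow(x0)
  coords <- array(NA_real_, dim = c(nfr, nb, 3))
  for (d in 1:3) coords[, , d] <- res$frames[, seq(d, 3 * nb, by = 3)]
  structure(
    list(replica_id = as.integer(replica_id),
         times_ns = as.numeric(res$times_ns),
         coords = coords, topology = seq,
         diagnostics = list(
           energy_initial = res$energy_initial,
           energy_final = res$energy_final,
           energy_current = res$energy_current,
           accepted_delta_sum = res$accepted_delta_sum,
           acceptance_rate = res$n_accept / max(1, res$n_attempt))),
    class = "replica_trajectory")
}

#' @export
print.replica_trajectory <- function(x, ...) {
  cat(sprintf(
    "<replica_trajectory> replica %d: %d frames x %d beads, t = %.3f..%.3f ns\n",
    x$replica_id, dim(x$coords)[1], dim(x$coords)[2],
    min(x$times_ns), max(x$times_ns)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `replica_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as a coordinate matrix
#' @param traj a `replica_trajectory`.
#' @param i frame index (1-based).
#' @return N x 3 coordinate matrix, Angstrom.
#' @export
traj_frame <- function(traj, i) {
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Simulate an ensemble of independent replicas
#'
#' Maps [simulate_replica()] over replica ids `1..n_replicas`. Replicas are
#' mutually independent given their counter-derived sub-seeds.
#'
#' @param seq an [fg_sequence()].
#' @param config a [sim_config()].
#' @param replica_ids which replicas to run (default `1:n_replicas`).
#' @return List of `replica_trajectory` objects.
#' @export
simulate_ensemble <- function(seq, config,
                              replica_ids = seq_len(config$n_replicas)) {
  lapply(replica_ids, function(k) simulate_replica(seq, config, k))
}

#' Radius of gyration of a conformation
#' @param coords N x 3 coordinate matrix.
#' @return scalar Rg, Angstrom.
#' @export
radius_of_gyration <- function(coords) {
  c0 <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2, c0)^2)))
}

#' End-to-end distance of a conformation
#' @param coords N x 3 coordinate matrix.
#' @return scalar distance, Angstrom.
#' @export
end_to_end <- function(coords) {
  sqrt(sum((coords[nrow(coords), ] - coords[1, ])^2))
}
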