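## van der Waals radii by element (Bondi), Angstrom
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

## reference maximum SASA of residue X in an extended Gly-X-Gly tripeptide
## (theoretical values of Tien et al. 2013), Angstrom^2
GXG_REF_SASA <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

## deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic test-point SASA: each atom is inflated by the probe radius and
#' covered with a deterministic quasi-uniform point set (golden-spiral
#' lattice); a point is accessible when it lies outside every other
#' inflated atom. Per-atom SASA = accessible fraction x sphere area.
#'
#' @param coords N x 3 atom coordinates, Angstrom.
#' @param elements length-N element symbols (H, C, N, O, S, P), used to
#'   assign van der Waals radii from the documented Bondi table; or supply
#'   `radii` directly.
#' @param radii optional explicit per-atom radii, Angstrom (overrides
#'   `elements`).
#' @param probe_radius solvent probe radius, Angstrom (default 1.4, water).
#' @param n_points test points per atom (default 960; minimum 92).
#' @return Numeric vector of per-atom SASA, Angstrom^2.
#' @export
shrake_rupley_sasa <- function(coords, elements = NULL, radii = NULL,
                               probe_radius = 1.4, n_points = 960L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n_points < 92L) stop("n_points must be >= 92")
  if (is.null(radii)) {
    if (is.null(elements)) stop("supply elements or radii")
    unknown <- setdiff(unique(elements), names(VDW_RADII))
    if (length(unknown) > 0)
      stop("radius-assignment error: unknown element(s) ",
           paste(unknown, collapse = ", "))
    radii <- VDW_RADII[elements]
  }
  if (length(radii) != n) stop("radii length must match atom count")
  inflated <- radii + probe_radius
  pts <- sphere_points(n_points)
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    ri <- inflated[i]
    # neighbours that can possibly occlude points on atom i's sphere
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(d2 < (ri + inflated)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      sasa[i] <- 4 * pi * ri^2
      next
    }
    p <- sweep(pts * ri, 2, coords[i, ], `+`)   # test points, absolute
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- rowSums(sweep(p, 2, coords[j, ])^2)
      free <- free & dj2 >= inflated[j]^2
    }
    sasa[i] <- sum(free) / n_points * 4 * pi * ri^2
  }
  unname(sasa)
}

#' Per-residue SASA from an all-atom structure
#'
#' @param atoms data.frame with columns `x`, `y`, `z`, `element`, `resno`
#'   (and optionally `resname`).
#' @inheritParams shrake_rupley_sasa
#' @return data.frame with columns `resno` and `sasa` (Angstrom^2).
#' @export
residue_sasa <- function(atoms, probe_radius = 1.4, n_points = 960L) {
  s <- shrake_rupley_sasa(as.matrix(atoms[, c("x", "y", "z")]),
                          elements = atoms$element,
                          probe_radius = probe_radius, n_points = n_points)
  agg <- aggregate(s, by = list(resno = atoms$resno), FUN = sum)
  names(agg)[2] <- "sasa"
  agg
}

#' Exposed/buried classification of a focus residue
#'
#' Classifies the focus residue in each frame by its relative SASA: the
#' residue SASA divided by the reference maximum SASA of that residue type
#' in an extended Gly-X-Gly tripeptide. `exposed` when the relative SASA is
#' at or above `exposure_threshold` (default 0.25, the common convention).
#'
#' @param sasa_per_frame numeric vector: the focus residue's SASA in each
#'   frame, Angstrom^2.
#' @param resname three-letter residue type (for the reference value).
#' @param exposure_threshold relative-SASA cutoff (default 0.25).
#' @param frame_ids optional frame labels.
#' @return An object of class `exposure_profile`: per-frame `sasa`,
#'   `relative_sasa`, `state` ("exposed"/"buried"), plus `fraction_exposed`
#'   and the threshold and reference used.
#' @export
exposure_state <- function(sasa_per_frame, resname,
                           exposure_threshold = 0.25, frame_ids = NULL) {
  resname <- toupper(resname)
  if (!resname %in% names(GXG_REF_SASA))
    stop("missing reference tripeptide SASA for residue type ", resname)
  if (any(sasa_per_frame < 0)) stop("negative SASA input")
  ref <- GXG_REF_SASA[[resname]]
  rel <- sasa_per_frame / ref
  state <- ifelse(rel >= exposure_threshold, "exposed", "buried")
  structure(
    list(sasa = sasa_per_frame, relative_sasa = rel, state = state,
         fraction_exposed = mean(state == "exposed"),
         exposure_threshold = exposure_threshold,
         reference_sasa = ref, resname = resname,
         frame_ids = if (is.null(frame_ids)) seq_along(sasa_per_frame)
                     else frame_ids,
         method = "shrake_rupley_relative_sasa"),
    class = "exposure_profile")
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat(sprintf(
    "<exposure_profile> %s: %d frames, %.0f%% exposed (threshold %.2f, ref %.0f A^2)\n",
    x$resname, length(x$sasa), 100 * x$fraction_exposed,
    x$exposure_threshold, x$reference_sasa))
  invisible(x)
}

#' Burial proxy for bead-per-residue (CA-only) ensembles
#'
#' All-atom SASA is undefined for a coarse bead chain, so burial of the
#' focus residue is proxied by its neighbour count: the residue is called
#' buried in a frame when at least `k_buried` non-bonded beads lie within
#' `cutoff` of its bead. The output is explicitly labelled as the proxy
#' method.
#'
#' @param traj a `replica_trajectory` (CA-only).
#' @param residue residue number of the focus residue.
#' @param cutoff neighbour distance cutoff, Angstrom (default 10).
#' @param k_buried minimum neighbour count for burial (default 12).
#' @return An object of class `exposure_profile` with `method =
#'   "ca_neighbor_proxy"`; `relative_sasa` holds the neighbour counts
#'   rescaled to `1 - count / k_buried` floored at 0 (a pseudo-exposure).
#' @export
burial_proxy <- function(traj, residue, cutoff = 10, k_buried = 12L) {
  stopifnot(inherits(traj, "replica_trajectory"))
  off <- traj$topology$numbering_offset
  i <- residue - off + 1L
  nb <- dim(traj$coords)[2]
  if (i < 1L || i > nb) stop("residue outside topology: ", residue)
  counts <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- traj_frame(traj, f)
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    excl <- unique(pmax(1L, pmin(nb, c(i - 1L, i, i + 1L))))
    sum(d[-excl] <= cutoff)
  }, numeric(1))
  state <- ifelse(counts >= k_buried, "buried", "exposed")
  pseudo <- pmax(0, 1 - counts / k_buried)
  structure(
    list(sasa = counts, relative_sasa = pseudo, state = state,
         fraction_exposed = mean(state == "exposed"),
         exposure_threshold = NA_real_, reference_sasa = NA_real_,
         resname = traj$topology$residues[i],
         frame_ids = seq_len(n_frames(traj)),
         method = "ca_neighbor_proxy",
         cutoff = cutoff, k_buried = k_buried),
    class = "exposure_profile")
}

## atoms whose names mark them as H-bond donors (heavy atom) / acceptors
is_donor_atom <- function(name, element) {
  element %in% c("N", "O", "S") &
    (element == "N" |
     name %in% c("OG", "OG1", "OH", "SG", "OW"))
}
is_acceptor_atom <- function(name, element) {
  element == "O" | name %in% c("ND1", "NE2", "SD", "OW")
}

#' Geometric hydrogen-bond detection
#'
#' Detects hydrogen bonds involving a focus residue by the standard
#' geometric criterion: donor-acceptor heavy-atom distance at most `d_max`
#' and, when explicit hydrogens are present (bonded to the donor within
#' 1.25 Angstrom), a D-H...A angle of at least `angle_min` degrees. Without
#' hydrogens the distance criterion alone applies. Donor/acceptor typing
#' follows a documented name/element table (all N plus hydroxyl/thiol O, S
#' as donors; all O plus His ND1/NE2 as acceptors).
#'
#' @param atoms data.frame with columns `name`, `element`, `resno`,
#'   `resname`, `x`, `y`, `z`.
#' @param focus_residue residue number whose bonds are reported.
#' @param d_max donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_min minimum D-H...A angle, degrees (default 120).
#' @return data.frame with one row per detected bond: `donor_resno`,
#'   `donor_atom`, `acceptor_resno`, `acceptor_atom`, `partner_resno`,
#'   `partner_label`, `distance`, `angle` (NA when no H present). Empty
#'   data.frame when no bonds are found.
#' @export
hydrogen_bonds <- function(atoms, focus_residue, d_max = 3.5,
                           angle_min = 120) {
  stopifnot(all(c("name", "element", "resno", "x", "y", "z") %in%
                names(atoms)))
  if (!"resname" %in% names(atoms)) atoms$resname <- ""
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  don <- which(is_donor_atom(atoms$name, atoms$element))
  acc <- which(is_acceptor_atom(atoms$name, atoms$element))
  hs <- which(atoms$element == "H")
  out <- list()
  for (d in don) for (a in acc) {
    if (d == a || atoms$resno[d] == atoms$resno[a]) next
    if (atoms$resno[d] != focus_residue && atoms$resno[a] != focus_residue)
      next
    dist <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
    if (dist > d_max) next
    ang <- NA_real_
    if (length(hs) > 0) {
      dh <- sqrt(rowSums(sweep(xyz[hs, , drop = FALSE], 2, xyz[d, ])^2))
      bonded_h <- hs[dh <= 1.25]
      if (length(bonded_h) > 0) {
        angs <- vapply(bonded_h, function(h) {
          v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        }, numeric(1))
        ang <- max(angs)
        if (ang < angle_min) next
      }
    }
    partner <- if (atoms$resno[d] == focus_residue) a else d
    out[[length(out) + 1L]] <- data.frame(
      donor_resno = atoms$resno[d], donor_atom = atoms$name[d],
      acceptor_resno = atoms$resno[a], acceptor_atom = atoms$name[a],
      partner_resno = atoms$resno[partner],
      partner_label = paste0(atoms$resname[partner], atoms$resno[partner]),
      distance = dist, angle = ang)
  }
  if (length(out) == 0L)
    return(data.frame(donor_resno = integer(0), donor_atom = character(0),
                      acceptor_resno = integer(0),
                      acceptor_atom = character(0),
                      partner_resno = integer(0),
                      partner_label = character(0),
                      distance = numeric(0), angle = numeric(0)))
  do.call(rbind, out)
}
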