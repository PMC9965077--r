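## hull facets (outward-oriented triangles, 1-based indices) for a frame
hull_facets <- function(coords, rel_eps = 1e-10) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 4)
    stop("geometry error: convex hull needs at least 4 points")
  tryCatch(convex_hull_facets_cpp(coords, rel_eps),
           error = function(e) stop("geometry error: ", conditionMessage(e)))
}

## volume, centroid and uniform-density covariance of a convex hull,
## by decomposition into tetrahedra against an interior point
hull_solid_moments <- function(coords, facets) {
  o <- colMeans(coords[unique(as.vector(facets)), , drop = FALSE])
  vol <- 0; ctr <- c(0, 0, 0)
  xx <- matrix(0, 3, 3)
  for (r in seq_len(nrow(facets))) {
    a <- coords[facets[r, 1], ]; b <- coords[facets[r, 2], ]
    c3 <- coords[facets[r, 3], ]
    va <- a - o; vb <- b - o; vc <- c3 - o
    v6 <- det(rbind(va, vb, vc))     # 6 x signed tetra volume (>0 outward)
    v <- v6 / 6
    vol <- vol + v
    ctr <- ctr + v * (o + a + b + c3) / 4
    # integral of x x^T over tetra with vertices o,a,b,c:
    # V/20 * (S S^T + sum_k v_k v_k^T), S = sum of vertices
    S <- o + a + b + c3
    M <- tcrossprod(S) + tcrossprod(o) + tcrossprod(a) +
         tcrossprod(b) + tcrossprod(c3)
    xx <- xx + (v / 20) * M
  }
  if (vol <= 0) stop("geometry error: degenerate hull (zero volume)")
  ctr <- ctr / vol
  cov <- xx / vol - tcrossprod(ctr)
  list(volume = vol, centroid = as.numeric(ctr), covariance = cov)
}

#' Perrin translational shape factor of a triaxial ellipsoid
#'
#' Ratio of the Stokes (hydrodynamic) radius of an ellipsoid with semi-axes
#' `a >= b >= c` to the radius of the equal-volume sphere. The ellipsoid
#' Stokes radius is `2 / S` with `S = int_0^inf ds / sqrt((a^2+s)(b^2+s)
#' (c^2+s))` (evaluated numerically); the factor is 1 for a sphere and
#' greater than 1 for any aspherical shape.
#'
#' @param semi_axes numeric length-3, Angstrom (any order).
#' @return dimensionless factor >= 1.
#' @export
perrin_shape_factor <- function(semi_axes) {
  ax <- sort(as.numeric(semi_axes), decreasing = TRUE)
  if (any(!is.finite(ax)) || any(ax <= 0))
    stop("geometry error: non-positive ellipsoid semi-axis")
  a2 <- ax[1]^2; b2 <- ax[2]^2; c2 <- ax[3]^2
  # substitution s = a2 * u/(1-u) maps (0,Inf) -> (0,1)
  f <- function(u) {
    s <- a2 * u / (1 - u)
    a2 / (1 - u)^2 / sqrt((a2 + s) * (b2 + s) * (c2 + s))
  }
  S <- stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
  r_ell <- 2 / S
  r_sph <- (ax[1] * ax[2] * ax[3])^(1 / 3)
  max(1, r_ell / r_sph)
}

#' Hull-based hydrodynamic radius of a conformation
#'
#' Estimates the hydrodynamic radius of a single conformation from the
#' convex hull of its coordinates: the hull volume gives the equivalent
#' sphere radius `(3V / 4 pi)^(1/3)`; an optional Perrin-type shape
#' correction (the translational friction factor of the ellipsoid whose
#' principal second moments match the solid hull's) accounts for
#' asphericity; a hydration shell thickness is added last. This is a
#' simplified, fully documented hull estimator — exact parity with any
#' particular hydrodynamics server is not claimed.
#'
#' @param coords N x 3 coordinate matrix (N >= 4, non-coplanar), Angstrom.
#' @param hydration_shell added shell thickness, Angstrom (default 0; a
#'   typical hydration value is 2.8).
#' @param use_shape_correction apply the Perrin factor (default TRUE).
#' @return An object of class `hull_radius`: `hull_volume` (A^3),
#'   `equivalent_sphere_radius`, `shape_correction`, `hydration_shell`,
#'   `hydrodynamic_radius` (all radii in Angstrom).
#' @export
hull_hydrodynamic_radius <- function(coords, hydration_shell = 0,
                                     use_shape_correction = TRUE) {
  stopifnot(hydration_shell >= 0)
  facets <- hull_facets(coords)
  mom <- hull_solid_moments(as.matrix(coords), facets)
  r_eq <- (3 * mom$volume / (4 * pi))^(1 / 3)
  shape <- 1
  if (use_shape_correction) {
    ev <- eigen(mom$covariance, symmetric = TRUE)$values
    ev <- pmax(ev, 1e-12)
    # solid ellipsoid: second moment lambda_i = a_i^2 / 5
    shape <- perrin_shape_factor(sqrt(5 * ev))
  }
  structure(
    list(hull_volume = mom$volume, equivalent_sphere_radius = r_eq,
         shape_correction = shape, hydration_shell = hydration_shell,
         hydrodynamic_radius = shape * r_eq + hydration_shell),
    class = "hull_radius")
}

#' @export
print.hull_radius <- function(x, ...) {
  cat(sprintf(
    "<hull_radius> Rh = %.2f A (hull %.1f A^3, Req %.2f A, shape %.3f, shell %.1f A)\n",
    x$hydrodynamic_radius, x$hull_volume, x$equivalent_sphere_radius,
    x$shape_correction, x$hydration_shell))
  invisible(x)
}

#' Ensemble summary of hydrodynamic radii
#'
#' Hydrodynamic radius of each representative conformation plus summary
#' statistics. Quartiles use the linear-interpolation convention
#' (`quantile(type = 7)`, the R default).
#'
#' @param representatives list of representatives from
#'   [cluster_representatives()], or a list of N x 3 coordinate matrices.
#' @inheritParams hull_hydrodynamic_radius
#' @return List: `radii` (per representative), `mean`, `median`, `q1`, `q3`,
#'   `iqr`, `n`.
#' @export
ensemble_radius_stats <- function(representatives, hydration_shell = 0,
                                  use_shape_correction = TRUE) {
  if (length(representatives) == 0) stop("empty representative list")
  radii <- vapply(representatives, function(r) {
    coords <- if (is.matrix(r)) r else r$coords
    hull_hydrodynamic_radius(coords, hydration_shell,
                             use_shape_correction)$hydrodynamic_radius
  }, numeric(1))
  qs <- quantile(radii, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(radii = radii, mean = mean(radii), median = qs[2],
       q1 = qs[1], q3 = qs[3], iqr = qs[3] - qs[1], n = length(radii))
}

#' Mean phenylalanine-phenylalanine distance matrix of a trajectory window
#'
#' Entry (i, j) is the mean over frames of the Euclidean distance between
#' the two phenylalanine sites (in bead-per-residue mode the bead position
#' is the residue's centre of mass). The trajectory should already be
#' restricted to its analysis window with [sample_window()].
#'
#' @param traj_window a `replica_trajectory`.
#' @param sites residue numbers of the F sites (see
#'   [phenylalanine_sites()]).
#' @return Symmetric matrix (Angstrom) with zero diagonal, dimnames =
#'   residue numbers.
#' @export
ff_distance_matrix <- function(traj_window, sites) {
  stopifnot(inherits(traj_window, "replica_trajectory"))
  off <- traj_window$topology$numbering_offset
  nb <- dim(traj_window$coords)[2]
  idx <- sites - off + 1L
  if (any(idx < 1L | idx > nb))
    stop("site outside topology: ",
         paste(sites[idx < 1L | idx > nb], collapse = ", "))
  ns <- length(sites)
  m <- matrix(0, ns, ns, dimnames = list(sites, sites))
  if (ns < 2) return(m)
  for (a in seq_len(ns - 1)) for (b in (a + 1):ns) {
    d <- sqrt((traj_window$coords[, idx[a], 1] - traj_window$coords[, idx[b], 1])^2 +
              (traj_window$coords[, idx[a], 2] - traj_window$coords[, idx[b], 2])^2 +
              (traj_window$coords[, idx[a], 3] - traj_window$coords[, idx[b], 3])^2)
    m[a, b] <- m[b, a] <- mean(d)
  }
  m
}

## mean of a list of matching matrices
matrix_mean <- function(mats) Reduce(`+`, mats) / length(mats)

#' Compare F-F cohesion between two conditions
#'
#' Aggregates per-replica mean-distance matrices (stable replicas only) into
#' one matrix per condition, then screens every F-F pair for its percent
#' variation relative to the first condition
#' (`|d_var - d_wt| / d_wt * 100`). Pairs exceeding `threshold` are flagged
#' as showing a meaningful cohesion change. Aggregation is the mean of
#' replica-mean matrices (each stable replica weighted equally); set
#' `pool = "frames"` upstream by passing frame-pooled matrices if desired.
#'
#' @param wt_matrices list of per-replica matrices ([ff_distance_matrix()])
#'   for the reference (wild-type) condition.
#' @param var_matrices same for the variant condition; site sets must match.
#' @param threshold percent-variation flag threshold (default 25).
#' @return An object of class `cohesion_comparison`: `site_indices`,
#'   `mean_distance_matrix_wt`, `mean_distance_matrix_var`,
#'   `percent_variation`, `flagged_pairs` (data.frame site_i, site_j,
#'   d_wt, d_var, percent_variation), `flagged_fraction` (percent of pairs),
#'   `grand_mean_wt`, `grand_mean_var` (mean off-diagonal distance),
#'   `threshold`.
#' @export
compare_cohesion <- function(wt_matrices, var_matrices, threshold = 25) {
  stopifnot(length(wt_matrices) >= 1, length(var_matrices) >= 1)
  sites <- rownames(wt_matrices[[1]])
  ok <- vapply(c(wt_matrices, var_matrices),
               function(m) identical(rownames(m), sites), logical(1))
  if (!all(ok)) stop("site-set mismatch between distance matrices")
  wt <- matrix_mean(wt_matrices)
  va <- matrix_mean(var_matrices)
  ns <- nrow(wt)
  ut <- upper.tri(wt)
  pv <- matrix(0, ns, ns, dimnames = dimnames(wt))
  pv[ut] <- abs(va[ut] - wt[ut]) / wt[ut] * 100
  pv[lower.tri(pv)] <- t(pv)[lower.tri(pv)]
  flag <- which(ut & pv > threshold, arr.ind = TRUE)
  flagged <- data.frame(
    site_i = as.integer(sites[flag[, 1]]),
    site_j = as.integer(sites[flag[, 2]]),
    d_wt = wt[flag], d_var = va[flag],
    percent_variation = pv[flag])
  flagged <- flagged[order(flagged$site_i, flagged$site_j), , drop = FALSE]
  rownames(flagged) <- NULL
  n_pairs <- sum(ut)
  structure(
    list(site_indices = as.integer(sites),
         mean_distance_matrix_wt = wt, mean_distance_matrix_var = va,
         percent_variation = pv, flagged_pairs = flagged,
         flagged_fraction = if (n_pairs > 0) 100 * nrow(flagged) / n_pairs else 0,
         grand_mean_wt = mean(wt[ut]), grand_mean_var = mean(va[ut]),
         threshold = threshold),
    class = "cohesion_comparison")
}

#' @export
print.cohesion_comparison <- function(x, ...) {
  np <- length(x$site_indices) * (length(x$site_indices) - 1) / 2
  cat(sprintf(
    "<cohesion_comparison> %d F sites, %d pairs; grand mean %.2f vs %.2f A\n",
    length(x$site_indices), np, x$grand_mean_wt, x$grand_mean_var))
  cat(sprintf("  %d pairs (%.1f%%) exceed %.0f%% variation\n",
              nrow(x$flagged_pairs), x$flagged_fraction, x$threshold))
  invisible(x)
}

#' F-F cohesion network graph
#'
#' Complete weighted graph over the phenylalanine sites of one condition:
#' nodes are F sites labelled by residue number, edge weights are the mean
#' F-F distances (Angstrom). The drawing attribute `thickness` increases
#' with distance — longer (less cohesive) pairs draw thicker, which keeps
#' the convention that the most changed pairs stand out.
#'
#' @param comparison a [compare_cohesion()] result.
#' @param condition `"wt"` or `"variant"`.
#' @return An igraph graph with edge attributes `weight` (Angstrom) and
#'   `thickness`.
#' @export
cohesion_network <- function(comparison, condition = c("wt", "variant")) {
  condition <- match.arg(condition)
  m <- if (condition == "wt") comparison$mean_distance_matrix_wt
       else comparison$mean_distance_matrix_var
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  rng <- range(igraph::E(g)$weight)
  w <- igraph::E(g)$weight
  igraph::E(g)$thickness <- if (diff(rng) > 0)
    0.5 + 4.5 * (w - rng[1]) / diff(rng) else rep(2.5, length(w))
  g
}

#' Export a cohesion network
#'
#' @param graph an igraph graph from [cohesion_network()].
#' @param path output path; format by extension: `.graphml` or `.tsv`
#'   (edge list: from, to, weight).
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path) {
  if (grepl("\\.graphml$", path)) {
    igraph::write_graph(graph, path, format = "graphml")
  } else if (grepl("\\.tsv$", path)) {
    el <- igraph::as_data_frame(graph, what = "edges")
    utils::write.table(el, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else stop("unsupported network format: ", path)
  invisible(path)
}

#' Write a cohesion comparison to CSV files
#'
#' Writes `<prefix>_matrix_wt.csv`, `<prefix>_matrix_var.csv` and
#' `<prefix>_variation.csv` (long table: site_i, site_j, d_wt, d_var,
#' percent_variation, flagged).
#'
#' @param comparison a [compare_cohesion()] result.
#' @param prefix output path prefix.
#' @return The variation-table path, invisibly.
#' @export
write_cohesion_csv <- function(comparison, prefix) {
  wm <- comparison$mean_distance_matrix_wt
  vm <- comparison$mean_distance_matrix_var
  utils::write.csv(wm, paste0(prefix, "_matrix_wt.csv"))
  utils::write.csv(vm, paste0(prefix, "_matrix_var.csv"))
  ut <- which(upper.tri(wm), arr.ind = TRUE)
  sites <- comparison$site_indices
  long <- data.frame(
    site_i = sites[ut[, 1]], site_j = sites[ut[, 2]],
    d_wt = wm[ut], d_var = vm[ut],
    percent_variation = comparison$percent_variation[ut])
  long$flagged <- long$percent_variation > comparison$threshold
  long <- long[order(long$site_i, long$site_j), ]
  p <- paste0(prefix, "_variation.csv")
  utils::write.csv(long, p, row.names = FALSE, quote = FALSE)
  invisible(p)
}
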