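#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `mobile` onto `reference`, via SVD of the cross-covariance matrix with
#' the standard determinant sign correction (so the rotation is never an
#' improper reflection).
#'
#' @param mobile N x 3 coordinate matrix.
#' @param reference N x 3 coordinate matrix with the same N.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd` (Angstrom) and `transformed` (mobile after superposition). The
#'   transform maps mobile as `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("point count mismatch: ", nrow(mobile), " vs ", nrow(reference))
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)                    # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)             # maps mobile frame -> reference
  transformed <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((transformed - B)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% t(R)),
       rmsd = rmsd, transformed = sweep(transformed, 2, cr, `+`))
}

#' RMSD of two conformations after optimal superposition
#' @param a,b N x 3 coordinate matrices.
#' @return scalar RMSD, Angstrom.
#' @export
rmsd_fit <- function(a, b) kabsch_superpose(a, b)$rmsd

#' RMSD-versus-initial series of a replica
#'
#' For each frame, the RMSD against the replica's first frame after optimal
#' superposition — the conventional convergence diagnostic: the series
#' plateaus once the replica has settled into a stable conformational
#' region.
#'
#' @param traj a `replica_trajectory` with at least 2 frames.
#' @return An object of class `rmsd_series`: `replica_id`, `times_ns`,
#'   `rmsd` (Angstrom; first value 0).
#' @export
rmsd_series <- function(traj) {
  stopifnot(inherits(traj, "replica_trajectory"))
  nf <- n_frames(traj)
  if (nf < 2) stop("need at least 2 frames")
  ref <- traj_frame(traj, 1)
  vals <- vapply(seq_len(nf), function(i) {
    if (i == 1) return(0)
    rmsd_fit(traj_frame(traj, i), ref)
  }, numeric(1))
  structure(list(replica_id = traj$replica_id, times_ns = traj$times_ns,
                 rmsd = vals), class = "rmsd_series")
}

#' Classify a replica as stable or unstable from its RMSD series
#'
#' A replica is called stable when, over the assessment window
#' `(assessment_start_ns, end]`, its RMSD-versus-initial series has both a
#' small standard deviation and a small least-squares drift slope — i.e. it
#' has reached a plateau. Both thresholds are exposed; the defaults suit
#' series whose plateau fluctuations are a couple of Angstrom.
#'
#' @param series an [rmsd_series()].
#' @param assessment_start_ns start of the assessment window, ns.
#' @param sd_threshold maximum plateau standard deviation, Angstrom.
#' @param slope_threshold maximum absolute drift slope, Angstrom/ns.
#' @return List: `replica_id`, `stable`, `plateau_start_ns`,
#'   `plateau_mean_rmsd`, `plateau_sd`, `drift_slope`.
#' @export
classify_stability <- function(series, assessment_start_ns = 40,
                               sd_threshold = 2.0, slope_threshold = 0.02) {
  stopifnot(inherits(series, "rmsd_series"))
  sel <- series$times_ns > assessment_start_ns
  if (sum(sel) < 3)
    stop("series too short: needs > 2 frames after ", assessment_start_ns,
         " ns")
  t <- series$times_ns[sel]; r <- series$rmsd[sel]
  slope <- as.numeric(coef(lm(r ~ t))[2])
  s <- sd(r)
  list(replica_id = series$replica_id,
       stable = (s <= sd_threshold) && (abs(slope) <= slope_threshold),
       plateau_start_ns = assessment_start_ns,
       plateau_mean_rmsd = mean(r), plateau_sd = s, drift_slope = slope)
}

#' Stability report for a whole ensemble
#'
#' Runs [rmsd_series()] and [classify_stability()] on every replica.
#'
#' @param ensemble list of `replica_trajectory`.
#' @inheritParams classify_stability
#' @param force_stable,force_unstable optional replica-id vectors overriding
#'   the automatic call (manual curation, e.g. after visual inspection).
#' @return An object of class `stability_report`: a data.frame with one row
#'   per replica (columns `replica_id`, `stable`, `plateau_start_ns`,
#'   `plateau_mean_rmsd`, `plateau_sd`, `drift_slope`), with the series
#'   stored in `attr(, "series")`.
#' @export
stability_report <- function(ensemble, assessment_start_ns = 40,
                             sd_threshold = 2.0, slope_threshold = 0.02,
                             force_stable = integer(0),
                             force_unstable = integer(0)) {
  series <- lapply(ensemble, rmsd_series)
  rows <- lapply(series, classify_stability,
                 assessment_start_ns = assessment_start_ns,
                 sd_threshold = sd_threshold,
                 slope_threshold = slope_threshold)
  df <- do.call(rbind, lapply(rows, as.data.frame))
  df$stable[df$replica_id %in% force_stable] <- TRUE
  df$stable[df$replica_id %in% force_unstable] <- FALSE
  attr(df, "series") <- series
  class(df) <- c("stability_report", class(df))
  df
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d/%d replicas stable\n",
              sum(x$stable), nrow(x)))
  NextMethod()
}

#' Write per-replica RMSD series to CSV
#' @param report a [stability_report()].
#' @param path output CSV (columns replica, time_ns, rmsd).
#' @return `path`, invisibly.
#' @export
write_rmsd_csv <- function(report, path) {
  series <- attr(report, "series")
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(replica = s$replica_id, time_ns = s$times_ns, rmsd = s$rmsd)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## all-pairs RMSD matrix over the frames of one trajectory
pairwise_rmsd_matrix <- function(traj) {
  nf <- n_frames(traj)
  frames <- lapply(seq_len(nf), traj_frame, traj = traj)
  m <- matrix(0, nf, nf)
  if (nf > 1)
    for (i in seq_len(nf - 1)) for (j in (i + 1):nf)
      m[i, j] <- m[j, i] <- rmsd_fit(frames[[i]], frames[[j]])
  m
}

#' Representative conformation of each stable replica
#'
#' Within each replica's analysis window, frames are grouped by
#' single-linkage clustering of the pairwise superposed-RMSD matrix, cut at
#' `rmsd_cutoff`; the representative is the medoid (minimum summed RMSD to
#' the other members) of the largest cluster. Ties — equal cluster sizes or
#' equal summed RMSD — are broken in favour of the earliest frame time.
#'
#' @param stable_trajs list of `replica_trajectory` (the stable replicas).
#' @param window an [analysis_window()].
#' @param rmsd_cutoff single-linkage cut height, Angstrom.
#' @param max_frames cap on frames per replica entering the clustering; the
#'   window is thinned evenly above it (pairwise RMSD is quadratic in frame
#'   count). Default 250.
#' @return List with one element per replica: `replica_id`, `coords` (the
#'   representative frame), `time_ns`, `cluster_size`, `n_frames`.
#' @export
cluster_representatives <- function(stable_trajs, window = analysis_window(),
                                    rmsd_cutoff = 3.0, max_frames = 250L) {
  lapply(stable_trajs, function(traj) {
    w <- sample_window(traj, window)
    nf <- n_frames(w)
    if (nf == 0) stop("empty window for replica ", traj$replica_id)
    if (nf > max_frames) {
      keep <- unique(round(seq(1, nf, length.out = max_frames)))
      w$coords <- w$coords[keep, , , drop = FALSE]
      w$times_ns <- w$times_ns[keep]
      nf <- length(keep)
    }
    if (nf == 1) {
      return(list(replica_id = traj$replica_id, coords = traj_frame(w, 1),
                  time_ns = w$times_ns[1], cluster_size = 1L, n_frames = 1L))
    }
    dm <- pairwise_rmsd_matrix(w)
    hc <- stats::hclust(stats::as.dist(dm), method = "single")
    memb <- stats::cutree(hc, h = rmsd_cutoff)
    sizes <- tabulate(memb)
    best_size <- max(sizes)
    cands <- which(sizes == best_size)
    # tie on cluster size: the cluster containing the earliest frame
    cl <- cands[which.min(vapply(cands, function(k)
      min(which(memb == k)), numeric(1)))]
    members <- which(memb == cl)
    ssum <- rowSums(dm[members, members, drop = FALSE])
    med <- members[order(ssum, w$times_ns[members])[1]]
    list(replica_id = traj$replica_id, coords = traj_frame(w, med),
         time_ns = w$times_ns[med], cluster_size = length(members),
         n_frames = nf)
  })
}

#' Write representative conformations as single-model PDB files
#' @param representatives output of [cluster_representatives()].
#' @param ensemble the matching list of `replica_trajectory` (for topology).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_representatives <- function(representatives, ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  topo <- setNames(lapply(ensemble, `[[`, "topology"),
                   vapply(ensemble, `[[`, 1L, "replica_id"))
  for (rep in representatives) {
    traj <- structure(
      list(replica_id = rep$replica_id, times_ns = rep$time_ns,
           coords = array(rep$coords, dim = c(1, nrow(rep$coords), 3)),
           topology = topo[[as.character(rep$replica_id)]],
           diagnostics = list()),
      class = "replica_trajectory")
    write_trajectory_pdb(traj,
      file.path(dir, sprintf("representative_%02d.pdb", rep$replica_id)),
      sidecar = FALSE)
  }
  invisible(dir)
}
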