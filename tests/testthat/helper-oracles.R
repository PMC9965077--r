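# Independent oracles and small fixture builders used across the suite.

# Brute-force motif enumeration: slide a window over the string and apply
# the GLFG-precedence rule directly. Independent of scan_motifs internals.
brute_force_motifs <- function(chars) {
  n <- length(chars)
  glfg_phe <- integer(0)
  out <- list()
  if (n >= 4) {
    for (i in seq_len(n - 3)) {
      if (chars[i] == "G" && chars[i + 1] == "L" && chars[i + 2] == "F" &&
          chars[i + 3] == "G") {
        out[[length(out) + 1]] <- list(kind = "GLFG", phe = i + 2L)
        glfg_phe <- c(glfg_phe, i + 2L)
      }
    }
  }
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      if (chars[i] == "F" && chars[i + 1] == "G" && !(i %in% glfg_phe))
        out[[length(out) + 1]] <- list(kind = "FG", phe = i)
    }
  }
  phe <- vapply(out, `[[`, 1L, "phe")
  kind <- vapply(out, `[[`, "", "kind")
  ord <- order(phe)
  data.frame(kind = kind[ord], phe_index = phe[ord],
             stringsAsFactors = FALSE)
}

# Monte-Carlo surface-sampling SASA oracle (random points on each inflated
# sphere, occlusion tested against all other inflated spheres).
mc_sasa_oracle <- function(coords, radii, probe = 1.4, npts = 1e5,
                           seed = 1234) {
  infl <- radii + probe
  n <- nrow(coords)
  vapply(seq_len(n), function(i) {
    set.seed(seed + i)
    p <- matrix(rnorm(3 * npts), ncol = 3)
    p <- p / sqrt(rowSums(p^2)) * infl[i]
    p <- sweep(p, 2, coords[i, ], `+`)
    free <- rep(TRUE, npts)
    for (j in seq_len(n)[-i])
      free <- free & rowSums(sweep(p, 2, coords[j, ])^2) >= infl[j]^2
    mean(free) * 4 * pi * infl[i]^2
  }, numeric(1))
}

# Brute-force rotation-grid RMSD oracle: centre both point sets, scan a
# 10-degree Euler-angle grid and return the minimum RMSD found.
grid_rmsd_oracle <- function(mobile, reference, step_deg = 10) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  ang <- seq(0, 350, by = step_deg) * pi / 180
  ang_b <- seq(0, 170, by = step_deg) * pi / 180
  best <- Inf
  for (a in ang) {
    Rz1 <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    for (b in ang_b) {
      Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
      Rzy <- Ry %*% Rz1
      for (g in ang) {
        Rz2 <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0),
                     c(0, 0, 1))
        R <- Rz2 %*% Rzy
        v <- sqrt(mean(rowSums((A %*% t(R) - B)^2)))
        if (v < best) best <- v
      }
    }
  }
  best
}

# Assemble a replica_trajectory directly from a list of frames (used to
# build analytically known inputs).
toy_trajectory <- function(frames, times_ns = NULL, seq = NULL,
                           replica_id = 1L) {
  nb <- nrow(frames[[1]])
  if (is.null(seq))
    seq <- fg_sequence(rep("G", nb), id = "toy")
  if (is.null(times_ns)) times_ns <- (seq_along(frames) - 1) * 0.005
  coords <- array(NA_real_, dim = c(length(frames), nb, 3))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  structure(list(replica_id = as.integer(replica_id),
                 times_ns = times_ns, coords = coords, topology = seq,
                 diagnostics = list()),
            class = "replica_trajectory")
}

random_rigid_motion <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- rbind(
    c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
      2 * (q[2] * q[4] + q[1] * q[3])),
    c(2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] - q[1] * q[2])),
    c(2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
      1 - 2 * (q[2]^2 + q[3]^2)))
  list(R = R, t = rnorm(3, sd = 5))
}

apply_rigid <- function(coords, motion) {
  sweep(coords %*% t(motion$R), 2, motion$t, `+`)
}

# scipy convex-hull volume (independent reference implementation)
scipy_hull_volume <- function(coords) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.table(coords, f, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  code <- sprintf(paste0(
    "import numpy as np; from scipy.spatial import ConvexHull; ",
    "print(repr(ConvexHull(np.loadtxt('%s', delimiter=',')).volume))"), f)
  out <- system2("python", c("-c", shQuote(code)), stdout = TRUE)
  as.numeric(out[length(out)])
}

matrix_mean_list <- function(mats) Reduce(`+`, mats) / length(mats)
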