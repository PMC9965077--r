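AA321 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
AA123 <- setNames(names(AA321), AA321)

#' Analysis window specification
#'
#' Defines the trailing portion of each replica used for ensemble averages:
#' frames with time in the half-open interval `(t_end - window_ns, t_end]`,
#' thinned to one frame per `stride_ns`. The defaults (final 25 ns sampled
#' every 0.01 ns) follow the conventional equilibrated-tail analysis of
#' 125 ns replicas.
#'
#' @param window_ns window length, ns (default 25).
#' @param stride_ns sampling stride, ns (default 0.01).
#' @return An object of class `analysis_window`.
#' @export
analysis_window <- function(window_ns = 25, stride_ns = 0.01) {
  if (!(stride_ns > 0 && stride_ns <= window_ns))
    stop("need 0 < stride_ns <= window_ns")
  structure(list(window_ns = window_ns, stride_ns = stride_ns),
            class = "analysis_window")
}

#' Restrict a trajectory to its analysis window
#'
#' Keeps frames with `time > t_end - window_ns` at the requested stride.
#' The stride must be an integer multiple of the frame spacing (tolerance
#' 1e-9 ns); sampling is anchored at the final frame so the last frame is
#' always retained.
#'
#' @param traj a `replica_trajectory`.
#' @param w an [analysis_window()].
#' @return A `replica_trajectory` containing only the sampled frames.
#' @export
sample_window <- function(traj, w) {
  stopifnot(inherits(traj, "replica_trajectory"),
            inherits(w, "analysis_window"))
  t <- traj$times_ns
  n <- length(t)
  if (n < 2) stop("window error: trajectory has fewer than 2 frames")
  span <- t[n] - t[1]
  # a trajectory that is itself a sampled window covers window - stride,
  # which keeps resampling at the same (window, stride) idempotent
  if (span < w$window_ns - w$stride_ns - 1e-9)
    stop(sprintf("window error: trajectory span %.4g ns < window %.4g ns",
                 span, w$window_ns))
  spacing <- (t[n] - t[1]) / (n - 1)
  if (max(abs(diff(t) - spacing)) > 1e-6)
    stop("window error: frame times are not uniformly spaced")
  k <- round(w$stride_ns / spacing)
  if (k < 1 || abs(w$stride_ns - k * spacing) > 1e-9)
    stop(sprintf(
      "stride error: stride %.4g ns is not an integer multiple of frame spacing %.4g ns",
      w$stride_ns, spacing))
  idx <- rev(seq(n, 1L, by = -k))
  thr <- t[n] - w$window_ns
  keep <- if (thr <= t[1] + 1e-9) idx else idx[t[idx] > thr + 1e-9]
  out <- traj
  out$times_ns <- t[keep]
  out$coords <- traj$coords[keep, , , drop = FALSE]
  out
}

#' Write a replica trajectory as a multi-model CA-only PDB file
#'
#' One MODEL per frame, one CA ATOM record per bead, occupancy 1.00 and
#' B-factor 0.00. A JSON sidecar `<path>.json` records the replica id and
#' frame times.
#'
#' @param traj a `replica_trajectory`.
#' @param path output PDB file.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path, sidecar = TRUE) {
  stopifnot(inherits(traj, "replica_trajectory"))
  res3 <- AA321[traj$topology$residues]
  off <- traj$topology$numbering_offset
  nb <- dim(traj$coords)[2]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj_frame(traj, f)
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nb), res3, seq_len(nb) + off - 1L,
      xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  if (sidecar)
    jsonlite::write_json(
      list(replica_id = traj$replica_id, times_ns = traj$times_ns,
           n_beads = nb, numbering_offset = off,
           sequence = as.character(traj$topology)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-model CA-only PDB file as a replica trajectory
#'
#' Frame count equals the MODEL count (a file without MODEL records is read
#' as a single frame). Times are taken from the JSON sidecar written by
#' [write_trajectory_pdb()] when present, otherwise uniform spacing at
#' `default_spacing_ns` starting from 0.
#'
#' @param path PDB file.
#' @param replica_id replica label if no sidecar is present.
#' @param default_spacing_ns assumed frame spacing without time metadata.
#' @return A `replica_trajectory`.
#' @export
read_trajectory_pdb <- function(path, replica_id = 1L,
                                default_spacing_ns = 0.005) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("parse error: empty PDB file: ", path)
  atom_mask <- startsWith(lines, "ATOM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (!any(atom_mask)) stop("parse error: no ATOM records in ", path)

  model_of <- if (length(model_starts) == 0L) {
    rep(1L, length(lines))
  } else {
    findInterval(seq_along(lines), model_starts)
  }
  atom_lines <- which(atom_mask)
  if (length(model_starts) > 0L && any(model_of[atom_lines] == 0L))
    stop("parse error: ATOM record before first MODEL at line ",
         atom_lines[model_of[atom_lines] == 0L][1])

  parse_field <- function(txt, from, to, what, lineno) {
    v <- suppressWarnings(as.numeric(substr(txt, from, to)))
    bad <- which(is.na(v))
    if (length(bad) > 0L)
      stop(sprintf("parse error at line %d: malformed %s field in ATOM record",
                   lineno[bad[1]], what))
    v
  }
  txt <- lines[atom_lines]
  short <- which(nchar(txt) < 54)
  if (length(short) > 0L)
    stop(sprintf("parse error at line %d: ATOM record shorter than 54 columns",
                 atom_lines[short[1]]))
  x <- parse_field(txt, 31, 38, "x", atom_lines)
  y <- parse_field(txt, 39, 46, "y", atom_lines)
  z <- parse_field(txt, 47, 54, "z", atom_lines)
  resnum <- parse_field(txt, 23, 26, "residue number", atom_lines)
  res3 <- trimws(substr(txt, 18, 20))

  fid <- model_of[atom_lines]
  fid <- match(fid, sort(unique(fid)))
  counts <- tabulate(fid)
  if (length(unique(counts)) != 1L)
    stop("structure error: inconsistent atom counts across models (",
         paste(unique(counts), collapse = ", "), ")")
  nb <- counts[1]
  nfr <- length(counts)

  first <- which(fid == 1L)
  unknown <- which(!(res3[first] %in% names(AA123)))
  if (length(unknown) > 0L)
    stop("parse error: unknown residue name ", res3[first][unknown[1]])
  seq <- fg_sequence(AA123[res3[first]],
                     id = sub("\\.pdb$", "", basename(path)),
                     numbering_offset = as.integer(resnum[first][1]))

  coords <- array(NA_real_, dim = c(nfr, nb, 3))
  ord <- order(fid, seq_along(fid))
  coords[, , 1] <- matrix(x[ord], nfr, nb, byrow = TRUE)
  coords[, , 2] <- matrix(y[ord], nfr, nb, byrow = TRUE)
  coords[, , 3] <- matrix(z[ord], nfr, nb, byrow = TRUE)

  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    times <- as.numeric(meta$times_ns)
    if (length(times) != nfr)
      stop("structure error: sidecar frame count (", length(times),
           ") does not match MODEL count (", nfr, ")")
    replica_id <- as.integer(meta$replica_id)
  } else {
    times <- (seq_len(nfr) - 1) * default_spacing_ns
  }
  structure(
    list(replica_id = as.integer(replica_id), times_ns = times,
         coords = coords, topology = seq, diagnostics = list()),
    class = "replica_trajectory")
}

#' Write an ensemble of replicas to a directory
#'
#' One multi-model PDB per replica (`replica_NN.pdb`) plus an
#' `ensemble.json` sidecar echoing the configuration and seeds.
#'
#' @param ensemble list of `replica_trajectory`.
#' @param dir output directory (created if needed).
#' @param config optional [sim_config()] to echo into the sidecar.
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (traj in ensemble)
    write_trajectory_pdb(traj,
      file.path(dir, sprintf("replica_%02d.pdb", traj$replica_id)))
  meta <- list(n_replicas = length(ensemble),
               replica_ids = vapply(ensemble, `[[`, 1L, "replica_id"))
  if (!is.null(config)) meta$config <- unclass(config)
  jsonlite::write_json(meta, file.path(dir, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an ensemble of replicas from a directory or file list
#'
#' @param path directory containing `replica_*.pdb` files, or a character
#'   vector of PDB paths.
#' @return List of `replica_trajectory`.
#' @export
read_ensemble <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
  } else path
  if (length(files) == 0L) stop("no PDB files found in ", path)
  lapply(seq_along(files), function(i)
    read_trajectory_pdb(files[i], replica_id = i))
}
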