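#' End-to-end wild-type versus variant ensemble comparison
#'
#' Orchestrates the full analysis: build the variant sequence, generate (or
#' reuse cached) replica ensembles for both conditions, classify replica
#' stability, pick representative conformations from the stable replicas,
#' summarise hydrodynamic radii, compare F-F cohesion, and profile the
#' burial of the variant residue. Deterministic given the seeds in `sim`.
#'
#' When `out_dir` is given, the ensembles are persisted as multi-model PDB
#' directories and every downstream stage reads its input back from the
#' persisted artifact, so a rerun over an existing `out_dir` skips the
#' simulation and reproduces the report bit-identically; stage outputs
#' (stability CSV/JSON, cohesion tables, networks, report JSON) are written
#' alongside.
#'
#' @param wt_seq wild-type [fg_sequence()].
#' @param variant a [variant_spec()] applied to `wt_seq`.
#' @param sim a [sim_config()]; the wild-type run clears
#'   `variant_position`, the variant run sets it to `variant$position`
#'   (keeping the configured penalty/repulsion).
#' @param window an [analysis_window()].
#' @param assessment_start_ns,sd_threshold,slope_threshold stability
#'   thresholds (see [classify_stability()]).
#' @param rmsd_cutoff clustering cut, Angstrom (see
#'   [cluster_representatives()]).
#' @param hydration_shell,use_shape_correction radius options (see
#'   [hull_hydrodynamic_radius()]).
#' @param variation_threshold percent-variation flag threshold (default 25).
#' @param burial_cutoff,burial_k burial-proxy options (see
#'   [burial_proxy()]).
#' @param out_dir optional output/cache directory.
#' @param wt_ensemble,var_ensemble optional pre-built ensembles (lists of
#'   `replica_trajectory`, e.g. from [read_ensemble()]); when supplied the
#'   simulation stage is skipped.
#' @return An object of class `comparison_report` (a nested list; see
#'   [write_comparison_report()]).
#' @export
run_comparison <- function(wt_seq, variant, sim = sim_config(),
                           window = analysis_window(),
                           assessment_start_ns = 40, sd_threshold = 2.0,
                           slope_threshold = 0.02, rmsd_cutoff = 3.0,
                           hydration_shell = 0, use_shape_correction = TRUE,
                           variation_threshold = 25, burial_cutoff = 10,
                           burial_k = 12L, out_dir = NULL,
                           wt_ensemble = NULL, var_ensemble = NULL) {
  stopifnot(inherits(wt_seq, "fg_sequence"), inherits(variant, "variant_spec"))
  var_seq <- apply_variant(wt_seq, variant)

  wt_sim <- sim; wt_sim$variant_position <- NULL
  var_sim <- sim; var_sim$variant_position <- variant$position

  get_ensemble <- function(label, seq, cfg, supplied) {
    stage <- function(msg) message(sprintf("[%s] %s", label, msg))
    if (!is.null(supplied)) {
      stage("using supplied ensemble")
      return(supplied)
    }
    if (!is.null(out_dir)) {
      dir <- file.path(out_dir, paste0(label, "_ensemble"))
      done <- file.path(dir, "ensemble.json")
      if (!file.exists(done)) {
        stage(sprintf("simulating %d replicas x %d sweeps",
                      cfg$n_replicas, cfg$n_sweeps))
        ens <- tryCatch(simulate_ensemble(seq, cfg),
                        error = function(e)
                          stop("simulate stage [", label, "]: ",
                               conditionMessage(e)))
        write_ensemble(ens, dir, config = cfg)
      } else stage("reusing cached ensemble")
      # downstream always consumes the persisted artifact
      ens <- read_ensemble(dir)
      for (k in seq_along(ens)) ens[[k]]$topology <- seq
      return(ens)
    }
    stage(sprintf("simulating %d replicas x %d sweeps",
                  cfg$n_replicas, cfg$n_sweeps))
    simulate_ensemble(seq, cfg)
  }

  wt_ens <- get_ensemble("wt", wt_seq, wt_sim, wt_ensemble)
  var_ens <- get_ensemble("variant", var_seq, var_sim, var_ensemble)

  analyze <- function(label, ens) {
    rep_stab <- tryCatch(
      stability_report(ens, assessment_start_ns = assessment_start_ns,
                       sd_threshold = sd_threshold,
                       slope_threshold = slope_threshold),
      error = function(e) stop("stability stage [", label, "]: ",
                               conditionMessage(e)))
    stable_ids <- rep_stab$replica_id[rep_stab$stable]
    if (length(stable_ids) == 0)
      stop("no stable replicas in condition '", label,
           "' under the current thresholds")
    stable <- ens[vapply(ens, `[[`, 1L, "replica_id") %in% stable_ids]
    reps <- tryCatch(
      cluster_representatives(stable, window, rmsd_cutoff = rmsd_cutoff),
      error = function(e) stop("cluster stage [", label, "]: ",
                               conditionMessage(e)))
    radius <- ensemble_radius_stats(reps, hydration_shell,
                                    use_shape_correction)
    sites <- phenylalanine_sites(ens[[1]]$topology)
    mats <- lapply(stable, function(tr)
      ff_distance_matrix(sample_window(tr, window), sites))
    list(stability = rep_stab, stable_ids = stable_ids, stable = stable,
         representatives = reps, radius = radius, ff_matrices = mats,
         sites = sites)
  }

  wt <- analyze("wt", wt_ens)
  va <- analyze("variant", var_ens)

  cohesion <- compare_cohesion(wt$ff_matrices, va$ff_matrices,
                               threshold = variation_threshold)

  exposure <- lapply(va$stable, function(tr) {
    p <- burial_proxy(sample_window(tr, window), variant$position,
                      cutoff = burial_cutoff, k_buried = burial_k)
    list(replica_id = tr$replica_id,
         fraction_exposed = p$fraction_exposed,
         mean_neighbors = mean(p$sasa), method = p$method)
  })

  report <- structure(list(
    sequence = list(id = wt_seq$id, length = length(wt_seq),
                    variant = sprintf("p.%s%d%s", variant$ref_aa,
                                      variant$position, variant$alt_aa),
                    f_sites = wt$sites),
    stability = list(
      wt = list(n_replicas = nrow(wt$stability),
                n_stable = sum(wt$stability$stable),
                stable_ids = wt$stable_ids),
      variant = list(n_replicas = nrow(va$stability),
                     n_stable = sum(va$stability$stable),
                     stable_ids = va$stable_ids)),
    representatives = list(
      wt = data.frame(
        replica_id = vapply(wt$representatives, `[[`, 1L, "replica_id"),
        time_ns = vapply(wt$representatives, `[[`, 1, "time_ns"),
        cluster_size = vapply(wt$representatives, `[[`, 1L, "cluster_size")),
      variant = data.frame(
        replica_id = vapply(va$representatives, `[[`, 1L, "replica_id"),
        time_ns = vapply(va$representatives, `[[`, 1, "time_ns"),
        cluster_size = vapply(va$representatives, `[[`, 1L,
                              "cluster_size"))),
    radius = list(
      wt = wt$radius[c("radii", "mean", "median", "q1", "q3", "iqr", "n")],
      variant = va$radius[c("radii", "mean", "median", "q1", "q3", "iqr",
                            "n")]),
    cohesion = list(
      site_indices = cohesion$site_indices,
      grand_mean_wt = cohesion$grand_mean_wt,
      grand_mean_var = cohesion$grand_mean_var,
      flagged_fraction = cohesion$flagged_fraction,
      n_flagged = nrow(cohesion$flagged_pairs),
      n_pairs = length(cohesion$site_indices) *
        (length(cohesion$site_indices) - 1) / 2,
      threshold = cohesion$threshold,
      flagged_pairs = cohesion$flagged_pairs),
    exposure = list(residue = variant$position,
                    method = "ca_neighbor_proxy",
                    per_replica = exposure,
                    fraction_exposed = mean(vapply(
                      exposure, `[[`, 1, "fraction_exposed"))),
    provenance = list(
      package_version = as.character(utils::packageVersion("fgcohesion")),
      seed = sim$seed,
      sim_config = unclass(sim)[setdiff(names(unclass(sim)),
                                        "variant_position")],
      window = unclass(window),
      thresholds = list(assessment_start_ns = assessment_start_ns,
                        sd_threshold = sd_threshold,
                        slope_threshold = slope_threshold,
                        rmsd_cutoff = rmsd_cutoff,
                        variation_threshold = variation_threshold,
                        hydration_shell = hydration_shell,
                        use_shape_correction = use_shape_correction,
                        burial_cutoff = burial_cutoff,
                        burial_k = burial_k))),
    class = "comparison_report")
  attr(report, "cohesion_full") <- cohesion

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_rmsd_csv(wt$stability, file.path(out_dir, "rmsd_wt.csv"))
    write_rmsd_csv(va$stability, file.path(out_dir, "rmsd_variant.csv"))
    write_cohesion_csv(cohesion, file.path(out_dir, "cohesion"))
    write_network(cohesion_network(cohesion, "wt"),
                  file.path(out_dir, "network_wt.graphml"))
    write_network(cohesion_network(cohesion, "variant"),
                  file.path(out_dir, "network_variant.graphml"))
    write_representatives(wt$representatives, wt_ens,
                          file.path(out_dir, "representatives_wt"))
    write_representatives(va$representatives, var_ens,
                          file.path(out_dir, "representatives_variant"))
    write_comparison_report(report, file.path(out_dir, "report.json"))
  }
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>", x$sequence$id, x$sequence$variant, "\n")
  cat(sprintf("  stable replicas: WT %d/%d, variant %d/%d\n",
              x$stability$wt$n_stable, x$stability$wt$n_replicas,
              x$stability$variant$n_stable, x$stability$variant$n_replicas))
  cat(sprintf("  mean Rh: WT %.2f A, variant %.2f A\n",
              x$radius$wt$mean, x$radius$variant$mean))
  cat(sprintf("  grand-mean F-F: WT %.2f A, variant %.2f A; %.1f%% of pairs > %.0f%% variation\n",
              x$cohesion$grand_mean_wt, x$cohesion$grand_mean_var,
              x$cohesion$flagged_fraction, x$cohesion$threshold))
  cat(sprintf("  variant residue exposed in %.0f%% of frames (%s)\n",
              100 * x$exposure$fraction_exposed, x$exposure$method))
  invisible(x)
}

#' Write a comparison report to JSON
#'
#' Full numeric precision (`digits = NA`), so a written report reloads
#' losslessly with [read_comparison_report()].
#'
#' @param report a `comparison_report`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", null = "null")
  invisible(path)
}

#' Read a comparison report written by [write_comparison_report()]
#' @param path JSON file.
#' @return A `comparison_report`.
#' @export
read_comparison_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "comparison_report")
}
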