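#' Write a result table as TSV with a commented provenance header
#'
#' @param df `data.frame` to write.
#' @param path Output path.
#' @param header Character vector of comment lines (written prefixed
#'   with `"# "`).
#' @return Invisibly, `path`.
#' @export
write_result_tsv <- function(df, path, header = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(header))
    writeLines(paste("#", header), con, sep = "\n", useBytes = TRUE)
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n",
             useBytes = TRUE)
  body <- do.call(paste, c(lapply(df, format_tsv_col), list(sep = "\t")))
  writeLines(body, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

format_tsv_col <- function(x) {
  if (is.numeric(x)) formatC(x, format = "g", digits = 10) else as.character(x)
}

#' Run the full label-trajectory analysis and write report tables
#'
#' Drives the unfolding and transition-kinetics analyses end to end for
#' every ensemble of a manifest (or a supplied list of ensembles) and
#' writes four TSV tables per ensemble into `outdir`:
#' \describe{
#'   \item{`<name>_run_summary.tsv`}{per-run unfolding time, region
#'     order and helix content, plus commented ensemble statistics.}
#'   \item{`<name>_residue_content.tsv`}{per-residue content of all
#'     eight classes.}
#'   \item{`<name>_transitions.tsv`}{tidy per-residue transition counts
#'     and probabilities (reduced or full classing).}
#'   \item{`<name>_triads.tsv`}{triad probabilities for the whole chain
#'     and each region.}
#' }
#'
#' @param manifest Path to a manifest file (see [load_manifest()]), or
#'   a named list of [run_ensemble()] objects.
#' @param outdir Output directory (created if needed).
#' @param part A [region_partition()].
#' @param classing `"reduced"` or `"full"` for the transition tables.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list of written file paths.
#' @export
run_analysis <- function(manifest, outdir, part = region_partition(),
                         classing = c("reduced", "full"), quiet = FALSE) {
  classing <- match.arg(classing)
  ensembles <- if (is.character(manifest)) load_manifest(manifest,
                                                         quiet = quiet)
               else manifest
  if (!all(vapply(ensembles, inherits, logical(1), "run_ensemble")))
    stop("manifest must be a file path or a list of run_ensemble objects",
         call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (ens in ensembles) {
    nm <- ens$name
    summ <- summarize_runs(ens, part)
    st <- summ$stats
    p1 <- file.path(outdir, paste0(nm, "_run_summary.tsv"))
    write_result_tsv(summ$runs, p1, header = c(
      sprintf("ensemble=%s runs=%d never_unfolded=%d", nm, st$n_runs,
              st$n_never),
      sprintf("t_u_ns mean=%.4g median=%.4g sd=%.4g", st$t_u_mean_ns,
              st$t_u_median_ns, st$t_u_sd_ns),
      sprintf("terminus_to_terminus=%d", st$n_terminus_to_terminus),
      "residue positions 1-based; t_u_ns=NA means the run never unfolded"))
    prof <- content_profile(ens)
    p2 <- file.path(outdir, paste0(nm, "_residue_content.tsv"))
    write_result_tsv(
      data.frame(i = seq_len(ncol(prof)), t(prof), check.names = FALSE),
      p2, header = sprintf("per-residue class content, ensemble=%s", nm))
    p3 <- file.path(outdir, paste0(nm, "_transitions.tsv"))
    write_result_tsv(
      cbind(ensemble = nm, transition_profile(ens, classing)), p3,
      header = sprintf("one-frame-lag transition table, classing=%s",
                       classing))
    tri <- triad_region_matrix(ens, part)
    p4 <- file.path(outdir, paste0(nm, "_triads.tsv"))
    anom <- triad_stats(ens, part, "All")$anomalies
    write_result_tsv(tri, p4, header = c(
      sprintf("triad next-frame helix probabilities, ensemble=%s", nm),
      sprintf("impossible_-H-_anomalies=%d", anom)))
    if (anom > 0L)
      warning(sprintf("ensemble '%s': %d impossible -H- triads found", nm,
                      anom), call. = FALSE)
    if (!quiet)
      message(sprintf("ensemble '%s': wrote 4 tables to %s", nm, outdir))
    paths[[nm]] <- c(run_summary = p1, residue_content = p2,
                     transitions = p3, triads = p4)
  }
  invisible(paths)
}

#' Simulate an ensemble to disk, with an analyzable manifest
#'
#' Writes `n_runs` synthetic label trajectories (frames-as-lines
#' dialect) plus a `manifest.yaml` that [run_analysis()] accepts.
#'
#' @param outdir Output directory.
#' @param n_runs Number of runs.
#' @param params A [helix_params()].
#' @param seed Master seed.
#' @param name Ensemble name.
#' @return Invisibly, the manifest path.
#' @export
run_simulation <- function(outdir, n_runs = 10, params = helix_params(),
                           seed = 1L, name = "synthetic") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ens <- make_synthetic_ensemble(n_runs, params, seed = seed, name = name)
  files <- character(n_runs)
  for (k in seq_len(n_runs)) {
    files[k] <- paste0(ens$members[[k]]$run_id, ".dat")
    write_ss_trajectory(ens$members[[k]], file.path(outdir, files[k]))
  }
  manifest <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(list(ensembles = list(list(
    name = name,
    frame_interval_ps = params$frame_interval,
    files = as.list(files)))), manifest)
  invisible(manifest)
}

# Fig-style color mapping of the eight classes.
.ss_colors <- c(H = "red", G = "maroon", I = "darkred", E = "gray",
                B = "black", T = "darkcyan", S = "cyan", O = "white")

#' Raster plot of a label trajectory
#'
#' Time (frames) on the horizontal axis, residue position on the
#' vertical axis, each cell colored by its secondary-structure class
#' with the conventional mapping (`H` red, `G` maroon, `I` dark red,
#' `E` gray, `B` black, `T` dark cyan, `S` cyan, `O` white).
#'
#' @param traj An [ss_trajectory()].
#' @return A ggplot object.
#' @export
plot_ss_raster <- function(traj) {
  stopifnot(inherits(traj, "ss_trajectory"))
  df <- data.frame(
    time_ns = rep(frame_times(traj, "ns"), times = n_residues(traj)),
    residue = rep(seq_len(n_residues(traj)), each = n_frames(traj)),
    ss = factor(as.vector(traj$labels), levels = ss_alphabet()))
  ggplot2::ggplot(df, ggplot2::aes(x = time_ns, y = residue, fill = ss)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = .ss_colors, drop = FALSE,
                               name = "class") +
    ggplot2::labs(x = "time (ns)", y = "residue",
                  title = traj$run_id) +
    ggplot2::theme_minimal()
}
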