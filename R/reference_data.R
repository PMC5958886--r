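#' Published per-run unfolding reference table
#'
#' The per-run unfolding statistics reported for 28 canonical MD
#' trajectories of a 20-residue fully protonated poly-glutamic acid
#' started from alpha-helical conformations: 20 runs from an ideal
#' helix (`Ide1`-`Ide20`) and eight from a simulated helical structure
#' (`Sim1`-`Sim8`). Columns: `run_id`, `ensemble`, `t_u_ns` (unfolding
#' time), `order` (region-ordered unfolding over the default N/M/C
#' partition) and `helix_content` (P(H)+P(G) over the full run).
#'
#' Useful as the input to [ensemble_stats()] to aggregate published
#' per-run values without the underlying label trajectories.
#'
#' @param ensemble Optional filter, `"Ide"` or `"Sim"`.
#' @return `data.frame` with 28 rows (or the filtered subset).
#' @export
#' @examples
#' ref <- reference_run_summary()
#' ensemble_stats(ref)$t_u_median_ns
reference_run_summary <- function(ensemble = NULL) {
  path <- system.file("extdata", "pga20_run_summary_reference.tsv",
                      package = "sshelix", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(ensemble)) df <- df[df$ensemble %in% ensemble, , drop = FALSE]
  df
}

#' Location of the deposited raw label trajectories, if installed
#'
#' The full raw data behind the reference table — per-residue
#' secondary-structure label trajectories for all 28 runs — is a
#' multi-megabyte public archive that is not bundled with the package.
#' To reproduce the full-trajectory statistics, place the unpacked
#' per-run label files (frames-as-lines or table dialect, one file per
#' run named `Ide1` ... `Ide20`, `Sim1` ... `Sim8` with any extension)
#' together with a `manifest.yaml` under
#' `<sshelix installation>/extdata/deposited/` (or pass the directory
#' explicitly).
#'
#' @param dir Directory to look in; defaults to the package's
#'   `extdata/deposited` directory.
#' @return The manifest path if present, otherwise `NA_character_`.
#' @export
deposited_data_manifest <- function(dir = system.file("extdata", "deposited",
                                                      package = "sshelix")) {
  if (is.null(dir) || !nzchar(dir)) return(NA_character_)
  manifest <- file.path(dir, "manifest.yaml")
  if (file.exists(manifest)) manifest else NA_character_
}
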