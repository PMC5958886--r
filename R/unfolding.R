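#' Unfolding time of a run
#'
#' The unfolding time `t_u` is the time of the first snapshot in which
#' no residue is alpha-helical (label `H`; the 3_10-helix `G` does not
#' count). Runs in which every frame retains at least one `H` residue
#' have no unfolding time and return `NA` ("never").
#'
#' @param traj An [ss_trajectory()].
#' @param units `"ns"` (default) or `"ps"`.
#' @return Numeric scalar time, or `NA_real_` if the run never unfolds.
#' @export
#' @examples
#' m <- rbind(rep("H", 20), rep("H", 20), rep("T", 20))
#' unfolding_time(ss_trajectory(m), units = "ps")   # 60 ps
unfolding_time <- function(traj, units = c("ns", "ps")) {
  units <- match.arg(units)
  stopifnot(inherits(traj, "ss_trajectory"))
  has_h <- rowSums(traj$labels == "H") > 0L
  k <- which(!has_h)
  if (length(k) == 0L) return(NA_real_)
  frame_times(traj, units)[k[1]]
}

#' Pooled per-residue content of secondary-structure classes
#'
#' For each residue position `i`, the fraction of frames (pooled over
#' all ensemble members) whose label at `i` belongs to `labels`.
#'
#' @param x An [ss_trajectory()] or [run_ensemble()].
#' @param labels Subset of [ss_alphabet()] to count (default `"H"`).
#' @return Named numeric vector of length `n_residues`, values in
#'   `[0, 1]`.
#' @export
residue_content <- function(x, labels = "H") {
  ens <- as_ensemble(x)
  labels <- normalize_ss_labels(labels)
  num <- 0
  den <- 0
  for (m in ens$members) {
    num <- num + colSums(matrix(m$labels %in% labels, nrow = n_frames(m)))
    den <- den + n_frames(m)
  }
  stats::setNames(num / den, paste0("res", seq_along(num)))
}

#' Full per-residue content profile over the eight classes
#'
#' @param x An [ss_trajectory()] or [run_ensemble()].
#' @return Numeric matrix (8 classes x n_residues); every column sums
#'   to 1.
#' @export
content_profile <- function(x) {
  out <- t(vapply(ss_alphabet(), function(s) residue_content(x, s),
                  numeric(n_residues(as_ensemble(x)$members[[1]]))))
  rownames(out) <- ss_alphabet()
  out
}

#' Helix content of a trajectory or ensemble
#'
#' The fraction of residue-frame cells labeled `H` or `G`
#' (alpha- plus 3_10-helix), pooled over all frames (and members),
#' optionally restricted to a time window.
#'
#' @param x An [ss_trajectory()] or [run_ensemble()].
#' @param window Optional numeric `c(t_min, t_max)` in the units of
#'   `units`; only frames with `t_min <= t <= t_max` are pooled.
#' @param labels Which classes count as helical (default `c("H", "G")`).
#' @param units Units of `window`, `"ns"` (default) or `"ps"`.
#' @return Fraction in `[0, 1]`.
#' @export
helix_content <- function(x, window = NULL, labels = c("H", "G"),
                          units = c("ns", "ps")) {
  units <- match.arg(units)
  ens <- as_ensemble(x)
  labels <- normalize_ss_labels(labels)
  num <- 0
  den <- 0
  for (m in ens$members) {
    keep <- rep(TRUE, n_frames(m))
    if (!is.null(window)) {
      tt <- frame_times(m, units)
      keep <- tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9
    }
    if (!any(keep)) next
    sub <- m$labels[keep, , drop = FALSE]
    num <- num + sum(sub %in% labels)
    den <- den + length(sub)
  }
  if (den == 0) stop("the requested window contains no frames", call. = FALSE)
  num / den
}

#' Running (time-accumulated) helix content
#'
#' At each frame `k`, the helix content pooled over frames `1..k` —
#' the average over the accumulated duration of the run, used to judge
#' convergence of a trajectory.
#'
#' @param traj An [ss_trajectory()].
#' @param labels Which classes count as helical (default `c("H", "G")`).
#' @return `data.frame` with columns `time_ps`, `time_ns`,
#'   `helix_content`.
#' @export
running_helix_content <- function(traj, labels = c("H", "G")) {
  stopifnot(inherits(traj, "ss_trajectory"))
  labels <- normalize_ss_labels(labels)
  per_frame <- rowSums(matrix(traj$labels %in% labels,
                              nrow = n_frames(traj))) / n_residues(traj)
  t_ps <- frame_times(traj, "ps")
  data.frame(time_ps = t_ps, time_ns = t_ps / 1000,
             helix_content = cumsum(per_frame) / seq_along(per_frame))
}

#' Region-ordered unfolding of one run
#'
#' Ranks the partition's regions by their mean alpha-helix content over
#' the window from the start of the run up to and including the
#' unfolding time `t_u`: the region with the lowest content unfolded
#' first. Ties are broken by the earlier time at which a region first
#' becomes completely helix-free within the window, then by the
#' partition's region order.
#'
#' @param traj An [ss_trajectory()].
#' @param part A [region_partition()].
#' @param labels Classes counted as helical for the ranking; default
#'   `"H"` only, matching the alpha-helix-based definition of `t_u`
#'   (set `c("H", "G")` to include 3_10-helix).
#' @param include_tu_frame Include the first helix-free frame in the
#'   window (default `TRUE`).
#' @return Character vector: the region names, first-unfolded first.
#' @export
unfolding_order <- function(traj, part = region_partition(), labels = "H",
                            include_tu_frame = TRUE) {
  stopifnot(inherits(traj, "ss_trajectory"), inherits(part, "region_partition"))
  check_partition(part, n_residues(traj))
  tu <- unfolding_time(traj, "ps")
  if (is.na(tu))
    stop("run ", traj$run_id, " did not unfold: t_u is undefined",
         call. = FALSE)
  tt <- frame_times(traj, "ps")
  keep <- if (include_tu_frame) tt <= tu + 1e-9 else tt < tu - 1e-9
  lab <- traj$labels[keep, , drop = FALSE]
  labels <- normalize_ss_labels(labels)
  is_h <- matrix(lab %in% labels, nrow = nrow(lab))
  content <- vapply(part$regions,
                    function(pos) mean(is_h[, pos, drop = FALSE]),
                    numeric(1))
  # first frame (within the window) at which the region holds no helix
  first_free <- vapply(part$regions, function(pos) {
    free <- rowSums(is_h[, pos, drop = FALSE]) == 0L
    if (any(free)) which(free)[1] else nrow(is_h) + 1L
  }, numeric(1))
  ord <- order(content, first_free, seq_along(part$regions))
  region_names(part)[ord]
}

#' Per-run unfolding summaries and ensemble statistics
#'
#' Computes, for every member of an ensemble, the unfolding time, the
#' region-ordered unfolding classification and the helix content, and
#' aggregates them into ensemble statistics (see [ensemble_stats()]).
#' Runs that never unfold are excluded from the `t_u` statistics and
#' from the order counts, and reported in `stats$n_never`.
#'
#' @param ens A [run_ensemble()].
#' @param part A [region_partition()].
#' @param order_labels Classes counted as helical by [unfolding_order()].
#' @return List of class `unfolding_summary` with elements `runs`
#'   (`data.frame`: `run_id`, `t_u_ns`, `order`, `helix_content`) and
#'   `stats` (see [ensemble_stats()]).
#' @export
summarize_runs <- function(ens, part = region_partition(),
                           order_labels = "H") {
  ens <- as_ensemble(ens)
  runs <- lapply(ens$members, function(m) {
    tu <- unfolding_time(m, "ns")
    ord <- if (is.na(tu)) NA_character_ else
      paste(unfolding_order(m, part, labels = order_labels), collapse = ",")
    data.frame(run_id = m$run_id, t_u_ns = tu, order = ord,
               helix_content = helix_content(m),
               stringsAsFactors = FALSE)
  })
  runs <- do.call(rbind, runs)
  structure(list(runs = runs, stats = ensemble_stats(runs, part)),
            class = "unfolding_summary")
}

#' Ensemble statistics from a per-run summary table
#'
#' Aggregates a table of per-run unfolding times and region orders:
#' mean, median and sample standard deviation (n - 1) of the defined
#' `t_u` values; counts of each order pattern; how many runs unfolded
#' from each terminal region first; and how many followed a
#' terminus-to-opposite-terminus order (first and last entries are the
#' two terminal regions with the middle region last, e.g. `N,M,C` or
#' `C,M,N`).
#'
#' @param runs `data.frame` with columns `run_id`, `t_u_ns` (`NA` =
#'   never unfolded) and `order` (comma-separated region names, e.g.
#'   `"C,N,M"`). A `helix_content` column is carried through if present.
#' @param part The [region_partition()] whose region names appear in
#'   `order`; the first and last names are taken as the termini.
#' @return List with `n_runs`, `n_never`, `t_u_mean_ns`,
#'   `t_u_median_ns`, `t_u_sd_ns`, `order_counts` (named integer),
#'   `first_region_counts`, and `n_terminus_to_terminus`.
#' @export
ensemble_stats <- function(runs, part = region_partition()) {
  stopifnot(is.data.frame(runs), all(c("t_u_ns", "order") %in% names(runs)))
  tu <- runs$t_u_ns[!is.na(runs$t_u_ns)]
  orders <- runs$order[!is.na(runs$order)]
  rn <- region_names(part)
  term <- c(rn[1], rn[length(rn)])
  mid <- setdiff(rn, term)
  t2t_patterns <- c(paste(c(term[1], mid, term[2]), collapse = ","),
                    paste(c(term[2], mid, term[1]), collapse = ","))
  first_region <- vapply(strsplit(orders, ","), `[`, character(1), 1L)
  list(n_runs = nrow(runs),
       n_never = sum(is.na(runs$t_u_ns)),
       t_u_mean_ns = if (length(tu)) mean(tu) else NA_real_,
       t_u_median_ns = if (length(tu)) stats::median(tu) else NA_real_,
       t_u_sd_ns = if (length(tu) > 1L) stats::sd(tu) else NA_real_,
       order_counts = table(orders),
       first_region_counts = table(factor(first_region, levels = rn)),
       n_terminus_to_terminus = sum(orders %in% t2t_patterns))
}

#' @export
print.unfolding_summary <- function(x, ...) {
  s <- x$stats
  cat(sprintf("unfolding summary: %d runs (%d never unfolded)\n",
              s$n_runs, s$n_never))
  cat(sprintf("  t_u  mean %.2f ns, median %.2f ns, SD %.2f ns\n",
              s$t_u_mean_ns, s$t_u_median_ns, s$t_u_sd_ns))
  cat("  order patterns:",
      paste(sprintf("%s x%d", names(s$order_counts), s$order_counts),
            collapse = "  "), "\n")
  cat(sprintf("  terminus-to-opposite-terminus runs: %d\n",
              s$n_terminus_to_terminus))
  invisible(x)
}
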