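#' Secondary-structure label trajectory
#'
#' An `ss_trajectory` holds the per-residue secondary-structure labels of
#' one simulation run as a character matrix with one row per recorded
#' snapshot (frame) and one column per residue. Residue positions are
#' 1-based; capping groups (Ace/Nme) are never residues. The time of
#' frame `k` (1-based row `k`) is `time_offset + (k - 1) * frame_interval`
#' picoseconds, i.e. the first stored frame is the snapshot recorded
#' `time_offset` ps after the initial structure.
#'
#' @param labels Character matrix (`n_frames x n_residues`) of symbols
#'   over [ss_alphabet()]; synonyms of the blank class are normalized.
#' @param run_id Short text label for the run (e.g. `"run07"`).
#' @param frame_interval Time between recorded frames, in ps (default 20).
#' @param time_offset Time of the first stored frame, in ps; defaults to
#'   `frame_interval`.
#' @return An object of class `ss_trajectory`.
#' @seealso [read_ss_trajectory()], [frame_times()], [unfolding_time()]
#' @export
#' @examples
#' m <- matrix("H", nrow = 3, ncol = 20)
#' m[3, ] <- "T"
#' traj <- ss_trajectory(m, run_id = "toy")
#' unfolding_time(traj)
ss_trajectory <- function(labels, run_id = "run",
                          frame_interval = 20,
                          time_offset = frame_interval) {
  if (!is.matrix(labels)) labels <- matrix(labels, nrow = 1)
  if (nrow(labels) < 1L || ncol(labels) < 1L)
    stop("a trajectory needs at least one frame and one residue",
         call. = FALSE)
  lab <- matrix(normalize_ss_labels(as.character(labels),
                                    context = paste0("trajectory ", run_id)),
                nrow = nrow(labels), ncol = ncol(labels))
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be a positive duration in ps", call. = FALSE)
  structure(list(run_id = as.character(run_id),
                 labels = lab,
                 frame_interval = as.numeric(frame_interval),
                 time_offset = as.numeric(time_offset)),
            class = "ss_trajectory")
}

#' @export
print.ss_trajectory <- function(x, ...) {
  cat(sprintf("ss_trajectory '%s': %d frames x %d residues, %g ps/frame (offset %g ps)\n",
              x$run_id, nrow(x$labels), ncol(x$labels),
              x$frame_interval, x$time_offset))
  tab <- sort(table(x$labels), decreasing = TRUE)
  cat("  label content:",
      paste(sprintf("%s=%.3f", names(tab), tab / sum(tab)), collapse = " "),
      "\n")
  invisible(x)
}

#' Number of frames / residues of a trajectory
#' @param traj An `ss_trajectory`.
#' @return Integer scalar.
#' @export
n_frames <- function(traj) nrow(traj$labels)

#' @rdname n_frames
#' @export
n_residues <- function(traj) ncol(traj$labels)

#' Times of the recorded frames
#'
#' @param traj An `ss_trajectory`.
#' @param units `"ps"` or `"ns"`.
#' @return Numeric vector of length `n_frames(traj)`.
#' @export
frame_times <- function(traj, units = c("ps", "ns")) {
  units <- match.arg(units)
  t_ps <- traj$time_offset + (seq_len(n_frames(traj)) - 1L) * traj$frame_interval
  if (units == "ns") t_ps / 1000 else t_ps
}

#' Truncate a trajectory in time
#'
#' Drops every frame whose time exceeds `t_max`. Used to build
#' fixed-duration ensembles from runs of unequal length (e.g. analyzing
#' only the first 400 ns of longer runs).
#'
#' @param traj An `ss_trajectory`.
#' @param t_max Maximum retained frame time.
#' @param units Units of `t_max`, `"ns"` (default) or `"ps"`.
#' @return An `ss_trajectory` with frames at time `<= t_max`.
#' @export
truncate_trajectory <- function(traj, t_max, units = c("ns", "ps")) {
  units <- match.arg(units)
  t_max_ps <- if (units == "ns") t_max * 1000 else t_max
  keep <- frame_times(traj, "ps") <= t_max_ps + 1e-9
  if (!any(keep))
    stop("truncation at ", t_max, " ", units, " leaves no frames in run ",
         traj$run_id, call. = FALSE)
  ss_trajectory(traj$labels[keep, , drop = FALSE], run_id = traj$run_id,
                frame_interval = traj$frame_interval,
                time_offset = traj$time_offset)
}

#' @export
as.matrix.ss_trajectory <- function(x, ...) x$labels
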