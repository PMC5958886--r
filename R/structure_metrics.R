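#' Coordinate trajectory of a peptide chain
#'
#' Holds per-frame Cartesian coordinates (in Angstrom) for a fixed atom
#' roster, for chain-geometry metrics (end-to-end distance, radius of
#' gyration). Construct directly from arrays or read a multi-model PDB
#' with [read_coord_trajectory()].
#'
#' @param xyz Numeric array `n_frames x n_atoms x 3`, or a matrix
#'   (`n_atoms x 3`) for a single frame.
#' @param atoms `data.frame` with one row per atom: columns `name`
#'   (atom name, e.g. `"CA"`), `resno` (residue number), `element`
#'   (element symbol, e.g. `"C"`; used to drop hydrogens).
#' @param run_id Run label.
#' @param frame_interval Time between frames in ps.
#' @return An object of class `coord_trajectory`.
#' @export
coord_trajectory <- function(xyz, atoms, run_id = "run", frame_interval = 20) {
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(1L, nrow(xyz), ncol(xyz)))
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[3] == 3L)
  if (!all(is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  stopifnot(is.data.frame(atoms), nrow(atoms) == dim(xyz)[2],
            all(c("name", "resno") %in% names(atoms)))
  if (is.null(atoms$element))
    atoms$element <- toupper(substr(trimws(atoms$name), 1, 1))
  structure(list(xyz = xyz, atoms = atoms, run_id = as.character(run_id),
                 frame_interval = as.numeric(frame_interval)),
            class = "coord_trajectory")
}

#' Read a multi-model PDB file as a coordinate trajectory
#'
#' Each MODEL of the PDB becomes one frame. Parsing is done with
#' \pkg{bio3d}; only ATOM/HETATM coordinates and the atom roster are
#' retained.
#'
#' @param path PDB file path.
#' @param run_id Run label; defaults to the file name.
#' @param frame_interval Time between models in ps.
#' @return A [coord_trajectory()].
#' @export
read_coord_trajectory <- function(path, run_id = NULL, frame_interval = 20) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(run_id)) run_id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)
  n_atoms <- ncol(xyz) / 3L
  arr <- array(NA_real_, dim = c(nrow(xyz), n_atoms, 3L))
  for (d in 1:3) arr[, , d] <- xyz[, seq(d, ncol(xyz), by = 3L), drop = FALSE]
  atoms <- data.frame(name = trimws(pdb$atom$elety),
                      resno = pdb$atom$resno,
                      element = toupper(trimws(ifelse(
                        is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
                        substr(trimws(pdb$atom$elety), 1, 1),
                        pdb$atom$elesy))),
                      stringsAsFactors = FALSE)
  coord_trajectory(arr, atoms, run_id = run_id,
                   frame_interval = frame_interval)
}

#' @export
print.coord_trajectory <- function(x, ...) {
  cat(sprintf("coord_trajectory '%s': %d frames x %d atoms (%d residues)\n",
              x$run_id, dim(x$xyz)[1], dim(x$xyz)[2],
              length(unique(x$atoms$resno))))
  invisible(x)
}

# Resolve an atom selector to row indices. A selector is either a
# logical/integer index vector or a list(name=, resno=) filter.
resolve_atoms <- function(ct, sel) {
  if (is.numeric(sel) || is.logical(sel)) {
    idx <- which(rep(TRUE, nrow(ct$atoms)))[sel]
  } else if (is.list(sel)) {
    keep <- rep(TRUE, nrow(ct$atoms))
    if (!is.null(sel$name)) keep <- keep & ct$atoms$name %in% sel$name
    if (!is.null(sel$resno)) keep <- keep & ct$atoms$resno %in% sel$resno
    if (!is.null(sel$element)) keep <- keep & ct$atoms$element %in% sel$element
    idx <- which(keep)
  } else stop("unsupported atom selector", call. = FALSE)
  idx
}

resolve_single_atom <- function(ct, sel, what) {
  idx <- resolve_atoms(ct, sel)
  if (length(idx) != 1L)
    stop(what, " selector must resolve to exactly one atom (got ",
         length(idx), ")", call. = FALSE)
  idx
}

# Approximate atomic masses for mass-weighted Rg.
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974)

#' End-to-end distance per frame
#'
#' Euclidean distance in Angstrom between two selected atoms, by
#' default the Calpha atoms of the first and last residues.
#'
#' @param ct A [coord_trajectory()].
#' @param start_sel,end_sel Atom selectors (`list(name=, resno=)` or an
#'   index), each resolving to exactly one atom.
#' @return Numeric vector, one distance per frame.
#' @export
end_to_end_distance <- function(ct,
                                start_sel = list(name = "CA",
                                                 resno = min(ct$atoms$resno)),
                                end_sel = list(name = "CA",
                                               resno = max(ct$atoms$resno))) {
  stopifnot(inherits(ct, "coord_trajectory"))
  a <- resolve_single_atom(ct, start_sel, "start")
  b <- resolve_single_atom(ct, end_sel, "end")
  d <- ct$xyz[, a, , drop = FALSE] - ct$xyz[, b, , drop = FALSE]
  sqrt(rowSums(matrix(d, nrow = dim(ct$xyz)[1])^2))
}

#' Radius of gyration per frame
#'
#' `sqrt( sum_j w_j |r_j - rbar|^2 / sum_j w_j )` with `rbar` the
#' (weighted) centroid of the selection. By default the selection is
#' all heavy (non-hydrogen) atoms with unit weights; `mass_weighted =
#' TRUE` uses atomic masses.
#'
#' @param ct A [coord_trajectory()].
#' @param sel Atom selector; default all non-hydrogen atoms.
#' @param mass_weighted Weight by atomic mass (default `FALSE`).
#' @return Numeric vector, one Rg (Angstrom) per frame.
#' @export
radius_of_gyration <- function(ct, sel = NULL, mass_weighted = FALSE) {
  stopifnot(inherits(ct, "coord_trajectory"))
  idx <- if (is.null(sel)) which(ct$atoms$element != "H")
         else resolve_atoms(ct, sel)
  if (length(idx) == 0L) stop("empty atom selection", call. = FALSE)
  w <- if (mass_weighted) {
    m <- .atomic_masses[ct$atoms$element[idx]]
    if (anyNA(m)) stop("unknown element(s) for mass weighting: ",
                       paste(unique(ct$atoms$element[idx][is.na(m)]),
                             collapse = ", "), call. = FALSE)
    m
  } else rep(1, length(idx))
  nf <- dim(ct$xyz)[1]
  vapply(seq_len(nf), function(k) {
    r <- matrix(ct$xyz[k, idx, ], ncol = 3L)
    ctr <- colSums(r * w) / sum(w)
    sqrt(sum(w * rowSums(sweep(r, 2L, ctr)^2)) / sum(w))
  }, numeric(1))
}

#' Time course of a chain metric, with ensemble mean and SD
#'
#' Evaluates a per-frame metric for one or more coordinate
#' trajectories and reports the per-frame values together with the
#' pooled (population over frames and runs) mean and standard
#' deviation.
#'
#' @param cts A [coord_trajectory()] or list of them.
#' @param metric `"end_to_end"` or `"rg"`, or a function
#'   `f(coord_trajectory) -> numeric`.
#' @param ... Passed to the metric function.
#' @return List with `series` (`data.frame`: `run_id`, `time_ps`,
#'   `value`) and `mean`, `sd` pooled over all frames of all runs.
#' @export
metric_timecourse <- function(cts, metric = c("end_to_end", "rg"), ...) {
  if (inherits(cts, "coord_trajectory")) cts <- list(cts)
  f <- if (is.function(metric)) metric
       else switch(match.arg(metric),
                   end_to_end = end_to_end_distance,
                   rg = radius_of_gyration)
  series <- do.call(rbind, lapply(cts, function(ct) {
    v <- f(ct, ...)
    data.frame(run_id = ct$run_id,
               time_ps = ct$frame_interval * seq_along(v),
               value = v, stringsAsFactors = FALSE)
  }))
  n <- nrow(series)
  list(series = series, mean = mean(series$value),
       sd = sqrt(sum((series$value - mean(series$value))^2) / n))
}
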