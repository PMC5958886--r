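#' A named collection of label trajectories
#'
#' A `run_ensemble` groups independent runs that are analyzed together
#' (pooled contents, pooled transition counts). All members must share
#' the residue count and frame interval. An optional truncation limits
#' every member to its first `truncation_ns` nanoseconds; truncation is
#' applied at construction so no downstream operation can see a frame
#' beyond the limit.
#'
#' @param members List of [ss_trajectory()] objects.
#' @param name Ensemble name (e.g. `"ideal-start"`).
#' @param truncation_ns Optional duration in ns; frames with time greater
#'   than this are discarded from every member.
#' @return An object of class `run_ensemble`.
#' @export
run_ensemble <- function(members, name = "ensemble", truncation_ns = NULL) {
  if (inherits(members, "ss_trajectory")) members <- list(members)
  if (length(members) < 1L)
    stop("an ensemble needs at least one member run", call. = FALSE)
  ok <- vapply(members, inherits, logical(1), "ss_trajectory")
  if (!all(ok)) stop("all members must be ss_trajectory objects", call. = FALSE)
  nres <- vapply(members, n_residues, integer(1))
  if (length(unique(nres)) != 1L)
    stop("members disagree on residue count: ",
         paste(unique(nres), collapse = ", "), call. = FALSE)
  dt <- vapply(members, function(m) m$frame_interval, numeric(1))
  if (length(unique(dt)) != 1L)
    stop("members disagree on frame interval: ",
         paste(unique(dt), collapse = ", "), call. = FALSE)
  if (!is.null(truncation_ns))
    members <- lapply(members, truncate_trajectory, t_max = truncation_ns,
                      units = "ns")
  structure(list(name = as.character(name), members = members,
                 truncation_ns = truncation_ns),
            class = "run_ensemble")
}

#' @export
print.run_ensemble <- function(x, ...) {
  nf <- vapply(x$members, n_frames, integer(1))
  cat(sprintf("run_ensemble '%s': %d runs x %d residues, %s frames total%s\n",
              x$name, length(x$members), n_residues(x$members[[1]]),
              format(sum(nf), big.mark = ","),
              if (is.null(x$truncation_ns)) ""
              else sprintf(" (truncated at %g ns)", x$truncation_ns)))
  invisible(x)
}

#' @export
length.run_ensemble <- function(x) length(x$members)

# Coerce a single trajectory to a one-member ensemble where convenient.
as_ensemble <- function(x) {
  if (inherits(x, "run_ensemble")) return(x)
  if (inherits(x, "ss_trajectory"))
    return(run_ensemble(list(x), name = x$run_id))
  stop("expected an ss_trajectory or run_ensemble", call. = FALSE)
}

#' Partition of the chain into named regions
#'
#' Maps residue positions to named regions for region-ordered unfolding
#' analysis. Regions must be pairwise disjoint and must not overlap the
#' excluded set. The default for a 20-residue chain splits positions
#' into an N-terminal region (2-7), a middle region (8-13) and a
#' C-terminal region (14-19), excluding the two terminal residues whose
#' secondary-structure assignment is distorted by chain truncation.
#'
#' @param regions Named list of integer vectors of residue positions.
#' @param excluded Integer vector of positions outside every region.
#' @return An object of class `region_partition`.
#' @export
#' @examples
#' region_partition()            # the default N/M/C split
region_partition <- function(regions = list(N = 2:7, M = 8:13, C = 14:19),
                             excluded = c(1L, 20L)) {
  if (is.null(names(regions)) || any(names(regions) == ""))
    stop("every region must be named", call. = FALSE)
  all_pos <- unlist(regions, use.names = FALSE)
  if (anyDuplicated(all_pos))
    stop("regions must be pairwise disjoint", call. = FALSE)
  if (length(intersect(all_pos, excluded)))
    stop("excluded positions cannot belong to a region", call. = FALSE)
  structure(list(regions = lapply(regions, as.integer),
                 excluded = as.integer(excluded)),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  for (nm in names(x$regions))
    cat(sprintf("  %s: residues %s\n", nm,
                paste(range(x$regions[[nm]]), collapse = "-")))
  if (length(x$excluded))
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Region names of a partition
#' @param part A [region_partition()].
#' @return Character vector.
#' @export
region_names <- function(part) names(part$regions)

check_partition <- function(part, nres) {
  pos <- unlist(part$regions, use.names = FALSE)
  if (any(pos < 1L) || any(pos > nres))
    stop("partition references residues outside 1..", nres, call. = FALSE)
  invisible(part)
}
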