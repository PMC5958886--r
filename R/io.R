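#' Read a secondary-structure label trajectory
#'
#' Three text dialects are supported:
#' \describe{
#'   \item{`lines`}{frames-as-lines: one line per frame, one character
#'     per residue (the deposited-raw-data style). Blank class may be
#'     written `O` or `-`.}
#'   \item{`table`}{delimited `frame`, `residue`, `label` rows (TSV/CSV,
#'     optional header, `#` comments ignored).}
#'   \item{`dssp`}{concatenated standard DSSP output blocks, one block
#'     per frame; only the summary structure letter (column 17 of each
#'     residue line) is consumed, with the blank class mapped to `O`.}
#' }
#' With `dialect = "auto"` the file is sniffed in the order
#' table, dssp, lines; a file matching none of them is an error rather
#' than a guess.
#'
#' @param path Path to the trajectory file.
#' @param dialect One of `"auto"`, `"lines"`, `"table"`, `"dssp"`.
#' @param run_id Run label; defaults to the file name without extension.
#' @param frame_interval,time_offset Frame timing in ps (see
#'   [ss_trajectory()]).
#' @return An [ss_trajectory()].
#' @export
read_ss_trajectory <- function(path, dialect = c("auto", "lines", "table", "dssp"),
                               run_id = NULL, frame_interval = 20,
                               time_offset = frame_interval) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  if (length(raw) == 0L || all(!nzchar(trimws(raw))))
    stop("empty trajectory file: ", path, call. = FALSE)
  if (is.null(run_id))
    run_id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "auto") dialect <- sniff_dialect(raw, path)
  labels <- switch(dialect,
                   lines = parse_lines_dialect(raw, path),
                   table = parse_table_dialect(raw, path),
                   dssp  = parse_dssp_dialect(raw, path))
  ss_trajectory(labels, run_id = run_id, frame_interval = frame_interval,
                time_offset = time_offset)
}

sniff_dialect <- function(raw, path) {
  body <- raw[nzchar(trimws(raw)) & !grepl("^\\s*#", raw)]
  if (any(grepl("#  RESIDUE AA STRUCTURE", raw, fixed = TRUE)))
    return("dssp")
  first <- body[1]
  fields <- strsplit(trimws(first), "[,\t ]+")[[1]]
  if (length(fields) >= 3L && !is.na(suppressWarnings(as.numeric(fields[1]))) &&
      !is.na(suppressWarnings(as.numeric(fields[2]))))
    return("table")
  if (all(tolower(fields[1:2]) %in% c("frame", "residue", "time", "label", "ss")))
    return("table")
  if (all(grepl("^[A-Za-z -]+$", body)))
    return("lines")
  stop("cannot determine the trajectory dialect of ", path,
       "; pass dialect explicitly", call. = FALSE)
}

parse_lines_dialect <- function(raw, path) {
  body_idx <- which(nzchar(trimws(raw)) & !grepl("^\\s*#", raw))
  lines <- raw[body_idx]
  widths <- nchar(lines)
  if (length(unique(widths)) != 1L) {
    off <- which(widths != widths[1])[1]
    stop("ragged frame lengths in ", path, ": line ", body_idx[off],
         " has ", widths[off], " residues, expected ", widths[1],
         call. = FALSE)
  }
  mat <- matrix(NA_character_, nrow = length(lines), ncol = widths[1])
  for (k in seq_along(lines)) {
    syms <- strsplit(lines[k], "", fixed = TRUE)[[1]]
    mat[k, ] <- normalize_ss_labels(syms,
                                    context = paste0(path, " line ", body_idx[k]))
  }
  mat
}

parse_table_dialect <- function(raw, path) {
  body <- raw[nzchar(trimws(raw)) & !grepl("^\\s*#", raw)]
  first_fields <- strsplit(trimws(body[1]), "[,\t ]+")[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first_fields[1])))
  if (has_header) body <- body[-1]
  parts <- strsplit(trimws(body), "[,\t ]+")
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("table dialect needs frame, residue, label columns; line with ",
         nf[which(nf < 3L)[1]], " fields in ", path, call. = FALSE)
  frame <- as.integer(vapply(parts, `[`, character(1), 1L))
  resid <- as.integer(vapply(parts, `[`, character(1), 2L))
  label <- vapply(parts, `[`, character(1), 3L)
  if (anyNA(frame) || anyNA(resid))
    stop("non-integer frame/residue index in table dialect of ", path,
         call. = FALSE)
  frames <- sort(unique(frame))
  resids <- sort(unique(resid))
  if (nrow(unique(cbind(frame, resid))) != length(frame))
    stop("duplicate (frame, residue) rows in ", path, call. = FALSE)
  if (length(frame) != length(frames) * length(resids))
    stop("table dialect of ", path, " is not a complete frame x residue grid",
         call. = FALSE)
  mat <- matrix(NA_character_, nrow = length(frames), ncol = length(resids))
  mat[cbind(match(frame, frames), match(resid, resids))] <-
    normalize_ss_labels(label, context = path)
  mat
}

parse_dssp_dialect <- function(raw, path) {
  starts <- grep("#  RESIDUE AA STRUCTURE", raw, fixed = TRUE)
  if (length(starts) == 0L)
    stop("no DSSP residue header found in ", path, call. = FALSE)
  ends <- c(starts[-1] - 1L, length(raw))
  frames <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- raw[(starts[b] + 1L):ends[b]]
    # residue lines carry the residue number in cols 6-10 and the
    # one-letter summary structure in col 17; chain breaks ("!") skipped
    block <- block[nchar(block) >= 17L]
    aa <- substr(block, 14, 14)
    keep <- aa != "!" & nzchar(trimws(substr(block, 6, 10)))
    block <- block[keep]
    if (length(block) == 0L)
      stop("DSSP block ", b, " of ", path, " has no residue lines",
           call. = FALSE)
    frames[[b]] <- normalize_ss_labels(substr(block, 17, 17),
                                       context = paste0(path, " block ", b))
  }
  nres <- lengths(frames)
  if (length(unique(nres)) != 1L)
    stop("DSSP blocks of ", path, " disagree on residue count", call. = FALSE)
  do.call(rbind, frames)
}

#' Write a label trajectory in the frames-as-lines dialect
#'
#' One line per frame, one character per residue; the blank class is
#' written as `O`. The output is UTF-8 with LF line endings and
#' round-trips exactly through [read_ss_trajectory()].
#'
#' @param traj An [ss_trajectory()].
#' @param path Output file path.
#' @param header Write a `#` comment header stating run id, frame
#'   timing, and 1-based residue indexing (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
write_ss_trajectory <- function(traj, path, header = TRUE) {
  stopifnot(inherits(traj, "ss_trajectory"))
  if (n_frames(traj) < 1L)
    stop("refusing to write an empty trajectory", call. = FALSE)
  lines <- apply(traj$labels, 1L, paste, collapse = "")
  if (header) {
    lines <- c(sprintf("# run_id=%s frame_interval_ps=%g time_offset_ps=%g",
                       traj$run_id, traj$frame_interval, traj$time_offset),
               "# one line per frame; residue positions 1-based, left to right",
               lines)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Load a run manifest describing one or more ensembles
#'
#' The manifest is a YAML file:
#' \preformatted{
#' ensembles:
#'   - name: ideal
#'     truncation_ns: 400        # optional
#'     frame_interval_ps: 20     # optional, default 20
#'     time_offset_ps: 20        # optional, default frame_interval
#'     files: [runs/ide1.dat, runs/ide2.dat]
#' }
#' Member paths are resolved relative to the manifest's directory.
#'
#' @param path Manifest file path.
#' @param quiet Suppress the per-ensemble member-count message.
#' @return Named list of [run_ensemble()] objects.
#' @export
load_manifest <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  spec <- yaml::read_yaml(path)
  if (is.null(spec$ensembles) || length(spec$ensembles) == 0L)
    stop("manifest ", path, " defines no ensembles", call. = FALSE)
  base <- dirname(normalizePath(path))
  out <- list()
  for (e in spec$ensembles) {
    if (is.null(e$name) || is.null(e$files))
      stop("each manifest ensemble needs 'name' and 'files'", call. = FALSE)
    dt <- if (is.null(e$frame_interval_ps)) 20 else e$frame_interval_ps
    t0 <- if (is.null(e$time_offset_ps)) dt else e$time_offset_ps
    files <- file.path(base, e$files)
    missing <- files[!file.exists(files)]
    if (length(missing))
      stop("manifest ensemble '", e$name, "': member file(s) not found: ",
           paste(missing, collapse = ", "), call. = FALSE)
    members <- lapply(files, read_ss_trajectory, frame_interval = dt,
                      time_offset = t0)
    ens <- run_ensemble(members, name = e$name,
                        truncation_ns = e$truncation_ns)
    if (!quiet)
      message(sprintf("ensemble '%s': %d runs, %s frames", e$name,
                      length(members),
                      format(sum(vapply(ens$members, n_frames, integer(1))),
                             big.mark = ",")))
    out[[e$name]] <- ens
  }
  out
}
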