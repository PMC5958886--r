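#' Secondary-structure transition table at one residue
#'
#' Counts transitions of the label at residue `i` between successive
#' recorded snapshots (one frame lag, 20 ps at the default recording
#' interval), pooled over all (frame t, frame t+lag) pairs of every
#' ensemble member; the last `lag` frames of each member are never a
#' source. Counts are pooled across runs before normalizing, giving one
#' probability estimate per ensemble. Rows of the probability matrix
#' whose source class was never observed are `NA` ("undefined"), which
#' is distinct from an observed class that never left (probability 1 on
#' the diagonal).
#'
#' @param x An [ss_trajectory()] or [run_ensemble()].
#' @param i Residue position (1-based).
#' @param classing `"reduced"` (`H`, `G`, `T`, `other` with `other` =
#'   \{I, E, S, B, O\}) or `"full"` (all eight classes).
#' @param lag Frame lag (default 1 recorded frame).
#' @return Object of class `transition_table`: list with `counts` and
#'   `prob` matrices (source class in rows, destination in columns),
#'   `scope`, `classing`, `lag`.
#' @export
#' @examples
#' m <- rbind(rep("H", 20), rep("T", 20))
#' tab <- transition_table(ss_trajectory(m), i = 5)
#' tab$prob["H", "T"]    # 1: the single observed H left to T
transition_table <- function(x, i, classing = c("reduced", "full"), lag = 1L) {
  classing <- match.arg(classing)
  ens <- as_ensemble(x)
  nres <- n_residues(ens$members[[1]])
  if (!(is.numeric(i) && length(i) == 1L && i >= 1 && i <= nres))
    stop("residue index i must be in 1..", nres, call. = FALSE)
  counts <- count_transitions(ens, as.integer(i), classing, as.integer(lag))
  new_transition_table(counts, scope = paste0("residue ", i),
                       classing = classing, lag = lag)
}

transition_classes <- function(classing) {
  if (classing == "reduced") ss_reduced_alphabet() else ss_alphabet()
}

class_labels <- function(v, classing) {
  if (classing == "reduced") reduce_ss_labels(v) else v
}

count_transitions <- function(ens, i, classing, lag) {
  cls <- transition_classes(classing)
  counts <- matrix(0L, length(cls), length(cls), dimnames = list(cls, cls))
  for (m in ens$members) {
    nf <- n_frames(m)
    if (nf <= lag) next
    v <- class_labels(m$labels[, i], classing)
    from <- factor(v[seq_len(nf - lag)], levels = cls)
    to <- factor(v[seq_len(nf - lag) + lag], levels = cls)
    counts <- counts + as.matrix(unclass(table(from, to)))
  }
  matrix(as.integer(counts), nrow = length(cls), ncol = length(cls),
         dimnames = list(cls, cls))
}

new_transition_table <- function(counts, scope, classing, lag) {
  prob <- counts / rowSums(counts)
  prob[rowSums(counts) == 0L, ] <- NA_real_
  structure(list(counts = counts, prob = prob, scope = scope,
                 classing = classing, lag = lag),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, digits = 3, ...) {
  cat(sprintf("transition_table (%s, %s classing, lag %d frame%s)\n",
              x$scope, x$classing, x$lag, if (x$lag == 1) "" else "s"))
  print(round(x$prob, digits))
  invisible(x)
}

#' Collapse a full-alphabet transition table to the reduced classing
#'
#' Sums the counts of the five classes \{I, E, S, B, O\} into `other`
#' on both axes; probabilities are re-derived from the collapsed counts.
#'
#' @param tab A full-classing `transition_table`.
#' @return A reduced-classing `transition_table` with identical pooled
#'   counts.
#' @export
reduce_transition_table <- function(tab) {
  stopifnot(inherits(tab, "transition_table"))
  if (tab$classing == "reduced") return(tab)
  cls <- ss_reduced_alphabet()
  grp <- reduce_ss_labels(rownames(tab$counts))
  counts <- matrix(0L, length(cls), length(cls), dimnames = list(cls, cls))
  for (a in seq_along(grp)) for (b in seq_along(grp))
    counts[grp[a], grp[b]] <- counts[grp[a], grp[b]] + tab$counts[a, b]
  new_transition_table(counts, scope = tab$scope, classing = "reduced",
                       lag = tab$lag)
}

#' Fraction of departures from a class that pass through another class
#'
#' Of all transitions that leave `from` (destination different from
#' `from`), the fraction that arrive at `via`:
#' `P(via, from) / sum over y != from of P(y, from)`. Used to quantify
#' kinetic intermediates, e.g. the share of helix departures that go
#' through the turn conformation.
#'
#' @param tab A `transition_table`.
#' @param from Source class.
#' @param via Destination class (must differ from `from`).
#' @return Fraction in `[0, 1]`; error if no departures from `from`
#'   were observed.
#' @export
flux_ratio <- function(tab, from, via) {
  stopifnot(inherits(tab, "transition_table"))
  cls <- rownames(tab$counts)
  if (!(from %in% cls) || !(via %in% cls))
    stop("classes must belong to ", paste(cls, collapse = ", "), call. = FALSE)
  if (from == via) stop("'via' must differ from 'from'", call. = FALSE)
  departures <- sum(tab$counts[from, setdiff(cls, from)])
  if (departures == 0L)
    stop("no departures from class ", from, " observed in ", tab$scope,
         call. = FALSE)
  tab$counts[from, via] / departures
}

#' Per-residue transition tables in tidy form
#'
#' [transition_table()] applied at every residue position, emitted as a
#' tidy `data.frame` keyed by residue, source and destination class.
#'
#' @inheritParams transition_table
#' @return `data.frame` with columns `i`, `from`, `to`, `count`,
#'   `probability` (`NA` where the source class was never observed at
#'   that position).
#' @export
transition_profile <- function(x, classing = c("reduced", "full"), lag = 1L) {
  classing <- match.arg(classing)
  ens <- as_ensemble(x)
  nres <- n_residues(ens$members[[1]])
  cls <- transition_classes(classing)
  out <- vector("list", nres)
  for (i in seq_len(nres)) {
    tab <- transition_table(ens, i, classing, lag)
    out[[i]] <- data.frame(i = i,
                           from = rep(cls, each = length(cls)),
                           to = rep(cls, times = length(cls)),
                           count = as.integer(t(tab$counts)),
                           probability = as.numeric(t(tab$prob)),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
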