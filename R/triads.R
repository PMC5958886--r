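#' The seven admissible triad classes
#'
#' Three consecutive residues are classed by their helix pattern, with
#' each residue either alpha-helical (`H`) or not (`-`). Because DSSP
#' assigns `H` only to runs of at least four consecutive residues, the
#' pattern `-H-` (an isolated helical residue) is impossible in valid
#' data; its occurrences are counted separately as anomalies.
#'
#' @return Character vector of the seven classes:
#'   `HHH, HH-, -HH, H-H, H--, --H, ---`.
#' @export
triad_classes <- function() c("HHH", "HH-", "-HH", "H-H", "H--", "--H", "---")

#' Helix-end elongation and unwinding statistics (triads)
#'
#' Every (frame `t`, center residue `c`) pair with a successor frame is
#' classified by the `H`/`-` pattern of residues `(c-1, c, c+1)` at
#' time `t`; the statistic of interest is the probability that the
#' center residue is `H` one frame later, per triad class. `P(H, HH-)`
#' is thus the retention probability of the C-terminal end of a helix,
#' `P(H, H--)` the probability of elongating a helix toward the
#' C-terminus, `P(H, ---)` the helix-nucleation probability, and so on;
#' the unwinding probability of a helix end is the complement
#' `P(-, class) = 1 - P(H, class)`.
#'
#' Centers are restricted to positions with both neighbors present
#' (2..n-1); a region scope further restricts centers to that region's
#' positions. Counts are pooled across all ensemble members.
#'
#' @param x An [ss_trajectory()] or [run_ensemble()].
#' @param part A [region_partition()] (used for region scopes).
#' @param scope `"All"` or one of the partition's region names.
#' @param lag Frame lag (default 1).
#' @return Object of class `triad_stats`: list with `scope`, `counts`
#'   (named integer per class), `p_next_H` (named numeric; `NA` where a
#'   class was never observed), and `anomalies` (count of impossible
#'   `-H-` patterns, excluded from the seven classes).
#' @export
#' @examples
#' m <- rbind(rep("H", 20), rep("H", 20))
#' triad_stats(ss_trajectory(m))$p_next_H[["HHH"]]   # 1
triad_stats <- function(x, part = region_partition(), scope = "All",
                        lag = 1L) {
  ens <- as_ensemble(x)
  nres <- n_residues(ens$members[[1]])
  check_partition(part, nres)
  if (!identical(scope, "All") && !(scope %in% region_names(part)))
    stop("scope must be \"All\" or one of: ",
         paste(region_names(part), collapse = ", "), call. = FALSE)
  centers <- if (identical(scope, "All")) 2:(nres - 1L)
             else intersect(part$regions[[scope]], 2:(nres - 1L))
  cls <- triad_classes()
  n_cls <- stats::setNames(integer(length(cls)), cls)
  n_next_H <- n_cls
  anomalies <- 0L
  for (m in ens$members) {
    nf <- n_frames(m)
    if (nf <= lag) next
    h <- m$labels == "H"
    src <- seq_len(nf - lag)
    for (c in centers) {
      pat <- paste0(ifelse(h[src, c - 1L], "H", "-"),
                    ifelse(h[src, c],      "H", "-"),
                    ifelse(h[src, c + 1L], "H", "-"))
      bad <- pat == "-H-"
      anomalies <- anomalies + sum(bad)
      ok <- !bad
      f <- factor(pat[ok], levels = cls)
      n_cls <- n_cls + table(f)
      n_next_H <- n_next_H + table(f[h[src + lag, c][ok]])
    }
  }
  p <- ifelse(n_cls > 0L, n_next_H / n_cls, NA_real_)
  structure(list(scope = scope,
                 counts = stats::setNames(as.integer(n_cls), cls),
                 p_next_H = stats::setNames(as.numeric(p), cls),
                 anomalies = anomalies),
            class = "triad_stats")
}

#' @export
print.triad_stats <- function(x, digits = 2, ...) {
  cat(sprintf("triad_stats (scope %s): %s triads, %d '-H-' anomalies\n",
              x$scope, format(sum(x$counts), big.mark = ","), x$anomalies))
  df <- data.frame(class = names(x$counts), count = x$counts,
                   p_next_H = round(x$p_next_H, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Triad probabilities across the whole chain and each region
#'
#' Assembles [triad_stats()] at scope `"All"` and at each region of the
#' partition into one report table of next-frame helix probabilities
#' per triad class, together with the unwinding complements
#' `P(-, HH-)` and `P(-, -HH)` for the two helix-end classes.
#'
#' @param x An [ss_trajectory()] or [run_ensemble()].
#' @param part A [region_partition()].
#' @param lag Frame lag (default 1).
#' @return `data.frame` with one row per reported probability
#'   (`P(H, HHH)`, `P(-, HH-)`, `P(-, -HH)`, `P(H, H--)`, `P(H, --H)`,
#'   `P(H, H-H)`, `P(H, ---)`) and one column per scope
#'   (`All` plus each region).
#' @export
triad_region_matrix <- function(x, part = region_partition(), lag = 1L) {
  ens <- as_ensemble(x)
  scopes <- c("All", region_names(part))
  stats <- lapply(scopes, function(s) triad_stats(ens, part, s, lag))
  names(stats) <- scopes
  rows <- list(c("H", "HHH"), c("-", "HH-"), c("-", "-HH"),
               c("H", "H--"), c("H", "--H"), c("H", "H-H"), c("H", "---"))
  out <- vapply(stats, function(st) {
    vapply(rows, function(r) {
      p <- st$p_next_H[[r[2]]]
      if (r[1] == "H") p else 1 - p
    }, numeric(1))
  }, numeric(length(rows)))
  data.frame(quantity = vapply(rows, function(r)
    sprintf("P(%s, %s)", r[1], r[2]), character(1)),
    out, check.names = FALSE, stringsAsFactors = FALSE)
}
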