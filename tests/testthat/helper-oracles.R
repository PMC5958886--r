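# Brute-force oracles and fixture builders, independent of the package's
# vectorized counting paths.

random_label_matrix <- function(n_frames, n_residues,
                                alphabet = ss_alphabet()) {
  matrix(sample(alphabet, n_frames * n_residues, replace = TRUE),
         nrow = n_frames, ncol = n_residues)
}

random_ensemble <- function(n_runs, n_frames, n_residues = 20,
                            alphabet = ss_alphabet()) {
  run_ensemble(lapply(seq_len(n_runs), function(k)
    ss_trajectory(random_label_matrix(n_frames, n_residues, alphabet),
                  run_id = paste0("r", k))))
}

# nested-loop per-residue content
brute_residue_content <- function(ens, labels) {
  nres <- ncol(ens$members[[1]]$labels)
  num <- numeric(nres); den <- 0
  for (m in ens$members) {
    for (k in seq_len(nrow(m$labels))) {
      den <- den + 1
      for (i in seq_len(nres))
        if (m$labels[k, i] %in% labels) num[i] <- num[i] + 1
    }
  }
  num / den
}

# nested-loop transition counts at residue i
brute_transition_counts <- function(ens, i, classing = "reduced", lag = 1) {
  cls <- if (classing == "reduced") ss_reduced_alphabet() else ss_alphabet()
  cnt <- matrix(0L, length(cls), length(cls), dimnames = list(cls, cls))
  red <- function(x) if (classing == "reduced") reduce_ss_labels(x) else x
  for (m in ens$members) {
    nf <- nrow(m$labels)
    if (nf <= lag) next
    for (t in seq_len(nf - lag)) {
      a <- red(m$labels[t, i]); b <- red(m$labels[t + lag, i])
      cnt[a, b] <- cnt[a, b] + 1L
    }
  }
  cnt
}

# nested-loop triad classification
brute_triads <- function(ens, centers, lag = 1) {
  cls <- triad_classes()
  n_cls <- setNames(integer(length(cls)), cls)
  n_H <- n_cls; anom <- 0L
  for (m in ens$members) {
    nf <- nrow(m$labels)
    if (nf <= lag) next
    for (t in seq_len(nf - lag)) {
      for (c in centers) {
        pat <- paste(ifelse(m$labels[t, (c - 1):(c + 1)] == "H", "H", "-"),
                     collapse = "")
        if (pat == "-H-") { anom <- anom + 1L; next }
        n_cls[pat] <- n_cls[pat] + 1L
        if (m$labels[t + lag, c] == "H") n_H[pat] <- n_H[pat] + 1L
      }
    }
  }
  list(counts = n_cls, n_next_H = n_H, anomalies = anom)
}
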