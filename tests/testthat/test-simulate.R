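test_that("simulation is bit-identical under a fixed seed", {
  p <- helix_params(n_frames = 150)
  a <- simulate_ss_trajectory(p, seed = 17)
  b <- simulate_ss_trajectory(p, seed = 17)
  expect_identical(a$labels, b$labels)
  c <- simulate_ss_trajectory(p, seed = 18)
  expect_false(identical(a$labels, c$labels))
  e1 <- make_synthetic_ensemble(4, p, seed = 3)
  e2 <- make_synthetic_ensemble(4, p, seed = 3)
  expect_identical(lapply(e1$members, `[[`, "labels"),
                   lapply(e2$members, `[[`, "labels"))
})

test_that("neutral energy (sigma = 1, s = 1) gives half helix occupancy", {
  p <- helix_params(n_residues = 10, n_frames = 1e4, s = rep(1, 10),
                    sigma = 1, min_run_mode = "off")
  st <- simulate_states(p, initial = "coil", seed = 5)
  occ <- colMeans(st)
  # binomial-scale tolerance at 1e4 (correlated) frames
  expect_true(all(abs(occ - 0.5) < 0.05))
})

test_that("overwhelming propensity freezes the helix: t_u never arrives", {
  p <- helix_params(n_frames = 300, s = rep(50, 20))
  traj <- simulate_ss_trajectory(p, initial = "helix", seed = 2)
  expect_true(is.na(unfolding_time(traj)))
  expect_gt(helix_content(traj), 0.99)
})

test_that("emitted H runs respect the minimum run length, with no -H- triads", {
  p <- helix_params(n_frames = 400)
  ens <- make_synthetic_ensemble(5, p, seed = 13)
  for (m in ens$members) {
    runs <- apply(m$labels, 1L, function(row) {
      r <- rle(row == "H")
      if (any(r$values)) min(r$lengths[r$values]) else Inf
    })
    expect_true(all(runs >= 4))
  }
  expect_equal(triad_stats(ens)$anomalies, 0L)
})

test_that("reject mode forbids sub-minimum helical runs in the state chain", {
  p <- helix_params(n_residues = 12, n_frames = 300,
                    s = rep(1, 12), sigma = 0.5, min_run_mode = "reject")
  st <- simulate_states(p, initial = "coil", seed = 7)
  bad <- apply(st, 1L, function(h) {
    r <- rle(h)
    any(r$values & r$lengths < 4)
  })
  expect_false(any(bad))
})

test_that("C-destabilized defaults unfold from the C terminus more than N", {
  ens <- make_synthetic_ensemble(50, helix_params(n_frames = 1500), seed = 7)
  st <- summarize_runs(ens)$stats
  expect_equal(st$n_never, 0L)
  fc <- st$first_region_counts
  expect_gt(fc[["C"]], fc[["N"]])
})

test_that("retention probabilities recover the generator's asymmetry", {
  p <- helix_params(n_frames = 1200)
  ens <- make_synthetic_ensemble(20, p, seed = 19)
  rec <- recover_parameters(ens, p)
  r <- rec$retention
  expect_true(sum(r$n_source) > 1e4)
  expect_lt(r$p_HH[19], r$p_HH[2])   # C-terminal residue less retentive
  expect_true(all(c("P(H, HHH)", "P(H, ---)") %in% rec$triads$quantity))
})

test_that("a position-independent energy gives a flat retention profile", {
  # with sigma = 1 the run term vanishes, so every position is
  # statistically equivalent and P(H,H;i) must be flat in i
  p <- helix_params(n_frames = 1500, s = rep(0.9, 20), sigma = 1,
                    min_run_mode = "off")
  ens <- make_synthetic_ensemble(20, p, seed = 23)
  rec <- recover_parameters(ens)$retention
  pooled <- sum(rec$p_HH * rec$n_source) / sum(rec$n_source)
  expect_true(all(rec$n_source > 1e3))
  # every estimate within 3 binomial SEs of the pooled value
  expect_true(all(abs(rec$p_HH - pooled) <= 3 * rec$se + 1e-12))
})

test_that("the chain's stationary distribution is the Zimm-Bragg Boltzmann law", {
  s <- seq(0.8, 1.2, length.out = 8)
  sigma <- 0.2
  p <- helix_params(n_residues = 8, n_frames = 1e5, s = s, sigma = sigma,
                    min_run_mode = "off", sweep_moves = 8)
  st <- simulate_states(p, initial = "coil", seed = 123)
  exact <- zb_state_distribution(s, sigma)
  expect_equal(sum(exact$probability), 1)
  key <- apply(st, 1L, function(h) paste(ifelse(h, "h", "c"), collapse = ""))
  emp <- as.numeric(table(factor(key, levels = exact$state))) / nrow(st)
  tv <- 0.5 * sum(abs(emp - exact$probability))
  expect_lt(tv, 0.02)
})

test_that("boundary decoration emits G/T intermediates at helix ends", {
  p <- helix_params(n_frames = 600, p_decorate_G = 1, p_decorate_T = 0)
  traj <- simulate_ss_trajectory(p, seed = 29)
  lab <- traj$labels
  # every coil residue immediately C-terminal to an H run end must be G
  for (k in seq_len(nrow(lab))) {
    r <- rle(lab[k, ] == "H")
    ends <- cumsum(r$lengths)
    for (q in which(r$values)) {
      nxt <- ends[q] + 1L
      if (nxt <= ncol(lab)) expect_true(lab[k, nxt] %in% c("G", "H"))
    }
  }
})
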