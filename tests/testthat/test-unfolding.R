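test_that("unfolding time is the first alpha-helix-free snapshot", {
  m <- rbind(rep("H", 20), rep("H", 20), rep("T", 20))
  traj <- ss_trajectory(m, frame_interval = 20, time_offset = 20)
  expect_equal(unfolding_time(traj, "ps"), 60)
  expect_equal(unfolding_time(traj, "ns"), 0.06)
  # G does not count as alpha-helix
  mg <- rbind(rep("H", 20), rep("G", 20))
  expect_equal(unfolding_time(ss_trajectory(mg), "ps"), 40)
  # all frames keep at least one H -> never
  mh <- rbind(rep("T", 20), c("H", rep("T", 19)))
  mh <- mh[c(2, 2), ]
  expect_true(is.na(unfolding_time(ss_trajectory(mh))))
})

test_that("unfolding time respects a configurable time offset", {
  m <- rbind(rep("H", 5), rep("O", 5))
  expect_equal(unfolding_time(ss_trajectory(m, time_offset = 0), "ps"), 20)
  expect_equal(unfolding_time(ss_trajectory(m, time_offset = 20), "ps"), 40)
})

test_that("unfolding time is monotone under truncation", {
  set.seed(31)
  p <- helix_params(n_frames = 400)
  traj <- simulate_ss_trajectory(p, seed = 8)
  tu <- unfolding_time(traj, "ns")
  expect_false(is.na(tu))
  after <- truncate_trajectory(traj, tu + 0.1, "ns")
  expect_equal(unfolding_time(after, "ns"), tu)
  before <- truncate_trajectory(traj, tu - 0.021, "ns")
  expect_true(is.na(unfolding_time(before, "ns")))
})

test_that("residue and helix content match brute-force pooling", {
  one <- ss_trajectory(matrix("H", 1, 20))
  expect_equal(unname(residue_content(one, "H")), rep(1, 20))
  two <- ss_trajectory(rbind(rep("H", 20), rep("T", 20)))
  expect_equal(unname(residue_content(two, "H")), rep(0.5, 20))
  expect_equal(helix_content(ss_trajectory(matrix("H", 3, 20))), 1.0)

  set.seed(7)
  ens <- random_ensemble(3, 40, 12)
  for (labs in list("H", c("H", "G"), c("E", "B"))) {
    expect_equal(unname(residue_content(ens, labs)),
                 brute_residue_content(ens, labs))
  }
  # helix_content equals the residue-wise H+G profile averaged over i
  expect_equal(helix_content(ens),
               mean(residue_content(ens, c("H", "G"))))
})

test_that("content profile columns sum to one over the eight classes", {
  set.seed(12)
  ens <- random_ensemble(2, 30, 10)
  prof <- content_profile(ens)
  expect_equal(unname(colSums(prof)), rep(1, 10), tolerance = 1e-9)
})

test_that("running helix content accumulates and ends at the pooled value", {
  traj <- ss_trajectory(rbind(rep("H", 20), rep("T", 20)))
  rc <- running_helix_content(traj)
  expect_equal(rc$time_ps, c(20, 40))
  expect_equal(rc$helix_content, c(1, 0.5))
  const <- ss_trajectory(matrix("G", 5, 10))
  expect_equal(running_helix_content(const)$helix_content, rep(1, 5))
  set.seed(3)
  rnd <- ss_trajectory(random_label_matrix(50, 20))
  expect_equal(tail(running_helix_content(rnd)$helix_content, 1),
               helix_content(rnd))
})

test_that("region unfolding order ranks regions by pre-t_u helix content", {
  # C loses helix at frame 2, N at frame 3, M at frame 4 (= t_u)
  m <- matrix("H", 4, 20)
  m[2:4, 14:20] <- "T"
  m[3:4, 1:7] <- "T"
  m[4, ] <- "T"
  traj <- ss_trajectory(m)
  expect_equal(unfolding_order(traj), c("C", "N", "M"))
  # never-unfolded runs are an error
  expect_error(unfolding_order(ss_trajectory(matrix("H", 3, 20))),
               "did not unfold")
  # relabeling regions permutes the output identically
  part2 <- region_partition(regions = list(early = 14:19, late = 2:7,
                                           mid = 8:13))
  expect_equal(unfolding_order(traj, part2), c("early", "late", "mid"))
})

test_that("order ties break by earlier helix-free time, then region order", {
  # N and C tie on mean helix content, but C is helix-free sooner
  m <- matrix("T", 4, 20)
  m[1:3, 8:13] <- "H"        # M: content 3/4
  m[1:2, 2:7] <- "H"         # N: content 2/4, first free at frame 3
  m[c(1, 3), 14:19] <- "H"   # C: content 2/4, first free at frame 2
  traj <- ss_trajectory(m)
  expect_equal(mean(m[, 2:7] == "H"), mean(m[, 14:19] == "H"))
  expect_equal(unfolding_order(traj), c("C", "N", "M"))

  m2 <- matrix("T", 2, 20)
  m2[1, ] <- "H"
  # perfect three-way tie -> partition's region order
  expect_equal(unfolding_order(ss_trajectory(m2)), c("N", "M", "C"))
})

test_that("summarize_runs aggregates per-run results and never-unfolded runs", {
  m_unfold <- rbind(rep("H", 20), rep("T", 20))
  m_never <- matrix("H", 2, 20)
  ens <- run_ensemble(list(ss_trajectory(m_unfold, run_id = "a"),
                           ss_trajectory(m_never, run_id = "b")))
  s <- summarize_runs(ens)
  expect_equal(s$runs$t_u_ns, c(0.04, NA))
  expect_equal(s$stats$n_never, 1L)
  expect_equal(s$stats$t_u_mean_ns, 0.04)
  expect_equal(s$stats$t_u_median_ns, 0.04)
  expect_true(is.na(s$stats$t_u_sd_ns))  # single defined t_u: SD undefined
  # counts over order patterns sum to the number of unfolded runs
  expect_equal(sum(s$stats$order_counts), s$stats$n_runs - s$stats$n_never)
})

test_that("ensemble_stats reproduces hand-computed aggregates", {
  runs <- data.frame(run_id = c("a", "b", "c", "d"),
                     t_u_ns = c(10, 30, 20, NA),
                     order = c("C,N,M", "C,M,N", "N,M,C", NA))
  st <- ensemble_stats(runs)
  expect_equal(st$t_u_mean_ns, 20)
  expect_equal(st$t_u_median_ns, 20)
  expect_equal(st$t_u_sd_ns, sd(c(10, 30, 20)))
  expect_equal(unname(st$first_region_counts[c("C", "N")]),
               c(2L, 1L), ignore_attr = TRUE)
  expect_equal(st$n_terminus_to_terminus, 2L)  # C,M,N and N,M,C
})
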