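make_ct <- function(xyz, resno = seq_len(dim(xyz)[2]),
                    name = rep("CA", dim(xyz)[2]),
                    element = rep("C", dim(xyz)[2])) {
  coord_trajectory(xyz, data.frame(name = name, resno = resno,
                                   element = element,
                                   stringsAsFactors = FALSE))
}

test_that("end-to-end distance is the Euclidean atom-atom norm", {
  xyz <- array(0, dim = c(1, 2, 3))
  xyz[1, 2, ] <- c(3, 4, 0)
  ct <- make_ct(xyz, resno = c(1, 2))
  expect_equal(end_to_end_distance(ct), 5)
  xyz2 <- array(1, dim = c(1, 2, 3))
  expect_equal(end_to_end_distance(make_ct(xyz2, resno = c(1, 2))), 0)
  # random coordinates against a hand-computed norm
  set.seed(51)
  xyz3 <- array(rnorm(5 * 4 * 3), dim = c(5, 4, 3))
  ct3 <- make_ct(xyz3, resno = 1:4)
  manual <- sapply(1:5, function(k) sqrt(sum((xyz3[k, 1, ] - xyz3[k, 4, ])^2)))
  expect_equal(end_to_end_distance(ct3), manual)
})

test_that("selectors must resolve to exactly one atom", {
  xyz <- array(0, dim = c(1, 3, 3))
  ct <- make_ct(xyz, resno = c(1, 1, 2))
  expect_error(end_to_end_distance(ct, start_sel = list(name = "CA",
                                                        resno = 1)),
               "exactly one atom")
  expect_error(end_to_end_distance(ct, start_sel = list(name = "CB")),
               "exactly one atom")
})

test_that("radius of gyration matches the closed form and brute force", {
  one <- make_ct(array(c(1, 2, 3), dim = c(1, 1, 3)))
  expect_equal(radius_of_gyration(one), 0)
  # two unit-mass atoms 2 A apart: each 1 A from the centroid
  two <- array(0, dim = c(1, 2, 3)); two[1, 2, 1] <- 2
  expect_equal(radius_of_gyration(make_ct(two)), 1)
  set.seed(52)
  xyz <- array(rnorm(3 * 10 * 3), dim = c(3, 10, 3))
  ct <- make_ct(xyz)
  brute <- sapply(1:3, function(k) {
    r <- xyz[k, , ]
    ctr <- colMeans(r)
    sqrt(mean(rowSums(sweep(r, 2, ctr)^2)))
  })
  expect_equal(radius_of_gyration(ct), brute)
  # Rg never exceeds the farthest atom-centroid distance
  maxdist <- sapply(1:3, function(k) {
    r <- xyz[k, , ]
    max(sqrt(rowSums(sweep(r, 2, colMeans(r))^2)))
  })
  expect_true(all(radius_of_gyration(ct) <= maxdist))
})

test_that("hydrogens are excluded by default and masses weight correctly", {
  xyz <- array(0, dim = c(1, 3, 3))
  xyz[1, 2, 1] <- 2; xyz[1, 3, 1] <- 10
  ct <- make_ct(xyz, name = c("C1", "C2", "H1"),
                element = c("C", "C", "H"))
  expect_equal(radius_of_gyration(ct), 1)  # H atom at x=10 ignored
  ctm <- make_ct(xyz[, 1:2, , drop = FALSE], name = c("C", "O"),
                 element = c("C", "O"))
  m <- c(12.011, 15.999)
  ctr <- sum(m * c(0, 2)) / sum(m)
  expect_equal(radius_of_gyration(ctm, mass_weighted = TRUE),
               sqrt(sum(m * (c(0, 2) - ctr)^2) / sum(m)))
})

test_that("both metrics are invariant under rigid rotation and translation", {
  set.seed(53)
  xyz <- array(rnorm(4 * 8 * 3, sd = 5), dim = c(4, 8, 3))
  ct <- make_ct(xyz, resno = 1:8)
  for (rep in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    shift <- rnorm(3, sd = 50)
    xyz2 <- xyz
    for (k in 1:4) xyz2[k, , ] <- sweep(xyz[k, , ] %*% q, 2, -shift)
    ct2 <- make_ct(xyz2, resno = 1:8)
    expect_equal(end_to_end_distance(ct2), end_to_end_distance(ct),
                 tolerance = 1e-8)
    expect_equal(radius_of_gyration(ct2), radius_of_gyration(ct),
                 tolerance = 1e-8)
  }
})

test_that("multi-model PDB files read as frames with the atom roster", {
  f <- withr::local_tempfile(fileext = ".pdb")
  mdl <- function(k, shift) c(
    sprintf("MODEL     %4d", k),
    sprintf("ATOM      1  N   GLU A   1    %8.3f%8.3f%8.3f  1.00  0.00           N",
            0 + shift, 0, 0),
    sprintf("ATOM      2  CA  GLU A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1.5 + shift, 0, 0),
    sprintf("ATOM      3  CA  GLU A   2    %8.3f%8.3f%8.3f  1.00  0.00           C",
            5.5 + shift, 0, 0),
    "ENDMDL")
  writeLines(c(mdl(1, 0), mdl(2, 3), "END"), f)
  ct <- read_coord_trajectory(f)
  expect_equal(dim(ct$xyz), c(2, 3, 3))
  expect_equal(ct$atoms$name, c("N", "CA", "CA"))
  # Calpha(res 1) to Calpha(res 2): 4 A in both models
  expect_equal(end_to_end_distance(ct), c(4, 4))
})

test_that("metric time courses pool ensemble mean and SD over frames", {
  const <- array(0, dim = c(3, 2, 3)); const[, 2, 1] <- 2
  ct <- make_ct(const)
  tc <- metric_timecourse(ct, "rg")
  expect_equal(tc$series$value, rep(1, 3))
  expect_equal(tc$sd, 0)
  expect_equal(nrow(tc$series), 3)
  set.seed(54)
  cts <- lapply(1:3, function(k) {
    xyz <- array(rnorm(4 * 5 * 3), dim = c(4, 5, 3))
    coord_trajectory(xyz, data.frame(name = rep("CA", 5), resno = 1:5,
                                     element = rep("C", 5)),
                     run_id = paste0("r", k))
  })
  tc2 <- metric_timecourse(cts, "rg")
  pooled <- unlist(lapply(cts, radius_of_gyration))
  expect_equal(tc2$mean, mean(pooled))
  expect_equal(tc2$sd, sqrt(mean((pooled - mean(pooled))^2)))
})
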