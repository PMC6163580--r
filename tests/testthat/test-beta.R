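test_that("dihedral reproduces planar and perpendicular references", {
  expect_equal(dihedral(c(0,0,0), c(1,0,0), c(1,1,0), c(2,1,0)), 180)
  expect_equal(dihedral(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)), 0)
  expect_equal(dihedral(c(0,0,0), c(1,0,0), c(1,1,0), c(1,1,1)), 90)
  expect_error(dihedral(c(0,0,0), c(1,0,0), c(2,0,0), c(3,1,0)),
               "undefined dihedral")
})

test_that("dihedral is invariant under rigid motion and matches the oracle", {
  set.seed(3)
  for (k in 1:30) {
    p <- matrix(rnorm(12), 4, 3)
    ang <- tryCatch(dihedral(p[1,], p[2,], p[3,], p[4,]),
                    error = function(e) NA)
    if (is.na(ang)) next
    expect_equal(ang, oracle_dihedral(p[1,], p[2,], p[3,], p[4,]),
                 tolerance = 1e-9)
    rot <- random_rotation(); tr <- rnorm(3)
    q <- sweep(p %*% t(rot), 2, tr, `+`)
    expect_equal(dihedral(q[1,], q[2,], q[3,], q[4,]), ang,
                 tolerance = 1e-6)
  }
})

test_that("ideal sheets are fully beta at interior beads, lone strands and separated coils are not", {
  sheet <- make_sheet(2, 8, orientation = "antiparallel")
  a <- assign_beta(sheet$frame, sheet$system)
  expect_true(all(a$beta[a$evaluable]))
  expect_equal(beta_fraction(a), 100)
  # matches the naive oracle bead-for-bead
  expect_equal(a$beta, oracle_assign_beta(sheet$frame, sheet$system)$beta)

  strand <- make_strand(10)
  expect_equal(sum(assign_beta(strand$frame, strand$system)$beta), 0)

  # exclusion above contact_dist: no bead pair can satisfy the
  # contact criterion, so zero beta is guaranteed by construction
  c1 <- make_coil(12, seed = 5, exclusion = 0.65, chain_id = "C1")
  c2 <- make_coil(12, seed = 6, exclusion = 0.65, chain_id = "C2")
  b2 <- c2$system$beads; b2$index <- b2$index + 12
  beads <- rbind(c1$system$beads, b2); beads$index <- seq_len(24)
  sys <- bead_system(beads)
  fr <- cg_frame(rbind(c1$frame$xyz,
                       sweep(c2$frame$xyz, 2, c(10, 0, 0), `+`)))
  a2 <- assign_beta(fr, sys)
  expect_equal(sum(a2$beta), 0)
  expect_equal(a2$beta, oracle_assign_beta(fr, sys)$beta)
})

test_that("assignment matches the brute-force oracle on randomized fixtures", {
  for (seed in 1:25) {
    fx <- random_beta_fixture(seed)
    a <- assign_beta(fx$frame, fx$system)
    o <- oracle_assign_beta(fx$frame, fx$system)
    expect_identical(a$beta, o$beta,
                     label = paste("fixture seed", seed))
  }
})

test_that("assignment and angles are invariant under rigid motion", {
  fx <- make_sheet(3, 8)
  a0 <- assign_beta(fx$frame, fx$system)
  set.seed(9)
  for (k in 1:5) {
    rot <- random_rotation()
    fr <- cg_frame(sweep(fx$frame$xyz %*% t(rot), 2, rnorm(3, 0, 5), `+`))
    a1 <- assign_beta(fr, fx$system)
    expect_identical(a1$beta, a0$beta)
    expect_equal(a1$dihedral_deg, a0$dihedral_deg, tolerance = 1e-6)
  }
})

test_that("thresholds act monotonically on the beta count", {
  for (seed in c(101, 102, 103)) {
    fx <- random_beta_fixture(seed)
    counts_d <- vapply(c(0.45, 0.55, 0.65, 0.8), function(x) {
      sum(assign_beta(fx$frame, fx$system,
                      beta_params(contact_dist = x))$beta)
    }, numeric(1))
    expect_true(all(diff(counts_d) >= 0))
    counts_a <- vapply(c(60, 100, 140, 175), function(x) {
      sum(assign_beta(fx$frame, fx$system, beta_params(angle_min = x))$beta)
    }, numeric(1))
    expect_true(all(diff(counts_a) <= 0))
  }
})

test_that("short chains are tolerated and empty fractions error", {
  xyz <- matrix(c(0,0,0, 0.35,0,0, 0.5,0.3,0), 3, 3, byrow = TRUE)
  sys <- toy_system(xyz)
  a <- assign_beta(cg_frame(xyz), sys)
  expect_true(all(!a$beta))
  expect_error(beta_fraction(a), "no evaluable")
})

test_that("beta fraction arithmetic", {
  fx <- make_sheet(2, 8)
  a <- assign_beta(fx$frame, fx$system)
  a$beta[] <- FALSE
  expect_equal(beta_fraction(a), 0)
  a$beta <- a$evaluable
  expect_equal(beta_fraction(a), 100)
  a$beta[] <- FALSE
  a$beta[which(a$evaluable)[1:5]] <- TRUE
  expect_equal(beta_fraction(a), 100 * 5 / sum(a$evaluable))
})

test_that("beta time series rises monotonically as strands condense onto a sheet", {
  sheet <- make_sheet(2, 8)
  # start from the sheet uniformly expanded about its centroid: every
  # inter-bead distance shrinks linearly along the interpolation, so each
  # bead's contact criterion switches on once and stays on
  ctr <- colMeans(sheet$frame$xyz)
  start <- cg_frame(sweep(sweep(sheet$frame$xyz, 2, ctr, `-`) * 4, 2, ctr,
                          `+`))
  tr <- make_interpolated_trajectory(start, sheet$frame, sheet$system, 6)
  ts <- beta_timeseries(tr)
  expect_equal(nrow(ts), 6)
  expect_equal(ts$beta_percent[1], 0)
  expect_equal(ts$beta_percent[6], 100)
  expect_true(all(diff(ts$beta_percent) >= 0))
  # stride and determinism
  expect_equal(nrow(beta_timeseries(tr, stride = 2)), 3)
  const <- make_interpolated_trajectory(sheet$frame, sheet$frame,
                                        sheet$system, 4)
  # identical endpoints give a constant series
  expect_equal(unique(beta_timeseries(const)$beta_percent), 100)
})

test_that("strand segments are maximal runs above the length threshold", {
  fx <- make_sheet(2, 10)
  a <- assign_beta(fx$frame, fx$system)
  segs <- find_strands(a, fx$frame, fx$system)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$start_res, c(2, 2))
  expect_equal(segs$end_res, c(8, 8))
  # drop a bead in the middle of chain P1: the run splits
  a2 <- a
  mid <- which(a2$chain_id == "P1" & a2$residue_index == 5)
  a2$beta[mid] <- FALSE
  segs2 <- find_strands(a2, fx$frame, fx$system)
  expect_equal(sum(segs2$chain_id == "P1"), 2)
  # runs shorter than min_strand_len are dropped: both 3-residue halves go
  segs3 <- find_strands(a2, fx$frame, fx$system,
                        beta_params(min_strand_len = 4))
  expect_equal(sum(segs3$chain_id == "P1"), 0)
  expect_equal(segs3$n_res[segs3$chain_id == "P2"], 7)
})

test_that("strand pairing recovers construction orientation and registry", {
  cases <- expand.grid(orient = c("antiparallel", "parallel"),
                       shift = -2:2, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cases))) {
    fx <- make_sheet(2, 9, orientation = cases$orient[k],
                     registry_shift = cases$shift[k])
    a <- assign_beta(fx$frame, fx$system)
    segs <- find_strands(a, fx$frame, fx$system)
    pr <- pair_strands(segs, fx$frame, fx$system)
    expect_equal(nrow(pr), 1)
    expect_equal(pr$orientation, cases$orient[k])
    expect_equal(pr$registry_shift, cases$shift[k],
                 label = paste(cases$orient[k], "shift", cases$shift[k]))
  }
})

test_that("distant strands do not pair", {
  fx <- make_sheet(2, 8)
  fr <- fx$frame
  rows <- fx$system$beads$chain_id == "P2"
  fr$xyz[rows, ] <- fr$xyz[rows, ] + 5
  a <- assign_beta(fx$frame, fx$system)  # pairing geometry from moved frame
  segs <- find_strands(a, fr, fx$system)
  expect_equal(nrow(pair_strands(segs, fr, fx$system)), 0)
})

test_that("strand tilt uses the acute-angle convention", {
  seg <- data.frame(dir_x = 0, dir_y = 0, dir_z = 1)
  expect_equal(strand_tilt(seg, c(0, 0, 1)), 0)
  expect_equal(strand_tilt(seg, c(1, 0, 0)), 90)
  expect_equal(strand_tilt(seg, c(0, 0, -1)), 0)
  expect_equal(strand_tilt(seg, c(1, 0, 1)), 45, tolerance = 1e-9)
  expect_error(strand_tilt(seg, c(0, 0, 0)), "non-zero")
})

test_that("assignments export to TSV with the documented columns", {
  fx <- make_sheet(2, 6)
  a <- assign_beta(fx$frame, fx$system)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_beta_tsv(a, f)
  got <- read.table(f, header = TRUE, sep = "\t")
  expect_named(got, c("chain", "residue_index", "beta_state",
                      "dihedral_deg", "n_contacts"))
  expect_equal(nrow(got), nrow(a))
  expect_equal(got$beta_state, as.integer(a$beta))
})
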