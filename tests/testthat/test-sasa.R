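single_bead_fixture <- function(radius = 0.26) {
  xyz <- matrix(0, 1, 3)
  list(system = toy_system(xyz, radius = radius), frame = cg_frame(xyz))
}

two_bead_fixture <- function(d, radius = 0.26) {
  xyz <- rbind(c(0, 0, 0), c(d, 0, 0))
  list(system = toy_system(xyz, radius = radius), frame = cg_frame(xyz))
}

test_that("single-bead SASA matches the closed form within quadrature error", {
  fx <- single_bead_fixture()
  p <- sasa_params()
  s <- sasa(fx$frame, fx$system, 1, p)
  closed <- 4 * pi * (0.26 + p$probe_radius)^2
  expect_lt(abs(s$total - closed) / closed, 0.01)
  expect_equal(s$total, sum(s$per_bead$area_nm2))
})

test_that("distant beads are additive; overlapping beads match the two-sphere analytic area", {
  p <- sasa_params()
  single <- 4 * pi * (0.26 + p$probe_radius)^2
  far <- two_bead_fixture(10)
  expect_lt(abs(sasa(far$frame, far$system, 1:2, p)$total - 2 * single) /
              (2 * single), 0.01)
  near <- two_bead_fixture(0.5)
  analytic <- oracle_two_sphere_area(0.516, 0.516, 0.5)
  got <- sasa(near$frame, near$system, 1:2, p)$total
  expect_lt(abs(got - analytic) / analytic, 0.01)
  # asymmetric radii through the class-table radius column
  sys <- near$system
  sys$beads$radius[2] <- 0.35
  analytic2 <- oracle_two_sphere_area(0.516, 0.35 + p$probe_radius, 0.5)
  got2 <- sasa(near$frame, sys, 1:2, p)$total
  expect_lt(abs(got2 - analytic2) / analytic2, 0.01)
})

test_that("quadrature converges with point count and is resolution-stable", {
  near <- two_bead_fixture(0.5)
  analytic <- oracle_two_sphere_area(0.516, 0.516, 0.5)
  errs <- vapply(c(96, 320, 960), function(n) {
    abs(sasa(near$frame, near$system, 1:2,
             sasa_params(n_sphere_points = n))$total - analytic) / analytic
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  a960 <- sasa(near$frame, near$system, 1:2,
               sasa_params(n_sphere_points = 960))$total
  a1920 <- sasa(near$frame, near$system, 1:2,
                sasa_params(n_sphere_points = 1920))$total
  expect_lt(abs(a1920 - a960) / a960, 0.005)
})

test_that("SASA context is selection-only", {
  # a bead pressed against another is unoccluded if the other is outside
  # the selection
  near <- two_bead_fixture(0.5)
  p <- sasa_params()
  s1 <- sasa(near$frame, near$system, 1, p)
  expect_lt(abs(s1$total - 4 * pi * 0.516^2) / s1$total, 0.01)
})

test_that("interface area is symmetric, non-negative, zero at distance and bounded", {
  p <- sasa_params()
  fixtures <- list(
    make_sheet(2, 8),
    make_barrel(6, 6),
    make_detergent_shell(make_cylinder_protein(5, 12, bundle_radius = 0.8),
                         12, 1.8, seed = 3)
  )
  # give the peptide fixtures two groups by chain
  for (fx in fixtures) {
    grp <- names(fx$system$groups)
    if (length(grp) == 1) {
      ch <- names(fx$system$chains)
      selA <- ch[1]; selB <- ch[-1]
    } else {
      selA <- grp[1]; selB <- grp[2]
    }
    ra <- interface_area(fx$frame, fx$system, selA, selB, p)
    rb <- interface_area(fx$frame, fx$system, selB, selA, p)
    expect_equal(ra$area, rb$area, tolerance = 1e-9)
    expect_gte(ra$area, 0)
    expect_lte(ra$area, min(ra$sasa_a, ra$sasa_b) + 1e-9)
  }
  # far-apart groups: exactly zero
  fx <- make_sheet(2, 8)
  fr <- fx$frame
  rows <- fx$system$beads$chain_id == "P2"
  fr$xyz[rows, ] <- fr$xyz[rows, ] + 10
  expect_equal(interface_area(fr, fx$system, "P1", "P2", p)$area, 0)
})

test_that("interface area matches an independent SASA recomputation on a contact fixture", {
  p <- sasa_params(n_sphere_points = 320)
  prot <- make_cylinder_protein(5, 10, bundle_radius = 0.8)
  pep <- make_strand(8)
  bp <- pep$system$beads
  bp$index <- bp$index + nrow(prot$system$beads)
  bp$chain_id <- "Z"
  beads <- rbind(prot$system$beads, bp)
  sys <- bead_system(beads, groups = list(
    protein = prot$system$beads$index, peptide = bp$index))
  # lay the strand against the bundle surface
  shift <- c(0.8 + 0.25 + 0.45, 0, 0.5)
  xyz <- rbind(prot$frame$xyz,
               sweep(pep$frame$xyz %*% diag(3), 2, shift, `+`))
  fr <- cg_frame(xyz)
  r <- interface_area(fr, sys, "protein", "peptide", p)
  expect_gt(r$area, 0)
  expect_equal(r$area, (r$sasa_a + r$sasa_b - r$sasa_ab) / 2,
               tolerance = 1e-12)
  # oracle: recompute each term with an independently-parameterised call
  oa <- sasa(fr, sys, "protein", p)$total
  ob <- sasa(fr, sys, "peptide", p)$total
  oab <- sasa(fr, sys, c(resolve_selection(sys, "protein"),
                         resolve_selection(sys, "peptide")), p)$total
  expect_equal(r$area, (oa + ob - oab) / 2, tolerance = 1e-9)
})

test_that("interface series decreases as a detergent shell is displaced outward", {
  prot <- make_cylinder_protein(5, 12, bundle_radius = 0.8)
  near <- make_detergent_shell(prot, 24, 1.8, seed = 7)
  far <- make_detergent_shell(prot, 24, 2.05, seed = 7)
  tr <- make_interpolated_trajectory(near$frame, far$frame, near$system, 5)
  ts <- interface_timeseries(tr, "protein", "detergent",
                             sasa_params(n_sphere_points = 320))
  expect_equal(nrow(ts), 5)
  expect_true(all(diff(ts$area_nm2) < 0))
  # static trajectory is constant
  st <- make_interpolated_trajectory(near$frame, near$frame, near$system, 3)
  expect_equal(length(unique(
    interface_timeseries(st, "protein", "detergent",
                         sasa_params(n_sphere_points = 96))$area_nm2)), 1)
})

test_that("overlapping or empty selections are rejected", {
  fx <- make_sheet(2, 6)
  expect_error(interface_area(fx$frame, fx$system, 1:4, 4:8), "overlap")
  expect_error(sasa(fx$frame, fx$system, integer(0)), "empty")
})
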