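test_that("concentration/areal-loading conversions reproduce the worked examples", {
  # 200 mg/kg over the top 1 cm at 2,000 kg/m^3 is 4,000,000 ug/m^2
  expect_equal(concentration_to_areal(200, 0.01, 2000), 4e6)
  # 1,000,000 ug/m^2 diluted over 5 cm is 10 mg/kg
  expect_equal(areal_to_concentration(1e6, 0.05, 2000), 10)
  x <- c(13.7, 452, 9000)
  expect_equal(areal_to_concentration(concentration_to_areal(x, 0.01, 2000),
                                      0.01, 2000), x, tolerance = 1e-12)
  expect_error(concentration_to_areal(-1, 0.01, 2000))
  expect_error(areal_to_concentration(1e6, 0, 2000))
})

test_that("a constant field has equal sector means and zero excess", {
  fld <- field_grid(make_grid(), matrix(2, 20, 900))
  rsm <- ring_sector_means(fld, r = 0.4)
  expect_equal(rsm$inside, rep(16, 20))
  expect_equal(rsm$outside, rep(16, 20))
  expect_equal(rsm$excess, rep(0, 20))

  for (R in c(0.5, 1, 1.5)) {
    avg <- average_excess_within(fld, R = R)
    expect_equal(unname(avg$avg_inside), rep(16, 3))
    expect_equal(unname(avg$avg_outside), rep(16, 3))
  }

  prof <- excess_profile(fld)
  expect_equal(prof$excess_mean, rep(0, 30))
  expect_equal(nrow(prof), 30)
  expect_true(all(diff(prof$r_km) > 0) && all(prof$r_km >= 0.1))

  expect_equal(integrated_excess_mass(fld, R = 1)$mass_kg[["mean"]], 0)
  expect_error(ring_sector_means(fld, r = 2), "radial range")
  expect_error(average_excess_within(fld, R = 0.05), "0.1 km")
  expect_error(integrated_excess_mass(fld, R = 1, depth = -1), "positive")
})

test_that("constant excess integrates to the closed-form mass", {
  # f^4 = b + c strictly inside the 50-degree sector, b outside
  grid <- make_grid()
  b <- 100; cc <- 250
  conc <- ifelse(in_sector(grid$bearing_deg), b + cc, b)
  fld <- field_grid(grid, matrix(conc^0.25, 3, 900, byrow = TRUE))
  got <- integrated_excess_mass(fld, R = 1, depth = 0.01,
                                bulk_density = 2000)$mass_kg[["mean"]]
  closed <- cc * 1e-6 * 20 * (50 / 360) * pi * 1000^2
  expect_equal(got, closed, tolerance = 1e-10)
  # and comfortably within the quadrature budget at this resolution
  expect_lt(abs(got - closed) / closed, 0.005)

  # inventory quantities scale linearly in depth and bulk density
  m2 <- integrated_excess_mass(fld, R = 1, depth = 0.02,
                               bulk_density = 2000)$mass_kg[["mean"]]
  m3 <- integrated_excess_mass(fld, R = 1, depth = 0.01,
                               bulk_density = 3000)$mass_kg[["mean"]]
  expect_equal(m2, 2 * got, tolerance = 1e-12)
  expect_equal(m3, 1.5 * got, tolerance = 1e-12)
})

test_that("area weighting matches the analytic annulus integral", {
  # a field whose concentration equals r: the area-weighted mean over the
  # annulus 0.1 < r < 1 km is  int r * 2 pi r dr / int 2 pi r dr
  grid <- make_grid()
  fld <- field_grid(grid, matrix(grid$r_km^0.25, 2, 900, byrow = TRUE))
  avg <- average_excess_within(fld, R = 1)
  analytic <- ((1 - 0.1^3) / 3) / ((1 - 0.1^2) / 2)
  expect_equal(unname(avg$avg_inside[["mean"]]), analytic, tolerance = 0.005)
  expect_equal(unname(avg$avg_outside[["mean"]]), analytic, tolerance = 0.005)
})

test_that("excess computations are deterministic and ring-consistent", {
  set.seed(17)
  grid <- make_grid()
  fld <- field_grid(grid, matrix(abs(rnorm(5 * 900, 3, 0.5)), 5, 900))
  p1 <- excess_profile(fld)
  p2 <- excess_profile(fld)
  expect_identical(p1, p2)

  # the area-weighted radial aggregate of per-ring excess equals the
  # difference of the within-radius averages
  R <- 1.2
  geo <- plumefall:::field_geometry(fld, plume_sector())
  wr <- plumefall:::radial_cell_weights(geo$rings, 0.1, R)
  keep <- wr > 0
  ex_r <- sapply(which(keep), function(k) {
    mean(ring_sector_means(fld, r = geo$rings[k])$excess)
  })
  agg <- sum(wr[keep] * ex_r) / sum(wr[keep])
  avg <- average_excess_within(fld, R = R)
  expect_equal(agg, unname(avg$excess[["mean"]]), tolerance = 1e-10)
})

test_that("a sector-supported bump is recovered by angular quadrature", {
  # bump in concentration units, supported strictly inside the sector
  bump_conc <- function(th) {
    ifelse(in_sector(th, plume_sector()),
           400 * exp(-(th - 285)^2 / (2 * 15^2)), 0)
  }
  grid <- make_grid(0.1, 1.5, 120)  # fine angular resolution: 3-degree cells
  conc <- 50 + bump_conc(grid$bearing_deg)
  fld <- field_grid(grid, matrix(conc^0.25, 2, nrow(grid), byrow = TRUE))
  rsm <- ring_sector_means(fld, r = 0.5)
  oracle <- integrate(function(t) 400 * exp(-(t - 285)^2 / (2 * 15^2)),
                      260, 310)$value / 50
  expect_equal(rsm$excess[1], oracle, tolerance = 0.02)

  # a bump decaying in r gives a decreasing excess profile
  conc_r <- 50 + outer(exp(-grid$r_km), rep(1, 1))[, 1] *
    bump_conc(grid$bearing_deg)
  fld_r <- field_grid(grid, matrix(conc_r^0.25, 1, nrow(grid), byrow = TRUE))
  prof <- excess_profile(fld_r)
  expect_true(all(diff(prof$excess_mean) < 0))
})

test_that("observation-level summaries require y draws", {
  fld <- field_grid(make_grid(0.2, 1, 8), matrix(2, 10, 64))
  expect_error(average_excess_within(fld, R = 0.9, level = "y"), "y_draws")
  fld$y_draws <- fld$f_draws
  avg <- average_excess_within(fld, R = 0.9, level = "y")
  expect_equal(unname(avg$avg_inside[["mean"]]), 16)
})
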