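test_that("an isolated sphere has the exact inflated-sphere area", {
  st <- rbind(c(0, 0, 0))
  res <- sasa_shrake_rupley(st, radii = 1.6, probe = 1.4, n_points = 960)
  expect_equal(res$total, 4 * pi * 3.0^2, tolerance = 1e-12)
})

test_that("well-separated beads have additive areas", {
  st <- rbind(c(0, 0, 0), c(50, 0, 0))
  res <- sasa_shrake_rupley(st, radii = c(1.6, 2.1), probe = 1.4)
  expect_equal(res$total, 4 * pi * (3.0^2 + 3.5^2), tolerance = 1e-12)
  expect_equal(res$per_bead, c(4 * pi * 9, 4 * pi * 12.25),
               tolerance = 1e-12)
})

test_that("overlapping spheres match the analytic spherical-cap area", {
  for (d in c(2.0, 3.5, 5.0)) {
    st <- rbind(c(0, 0, 0), c(d, 0, 0))
    got <- sasa_shrake_rupley(st, radii = c(1.7, 1.7), probe = 1.4,
                              n_points = 960)$total
    want <- oracle_two_sphere_area(1.7, 1.7, d, 1.4)
    expect_equal(got, want, tolerance = 0.01)
  }
  # unequal radii
  st <- rbind(c(0, 0, 0), c(3.1, 0, 0))
  got <- sasa_shrake_rupley(st, radii = c(1.5, 2.2), probe = 1.4,
                            n_points = 960)$total
  expect_equal(got, oracle_two_sphere_area(1.5, 2.2, 3.1, 1.4),
               tolerance = 0.01)
})

test_that("SASA converges under quadrature refinement", {
  st <- make_random_state(4, 5, box = 25, seed = 21)
  a <- sasa_shrake_rupley(st, probe = 1.4, n_points = 960)$total
  b <- sasa_shrake_rupley(st, probe = 1.4, n_points = 1920)$total
  expect_lt(abs(a - b) / b, 0.005)
})

test_that("bringing molecules together does not increase SASA", {
  spec <- to_molecule_spec(peptide_entry("T", "KLWHHRKAVVAL"))
  st <- pack_system(spec, 2, 200, seed = 8)
  i2 <- st$beads$molecule_id == 2
  # translate molecule 2 toward molecule 1 in steps
  com1 <- colMeans(st$coords[!i2, ])
  com2 <- colMeans(st$coords[i2, ])
  prev <- Inf
  for (lambda in c(0, 0.4, 0.7, 0.85, 0.95)) {
    stx <- st
    stx$coords[i2, ] <- sweep(st$coords[i2, , drop = FALSE], 2,
                              lambda * (com2 - com1))
    s <- sasa_shrake_rupley(stx)$total
    expect_lte(s, prev + 1)  # 1 A^2 quadrature-noise allowance
    prev <- s
  }
})

test_that("radius of gyration reproduces closed-form cases", {
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)),
                                  masses = c(1, 1)), 1.0)
  expect_equal(radius_of_gyration(rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)),
                                  masses = c(1, 2, 3)), 0)
  sq <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))
  expect_equal(radius_of_gyration(sq, masses = rep(1, 4)), sqrt(2))
  # mass weighting: heavy bead pulls the COM
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(3, 0, 0)),
                                  masses = c(2, 1)), sqrt((2 * 1^2 + 2^2) / 3))
})

test_that("vacuum energy covers only inter-molecular pairs", {
  ff <- force_field_params()
  same <- two_bead_state(4, same_molecule = TRUE)
  expect_equal(vacuum_energy(same, ff), list(vdw = 0, ele = 0))
  st <- two_bead_state(2^(1/6) * 4, eps = c(1, 1), sigma = c(4, 4))
  en <- vacuum_energy(st, ff)
  expect_equal(en$vdw, -1, tolerance = 1e-12)
  expect_equal(en$ele, 0)
})

test_that("the Coulomb term reproduces the textbook value", {
  ff <- force_field_params(dielectric = 1)
  st <- two_bead_state(3.320636, charge = c(1, -1), eps = c(0, 0))
  expect_equal(vacuum_energy(st, ff)$ele, -100.0, tolerance = 1e-10)
})

test_that("vacuum energy matches the brute-force oracle on random frames", {
  ff <- force_field_params()
  for (seed in 1:6) {
    st <- make_random_state(5, 4, box = 28, seed = seed)
    got <- vacuum_energy(st, ff)
    want <- oracle_pair_energy(st, ff)
    expect_equal(got$vdw, want$vdw, tolerance = 1e-10)
    expect_equal(got$ele, want$ele, tolerance = 1e-10)
  }
})

test_that("saturation numbers follow the surface-distance rule", {
  # three CTDs mutually within the cutoff: every molecule sees 2 others
  beads <- data.frame(
    bead_id = 1:3, molecule_id = 1:3, group = "CTD",
    residue_code = "CHOL", charge = 0, lj_epsilon = 1.5, lj_sigma = 6,
    radius = 3, mass = 40, stringsAsFactors = FALSE
  )
  tri <- system_state(beads, rbind(c(0, 0, 0), c(8, 0, 0), c(4, 7, 0)), 100)
  sat <- saturation_number(tri, cutoff = 3)
  expect_equal(unname(sat$counts), c(2, 2, 2))
  expect_equal(sat$max, 2)
  expect_equal(sat$min, 2)
  # far apart: all zero
  far <- system_state(beads, rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0)), 100)
  expect_equal(saturation_number(far, 3)$max, 0)
  # molecule without a CTD bead is a topology error
  bad <- tri
  bad$beads$group[2] <- "RESIDUE"
  expect_error(saturation_number(bad), "without a CTD")
})

test_that("saturation counts equal the brute-force recount on random frames", {
  for (seed in 1:8) {
    st <- make_random_state(8, 3, box = 26, seed = seed)
    sat <- saturation_number(st, cutoff = 3)
    expect_identical(unname(sat$counts), as.numeric(oracle_sat_counts(st, 3)))
  }
  # a 16-molecule frame at the screen's scale
  st <- make_random_state(16, 4, box = 40, seed = 99)
  sat <- saturation_number(st, cutoff = 3)
  expect_identical(unname(sat$counts), as.numeric(oracle_sat_counts(st, 3)))
})

test_that("saturation numbers are invariant under relabeling and rigid motion", {
  st <- make_random_state(6, 3, box = 70, seed = 31, spread = 18)
  st$coords <- st$coords - min(st$coords) + 15  # compact, away from faces
  base <- sort(unname(saturation_number(st, 4)$counts))
  # global translation
  tr <- st; tr$coords <- tr$coords + 3.7
  expect_equal(sort(unname(saturation_number(tr, 4)$counts)), base)
  # rotation about the centroid (all separations < box/2)
  th <- 0.8
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ce <- colMeans(st$coords)
  rs <- st; rs$coords <- sweep(sweep(st$coords, 2, ce) %*% rot, 2, ce, "+")
  expect_equal(sort(unname(saturation_number(rs, 4)$counts)), base)
  # molecule relabeling
  perm <- c(3L, 1L, 2L, 6L, 5L, 4L)
  rl <- st; rl$beads$molecule_id <- perm[rl$beads$molecule_id]
  expect_equal(sort(unname(saturation_number(rl, 4)$counts)), base)
})

test_that("metric summaries use post-burn-in sample statistics", {
  expect_equal(summarize_metrics(c(5, 5, 5, 5), 0)[c("mean", "sd")],
               list(mean = 5, sd = 0))
  s <- summarize_metrics(c(1, 2, 3, 4), 0.5)
  expect_equal(s$mean, 3.5)
  expect_equal(s$sd, sd(c(3, 4)))
  expect_equal(s$n_frames, 2L)
  expect_error(summarize_metrics(c(1), 0), "insufficient")
  expect_error(summarize_metrics(c(1, 2, 3), 0.9), "insufficient")
})

test_that("per-frame metric series carry all screening observables", {
  tr <- run_scenario("aggregator", seed = 4, n_steps = 1000,
                     save_every = 500)
  ms <- compute_metrics(tr, n_points = 240)
  expect_s3_class(ms, "metric_series")
  expect_equal(nrow(ms), 3L)
  expect_true(all(ms$sasa_total > 0))
  expect_true(all(ms$sat_min <= ms$sat_max))
  expect_true(all(ms$largest_cluster_fraction > 0 &
                    ms$largest_cluster_fraction <= 1))
  expect_equal(ms$time, c(0, 25, 50))
})
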