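test_that("hull radius matches closed forms for cube and tetrahedron", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  h <- hull_hydrodynamic_radius(cube, use_shape_correction = FALSE)
  expect_equal(h$hull_volume, 1, tolerance = 1e-12)
  expect_equal(h$equivalent_sphere_radius, (3 / (4 * pi))^(1 / 3),
               tolerance = 1e-12)
  expect_equal(h$hydrodynamic_radius, h$equivalent_sphere_radius)

  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  h <- hull_hydrodynamic_radius(tet, use_shape_correction = FALSE)
  expect_equal(h$hull_volume, sqrt(2) / 12, tolerance = 1e-12)
  expect_equal(h$equivalent_sphere_radius,
               (3 * sqrt(2) / 12 / (4 * pi))^(1 / 3), tolerance = 1e-12)
})

test_that("hull radius converges to the radius of a densely sampled sphere", {
  set.seed(8)
  radii <- vapply(c(100, 1000, 5000), function(n) {
    p <- matrix(rnorm(3 * n), ncol = 3)
    p <- p / sqrt(rowSums(p^2)) * 7
    hull_hydrodynamic_radius(p,
      use_shape_correction = FALSE)$equivalent_sphere_radius
  }, numeric(1))
  expect_true(all(diff(radii) > 0))    # monotone approach from inside
  expect_equal(radii[3], 7, tolerance = 0.01)
})

test_that("hull volume agrees with an independent implementation on random sets", {
  set.seed(19)
  for (n in c(8, 40, 160)) {
    p <- matrix(rnorm(3 * n, sd = 4), ncol = 3)
    ours <- hull_hydrodynamic_radius(p,
      use_shape_correction = FALSE)$hull_volume
    ref <- scipy_hull_volume(p)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("hull estimate is rigid-motion invariant and rejects degenerate input", {
  set.seed(4)
  p <- matrix(rnorm(90, sd = 3), ncol = 3)
  a <- hull_hydrodynamic_radius(p, hydration_shell = 2.8)
  m <- random_rigid_motion()
  b <- hull_hydrodynamic_radius(apply_rigid(p, m), hydration_shell = 2.8)
  expect_equal(a$hull_volume, b$hull_volume, tolerance = 1e-9)
  expect_equal(a$shape_correction, b$shape_correction, tolerance = 1e-9)
  expect_equal(a$hydrodynamic_radius, b$hydrodynamic_radius,
               tolerance = 1e-9)
  expect_gte(a$hydrodynamic_radius, a$equivalent_sphere_radius)

  flat <- cbind(matrix(rnorm(20), ncol = 2), 0)
  expect_error(hull_hydrodynamic_radius(flat), "geometry error")
  expect_error(hull_hydrodynamic_radius(p[1:3, ]), "geometry error")
})

test_that("Perrin factor is 1 for spheres and matches the prolate closed form", {
  expect_equal(perrin_shape_factor(c(3, 3, 3)), 1, tolerance = 1e-9)
  for (ab in list(c(2, 1), c(4, 1), c(10, 1))) {
    a <- ab[1]; b <- ab[2]
    xi <- sqrt(a^2 - b^2)
    rh <- xi / log((a + xi) / b)          # prolate spheroid Stokes radius
    expect_equal(perrin_shape_factor(c(a, b, b)), rh / (a * b * b)^(1 / 3),
                 tolerance = 1e-8)
  }
  expect_gt(perrin_shape_factor(c(5, 2, 1)), 1)
})

test_that("ensemble radius summaries follow the stated conventions", {
  set.seed(2)
  p <- matrix(rnorm(60, sd = 5), ncol = 3)
  one <- ensemble_radius_stats(list(p))
  expect_equal(one$mean, one$median)
  expect_equal(one$iqr, 0)
  expect_equal(one$n, 1L)

  # injected radii via spheres of known size: scale one frame
  reps <- lapply(c(1, 2, 3, 4, 5), function(s) p * s)
  st <- ensemble_radius_stats(reps, use_shape_correction = FALSE)
  expect_equal(st$radii, st$radii[1] * 1:5, tolerance = 1e-9)
  expect_equal(st$median, st$radii[3])
  expect_equal(st$mean, mean(st$radii))

  # duplicated ensembles give identical statistics
  st2 <- ensemble_radius_stats(c(reps, reps), use_shape_correction = FALSE)
  expect_equal(st2$mean, st$mean)
  expect_equal(st2$median, st$median)
  expect_error(ensemble_radius_stats(list()), "empty")
})

test_that("F-F distance matrices average per-frame distances correctly", {
  seq <- fg_sequence("AFGAAFGA")
  sites <- phenylalanine_sites(seq)   # 2 and 6
  # two F beads held 5 A apart in every frame
  mk <- function(d) {
    x <- build_extended_chain(seq, 1.0)
    x[6, ] <- x[2, ] + c(d, 0, 0)
    x
  }
  tr <- toy_trajectory(list(mk(5), mk(5), mk(5)))
  m <- ff_distance_matrix(tr, sites)
  expect_equal(m["2", "6"], 5)
  expect_equal(diag(m), c("2" = 0, "6" = 0))

  # 3-frame toy against hand-computed mean
  tr2 <- toy_trajectory(list(mk(4), mk(5), mk(9)))
  expect_equal(ff_distance_matrix(tr2, sites)["2", "6"], 6)

  # permuting the site order permutes rows/columns consistently
  m12 <- ff_distance_matrix(tr2, sites)
  m21 <- ff_distance_matrix(tr2, rev(sites))
  expect_equal(m21, m12[c("6", "2"), c("6", "2")])

  expect_error(ff_distance_matrix(tr2, c(2L, 99L)), "outside topology")
})

test_that("percent-variation screening reproduces the reference arithmetic", {
  sites <- c(10L, 40L)
  mk <- function(d) matrix(c(0, d, d, 0), 2, 2,
                           dimnames = list(sites, sites))
  # 19 A -> 24 A is a 26.3% change and is flagged at the 25% threshold
  cmp <- compare_cohesion(list(mk(19)), list(mk(24)))
  expect_equal(cmp$percent_variation[1, 2], 5 / 19 * 100, tolerance = 1e-9)
  expect_equal(nrow(cmp$flagged_pairs), 1L)
  expect_equal(cmp$flagged_fraction, 100)
  # 19 A -> 20.5 A is only 7.9% and is not flagged
  cmp2 <- compare_cohesion(list(mk(19)), list(mk(20.5)))
  expect_equal(cmp2$percent_variation[1, 2], 1.5 / 19 * 100,
               tolerance = 1e-9)
  expect_equal(nrow(cmp2$flagged_pairs), 0L)
  expect_equal(cmp2$grand_mean_wt, 19)
  expect_equal(cmp2$grand_mean_var, 20.5)
})

test_that("flagged fraction counts pairs above threshold, identical inputs flag none", {
  sites <- c(1L, 5L, 9L, 13L)
  base <- matrix(20, 4, 4, dimnames = list(sites, sites)); diag(base) <- 0
  varm <- base
  varm[1, 2] <- varm[2, 1] <- 30   # one of six pairs changed by 50%
  cmp <- compare_cohesion(list(base), list(varm))
  expect_equal(cmp$flagged_fraction, 100 / 6, tolerance = 1e-9)
  expect_equal(cmp$flagged_pairs$site_i, 1L)
  expect_equal(cmp$flagged_pairs$site_j, 5L)

  self <- compare_cohesion(list(base, varm), list(base, varm))
  expect_equal(self$flagged_fraction, 0)
  expect_true(all(self$percent_variation == 0))

  # flagged fraction is monotone non-increasing in the threshold
  fracs <- vapply(c(5, 25, 45, 60), function(th)
    compare_cohesion(list(base), list(varm), threshold = th)$flagged_fraction,
    numeric(1))
  expect_true(all(diff(fracs) <= 0))

  bad <- base[1:3, 1:3]
  expect_error(compare_cohesion(list(base), list(bad)), "mismatch")
})

test_that("cohesion networks are complete graphs carrying the distances", {
  sites <- c(3L, 7L, 11L)
  m <- matrix(c(0, 12, 18, 12, 0, 25, 18, 25, 0), 3, 3,
              dimnames = list(sites, sites))
  cmp <- compare_cohesion(list(m), list(m * 1.1))
  g <- cohesion_network(cmp, "wt")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)          # K3
  el <- igraph::as_data_frame(g)
  expect_setequal(el$weight, c(12, 18, 25))
  # drawing thickness increases with distance
  expect_equal(order(igraph::E(g)$thickness), order(igraph::E(g)$weight))
  gv <- cohesion_network(cmp, "variant")
  expect_equal(sort(igraph::E(gv)$weight), sort(c(12, 18, 25) * 1.1))

  f <- tempfile(fileext = ".graphml")
  write_network(g, f)
  back <- igraph::read_graph(f, format = "graphml")
  expect_equal(sort(igraph::E(back)$weight), sort(c(12, 18, 25)))
  f2 <- tempfile(fileext = ".tsv")
  write_network(g, f2)
  tab <- read.delim(f2)
  expect_equal(nrow(tab), 3)
})
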