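test_that("particle radius follows the occupancy scale", {
  expect_equal(particle_radius(10000, 0.0201), 100.5)
  expect_equal(particle_radius(1, 2.0), 1.0)
  expect_equal(particle_radius(3000, 0.0201), 30.15)
  expect_error(particle_radius(-1), "positive")
})

test_that("modeling config validates cutoffs and selection sizes", {
  expect_error(modeling_config(lower_cutoff = -0.2, upper_cutoff = -0.6), "lower_cutoff")
  expect_error(modeling_config(n_models = 10, n_keep = 20), "n_keep")
  expect_error(modeling_config(scale = 0), "positive")
})

test_that("restraint construction follows the z-score rules", {
  set.seed(1)
  v <- matrix(rpois(9, 5) + 1, 3); v <- (v + t(v)) / 2; diag(v) <- 0
  v[1, 3] <- v[3, 1] <- 1000  # dominant non-adjacent pair? (circular: all adjacent)
  m5 <- matrix(2, 5, 5); diag(m5) <- 0
  m5[1, 3] <- m5[3, 1] <- 1000   # strong pair
  m5[2, 5] <- m5[5, 2] <- 0.001  # weak pair
  cm <- contact_matrix(m5, 10000, state = "normalized")
  rs <- build_restraints(cm, modeling_config())
  # adjacency: circular chain of 5 at sum of radii
  adj <- rs[rs$kind == "adjacent", ]
  expect_equal(nrow(adj), 5L)
  expect_true(all(adj$dist == 2 * 100.5))
  att <- rs[rs$kind == "attract", ]
  expect_true(any(att$i == 1 & att$j == 3))
  expect_true(all(att$dist >= 2 * 100.5 & att$dist < 250))
  rep_ <- rs[rs$kind == "repel_lower_bound", ]
  expect_true(any(rep_$i == 2 & rep_$j == 5))
  expect_true(all(rep_$dist == 250))
  # attract distance decreases monotonically with z-score
  expect_lt(att$dist[which(att$i == 1 & att$j == 3)], max(att$dist) + 1e-9)

  expect_error(build_restraints(contact_matrix(matrix(0, 4, 4), 1, state = "normalized")),
               "no signal")
})

test_that("annealing reaches closed-form minima and is deterministic", {
  two <- structure(tibble::tibble(i = 1L, j = 2L, kind = "attract", dist = 5, k = 1),
                   radii = c(1, 1), n_particles = 2L,
                   class = c("restraint_set", "data.frame"))
  cfg <- modeling_config(n_models = 3, n_keep = 3, t0 = 10, move_sigma = 3, seed = 5)
  ens <- optimize_ensemble(two, cfg)
  d <- sapply(ens$coords, function(x) dist(x))
  expect_true(all(abs(d - 5) / 5 < 0.01))
  expect_true(all(ens$penalty <= ens$initial_penalty))

  # circular 3-chain with adjacency only: all pairs at sum of radii
  chain <- structure(tibble::tibble(i = c(1L, 2L, 1L), j = c(2L, 3L, 3L),
                                    kind = "adjacent", dist = 4, k = 1),
                     radii = rep(2, 3), n_particles = 3L,
                     class = c("restraint_set", "data.frame"))
  ens3 <- optimize_ensemble(chain, modeling_config(n_models = 3, n_keep = 3, t0 = 10,
                                                   move_sigma = 2, seed = 2))
  for (x in ens3$coords) {
    expect_true(all(abs(dist(x) - 4) / 4 < 0.01))
  }

  again <- optimize_ensemble(two, cfg)
  expect_identical(ens$coords, again$coords)
  expect_identical(ens$penalty, again$penalty)
})

test_that("model selection keeps the lowest penalties and is idempotent", {
  coords <- lapply(1:3, function(i) matrix(rnorm(6), 2))
  ens <- model_ensemble(coords, penalty = c(3, 1, 2))
  kept <- select_models(ens, 2)
  expect_equal(kept$penalty, c(1, 2))
  expect_identical(select_models(kept, 2), kept)
  expect_identical(select_models(ens, 3)$penalty, c(1, 2, 3))
  expect_error(select_models(ens, 4), "exceeds")
})

test_that("mirror images split into two clusters; achiral structures do not", {
  st <- generate_true_structure(30, 50, seed = 2)
  mir <- st %*% diag(c(1, 1, -1))
  set.seed(3)
  jig <- function(x) x + matrix(rnorm(length(x), 0, 0.5), nrow(x))
  ens <- model_ensemble(c(lapply(1:8, function(i) jig(st)),
                          lapply(1:8, function(i) jig(mir))))
  cl <- cluster_models(ens)
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_equal(unname(as.vector(table(cl$cluster))), c(8L, 8L))
  # centroids belong to their clusters
  expect_true(all(cl$cluster[cl$centroids] == seq_along(cl$centroids)))

  flat <- st; flat[, 3] <- 0
  ensf <- model_ensemble(list(flat, flat %*% diag(c(1, 1, -1)), flat))
  expect_equal(length(unique(cluster_models(ensf)$cluster)), 1L)

  # reflection-merged clustering collapses the mirror split
  clm <- cluster_models(ens, allow_reflection = TRUE)
  expect_equal(length(unique(clm$cluster)), 1L)

  expect_error(cluster_models(model_ensemble(list(st))), "at least 2")
})

test_that("geometry formulas and rigid-motion invariance", {
  two <- model_ensemble(list(matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE)))
  g <- ensemble_geometry(two)
  expect_equal(g$length_nm, 10)
  expect_equal(g$width_nm, 10)  # 2 * Rg, Rg = 5

  # volume: length 1000, width 500 -> (4/3) pi 500 250^2 nm^3 = 0.1309 um^3
  expect_equal((4 / 3) * pi * 500 * 250^2 / 1e9, 0.1308997, tolerance = 1e-6)

  st <- generate_true_structure(20, 30, seed = 1)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0), c(0, 0, 1))
  rot <- st %*% R + matrix(rep(c(5, -3, 11), each = 20), 20)
  refl <- st %*% diag(c(-1, 1, 1))
  g0 <- ensemble_geometry(model_ensemble(list(st)))
  g1 <- ensemble_geometry(model_ensemble(list(rot)))
  g2 <- ensemble_geometry(model_ensemble(list(refl)))
  expect_equal(g1$length_nm, g0$length_nm, tolerance = 1e-8)
  expect_equal(g1$width_nm, g0$width_nm, tolerance = 1e-8)
  expect_equal(g2$volume_um3, g0$volume_um3, tolerance = 1e-12)

  expect_error(ensemble_geometry(model_ensemble(list(matrix(0, 1, 3)))), "2 particles")
})

test_that("model contact maps degenerate correctly", {
  st <- generate_true_structure(12, 40, seed = 4)
  same3 <- model_ensemble(list(st, st, st))
  mm <- model_contact_map(same3, 150)
  expect_true(all(mm$values %in% c(0, 1)))
  all1 <- model_contact_map(same3, 1e9)
  expect_true(all(all1$values == 1))
  ref <- contact_matrix(matrix(1, 12, 12), 1, state = "normalized")
  expect_error(model_contact_map(same3, 1e9, reference = ref), "degenerate")
})

test_that("locus distances and centre-of-mass profiles", {
  st <- generate_true_structure(16, 25, seed = 6)
  ens <- model_ensemble(list(st))
  ld <- locus_distances(ens, c(a = 3, b = 3))
  expect_equal(ld$median_nm, 0)
  ld2 <- locus_distances(ens, c(4, 9))
  expect_equal(ld2$median_nm, sqrt(sum((st[4, ] - st[9, ])^2)))
  expect_error(locus_distances(ens, c(1, 99)), "out of range")

  # planar ring: equal radii implies equal centre-of-mass distances
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- cbind(cos(ang), sin(ang), 0)
  prof <- center_of_mass_profile(model_ensemble(list(ring)))
  expect_true(all(abs(prof$median_nm - 1) < 1e-10))
  single <- center_of_mass_profile(model_ensemble(list(matrix(c(1, 2, 3), 1))))
  expect_equal(single$median_nm, 0)

  # poles of the generated truth have maximal profile values
  big <- generate_true_structure(40, 30, seed = 2)
  p <- center_of_mass_profile(model_ensemble(list(big)))
  expect_setequal(order(p$median_nm, decreasing = TRUE)[1:2], c(1, 21))
})
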