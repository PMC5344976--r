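test_that("distance decay fitting recovers the generator's exponent", {
  tr <- planted_truth(decay_exponent = -1, domain_boost = 1, epsilon = 0)
  fits <- sapply(1:5, function(s) {
    cm <- simulate_contact_map(tr, 80, 200, seed = s)
    fit_distance_decay(cm)$b
  })
  expect_lt(abs(mean(fits) + 1), 0.05)

  flat <- contact_matrix(matrix(3, 20, 20), 1)
  fit <- fit_distance_decay(flat)
  expect_equal(fit$b, 0)
  expect_true(all(fit$means$mean == 3))
  expect_error(fit_distance_decay(contact_matrix(matrix(0, 10, 10), 1)), "positive mean")
})

test_that("uniform power-law maps yield a single domain", {
  tr <- planted_truth(decay_exponent = -1, domain_boost = 1, epsilon = 0)
  cm <- simulate_contact_map(tr, 60, 50, seed = 3)
  seg <- detect_cids(cm, segmentation_config(bin_size = 1, band = 15))
  expect_equal(seg$borders, 1L)
  expect_equal(nrow(seg$domains), 1L)
  expect_error(detect_cids(simulate_contact_map(tr, 8, 50, seed = 1),
                           segmentation_config(bin_size = 1, min_domain = 5)),
               "smaller than")
})

test_that("planted borders on a small circular map are recovered", {
  tr <- toy_truth(c(11, 21), boost = 3)
  hits <- 0; total <- 0
  for (s in 1:10) {
    cm <- simulate_contact_map(tr, 30, 50, seed = s)
    seg <- detect_cids(cm, segmentation_config(bin_size = 1, band = 10))
    found <- setdiff(seg$borders, 1L)
    hits <- hits + sum(sapply(c(11, 21), function(b) any(abs(found - b) <= 1)))
    total <- total + 2
  }
  expect_gte(hits / total, 0.8)
})

test_that("segmentation is invariant to positive scaling of the matrix", {
  tr <- toy_truth(c(16, 31), boost = 3)
  cm <- simulate_contact_map(tr, 45, 50, seed = 2)
  cfg <- segmentation_config(bin_size = 1, band = 12)
  seg1 <- detect_cids(cm, cfg)
  scaled <- contact_matrix(cm$values * 7.3, cm$bin_size)
  seg2 <- detect_cids(scaled, cfg)
  expect_identical(seg1$borders, seg2$borders)
})

test_that("stronger BIC penalties never add borders", {
  tr <- toy_truth(c(11, 21, 31), boost = 2.5)
  cm <- simulate_contact_map(tr, 42, 50, seed = 8)
  counts <- sapply(c(0.3, 1, 3, 10), function(mult) {
    length(detect_cids(cm, segmentation_config(bin_size = 1, band = 10,
                                               bic_multiplier = mult))$borders)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("border confidence lies in 1..10 and tracks penalty persistence", {
  tr <- toy_truth(c(11, 21), boost = 3)
  cm <- simulate_contact_map(tr, 30, 50, seed = 2)
  seg <- detect_cids(cm, segmentation_config(bin_size = 1, band = 10))
  expect_true(all(seg$confidence >= 1 & seg$confidence <= 10))
  expect_equal(length(seg$confidence), length(seg$borders))
})

test_that("domain density matches a direct hand computation", {
  # matrix whose entries equal the per-distance averages -> density 1
  n <- 12
  d <- minihic:::circular_distance_matrix(n)
  vals <- ifelse(d == 0, 0, 10 / d)
  cm <- contact_matrix(vals, 1)
  seg <- domain_segmentation(c(4, 9), n, 1)
  expect_equal(cid_density(cm, seg)$density, rep(1, 3))
  whole <- domain_segmentation(integer(), n, 1)
  expect_equal(cid_density(cm, whole)$density, 1)

  # independent enumeration oracle on a perturbed matrix
  set.seed(5)
  vals2 <- vals * (1 + 0.3 * abs(matrix(rnorm(n * n), n)))
  vals2 <- (vals2 + t(vals2)) / 2; diag(vals2) <- 0
  cm2 <- contact_matrix(vals2, 1)
  means <- sapply(1:max(d), function(k) mean(vals2[d == k]))
  oracle <- function(bins) {
    s <- 0; e <- 0
    for (i in bins) for (j in bins) if (i < j) {
      s <- s + vals2[i, j]; e <- e + means[d[i, j]]
    }
    s / e
  }
  dens <- cid_density(cm2, seg)$density
  expect_equal(dens, c(oracle(1:3), oracle(4:8), oracle(9:12)))

  # block doubled relative to the expectation -> density approx 2
  vals3 <- vals
  vals3[1:4, 1:4] <- vals3[1:4, 1:4] * 2
  dens3 <- cid_density(contact_matrix(vals3, 1), domain_segmentation(5, n, 1))$density
  means3 <- sapply(1:max(d), function(k) mean(vals3[d == k]))
  exp_oracle <- sum(vals3[1:4, 1:4][upper.tri(matrix(0, 4, 4))]) /
    sum(means3[d[1:4, 1:4][upper.tri(matrix(0, 4, 4))]])
  expect_equal(dens3[1], exp_oracle)
  expect_gt(dens3[1], 1.5)
})

test_that("segmentations tile the genome", {
  tr <- toy_truth(c(11, 21), boost = 3)
  cm <- simulate_contact_map(tr, 30, 50, seed = 4)
  seg <- detect_cids(cm, segmentation_config(bin_size = 1, band = 10))
  expect_equal(sum(seg$domains$size), 30L)
  expect_equal(seg$domains$start[1], 1L)
  expect_true(all(diff(seg$borders) >= 3))
})

test_that("border alignment scores and null test behave", {
  a <- domain_segmentation(c(11, 21, 31), 60, 1)
  b <- domain_segmentation(c(12, 20, 31), 60, 1)  # within tolerance 1
  al <- align_borders(list(a, a), tolerance = 0)
  expect_equal(al$score, 1.0)
  al2 <- align_borders(list(a, b), tolerance = 1)
  expect_equal(al2$score, 1.0)
  al0 <- align_borders(list(domain_segmentation(c(11, 31), 60, 1),
                            domain_segmentation(c(21, 41), 60, 1)), tolerance = 1)
  expect_lt(al0$score, 1.0)
  expect_error(align_borders(list(a)), "at least 2")
  expect_error(align_borders(list(a, domain_segmentation(5, 20, 1))), "mixed binning")

  rep_seg <- domain_segmentation(seq(7, 259, by = 6), 273, 1)
  nt <- border_alignment_null_test(list(rep_seg, rep_seg, rep_seg),
                                   tolerance = 1, n_random = 500, seed = 2)
  expect_lte(nt$p_value, 1 / 500)
  expect_error(border_alignment_null_test(list(a, a), n_random = 0), "n_random")
})

test_that("segmentation comparison counts conserved domains", {
  a <- domain_segmentation(c(11, 21, 31), 60, 1)
  self <- compare_segmentations(a, a, tolerance = 0)
  expect_equal(self$n_conserved, 4L)
  dis <- compare_segmentations(a, domain_segmentation(c(16, 26, 36, 46), 60, 1),
                               tolerance = 1)
  expect_equal(dis$n_conserved, 0L)
  expect_equal(dis$summary$n_domains, c(4L, 5L))
  expect_error(compare_segmentations(a, domain_segmentation(5, 20, 1)), "mixed")
})
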