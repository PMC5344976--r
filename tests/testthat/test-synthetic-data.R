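test_that("annotation bin arithmetic, tracks and determinism", {
  ann <- generate_genome_annotation(816394, 869, 3000, seed = 1)
  expect_equal(ann$n_bins, 273L)  # ceiling(816394 / 3000)
  expect_equal(generate_genome_annotation(30000, 2, 10000, seed = 0)$n_bins, 3L)
  expect_identical(ann, generate_genome_annotation(816394, 869, 3000, seed = 1))
  expect_false(identical(ann$genes,
                         generate_genome_annotation(816394, 869, 3000, seed = 2)$genes))

  expect_true(all(ann$gc_track >= 0 & ann$gc_track <= 1))
  expect_true(all(ann$site_track >= 0))
  expect_length(ann$gc_track, 273)
  g <- ann$genes
  expect_true(all(g$start < g$end))
  expect_true(all(g$start >= 0 & g$end <= 816394))
  expect_setequal(unique(g$strand), c("+", "-"))

  expect_error(generate_genome_annotation(-5, 10, 1000), "positive")
  expect_error(generate_genome_annotation(1e5, 1, 3000), "2 genes")
})

test_that("true structures form closed chains with opposite poles", {
  st <- generate_true_structure(82, 100.5, seed = 7)
  cons <- sqrt(rowSums((st - st[c(2:82, 1), ])^2))
  expect_true(all(abs(cons - 201) / 201 < 0.02))
  # brute force: the most distant pair is (i, i + n/2) up to 2 positions
  D <- as.matrix(dist(st))
  w <- which(D == max(D), arr.ind = TRUE)[1, ]
  sep <- min(abs(w[1] - w[2]), 82 - abs(w[1] - w[2]))
  expect_lte(abs(sep - 41), 2)

  st4 <- generate_true_structure(4, 1, seed = 0)
  D4 <- as.matrix(dist(st4))
  expect_equal(unname(which(D4 == max(D4), arr.ind = TRUE)[1, ]), c(3, 1))

  expect_error(generate_true_structure(3, 1), "at least 4")
})

test_that("planted truth validates its parameters", {
  expect_error(planted_truth(c(5, 3)), "strictly increasing")
  expect_error(planted_truth(decay_exponent = 0.5), "negative")
  expect_error(planted_truth(domain_boost = 0.5), ">= 1")
})

test_that("simulated contact maps are symmetric, integer and deterministic", {
  tr <- toy_truth()
  cm <- simulate_contact_map(tr, 30, 50, seed = 3)
  expect_true(isSymmetric(cm$values))
  expect_true(all(cm$values >= 0))
  expect_true(all(cm$values == round(cm$values)))
  expect_identical(cm$values, simulate_contact_map(tr, 30, 50, seed = 3)$values)
  expect_error(simulate_contact_map(tr, 6, 50), "at least 8")
  expect_error(simulate_contact_map(toy_truth(c(50, 60)), 30, 50), "exceed")

  # low-intensity Poisson: mostly zero, still symmetric
  sparse <- simulate_contact_map(planted_truth(), 20, 0.001, seed = 1)
  expect_true(isSymmetric(sparse$values))
  expect_gt(mean(sparse$values == 0), 0.95)
})

test_that("homogeneous model has no position effect at fixed distance", {
  tr <- planted_truth(decay_exponent = -1, domain_boost = 1, epsilon = 0)
  cm <- simulate_contact_map(tr, 40, 200, seed = 5)
  d1 <- cm$values[cbind(1:39, 2:40)]
  first <- mean(d1[1:19]); second <- mean(d1[20:39])
  expect_lt(abs(first - second) / first, 0.15)
})

test_that("planted domain boost is recoverable at matched distance", {
  tr <- toy_truth(c(11, 21), boost = 3)
  dom <- minihic:::bin_domains(30, c(11, 21))
  rat <- sapply(1:30, function(s) {
    m <- simulate_contact_map(tr, 30, 50, seed = s)$values
    idx <- cbind(1:27, 1:27 + 3)  # distance 3 cells
    same <- dom[idx[, 1]] == dom[idx[, 2]]
    mean(m[idx[same, ]]) / mean(m[idx[!same, ]])
  })
  expect_lt(abs(mean(rat) - 3), 0.3)
})

test_that("secondary diagonal enhancement lands on wrap-around cells", {
  tr <- planted_truth(decay_exponent = -1, domain_boost = 1, epsilon = 1)
  mu <- minihic:::planted_expectation(tr, 20, 10)
  # 0-based (i + j) %% n == 0 cells are enhanced
  expect_equal(mu[2, 20] / (10 * minihic:::circular_distance(2, 20, 20)^-1), 2)
  expect_equal(mu[3, 19] / (10 * minihic:::circular_distance(3, 19, 20)^-1), 2)
  expect_equal(mu[3, 18] / (10 * minihic:::circular_distance(3, 18, 20)^-1), 1)
})

test_that("replicates share expectation and correlate at depth", {
  tr <- toy_truth(c(25, 50, 75), boost = 2)
  reps <- simulate_replicates(tr, 100, 100, 5, 0.1, seed = 3)
  expect_length(reps, 5)
  cors <- combn(5, 2, function(ix) replicate_correlation(reps[[ix[1]]], reps[[ix[2]]]))
  expect_true(all(cors > 0.9))

  shallow <- simulate_replicates(tr, 100, 0.01, 2, 0.1, seed = 4)
  expect_lt(abs(replicate_correlation(shallow[[1]], shallow[[2]])), 0.2)

  expect_length(simulate_replicates(tr, 100, 10, 1, 0.1, seed = 1), 1)
})

test_that("expression generator plants within-domain correlation", {
  ann <- generate_genome_annotation(300000, 120, 3000, seed = 2)
  borders <- seq(11, 91, by = 10)
  ex <- simulate_expression(ann, borders, 141, 0.5, seed = 1)
  expect_identical(ex, simulate_expression(ann, borders, 141, 0.5, seed = 1))
  expect_equal(dim(ex), c(120L, 282L))

  # recovered mean within-domain correlation approx 0.5 (several seeds)
  rec <- sapply(1:5, function(s) {
    e <- simulate_expression(ann, borders, 141, 0.5, seed = s)
    co <- pearson_coexpression(e)
    gd <- minihic:::gene_domains(co, domain_segmentation(borders, 100, 3000))
    pair <- which(upper.tri(co$values), arr.ind = TRUE)
    same <- gd$domain[pair[, 1]] == gd$domain[pair[, 2]]
    mean(co$values[pair][same])
  })
  expect_lt(abs(mean(rec) - 0.5), 0.1)

  # null: within and between indistinguishable
  e0 <- simulate_expression(ann, borders, 80, 0, seed = 9)
  co0 <- pearson_coexpression(e0)
  gd <- minihic:::gene_domains(co0, domain_segmentation(borders, 100, 3000))
  pair <- which(upper.tri(co0$values), arr.ind = TRUE)
  same <- gd$domain[pair[, 1]] == gd$domain[pair[, 2]]
  expect_lt(abs(mean(abs(co0$values[pair][same])) -
                mean(abs(co0$values[pair][!same]))), 0.03)

  expect_error(simulate_expression(ann, borders, 10, 1.0), "\\[0, 1\\)")
})
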