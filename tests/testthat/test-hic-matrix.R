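test_that("binning pools contacts and conserves counts", {
  m <- bin_contacts(data.frame(pos_i = 0, pos_j = 15000, count = 1), 816394, 10000)
  expect_equal(n_bins(m), 82L)
  expect_equal(m$values[1, 2], 1)
  expect_equal(m$values[2, 1], 1)
  expect_equal(sum(m$values != 0), 2)

  set.seed(42)
  contacts <- data.frame(pos_i = runif(1000, 0, 816394),
                         pos_j = runif(1000, 0, 816394), count = 1)
  mm <- bin_contacts(contacts, 816394, 10000)
  expect_equal(sum(mm$values[upper.tri(mm$values)]) + sum(diag(mm$values)), 1000)

  expect_error(bin_contacts(data.frame(pos_i = -1, pos_j = 0, count = 1), 1e5, 1e4),
               "record 1")
})

test_that("pair classification follows the digest rule table", {
  pairs <- tibble::tibble(
    fragment_i = c(5, 5, 5, 6, 2, 10, 1),
    fragment_j = c(5, 5, 5, 5, 3, 1, 12),
    strand_i   = c("-", "+", "+", "-", "+", "+", "-"),
    strand_j   = c("+", "-", "+", "+", "-", "-", "+"))
  cls <- classify_pairs(pairs, 12)$class
  expect_equal(as.character(cls),
               c("self_ligation",  # same fragment, outward
                 "non_ligation",   # same fragment, inward (dangling)
                 "self_ligation",  # same fragment, co-directional
                 "non_ligation",   # adjacent, inward
                 "non_ligation",   # adjacent, inward
                 "valid",          # distant
                 "non_ligation"))  # circularly adjacent (1 vs 12), inward
  # partition is exhaustive and disjoint
  expect_false(anyNA(cls))
  expect_error(classify_pairs(pairs, 4), "digest map")
})

test_that("control filtering removes only supported distant cells", {
  tr <- planted_truth(decay_exponent = -1)
  m <- simulate_contact_map(tr, 20, 50, seed = 1)
  ctrl_vals <- simulate_contact_map(tr, 20, 5, seed = 2)$values
  ctrl_vals[3, 8] <- ctrl_vals[8, 3] <- 500  # artefact spike
  ctrl <- contact_matrix(ctrl_vals, 1)

  unchanged <- filter_with_control(m, ctrl, integer())
  expect_equal(unchanged$values, m$values)
  expect_equal(unchanged$state, "filtered")

  f <- filter_with_control(m, ctrl, c(3, 8))
  expect_equal(f$values[3, 8], 0)
  expect_equal(f$values[8, 3], 0)
  expect_true(all(f$values <= m$values))
  expect_gt(attr(f, "removed_fraction"), 0)

  # diagonal and first off-diagonal are never touched
  ctrl2 <- ctrl; ctrl2$values[4, 5] <- ctrl2$values[5, 4] <- 1000
  f2 <- filter_with_control(m, ctrl2, c(4, 5))
  expect_equal(f2$values[4, 5], m$values[4, 5])

  expect_error(filter_with_control(m, contact_matrix(matrix(1, 5, 5), 1), 1:2),
               "share shape")
})

test_that("ICE matches the brute-force printed update and balances rows", {
  # worked example
  m0 <- contact_matrix(matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3), 1)
  out <- ice_normalize(m0, rescale = FALSE)
  rs <- rowSums(out$values)
  expect_lt(max(abs(rs - mean(rs)) / mean(rs)), 1e-5)
  expect_equal(out$values, ice_oracle(m0$values), tolerance = 1e-9)

  for (seed in 1:4) {
    n <- sample(10:50, 1)
    raw <- random_symmetric_counts(n, seed)
    out <- ice_normalize(contact_matrix(raw, 1), rescale = FALSE)
    rs <- rowSums(out$values)
    expect_lt(max(abs(rs - mean(rs)) / mean(rs)), 1e-5)
    expect_lt(max(abs(out$values - ice_oracle(raw))), 1e-9)
    expect_true(isSymmetric(out$values))
  }
})

test_that("ICE converges immediately on a balanced matrix and is idempotent", {
  const <- contact_matrix(matrix(5, 6, 6), 1)
  out <- ice_normalize(const)
  expect_lte(attr(out, "iterations"), 1L)
  expect_equal(out$values, matrix(1, 6, 6))  # rescaled to mean 1

  raw <- random_symmetric_counts(15, 99)
  once <- ice_normalize(contact_matrix(raw, 1))
  twice <- ice_normalize(once)
  expect_lt(max(abs(once$values - twice$values)), 1e-4)
  expect_lte(attr(twice, "iterations"), 1L)
})

test_that("zero-total bins are auto-blacklisted with a warning", {
  raw <- random_symmetric_counts(10, 7)
  raw[4, ] <- 0; raw[, 4] <- 0
  expect_warning(out <- ice_normalize(contact_matrix(raw, 1)), "auto-blacklisting")
  expect_true(4L %in% out$blacklist)
  expect_equal(sum(out$values[4, ]), 0)
  expect_error(ice_normalize(contact_matrix(raw, 1), on_zero_bin = "error"), "zero total")
})

test_that("replicate pooling depth-normalizes before summing", {
  a <- contact_matrix(random_symmetric_counts(8, 1), 1)
  expect_equal(sum_replicates(list(a))$values, a$values / sum(a$values))
  two <- sum_replicates(list(a, a))
  expect_equal(two$values, 2 * a$values / sum(a$values))
  # 1x and 10x depths of the same expectation
  tr <- planted_truth(decay_exponent = -1)
  r1 <- simulate_contact_map(tr, 40, 20, seed = 1)
  r10 <- simulate_contact_map(tr, 40, 200, seed = 2)
  pooled <- sum_replicates(list(r1, r10))
  expect_equal(sum(pooled$values), 2)
  expect_error(sum_replicates(list()), "empty")
})

test_that("replicate correlation handles identity, anti-correlation, degeneracy", {
  a <- contact_matrix(random_symmetric_counts(12, 3), 1)
  expect_equal(replicate_correlation(a, a), 1.0)
  b <- contact_matrix(max(a$values) + 1 - a$values, 1)
  expect_equal(replicate_correlation(a, b), -1.0)
  flat <- contact_matrix(matrix(2, 12, 12), 1)
  expect_error(replicate_correlation(a, flat), "zero variance")
})

test_that("MMP score is in range and drops under entry shuffling", {
  tr <- planted_truth(c(15, 30, 45, 60, 70), decay_exponent = -1, domain_boost = 2)
  diffs <- sapply(1:8, function(s) {
    cm <- simulate_contact_map(tr, 82, 50, seed = s)
    norm <- ice_normalize(cm)
    rep <- mmp_score(norm, 10, seed = s)
    expect_gt(rep$mmp_score, 0); expect_lt(rep$mmp_score, 1)
    v <- norm$values; ut <- upper.tri(v)
    set.seed(s); v[ut] <- sample(v[ut])
    v[lower.tri(v)] <- t(v)[lower.tri(v)]
    shuf <- contact_matrix(v, 1, state = "normalized")
    rep$mmp_score - mmp_score(shuf, 10, seed = s)$mmp_score
  })
  expect_true(all(diffs >= 0))
  expect_gt(mean(diffs), 0.05)
  expect_error(mmp_score(contact_matrix(matrix(1, 5, 5), 1, state = "normalized")),
               "too small")
})
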