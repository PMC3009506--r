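test_that("least-squares fit recovers identity and known transforms", {
  ch <- make_coil(20, seed = 1)
  pairs <- cbind(1:20, 1:20)
  tr <- fit_transform(pairs, ch, ch)
  expect_lt(max(abs(tr$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(tr$translation)), 1e-9)

  # s2 = s1 rotated 90 deg about z and translated (1, 2, 3)
  rot <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  known <- rigid_transform(rot, c(1, 2, 3))
  s2 <- perturb_copy(ch, 0, known)
  fit <- fit_transform(pairs, ch, s2)
  expect_lt(rotation_angle(fit$rotation, t(rot)), 1e-5)
  expect_lt(rmsd_pairs(pairs, ca_coords(ch),
                       apply_transform(fit, ca_coords(s2))), 1e-9)

  expect_error(fit_transform(cbind(1:2, 1:2), ch, ch),
               class = "castalign_error_too_few_pairs")
  line <- ca_chain(cbind(1:10 * 3.8, 0, 0), "line_A")
  expect_error(fit_transform(cbind(1:10, 1:10), line, line),
               class = "castalign_error_degenerate_points")
})

test_that("fit is optimal against random rigid transforms", {
  withr::with_seed(99, {
    for (case in 1:10) {
      n <- sample(4:50, 1)
      s1 <- random_frame_chain(sample.int(1e6, 1), n)
      s2 <- ca_chain(ca_coords(s1) + matrix(rnorm(3 * n, 0, 0.5), n, 3),
                     "noisy_A")
      pairs <- cbind(seq_len(n), seq_len(n))
      fit <- fit_transform(pairs, s1, s2)
      best <- rmsd_pairs(pairs, ca_coords(s1),
                         apply_transform(fit, ca_coords(s2)))
      for (k in 1:100) {
        rnd <- rigid_transform(random_rotation(), runif(3, -30, 30))
        expect_gte(rmsd_pairs(pairs, ca_coords(s1),
                              apply_transform(rnd, ca_coords(s2))) + 1e-9,
                   best)
      }
    }
  })
})

test_that("returned rotations are proper even for noisy near-planar inputs", {
  withr::with_seed(42, {
    for (k in 1:20) {
      n <- sample(4:30, 1)
      xyz <- cbind(runif(n, 0, 40), runif(n, 0, 40), rnorm(n, 0, 1e-4))
      s1 <- ca_chain(xyz, "flat1_A")
      s2 <- ca_chain(xyz[sample(n), ] + rnorm(3 * n, 0, 2), "flat2_A")
      tr <- fit_transform(cbind(1:n, 1:n), s1, s2)
      expect_lt(max(abs(crossprod(tr$rotation) - diag(3))), 1e-9)
      expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
    }
  })
})

test_that("rmsd matches its definition", {
  p <- ca_chain(rbind(c(0, 0, 0), c(10, 0, 0)), "p_A")
  q <- rbind(c(3, 0, 0), c(10, 4, 0))
  expect_equal(rmsd_pairs(cbind(1:2, 1:2), ca_coords(p), q), 5 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(rmsd_pairs(cbind(1:2, 1:2), ca_coords(p), ca_coords(p)), 0)
  expect_error(rmsd_pairs(matrix(integer(), 0, 2), ca_coords(p), q),
               class = "castalign_error_empty_pairs")
})

test_that("collect_pairs equals the brute-force all-pairs scan", {
  withr::with_seed(7, {
    for (k in 1:5) {
      s1 <- random_frame_chain(sample.int(1e6, 1), 15)
      s2 <- random_frame_chain(sample.int(1e6, 1), 18)
      tr <- rigid_transform(random_rotation(), runif(3, -5, 5))
      for (delta in c(2, 5, 12)) {
        got <- collect_pairs(s1, s2, tr, delta)
        want <- brute_collect_pairs(s1, s2, tr, delta)
        expect_equal(unname(got), unname(want))
      }
    }
  })
  # identical chains, identity transform: the full diagonal is present
  ch <- make_coil(25, seed = 5)
  h <- collect_pairs(ch, ch, identity_transform(), 1)
  expect_true(all(paste(1:25, 1:25) %in% paste(h[, 1], h[, 2])))
  # delta below the minimum inter-structure distance: empty
  far <- ca_chain(ca_coords(ch) + 100, "far_A")
  expect_equal(nrow(collect_pairs(ch, far, identity_transform(), 1)), 0L)
})

test_that("refinement converges to the full diagonal on an exact rigid copy", {
  ch <- make_coil(40, seed = 8)
  cp <- perturb_copy(ch, 0, random_rigid_transform(3))
  ref <- refine_transform(ch, cp, list(i = 10L, j = 10L, l = 6L))
  # the converged candidate set contains every diagonal pair (plus spatial
  # neighbours within delta, conflicts being allowed)
  expect_gte(nrow(ref$pairs), 40L)
  expect_true(all(paste(1:40, 1:40) %in%
                    paste(ref$pairs[, 1], ref$pairs[, 2])))
  expect_lt(rmsd_pairs(cbind(1:40, 1:40), ca_coords(ch),
                       apply_transform(ref$transform, ca_coords(cp))), 1e-9)
  # |H| grows strictly until the stopping iteration
  expect_true(all(diff(head(ref$sizes, -1)) > 0))
})

test_that("refinement recovers a noisy ground-truth transform", {
  case <- recovery_case(seed = 17, n = 150, sigma = 0.3)
  ref <- refine_transform(case$a, case$b, list(i = 30L, j = 30L, l = 10L))
  expect_lt(rotation_angle(ref$transform$rotation,
                           t(case$truth$rotation)), 2)
  on_diag <- sum(ref$pairs[, 1] == ref$pairs[, 2])
  expect_gte(on_diag, 0.95 * 150)
})

test_that("final alignment RMSD is monotone in the noise level", {
  mean_rmsd <- vapply(c(0.1, 0.2, 0.4), function(sigma) {
    vals <- vapply(1:8, function(s) {
      case <- recovery_case(seed = 100 + s, n = 80, sigma = sigma)
      pairwise_align(case$a, case$b)$rmsd
    }, 1)
    mean(vals)
  }, 1)
  expect_true(all(diff(mean_rmsd) > 0))
})

test_that("transform-redundancy filter behaves at both extremes", {
  ch <- make_coil(50, seed = 14)
  cp <- perturb_copy(ch, 0.2, random_rigid_transform(6), seed = 15)
  seed <- list(i = 5L, j = 5L, l = 10L)
  expect_false(is_redundant(seed, list(), ch, cp))
  ref <- refine_transform(ch, cp, seed)
  expect_true(is_redundant(seed, list(ref$transform), ch, cp, r_skip = 2))

  # a seed in the other part of a chimera is not redundant under the
  # transform fitted to the first part
  shared <- make_coil(50, seed = 41)
  c1 <- make_chimera(list(shared, make_coil(50, seed = 42)), seed = 43)
  c2 <- make_chimera(list(shared, make_coil(50, seed = 42)), seed = 44)
  ref1 <- refine_transform(c1, c2, list(i = 10L, j = 10L, l = 10L))
  far_seed <- list(i = 61L, j = 61L, l = 10L)
  expect_false(is_redundant(far_seed, list(ref1$transform), c1, c2,
                            r_skip = 2))
})
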