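test_that("run decomposition enforces the minimum run length of 4", {
  h4 <- cbind(0:3 + 1L, 0:3 + 1L)
  runs <- runs_from_pairset(h4, min_run = 4L)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$length, 4L)

  h3 <- cbind(1:3, 1:3)
  expect_equal(nrow(runs_from_pairset(h3, min_run = 4L)), 0L)

  # a 10-run plus scattered isolated pairs: only the run survives
  h <- rbind(cbind(1:10, 1:10),
             cbind(c(15L, 18L, 12L, 20L, 25L), c(3L, 30L, 26L, 9L, 14L)))
  runs <- runs_from_pairset(h, min_run = 4L)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$length, 10L)
})

test_that("sequential DP returns whole runs and resolves crossings", {
  s1 <- random_frame_chain(1, 40)
  s2t <- ca_coords(random_frame_chain(2, 40))

  one_run <- cbind(5:24, 11:30)
  sel <- dp_sequential(one_run, s1, s2t, min_run = 4L)
  expect_equal(nrow(sel), 20L)
  expect_equal(unname(sel), unname(one_run))

  # two mutually crossing runs: the longer one wins
  crossing <- rbind(cbind(1:10, 21:30), cbind(15:20, 1:6))
  sel <- dp_sequential(crossing, s1, s2t, min_run = 4L)
  expect_equal(nrow(sel), 10L)
  expect_equal(sel[, "u"], 1:10)
})

test_that("DP output is strictly increasing and conflict-free", {
  for (s in 1:30) {
    h <- random_pairset(s)
    s1 <- random_frame_chain(s + 50, 12)
    s2t <- ca_coords(random_frame_chain(s + 100, 12))
    sel <- dp_sequential(h, s1, s2t, min_run = 4L)
    if (nrow(sel) > 1) {
      expect_true(all(diff(sel[, "u"]) > 0))
      expect_true(all(diff(sel[, "v"]) > 0))
    }
    expect_false(any(duplicated(sel[, "u"])))
    expect_false(any(duplicated(sel[, "v"])))
    # every selected pair comes from the candidate set
    expect_true(all(paste(sel[, 1], sel[, 2]) %in% paste(h[, 1], h[, 2])))
  }
})

test_that("sequential DP matches the exhaustive non-crossing optimum", {
  for (s in 1:60) {
    h <- random_pairset(s)
    s1 <- random_frame_chain(s + 200, 12)
    s2t <- ca_coords(random_frame_chain(s + 300, 12))
    sel <- dp_sequential(h, s1, s2t, min_run = 4L)
    want <- brute_seq_optimum(runs_from_pairset(h, 4L), 4L)
    expect_equal(nrow(sel), want)
  }
})

test_that("maximum matching keeps conflict-free sets and resolves conflicts", {
  s1 <- random_frame_chain(3, 40)
  s2t <- ca_coords(random_frame_chain(4, 40))

  clean <- cbind(1:10, 5:14)
  sel <- mm_nonsequential(clean, s1, s2t, min_run = 4L)
  expect_equal(unname(sel), unname(clean))

  # two runs of length >= 4 sharing one residue of structure 1
  conflicted <- rbind(cbind(1:5, 1:5), cbind(5:9, 21:25))
  sel <- mm_nonsequential(conflicted, s1, s2t, min_run = 4L)
  expect_equal(nrow(sel), 9L)                      # 10 pairs - 1 conflict
  expect_false(any(duplicated(sel[, "u"])))
  expect_false(any(duplicated(sel[, "v"])))
})

test_that("maximum matching cardinality equals exhaustive search", {
  for (s in 1:60) {
    h <- random_pairset(s, max_runs = 4L)
    s1 <- random_frame_chain(s + 400, 12)
    s2t <- ca_coords(random_frame_chain(s + 500, 12))
    sel <- mm_nonsequential(h, s1, s2t, min_run = 3L)
    runs <- runs_from_pairset(h, 3L)
    edges <- do.call(rbind, lapply(seq_len(nrow(runs)), function(r) {
      cbind(runs$u_start[r] + seq_len(runs$length[r]) - 1L,
            runs$v_start[r] + seq_len(runs$length[r]) - 1L)
    }))
    if (is.null(edges)) edges <- matrix(integer(), 0L, 2L)
    expect_equal(nrow(sel), brute_matching(edges))
    expect_false(any(duplicated(sel[, "u"])))
    expect_false(any(duplicated(sel[, "v"])))
  }
})

test_that("matching cardinality agrees with igraph on random instances", {
  skip_if_not_installed("igraph")
  for (s in 1:20) {
    h <- random_pairset(s + 900, n_side = 20L, max_runs = 5L)
    s1 <- random_frame_chain(s + 600, 20)
    s2t <- ca_coords(random_frame_chain(s + 700, 20))
    sel <- mm_nonsequential(h, s1, s2t, min_run = 2L)
    runs <- runs_from_pairset(h, 2L)
    edges <- do.call(rbind, lapply(seq_len(nrow(runs)), function(r) {
      cbind(runs$u_start[r] + seq_len(runs$length[r]) - 1L,
            runs$v_start[r] + seq_len(runs$length[r]) - 1L)
    }))
    if (is.null(edges)) {
      expect_equal(nrow(sel), 0L)
      next
    }
    g <- igraph::graph_from_edgelist(
      cbind(paste0("u", edges[, 1]), paste0("v", edges[, 2])), directed = FALSE)
    igraph::V(g)$type <- grepl("^v", igraph::V(g)$name)
    expect_equal(nrow(sel),
                 igraph::max_bipartite_match(g)$matching_size)
  }
})

test_that("pairwise alignment is exact on a rigid copy in both modes", {
  ch <- make_coil(60, seed = 5)
  cp <- perturb_copy(ch, 0, random_rigid_transform(7))
  for (mode in c("sequential", "nonsequential")) {
    res <- pairwise_align(ch, cp, mode = mode)
    expect_equal(res$n_mat, 60L)
    expect_lt(res$rmsd, 1e-6)
    expect_equal(res$scores$q_score, 1, tolerance = 1e-9)
    expect_equal(res$mode, mode)
  }
})

test_that("pairwise alignment recovers a noisy copy nearly in full", {
  case <- recovery_case(seed = 23, n = 120, sigma = 0.3)
  res <- pairwise_align(case$a, case$b)
  expect_gte(res$n_mat, 0.95 * 120)
  expect_lte(res$rmsd, 1.0)
  expect_lt(rotation_angle(res$transform$rotation,
                           t(case$truth$rotation)), 2)
})

test_that("partial homology is found inside the shared chimera part", {
  shared <- make_coil(60, seed = 33)
  c1 <- make_chimera(list(shared, make_coil(40, seed = 34)), seed = 35)
  c2 <- make_chimera(list(shared, make_coil(40, seed = 36)), seed = 37)
  res <- pairwise_align(c1, c2)
  expect_gte(res$n_mat, 0.9 * 60)
  in_a <- res$pairs$u <= 60 & res$pairs$v <= 60
  expect_gte(mean(in_a), 0.9)   # junction-adjacent residues may tag along
})

test_that("alignment with no seeds returns an empty result with a warning", {
  a <- ca_chain(matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0, 7.6, 3.8, 0),
                       4, 3, byrow = TRUE), "tiny1_A")
  b <- make_helix(9, source_id = "tiny2_A")
  expect_warning(res <- pairwise_align(a, b),
                 class = "castalign_warning_no_seeds")
  expect_equal(res$n_mat, 0L)
  expect_true(res$no_seeds)
  expect_equal(res$scores$q_score, 0)
})

test_that("alignment is deterministic", {
  a <- make_coil(50, seed = 44)
  b <- perturb_copy(a, 0.3, random_rigid_transform(12), seed = 45)
  r1 <- pairwise_align(a, b)
  r2 <- pairwise_align(a, b)
  expect_identical(glance(r1), glance(r2))
  expect_identical(r1$pairs, r2$pairs)
})

test_that("order relaxation never loses matched pairs from a shared transform", {
  shared <- make_coil(40, seed = 46)
  cases <- c(
    lapply(1:4, function(k) {
      a <- make_coil(60, seed = 240 + k)
      list(a, perturb_copy(a, 0.3, random_rigid_transform(250 + k),
                           seed = 260 + k))
    }),
    lapply(1:2, function(k) {
      list(make_chimera(list(shared, make_coil(30, seed = 270 + k)),
                        seed = 280 + k),
           make_chimera(list(shared, make_coil(30, seed = 290 + k)),
                        seed = 300 + k))
    })
  )
  for (case in cases) {
    res <- pairwise_align(case[[1]], case[[2]])
    expect_gt(res$n_mat, 0L)
    s2t <- apply_transform(res$transform, ca_coords(case[[2]]))
    n_seq <- nrow(dp_sequential(res$candidates, case[[1]], s2t, 4L))
    n_mm <- nrow(mm_nonsequential(res$candidates, case[[1]], s2t, 4L))
    expect_gte(n_mm, n_seq)
  }
})
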