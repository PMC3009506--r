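# Independent oracles and fixture builders.  Everything here is deliberately
# naive (loops, recursion, exhaustive enumeration) and shares no code with
# the implementation it checks.

# O(n^2) candidate-pair scan by definition.
brute_collect_pairs <- function(s1, s2, transform, delta) {
  P <- ca_coords(s1)
  Qt <- apply_transform(transform, ca_coords(s2))
  out <- NULL
  for (u in seq_len(nrow(P))) {
    for (v in seq_len(nrow(Qt))) {
      if (sqrt(sum((P[u, ] - Qt[v, ])^2)) <= delta) {
        out <- rbind(out, c(u, v))
      }
    }
  }
  if (is.null(out)) out <- matrix(integer(), 0L, 2L)
  out
}

# Exhaustive maximal-seed finder straight from the band-condition definition:
# O(m1 * m2 * l * d1).
brute_seeds <- function(s1, s2, epsilon, d1, lmin) {
  D1 <- ca_distance_matrix(s1)
  D2 <- ca_distance_matrix(s2)
  br1 <- chain_breaks(s1)
  br2 <- chain_breaks(s2)
  m1 <- nrow(D1); m2 <- nrow(D2)
  valid <- function(i, j, l) {
    if (i + l - 1L > m1 || j + l - 1L > m2) return(FALSE)
    if (l > 1L) {
      if (any(br1[i:(i + l - 2L)]) || any(br2[j:(j + l - 2L)])) return(FALSE)
    }
    for (a in seq_len(l) - 1L) {
      for (b in max(0L, a - d1):(a - 1L)) {
        if (b < 0L) next
        if (abs(D1[i + a, i + b] - D2[j + a, j + b]) > epsilon) return(FALSE)
      }
    }
    TRUE
  }
  seeds <- NULL
  for (i in seq_len(m1)) {
    for (j in seq_len(m2)) {
      l <- 0L
      while (valid(i, j, l + 1L)) l <- l + 1L
      if (l >= lmin) seeds <- rbind(seeds, c(i, j, l))
    }
  }
  if (is.null(seeds)) return(matrix(integer(), 0L, 3L,
                                    dimnames = list(NULL, c("i", "j", "l"))))
  colnames(seeds) <- c("i", "j", "l")
  # keep only maximal seeds: drop (i, j, l) contained in (i-1, j-1, l') with
  # l' >= l + 1 (same diagonal, extendable to the left)
  keep <- vapply(seq_len(nrow(seeds)), function(k) {
    i <- seeds[k, 1L]; j <- seeds[k, 2L]; l <- seeds[k, 3L]
    if (i == 1L || j == 1L) return(TRUE)
    prev <- seeds[seeds[, 1L] == i - 1L & seeds[, 2L] == j - 1L, , drop = FALSE]
    nrow(prev) == 0L || prev[1L, 3L] < l + 1L
  }, TRUE)
  seeds[keep, , drop = FALSE]
}

# Exhaustive non-crossing optimum over all contiguous sub-blocks (length >=
# min_run) of the given runs; memoized on the frontier (u_prev, v_prev).
brute_seq_optimum <- function(runs, min_run) {
  if (nrow(runs) == 0L) return(0L)
  memo <- new.env(parent = emptyenv())
  rec <- function(u_prev, v_prev) {
    key <- paste(u_prev, v_prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- 0L
    for (r in seq_len(nrow(runs))) {
      len <- runs$length[r]
      for (s in 0:(len - min_run)) {
        us <- runs$u_start[r] + s
        vs <- runs$v_start[r] + s
        if (us <= u_prev || vs <= v_prev) next
        for (e in (s + min_run - 1L):(len - 1L)) {
          best <- max(best, (e - s + 1L) +
                        rec(runs$u_start[r] + e, runs$v_start[r] + e))
        }
      }
    }
    memo[[key]] <- best
    best
  }
  rec(0L, 0L)
}

# Exhaustive maximum bipartite matching cardinality by recursion over the
# left-side nodes.
brute_matching <- function(edges) {
  if (nrow(edges) == 0L) return(0L)
  us <- sort(unique(edges[, 1L]))
  rec <- function(k, used_v) {
    if (k > length(us)) return(0L)
    best <- rec(k + 1L, used_v)            # leave us[k] unmatched
    vs <- edges[edges[, 1L] == us[k], 2L]
    for (v in setdiff(vs, used_v)) {
      best <- max(best, 1L + rec(k + 1L, c(used_v, v)))
    }
    best
  }
  rec(1L, integer(0))
}

# Random conflicted pair set made of diagonal runs on small index ranges.
random_pairset <- function(seed, n_side = 12L, max_runs = 5L) {
  withr::with_seed(seed, {
    n_runs <- sample(1:max_runs, 1L)
    h <- NULL
    for (r in seq_len(n_runs)) {
      len <- sample(1:8, 1L)
      u0 <- sample(seq_len(max(1L, n_side - len + 1L)), 1L)
      v0 <- sample(seq_len(max(1L, n_side - len + 1L)), 1L)
      len <- min(len, n_side - u0 + 1L, n_side - v0 + 1L)
      h <- rbind(h, cbind(u0 + seq_len(len) - 1L, v0 + seq_len(len) - 1L))
    }
    unique(h)
  })
}

# A small fixed-frame chain whose coordinates are random but well separated;
# used when finisher tests need distances.
random_frame_chain <- function(seed, n, id = paste0("frame", seed, "_A")) {
  withr::with_seed(seed, {
    ca_chain(matrix(runif(n * 3, 0, 50), n, 3L), source_id = id)
  })
}

# Minimal PDB writer used only to build reader fixtures; fixed-width columns
# per the PDB ATOM record layout.
write_fixture_pdb <- function(path, records) {
  lines <- vapply(records, function(r) {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
            r$type %||% "ATOM", r$serial %||% 1L,
            paste0(" ", r$name %||% "CA"), r$alt %||% " ",
            r$resn %||% "ALA", r$chain %||% "A", r$resno,
            r$icode %||% " ", r$x, r$y, r$z, r$occ %||% 1.00, 0.00)
  }, "")
  writeLines(c(lines, "END"), path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Ground-truth noisy-copy alignment case.
recovery_case <- function(seed, n = 150L, sigma = 0.3) {
  a <- make_coil(n, seed = seed)
  tr <- random_rigid_transform(seed + 1000L)
  b <- perturb_copy(a, noise_sigma = sigma, transform = tr, seed = seed + 2000L)
  list(a = a, b = b, truth = tr)
}
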