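#' Decompose a candidate pair set into diagonal runs
#'
#' Groups a (possibly conflicted) pair set into maximal runs of consecutive
#' pairs `(u + k, v + k)` and discards runs shorter than `min_run`:
#' short runs amount to isolated pairs and are not biologically meaningful.
#'
#' @param h Two-column `(u, v)` pair matrix.
#' @param min_run Minimum surviving run length (default 4).
#' @return Tibble with columns `u_start`, `v_start`, `length`.
#' @export
runs_from_pairset <- function(h, min_run = 4L) {
  pr <- as_pair_matrix(h)
  if (nrow(pr) == 0L) {
    return(tibble::tibble(u_start = integer(), v_start = integer(),
                          length = integer()))
  }
  sp <- split(seq_len(nrow(pr)), pr[, 1L] - pr[, 2L])
  res <- lapply(names(sp), function(dg) {
    u <- sort(unique(pr[sp[[dg]], 1L]))
    brk <- c(TRUE, diff(u) != 1L)
    tibble::tibble(u_start = u[brk],
                   v_start = u[brk] - as.integer(dg),
                   length = tabulate(cumsum(brk)))
  })
  out <- dplyr::bind_rows(res)
  out <- out[out$length >= min_run, , drop = FALSE]
  out[order(out$u_start, out$v_start), ]
}

# Pairs (with distances) belonging to runs of length >= min_run, annotated
# with run id and position; the common preprocessing of both finishers.
eligible_run_pairs <- function(h, coords1, coords2t, min_run) {
  runs <- runs_from_pairset(h, min_run)
  if (nrow(runs) == 0L) return(NULL)
  u <- unlist(lapply(seq_len(nrow(runs)), function(r) {
    runs$u_start[r] + seq_len(runs$length[r]) - 1L
  }))
  v <- unlist(lapply(seq_len(nrow(runs)), function(r) {
    runs$v_start[r] + seq_len(runs$length[r]) - 1L
  }))
  run_id <- rep(seq_len(nrow(runs)), runs$length)
  pos <- unlist(lapply(runs$length, seq_len))
  d <- sqrt(rowSums((coords1[u, , drop = FALSE] -
                       coords2t[v, , drop = FALSE])^2))
  list(runs = runs, u = u, v = v, run_id = run_id, pos = pos, dist = d)
}

#' Stage 3, sequential finisher (SPSA): dynamic programming over runs
#'
#' Selects a conflict-free, order-preserving subset of the candidate pairs:
#' both indices strictly increase along the alignment.  Candidate pairs are
#' restricted to diagonal runs of length at least `min_run`; runs may be
#' truncated at their ends to resolve crossings, but every surviving
#' contiguous block must itself still have at least `min_run` pairs.  Among
#' selections of maximal size, the one with the smaller total pair distance
#' is preferred, then the lexicographically earlier one.
#'
#' @param h Two-column `(u, v)` candidate pair matrix (conflicts allowed).
#' @param s1 [ca_chain()] of structure 1.
#' @param s2t Transformed coordinates of structure 2 (n2 x 3 matrix).
#' @param min_run Minimum block length (default 4).
#' @return Two-column integer matrix of selected `(u, v)` pairs, ordered
#'   by `u`.
#' @export
dp_sequential <- function(h, s1, s2t, min_run = 4L) {
  ep <- eligible_run_pairs(h, ca_coords(s1), as.matrix(s2t), min_run)
  empty <- matrix(integer(), 0L, 2L, dimnames = list(NULL, c("u", "v")))
  if (is.null(ep)) return(empty)
  np <- length(ep$u)
  # f[p]: best (count, dist) over selections ending with a block that ends at
  # pair p; a block is a contiguous stretch of one run with >= min_run pairs.
  f_cnt <- rep(-1L, np)
  f_dist <- rep(Inf, np)
  f_q <- rep(NA_integer_, np)     # block start (pair index)
  f_prev <- rep(NA_integer_, np)  # predecessor pair (end of previous block)
  ord <- order(ep$u, ep$v)
  # cumulative block distances per run
  cum <- stats::ave(ep$dist, ep$run_id, FUN = cumsum)
  # G[q]: best completed selection strictly before a block starting at pair q
  # (u and v both smaller).  Pairs are processed as block ends in u order, so
  # when G[q] is first needed every candidate predecessor is already final
  # and the value can be cached.
  g_cnt <- rep(NA_integer_, np)
  g_dist <- rep(NA_real_, np)
  g_ptr <- rep(NA_integer_, np)
  get_g <- function(q) {
    if (!is.na(g_cnt[q])) return(q)
    cand <- which(f_cnt >= 0L & ep$u < ep$u[q] & ep$v < ep$v[q])
    bc <- 0L; bd <- 0; bp <- NA_integer_
    for (p2 in cand) {
      if (f_cnt[p2] > bc ||
          (f_cnt[p2] == bc && f_dist[p2] < bd - 1e-12)) {
        bc <- f_cnt[p2]; bd <- f_dist[p2]; bp <- p2
      }
    }
    g_cnt[q] <<- bc; g_dist[q] <<- bd; g_ptr[q] <<- bp
    q
  }
  for (p in ord) {
    run_first <- p - ep$pos[p] + 1L           # pairs are stored run-contiguous
    q_hi <- p - min_run + 1L
    if (q_hi < run_first) next
    for (q in run_first:q_hi) {
      blk_cnt <- p - q + 1L
      blk_dist <- cum[p] - if (q > run_first) cum[q - 1L] else 0
      get_g(q)
      tot_cnt <- blk_cnt + g_cnt[q]
      tot_dist <- blk_dist + g_dist[q]
      if (tot_cnt > f_cnt[p] ||
          (tot_cnt == f_cnt[p] && tot_dist < f_dist[p] - 1e-12)) {
        f_cnt[p] <- tot_cnt
        f_dist[p] <- tot_dist
        f_q[p] <- q
        f_prev[p] <- g_ptr[q]
      }
    }
  }
  if (all(f_cnt < 0L)) return(empty)
  best <- which(f_cnt == max(f_cnt))
  best <- best[order(f_dist[best], ep$u[best])][1L]
  sel <- integer(0)
  p <- best
  while (!is.na(p)) {
    sel <- c(f_q[p]:p, sel)
    p <- f_prev[p]
  }
  out <- cbind(u = ep$u[sel], v = ep$v[sel])
  out[order(out[, 1L]), , drop = FALSE]
}

#' Stage 3, non-sequential finisher (NPSA): maximum bipartite matching
#'
#' Builds the bipartite graph whose edges are the candidate pairs belonging
#' to runs of length at least `min_run`, and returns a maximum-cardinality
#' matching; among maximum matchings the one with the smaller total pair
#' distance is chosen (solved as a linear assignment with a large penalty on
#' non-edges).
#'
#' @inheritParams dp_sequential
#' @return Two-column integer matrix of matched `(u, v)` pairs, ordered by
#'   `u`.
#' @export
mm_nonsequential <- function(h, s1, s2t, min_run = 4L) {
  ep <- eligible_run_pairs(h, ca_coords(s1), as.matrix(s2t), min_run)
  empty <- matrix(integer(), 0L, 2L, dimnames = list(NULL, c("u", "v")))
  if (is.null(ep)) return(empty)
  us <- sort(unique(ep$u))
  vs <- sort(unique(ep$v))
  n <- max(length(us), length(vs))
  big <- 1e6
  cost <- matrix(big, n, n)
  if (length(us) < n) cost[(length(us) + 1L):n, ] <- 0  # dummy rows
  ui <- match(ep$u, us)
  vi <- match(ep$v, vs)
  # duplicate (u, v) cannot occur within one run decomposition
  cost[cbind(ui, vi)] <- ep$dist
  asg <- solve_assignment(cost)
  keep <- which(seq_len(n) <= length(us) & asg <= length(vs))
  edge_key <- paste(ui, vi)
  sel <- keep[paste(keep, asg[keep]) %in% edge_key]
  out <- cbind(u = us[sel], v = vs[asg[sel]])
  out[order(out[, 1L]), , drop = FALSE]
}

#' Pairwise structure alignment (three-stage pipeline)
#'
#' Runs the full aligner: stage 1 seeds gapless local alignments from
#' distance-matrix comparison; each non-redundant seed is grown in stage 2
#' into a rigid superposition by iterated least-squares over a
#' conflict-tolerant candidate set; stage 3 turns the candidate set into a
#' conflict-free alignment, either order-preserving (`"sequential"`, dynamic
#' programming) or order-free (`"nonsequential"`, maximum matching).  The
#' largest alignment over all seeds wins (ties: lower RMSD, then higher
#' Q-score); its transform is then refit on the final conflict-free pairs and
#' the reported RMSD and scores refer to those pairs.
#'
#' @param s1,s2 [ca_chain()]s; structure 2 is superimposed onto structure 1.
#' @param mode `"sequential"` or `"nonsequential"`.
#' @param params An [align_params()] bundle.
#' @return An object of class `ca_alignment`: fields `pairs` (tibble of
#'   aligned residues with distances), `transform`, `rmsd`, `n_mat`, `mode`,
#'   `scores` (Q-score and SAS_1..3), `candidates` (the winning seed's full
#'   conflict-tolerant set), `no_seeds` flag, and the two chain ids/lengths.
#'   Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' a <- make_coil(40, seed = 2)
#' res <- pairwise_align(a, perturb_copy(a, 0.2, seed = 3))
#' glance(res)
#' @export
pairwise_align <- function(s1, s2, mode = c("sequential", "nonsequential"),
                           params = align_params()) {
  mode <- match.arg(mode)
  seeds <- find_local_alignments(s1, s2, params)
  best <- NULL
  prior <- list()
  coords1 <- ca_coords(s1)
  coords2 <- ca_coords(s2)
  for (k in seq_len(nrow(seeds))) {
    seed <- seeds[k, ]
    if (is_redundant(seed, prior, s1, s2, params$r_skip)) next
    ref <- tryCatch(refine_transform(s1, s2, seed, params$delta,
                                     params$max_iter),
                    castalign_error = function(e) NULL)
    if (is.null(ref)) next
    prior <- c(prior, list(ref$transform))
    s2t <- apply_transform(ref$transform, coords2)
    finish <- if (mode == "sequential") dp_sequential else mm_nonsequential
    sel <- finish(ref$pairs, s1, s2t, params$min_run)
    if (nrow(sel) == 0L) next
    r <- rmsd_pairs(sel, coords1, s2t)
    q <- q_score(nrow(sel), r, nrow(s1), nrow(s2), params$r0)
    if (is.null(best) || nrow(sel) > best$n_mat ||
        (nrow(sel) == best$n_mat && (r < best$rmsd ||
                                     (r == best$rmsd && q > best$q)))) {
      best <- list(pairs = sel, transform = ref$transform,
                   candidates = ref$pairs, n_mat = nrow(sel), rmsd = r, q = q)
    }
  }
  if (is.null(best)) {
    return(new_ca_alignment(
      pairs = matrix(integer(), 0L, 2L), transform = identity_transform(),
      candidates = matrix(integer(), 0L, 2L), s1 = s1, s2 = s2, mode = mode,
      params = params, no_seeds = nrow(seeds) == 0L
    ))
  }
  # refit on the final conflict-free pairs and report RMSD over them
  final_tr <- if (best$n_mat >= 3L) {
    tryCatch(fit_transform(best$pairs, s1, s2),
             castalign_error = function(e) best$transform)
  } else best$transform
  new_ca_alignment(pairs = best$pairs, transform = final_tr,
                   candidates = best$candidates, s1 = s1, s2 = s2,
                   mode = mode, params = params, no_seeds = FALSE)
}

new_ca_alignment <- function(pairs, transform, candidates, s1, s2, mode,
                             params, no_seeds = FALSE) {
  pr <- as_pair_matrix(pairs)
  coords1 <- ca_coords(s1)
  s2t <- apply_transform(transform, ca_coords(s2))
  n_mat <- nrow(pr)
  if (n_mat > 0L) {
    d <- sqrt(rowSums((coords1[pr[, 1L], , drop = FALSE] -
                         s2t[pr[, 2L], , drop = FALSE])^2))
    rmsd <- sqrt(mean(d^2))
  } else {
    d <- numeric(0)
    rmsd <- NA_real_
  }
  scores <- score_report(n_mat, rmsd, nrow(s1), nrow(s2), r0 = params$r0)
  pairs_tbl <- tibble::tibble(
    u = as.integer(pr[, 1L]), v = as.integer(pr[, 2L]),
    resno1 = if (n_mat) res_label(s1, pr[, 1L]) else character(0),
    resno2 = if (n_mat) res_label(s2, pr[, 2L]) else character(0),
    distance = d
  )
  if (no_seeds) {
    warn("no stage-1 seeds found; returning an empty alignment",
         class = "castalign_warning_no_seeds")
  }
  structure(list(
    id1 = source_id(s1), id2 = source_id(s2),
    n1 = nrow(s1), n2 = nrow(s2),
    mode = mode, n_mat = n_mat, rmsd = rmsd,
    pairs = pairs_tbl, transform = transform,
    candidates = as_pair_matrix(candidates),
    scores = scores, params = params, no_seeds = no_seeds
  ), class = "ca_alignment")
}

#' @export
print.ca_alignment <- function(x, ...) {
  cat(sprintf("<ca_alignment> %s vs %s (%s)\n", x$id1, x$id2, x$mode))
  cat(sprintf("  n_mat %d / (%d, %d)  rmsd %.3f A  Q %.4f  SAS1 %.3f\n",
              x$n_mat, x$n1, x$n2,
              ifelse(is.na(x$rmsd), NA, x$rmsd),
              x$scores$q_score, x$scores$sas[["1"]]))
  invisible(x)
}
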