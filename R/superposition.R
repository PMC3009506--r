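#' Least-squares rigid superposition over a pair set
#'
#' Fits the proper rigid transform `T` minimizing
#' `sum ||p_u - T(q_v)||^2` over a set of candidate residue pairs.  The pair
#' set is *conflict-tolerant*: a residue may appear in several pairs; the fit
#' simply treats every pair as one weighted point correspondence, which keeps
#' stage 2 simple and fast.  Reflections are excluded by a determinant-sign
#' correction on the smallest singular direction (Kabsch).
#'
#' @param pairs Two-column integer matrix (or data frame) of `(u, v)` indices
#'   into `s1` and `s2`; at least 3 pairs.
#' @param s1,s2 [ca_chain()]s (structure 1 is the fixed frame).
#' @return A [rigid_transform()] mapping `s2` coordinates onto `s1`.
#' @examples
#' ch <- make_helix(10)
#' fit_transform(cbind(1:10, 1:10), ch, ch)
#' @export
fit_transform <- function(pairs, s1, s2) {
  pr <- as_pair_matrix(pairs)
  if (nrow(pr) < 3L) {
    abort("at least 3 pairs are required to fit a rigid transform",
          class = "castalign_error_too_few_pairs")
  }
  P <- ca_coords(s1)[pr[, 1L], , drop = FALSE]
  Q <- ca_coords(s2)[pr[, 2L], , drop = FALSE]
  pc <- colMeans(P)
  qc <- colMeans(Q)
  Pc <- sweep(P, 2L, pc)
  Qc <- sweep(Q, 2L, qc)
  sv_p <- svd(Pc)$d
  if (sv_p[2L] < 1e-8 * max(sv_p[1L], 1)) {
    abort("degenerate (collinear or coincident) point configuration",
          class = "castalign_error_degenerate_points")
  }
  H <- crossprod(Qc, Pc)                      # sum over pairs of q p^T
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, pc - drop(R %*% qc))
}

as_pair_matrix <- function(pairs) {
  if (is.data.frame(pairs)) pairs <- cbind(pairs[[1L]], pairs[[2L]])
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  colnames(pairs) <- c("u", "v")
  pairs
}

#' Root-mean-square distance over a pair set
#'
#' @param pairs Two-column `(u, v)` pair matrix; non-empty.
#' @param coords1 Coordinates of structure 1 (n1 x 3).
#' @param coords2t Coordinates of structure 2, already transformed (n2 x 3).
#' @return RMSD in Angstrom.
#' @export
rmsd_pairs <- function(pairs, coords1, coords2t) {
  pr <- as_pair_matrix(pairs)
  if (nrow(pr) == 0L) {
    abort("RMSD of an empty pair set is undefined",
          class = "castalign_error_empty_pairs")
  }
  d2 <- rowSums((coords1[pr[, 1L], , drop = FALSE] -
                   coords2t[pr[, 2L], , drop = FALSE])^2)
  sqrt(mean(d2))
}

#' Collect all candidate pairs within a distance cutoff
#'
#' After superimposing structure 2 with `transform`, returns every residue
#' pair `(u, v)` with `||p_u - T(q_v)|| <= delta` — conflicts included.  This
#' is an exact all-pairs scan; it is the contract any accelerated
#' implementation must reproduce bit for bit.
#'
#' @inheritParams fit_transform
#' @param transform A [rigid_transform()] for `s2`.
#' @param delta Distance cutoff in Angstrom (> 0).
#' @return Integer matrix with columns `u`, `v`, ordered by `u` then `v`.
#' @export
collect_pairs <- function(s1, s2, transform, delta) {
  stopifnot(delta > 0)
  P <- ca_coords(s1)
  Qt <- apply_transform(transform, ca_coords(s2))
  d2 <- outer(rowSums(P^2), rowSums(Qt^2), "+") - 2 * tcrossprod(P, Qt)
  hit <- which(d2 <= delta^2, arr.ind = TRUE)
  out <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
  dimnames(out) <- list(NULL, c("u", "v"))
  out
}

#' Stage 2: grow a seed into a refined superposition
#'
#' Fits an initial transform on the seed's gapless pair set
#' `H0 = {(i+k, j+k)}`, then repeats: superimpose, collect every pair within
#' `delta` (conflicts allowed, the set is rebuilt from scratch each
#' iteration), refit.  Stops when the candidate set stops growing strictly,
#' or after `max_iter` iterations.
#'
#' @inheritParams collect_pairs
#' @param seed A one-row seed (`i`, `j`, `l`) as returned by
#'   [find_local_alignments()], or a list with those fields; `l >= 3`.
#' @param max_iter Iteration cap.
#' @return A list with `transform` (last fit), `pairs` (largest candidate set
#'   seen), and `sizes` (trace of `|H|` per iteration).
#' @export
refine_transform <- function(s1, s2, seed, delta = 4.0, max_iter = 30L) {
  h0 <- cbind(seed$i + seq_len(seed$l) - 1L, seed$j + seq_len(seed$l) - 1L)
  tr <- fit_transform(h0, s1, s2)
  best <- h0
  sizes <- integer(0)
  n_prev <- 0L
  for (it in seq_len(max_iter)) {
    h <- collect_pairs(s1, s2, tr, delta)
    sizes <- c(sizes, nrow(h))
    if (nrow(h) > nrow(best)) best <- h
    if (nrow(h) <= n_prev) break
    n_prev <- nrow(h)
    tr_new <- tryCatch(fit_transform(h, s1, s2), castalign_error = function(e) NULL)
    if (is.null(tr_new)) break
    tr <- tr_new
  }
  list(transform = tr, pairs = best, sizes = sizes)
}

#' Transform-redundancy filter
#'
#' A seed whose pair set already superimposes well (RMSD at most `r_skip`)
#' under some previously fitted transform would lead to a global alignment
#' similar to one already computed, and can be skipped.
#'
#' @inheritParams refine_transform
#' @param prior List of previously obtained [rigid_transform()]s.
#' @param r_skip RMSD cutoff in Angstrom.
#' @return `TRUE` iff some prior transform reproduces the seed within
#'   `r_skip`.
#' @export
is_redundant <- function(seed, prior, s1, s2, r_skip = 2.0) {
  if (length(prior) == 0L) return(FALSE)
  h0 <- cbind(seed$i + seq_len(seed$l) - 1L, seed$j + seq_len(seed$l) - 1L)
  P <- ca_coords(s1)
  Q <- ca_coords(s2)
  for (tr in prior) {
    if (rmsd_pairs(h0, P, apply_transform(tr, Q)) <= r_skip) return(TRUE)
  }
  FALSE
}
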