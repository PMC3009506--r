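#' Intra-molecular C-alpha distance matrix
#'
#' @param chain A [ca_chain()].
#' @return Symmetric n x n matrix of Euclidean distances (Angstrom), zero
#'   diagonal.
#' @export
ca_distance_matrix <- function(chain) {
  unname(as.matrix(dist(ca_coords(chain))))
}

#' Mask short alpha-helices
#'
#' Residue `i` carries the helical signature when `d(i, i+3)` lies in
#' \[4.5, 5.5\] and `d(i, i+4)` in \[5.0, 6.5\] Angstrom; residues within 4 of a
#' run's end inherit its label.  Maximal helical runs *shorter* than
#' `helix_min_keep` are masked: such short helices are ubiquitous in proteins
#' and would otherwise swamp stage 1 with uninformative seeds.  Long helices
#' are kept.
#'
#' @param chain A [ca_chain()].
#' @param helix_min_keep Minimum helical run length that escapes masking
#'   (default 8).
#' @return Logical vector over residues; `TRUE` = masked.
#' @export
detect_short_helices <- function(chain, helix_min_keep = 8L) {
  n <- n_res(chain)
  if (n < 5L) return(rep(FALSE, n))
  xyz <- ca_coords(chain)
  d3 <- sqrt(rowSums((xyz[seq_len(n - 3L) + 3L, , drop = FALSE] -
                        xyz[seq_len(n - 3L), , drop = FALSE])^2))
  d4 <- sqrt(rowSums((xyz[seq_len(n - 4L) + 4L, , drop = FALSE] -
                        xyz[seq_len(n - 4L), , drop = FALSE])^2))
  sig <- d3[seq_len(n - 4L)] >= 4.5 & d3[seq_len(n - 4L)] <= 5.5 &
    d4 >= 5.0 & d4 <= 6.5
  helical <- vapply(seq_len(n), function(r) {
    lo <- max(1L, r - 4L)
    hi <- min(n - 4L, r)
    hi >= lo && any(sig[lo:hi])
  }, logical(1))
  mask <- rep(FALSE, n)
  r <- rle(helical)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] < helix_min_keep) {
      mask[starts[k]:ends[k]] <- TRUE
    }
  }
  mask
}

#' Stage 1: gapless local alignments from distance-matrix comparison
#'
#' Finds every maximal gapless seed `(i, j, l)` — segment
#' `p_i..p_{i+l-1}` of `s1` matching `q_j..q_{j+l-1}` of `s2` — on which the
#' two intra-molecular distance matrices agree within `epsilon` over a band
#' of width `d1` (position `a` of the seed is checked against the `d1`
#' positions before it).  Runs in O(`d1 * m1 * m2`).  Seeds shorter than
#' `l_min_seed` are discarded; overlapping seeds on the same diagonal are
#' merged; seeds whose segments are both at least 90% covered by masked
#' short-helix residues are dropped; seeds never span a chain break.
#'
#' @param s1,s2 [ca_chain()]s.
#' @param params An [align_params()] bundle (`epsilon`, `d1`, `l_min_seed`,
#'   `helix_min_keep` are used).
#' @return Tibble with columns `i`, `j`, `l` (1-based starts and length),
#'   sorted by `l` descending, then `i`, `j` ascending.
#' @export
find_local_alignments <- function(s1, s2, params = align_params()) {
  d1m <- ca_distance_matrix(s1)
  d2m <- ca_distance_matrix(s2)
  runs <- scan_seed_runs(d1m, d2m, params$epsilon, params$d1,
                         params$l_min_seed, chain_breaks(s1), chain_breaks(s2))
  runs <- merge_diagonal_runs(runs)
  if (nrow(runs) > 0L) {
    m1 <- detect_short_helices(s1, params$helix_min_keep)
    m2 <- detect_short_helices(s2, params$helix_min_keep)
    if (any(m1) || any(m2)) {
      cm1 <- c(0, cumsum(m1))
      cm2 <- c(0, cumsum(m2))
      cov1 <- (cm1[runs[, "i"] + runs[, "l"]] - cm1[runs[, "i"]]) / runs[, "l"]
      cov2 <- (cm2[runs[, "j"] + runs[, "l"]] - cm2[runs[, "j"]]) / runs[, "l"]
      runs <- runs[!(cov1 >= 0.9 & cov2 >= 0.9), , drop = FALSE]
    }
  }
  ord <- order(-runs[, "l"], runs[, "i"], runs[, "j"])
  tibble::tibble(i = runs[ord, "i"], j = runs[ord, "j"], l = runs[ord, "l"])
}

# Merge overlapping seeds that lie on the same (i - j) diagonal into their
# union interval; both constituents already satisfy the band condition, and
# the union remains non-extendable at either end.
merge_diagonal_runs <- function(runs) {
  if (nrow(runs) <= 1L) return(runs)
  diag_id <- runs[, "i"] - runs[, "j"]
  out <- lapply(split(seq_len(nrow(runs)), diag_id), function(idx) {
    r <- runs[idx, , drop = FALSE]
    r <- r[order(r[, "i"]), , drop = FALSE]
    merged <- r[1L, , drop = FALSE]
    for (k in seq_len(nrow(r))[-1L]) {
      last <- nrow(merged)
      if (r[k, "i"] <= merged[last, "i"] + merged[last, "l"] - 1L) {
        new_end <- max(merged[last, "i"] + merged[last, "l"],
                       r[k, "i"] + r[k, "l"])
        merged[last, "l"] <- new_end - merged[last, "i"]
      } else {
        merged <- rbind(merged, r[k, , drop = FALSE])
      }
    }
    merged
  })
  do.call(rbind, out)
}
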