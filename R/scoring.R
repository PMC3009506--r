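#' Q-score of a structural alignment
#'
#' Combines alignment length and accuracy into one number in `[0, 1]`
#' (SSM convention):
#' `Q = Nmat^2 / ((1 + (rmsd/r0)^2) * N1 * N2)`.
#' It is 1 exactly for a full-length zero-RMSD superposition of two chains of
#' equal length, increases with the number of matched pairs and decreases
#' with RMSD.
#'
#' @param n_mat Number of matched C-alpha pairs (`0 <= n_mat <= min(n1, n2)`).
#' @param rmsd RMSD over the matched pairs (Angstrom, >= 0); ignored when
#'   `n_mat` is 0.
#' @param n1,n2 Chain lengths (>= 1).
#' @param r0 Distance scale in Angstrom (default 3.0).
#' @return Q-score in `[0, 1]`.
#' @examples
#' q_score(50, 3, 100, 100)  # 0.125
#' @export
q_score <- function(n_mat, rmsd, n1, n2, r0 = 3.0) {
  stopifnot(n1 >= 1, n2 >= 1, n_mat >= 0, n_mat <= min(n1, n2), r0 > 0)
  if (n_mat == 0) return(0)
  stopifnot(rmsd >= 0)
  n_mat^2 / ((1 + (rmsd / r0)^2) * n1 * n2)
}

#' SAS_k match measure
#'
#' Subbiah-style geometric match measure, generalized with an exponent `k`
#' on the length term: `SAS_k = rmsd * (100 / n_mat)^k`, so `SAS_1` is the
#' classical `100 * rmsd / n_mat`.  Lower is better; a smaller `k` favors
#' longer alignments, a larger `k` favors smaller RMSD.
#'
#' @param n_mat Number of matched pairs (>= 1).
#' @param rmsd RMSD over the matched pairs (Angstrom, >= 0).
#' @param k Exponent, one of 1, 2, 3.
#' @return SAS_k (unitless, >= 0).
#' @examples
#' sas_k(100, 2.0, k = 1)  # 2.0
#' @export
sas_k <- function(n_mat, rmsd, k = 1L) {
  if (n_mat == 0) {
    abort("SAS_k is undefined for an empty alignment",
          class = "castalign_error_empty_alignment")
  }
  stopifnot(n_mat >= 1, rmsd >= 0, k %in% 1:3)
  rmsd * (100 / n_mat)^k
}

#' Score report for an alignment
#'
#' @inheritParams q_score
#' @return A list with `n_mat`, `rmsd`, `n1`, `n2`, `q_score` and `sas`
#'   (named list for k = 1, 2, 3; `NA` when `n_mat` is 0).
#' @export
score_report <- function(n_mat, rmsd, n1, n2, r0 = 3.0) {
  q <- if (n_mat == 0) 0 else q_score(n_mat, rmsd, n1, n2, r0)
  sas <- if (n_mat == 0) {
    list(`1` = NA_real_, `2` = NA_real_, `3` = NA_real_)
  } else {
    list(`1` = sas_k(n_mat, rmsd, 1L), `2` = sas_k(n_mat, rmsd, 2L),
         `3` = sas_k(n_mat, rmsd, 3L))
  }
  list(n_mat = n_mat, rmsd = rmsd, n1 = n1, n2 = n2, q_score = q, sas = sas)
}
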