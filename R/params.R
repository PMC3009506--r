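#' Alignment parameter set
#'
#' Bundles every tunable of the three-stage aligner and the search engine,
#' with the package defaults.  All distances are in Angstrom.
#'
#' @param delta Candidate-pair distance cutoff used while refining a
#'   superposition: after transforming structure 2, every residue pair closer
#'   than `delta` joins the conflict-tolerant candidate set. Default 4.0.
#' @param epsilon Maximum discrepancy allowed between corresponding entries of
#'   the two intra-molecular distance matrices when growing a stage-1 seed.
#'   Default 1.5.
#' @param d1 Band width of the distance-matrix comparison: position `a` of a
#'   seed is checked against the `d1` positions preceding it.  Default 8.
#' @param l_min_seed Minimum length (residues) of a stage-1 seed.  Default 8.
#' @param helix_min_keep Helical runs shorter than this are masked before
#'   seeding; longer helices are kept.  Default 8.
#' @param min_run Minimum length of a gapless run eligible for the stage-3
#'   finishers; shorter runs are treated as isolated pairs and discarded.
#'   Default 4.
#' @param r_skip Redundancy cutoff: a seed whose RMSD under some previously
#'   fitted transform is at most `r_skip` is skipped.  Default 2.0.
#' @param max_iter Cap on stage-2 refinement iterations (the loop otherwise
#'   stops as soon as the candidate set stops growing).  Default 30.
#' @param r0 Distance scale of the Q-score denominator.  Default 3.0.
#' @param q_threshold Q-score at or above which two chains are grouped
#'   together when building a search index.  Default 0.5.
#' @param expand_groups Number of best groups whose full membership is aligned
#'   in the second query phase.  Default 10.
#'
#' @return A named list of class `castalign_params`.
#' @examples
#' p <- align_params(delta = 5)
#' p$delta
#' @export
align_params <- function(delta = 4.0, epsilon = 1.5, d1 = 8L,
                         l_min_seed = 8L, helix_min_keep = 8L,
                         min_run = 4L, r_skip = 2.0, max_iter = 30L,
                         r0 = 3.0, q_threshold = 0.5, expand_groups = 10L) {
  p <- list(
    delta = as.numeric(delta), epsilon = as.numeric(epsilon),
    d1 = as.integer(d1), l_min_seed = as.integer(l_min_seed),
    helix_min_keep = as.integer(helix_min_keep), min_run = as.integer(min_run),
    r_skip = as.numeric(r_skip), max_iter = as.integer(max_iter),
    r0 = as.numeric(r0), q_threshold = as.numeric(q_threshold),
    expand_groups = as.integer(expand_groups)
  )
  stopifnot(
    p$delta > 0, p$epsilon > 0, p$d1 >= 2L, p$l_min_seed >= 4L,
    p$helix_min_keep >= 1L, p$min_run >= 1L, p$r_skip >= 0,
    p$max_iter >= 1L, p$r0 > 0, p$q_threshold > 0, p$q_threshold < 1,
    p$expand_groups >= 0L
  )
  structure(p, class = "castalign_params")
}

#' @export
print.castalign_params <- function(x, ...) {
  cat("<castalign_params>\n")
  for (nm in names(x)) cat(sprintf("  %-15s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
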