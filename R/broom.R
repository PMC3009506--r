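#' Tidiers and plots for alignment results
#'
#' `tidy()` returns one row per aligned residue pair; `glance()` returns a
#' one-row summary with lengths, `n_mat`, RMSD, Q-score and SAS_1..3;
#' `autoplot()` draws the alignment map (aligned `u` against `v`, colored by
#' residual pair distance).
#'
#' @param x A `ca_alignment` from [pairwise_align()].
#' @param ... Unused.
#' @return A tibble (`tidy`, `glance`) or a ggplot (`autoplot`).
#' @name ca_alignment-methods
NULL

#' @rdname ca_alignment-methods
#' @method tidy ca_alignment
#' @export
tidy.ca_alignment <- function(x, ...) x$pairs

#' @rdname ca_alignment-methods
#' @method glance ca_alignment
#' @export
glance.ca_alignment <- function(x, ...) {
  tibble::tibble(
    id1 = x$id1, id2 = x$id2, mode = x$mode,
    n1 = x$n1, n2 = x$n2, n_mat = x$n_mat, rmsd = x$rmsd,
    q_score = x$scores$q_score,
    sas1 = x$scores$sas[["1"]], sas2 = x$scores$sas[["2"]],
    sas3 = x$scores$sas[["3"]]
  )
}

#' @rdname ca_alignment-methods
#' @param object A `ca_alignment`.
#' @method autoplot ca_alignment
#' @export
autoplot.ca_alignment <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$u, y = .data$v,
                               colour = .data$distance)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c(name = "pair distance (Å)") +
    ggplot2::labs(
      x = object$id1, y = object$id2,
      title = sprintf("%s alignment: n_mat = %d, rmsd = %.2f Å, Q = %.3f",
                      object$mode, object$n_mat,
                      ifelse(is.na(object$rmsd), 0, object$rmsd),
                      object$scores$q_score)
    ) +
    ggplot2::theme_minimal()
}

#' Superposition plot
#'
#' Projects the fixed chain and the transformed second chain onto the x-y
#' plane and draws both traces.
#'
#' @param result A `ca_alignment`.
#' @param s1,s2 The two [ca_chain()]s that were aligned.
#' @return A ggplot.
#' @export
plot_superposition <- function(result, s1, s2) {
  s2t <- apply_transform(result$transform, ca_coords(s2))
  df <- dplyr::bind_rows(
    tibble::tibble(x = s1$x, y = s1$y, chain = result$id1,
                   idx = seq_len(nrow(s1))),
    tibble::tibble(x = s2t[, 1L], y = s2t[, 2L], chain = result$id2,
                   idx = seq_len(nrow(s2)))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$chain)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Å)", y = "y (Å)",
                  title = "superposed C-alpha traces (x-y projection)") +
    ggplot2::theme_minimal()
}
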