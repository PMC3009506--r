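#' Synthetic C-alpha backbones
#'
#' Generators used to exercise every stage of the aligner without external
#' structure downloads: ideal alpha-helices, self-avoiding random coils,
#' noisy rigid copies with known ground-truth transform, and chimeras of
#' independently oriented parts.  All generators are pure functions of their
#' arguments (seed included).
#'
#' @name synthetic_structures
NULL

#' @describeIn synthetic_structures Ideal alpha-helix: radius 2.3 Angstrom,
#'   rise 1.5 Angstrom per residue, 100 degrees per residue, giving the
#'   textbook ~3.8 Angstrom C-alpha step and the d(i, i+3) ~ 5 Angstrom
#'   helical signature.
#' @param n Number of residues (at least 4).
#' @param source_id Identifier stored on the chain.
#' @export
make_helix <- function(n, source_id = "helix_A") {
  n <- as.integer(n)
  if (n < 4L) abort("a helix needs at least 4 residues",
                    class = "castalign_error_bad_spec")
  phi <- (seq_len(n) - 1L) * 100 * pi / 180
  ca_chain(cbind(2.3 * cos(phi), 2.3 * sin(phi), 1.5 * (seq_len(n) - 1L)),
           source_id = source_id)
}

#' @describeIn synthetic_structures Self-avoiding random coil: fixed
#'   3.8 Angstrom steps, every non-consecutive pair at least `min_sep`
#'   apart.  Deterministic for a given seed; errors if construction fails
#'   after bounded retries.
#' @param seed Integer seed.
#' @param min_sep Minimum non-consecutive inter-atom distance (default 4.0).
#' @export
make_coil <- function(n, seed, min_sep = 4.0, source_id = NULL) {
  n <- as.integer(n)
  if (n < 4L) abort("a coil needs at least 4 residues",
                    class = "castalign_error_bad_spec")
  source_id <- source_id %||% paste0("coil", seed, "_A")
  withr::with_seed(as.integer(seed), {
    for (attempt in seq_len(60L)) {
      xyz <- matrix(NA_real_, n, 3L)
      xyz[1L, ] <- 0
      ok <- TRUE
      for (k in 2L:n) {
        placed <- FALSE
        for (try in seq_len(200L)) {
          dir <- rnorm(3)
          cand <- xyz[k - 1L, ] + 3.8 * dir / sqrt(sum(dir^2))
          if (k > 2L) {
            d2 <- colSums((t(xyz[seq_len(k - 2L), , drop = FALSE]) - cand)^2)
            if (min(d2) < min_sep^2) next
          }
          xyz[k, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) return(ca_chain(xyz, source_id = source_id))
    }
    abort("self-avoiding coil construction failed; relax min_sep or n",
          class = "castalign_error_coil_failed")
  })
}

#' @describeIn synthetic_structures Rigid copy with noise: applies
#'   `transform` to the chain and adds isotropic Gaussian noise of standard
#'   deviation `noise_sigma` per coordinate axis.  Residue labels are
#'   preserved, so the true correspondence is row-by-row.
#' @param chain A [ca_chain()].
#' @param noise_sigma Per-axis noise standard deviation (Angstrom, >= 0).
#' @param transform Ground-truth [rigid_transform()] (default identity).
#' @export
perturb_copy <- function(chain, noise_sigma = 0, transform = identity_transform(),
                         seed = 1L, source_id = NULL) {
  stopifnot(noise_sigma >= 0)
  source_id <- source_id %||% paste0(sub("_[^_]*$", "", source_id(chain)),
                                     "cp", seed, "_A")
  xyz <- apply_transform(transform, ca_coords(chain))
  if (noise_sigma > 0) {
    xyz <- xyz + withr::with_seed(as.integer(seed),
                                  matrix(rnorm(length(xyz), 0, noise_sigma),
                                         nrow(xyz), 3L))
  }
  ca_chain(xyz, source_id = source_id, resno = chain$resno,
           icode = chain$icode)
}

#' @describeIn synthetic_structures Chimera: concatenates the given parts,
#'   each independently re-oriented by a random rotation, joined by
#'   3.8 Angstrom virtual bonds.  Part boundaries are recorded in the
#'   `"boundaries"` attribute (start index of each part) for test assertions.
#' @param parts List of at least two `ca_chain`s.
#' @export
make_chimera <- function(parts, seed, source_id = NULL) {
  if (length(parts) < 2L) abort("a chimera needs at least 2 parts",
                                class = "castalign_error_bad_spec")
  source_id <- source_id %||% paste0("chimera", seed, "_A")
  withr::with_seed(as.integer(seed), {
    placed <- list()
    for (k in seq_along(parts)) {
      xyz <- ca_coords(parts[[k]])
      xyz <- xyz %*% t(random_rotation())
      xyz <- sweep(xyz, 2L, xyz[1L, ])            # part starts at origin
      if (k > 1L) {
        prev_end <- placed[[k - 1L]][nrow(placed[[k - 1L]]), ]
        dir <- rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        xyz <- sweep(xyz, 2L, -(prev_end + 3.8 * dir))
      }
      placed[[k]] <- xyz
    }
    out <- ca_chain(do.call(rbind, placed), source_id = source_id)
    attr(out, "boundaries") <- cumsum(c(1L, vapply(placed[-length(placed)],
                                                   nrow, 1L)))
    out
  })
}

#' @describeIn synthetic_structures Index range of part `k` of a chimera.
#' @param chimera A chain produced by `make_chimera()`.
#' @param k Part number.
#' @export
chimera_part <- function(chimera, k) {
  b <- attr(chimera, "boundaries")
  if (is.null(b)) abort("not a chimera", class = "castalign_error_bad_spec")
  start <- b[k]
  end <- if (k < length(b)) b[k + 1L] - 1L else nrow(chimera)
  seq.int(start, end)
}
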