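#' C-alpha chains
#'
#' A `ca_chain` is one protein chain reduced to its ordered C-alpha trace: a
#' tibble with one row per residue and columns `resno` (PDB residue number),
#' `icode` (insertion code, `""` if none) and `x`, `y`, `z` (Angstrom), plus a
#' `source_id` attribute (`"<file stem>_<chain>"`).  Row order is file order.
#'
#' @param coords n x 3 numeric matrix of C-alpha positions (Angstrom).
#' @param source_id Identifier, conventionally `"<stem>_<chain>"`.
#' @param resno Integer residue numbers (default `1:n`).
#' @param icode Character insertion codes (default all `""`).
#' @return A tibble of subclass `ca_chain`.
#' @examples
#' ch <- ca_chain(matrix(rnorm(30), 10, 3), "toy_A")
#' n_res(ch)
#' @export
ca_chain <- function(coords, source_id = "chain_A",
                     resno = seq_len(nrow(coords)),
                     icode = rep("", nrow(coords))) {
  coords <- unname(as.matrix(coords))
  if (ncol(coords) != 3L || nrow(coords) < 1L) {
    abort("coords must be a non-empty n x 3 matrix",
          class = "castalign_error_bad_chain")
  }
  if (!all(is.finite(coords))) {
    abort("coords must be finite", class = "castalign_error_bad_chain")
  }
  if (length(resno) != nrow(coords) || length(icode) != nrow(coords)) {
    abort("resno/icode lengths must match coords",
          class = "castalign_error_bad_chain")
  }
  if (nrow(coords) > 1L) {
    step <- sqrt(rowSums((coords[-1L, , drop = FALSE] -
                            coords[-nrow(coords), , drop = FALSE])^2))
    if (any(step <= 0)) {
      abort("duplicated consecutive C-alpha positions",
            class = "castalign_error_bad_chain")
    }
  }
  out <- tibble::tibble(
    resno = as.integer(resno), icode = as.character(icode),
    x = coords[, 1L], y = coords[, 2L], z = coords[, 3L]
  )
  attr(out, "source_id") <- as.character(source_id)
  class(out) <- c("ca_chain", class(tibble::tibble()))
  out
}

#' @rdname ca_chain
#' @param chain A `ca_chain`.
#' @export
ca_coords <- function(chain) {
  unname(cbind(chain$x, chain$y, chain$z))
}

#' @rdname ca_chain
#' @export
n_res <- function(chain) nrow(chain)

#' @rdname ca_chain
#' @export
source_id <- function(chain) attr(chain, "source_id") %||% "chain"

#' Chain-break mask
#'
#' Flags physical breaks in the trace: element `k` is `TRUE` when the
#' distance between C-alpha `k` and `k + 1` exceeds `cutoff` (a real peptide
#' step is ~3.8 Angstrom).  Stage-1 seeds never span a break.
#'
#' @param chain A `ca_chain`.
#' @param cutoff Break distance cutoff in Angstrom (default 4.5).
#' @return Logical vector of length `n_res(chain) - 1` (length 0 for a
#'   single-residue chain).
#' @export
chain_breaks <- function(chain, cutoff = 4.5) {
  xyz <- ca_coords(chain)
  n <- nrow(xyz)
  if (n < 2L) return(logical(0))
  step <- sqrt(rowSums((xyz[-1L, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  step > cutoff
}

#' Read one chain's C-alpha trace from a PDB file
#'
#' Parses `path` (PDB format, via bio3d) and returns the requested chain as a
#' [ca_chain()].  Only `ATOM` records of the first model are considered;
#' residues lacking a C-alpha are skipped; for alternate locations the
#' highest-occupancy altloc is kept (ties: first listed).
#'
#' @param path PDB file.
#' @param chain_id Chain identifier; default is the first chain in the file
#'   that contains C-alpha atoms.
#' @return A `ca_chain` with `source_id = "<file stem>_<chain>"`.
#' @export
read_ca_chain <- function(path, chain_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path),
          class = "castalign_error_missing_file")
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  ca <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  chains_present <- unique(ca$chain)
  if (is.null(chain_id)) {
    if (nrow(ca) == 0L) {
      abort(paste0("no C-alpha atoms in ", path),
            class = "castalign_error_empty_chain")
    }
    chain_id <- chains_present[1L]
  } else if (!chain_id %in% unique(at$chain)) {
    abort(paste0("chain '", chain_id, "' not found in ", path),
          class = "castalign_error_chain_not_found")
  }
  ca <- ca[ca$chain %in% chain_id, , drop = FALSE]
  if (nrow(ca) == 0L) {
    abort(paste0("chain '", chain_id, "' has no C-alpha atoms in ", path),
          class = "castalign_error_empty_chain")
  }
  ca$insert[is.na(ca$insert)] <- ""
  ca$alt[is.na(ca$alt)] <- ""
  ca$o[is.na(ca$o)] <- 1
  # one CA per residue: highest occupancy altloc, ties broken by file order
  key <- paste(ca$resno, ca$insert)
  keep <- unlist(lapply(split(seq_len(nrow(ca)), factor(key, unique(key))),
                        function(idx) idx[which.max(ca$o[idx])]),
                 use.names = FALSE)
  ca <- ca[sort(keep), , drop = FALSE]
  stem <- sub("\\.[^.]*$", "", basename(path))
  ca_chain(cbind(ca$x, ca$y, ca$z),
           source_id = paste0(stem, "_", chain_id),
           resno = ca$resno, icode = ca$insert)
}

#' Write a transformed C-alpha trace as a minimal PDB file
#'
#' Applies `transform` to the chain's coordinates and writes a C-alpha-only
#' PDB file (fixed-width `ATOM` records, coordinates to 3 decimals).
#'
#' @param chain A `ca_chain`.
#' @param transform A [rigid_transform()] (default identity).
#' @param out Output path.
#' @return `out`, invisibly.
#' @export
write_transformed_pdb <- function(chain, transform = identity_transform(),
                                  out) {
  xyz <- apply_transform(transform, ca_coords(chain))
  chain_letter <- sub(".*_", "", source_id(chain))
  if (nchar(chain_letter) != 1L) chain_letter <- "A"
  n <- nrow(xyz)
  bio3d::write.pdb(
    file = out,
    xyz = as.numeric(t(xyz)),
    resno = chain$resno,
    resid = rep("ALA", n),
    elety = rep("CA", n),
    chain = rep(chain_letter, n),
    insert = ifelse(chain$icode == "", NA, chain$icode)
  )
  invisible(out)
}

res_label <- function(chain, idx) {
  paste0(chain$resno[idx], ifelse(chain$icode[idx] == "", "",
                                  chain$icode[idx]))
}

#' @export
print.ca_chain <- function(x, ...) {
  cat(sprintf("<ca_chain> %s: %d residues\n", source_id(x), nrow(x)))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
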