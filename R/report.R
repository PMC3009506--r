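#' Write and re-read alignment reports
#'
#' The report is a stable, line-oriented text format: header fields
#' (chain ids, mode, `n_mat`, RMSD to 3 decimals, Q-score, SAS_1..3), the
#' rotation matrix (row-major) and translation to 6 decimals, then one line
#' per aligned pair, `"<resno1> <-> <resno2> <distance>"` using original PDB
#' residue numbers (insertion codes appended).  `parse_alignment_report()`
#' reproduces `n_mat` and the pair list exactly.
#'
#' @param result A `ca_alignment` from [pairwise_align()].
#' @param out Output path.
#' @return `out` invisibly (`write`); a list with `id1`, `id2`, `mode`,
#'   `n_mat`, `rmsd` and a `pairs` tibble (`parse`).
#' @export
write_alignment_report <- function(result, out) {
  rot <- t(result$transform$rotation)      # t() so the write is row-major
  lines <- c(
    "# castalign alignment report",
    paste0("structure1: ", result$id1),
    paste0("structure2: ", result$id2),
    paste0("mode: ", result$mode),
    paste0("n_mat: ", result$n_mat),
    paste0("rmsd: ", ifelse(is.na(result$rmsd), "NA",
                            sprintf("%.3f", result$rmsd))),
    paste0("q_score: ", sprintf("%.6f", result$scores$q_score)),
    paste0("sas_1: ", format_score(result$scores$sas[["1"]])),
    paste0("sas_2: ", format_score(result$scores$sas[["2"]])),
    paste0("sas_3: ", format_score(result$scores$sas[["3"]])),
    paste0("rotation: ", paste(sprintf("%.6f", rot), collapse = " ")),
    paste0("translation: ",
           paste(sprintf("%.6f", result$transform$translation),
                 collapse = " ")),
    "pairs:"
  )
  if (result$n_mat > 0L) {
    lines <- c(lines, sprintf("%s <-> %s %.3f", result$pairs$resno1,
                              result$pairs$resno2, result$pairs$distance))
  }
  con <- file(out, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(out)
}

format_score <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))

#' @rdname write_alignment_report
#' @param path Report file written by `write_alignment_report()`.
#' @export
parse_alignment_report <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("report not found: ", path),
          class = "castalign_error_missing_file")
  }
  lines <- readLines(path)
  field <- function(key) {
    ln <- grep(paste0("^", key, ": "), lines, value = TRUE)[1L]
    sub(paste0("^", key, ": "), "", ln)
  }
  pair_start <- which(lines == "pairs:")[1L]
  pair_lines <- if (pair_start < length(lines)) {
    lines[(pair_start + 1L):length(lines)]
  } else character(0)
  pair_lines <- pair_lines[nzchar(pair_lines)]
  toks <- strsplit(pair_lines, " <-> | ")
  pairs <- tibble::tibble(
    resno1 = vapply(toks, `[`, "", 1L),
    resno2 = vapply(toks, `[`, "", 2L),
    distance = as.numeric(vapply(toks, `[`, "", 3L))
  )
  list(id1 = field("structure1"), id2 = field("structure2"),
       mode = field("mode"), n_mat = as.integer(field("n_mat")),
       rmsd = suppressWarnings(as.numeric(field("rmsd"))), pairs = pairs)
}
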