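#' Offline classification of a structure library
#'
#' Partitions a library of chains into groups in which every two members
#' have a pairwise alignment Q-score of at least `q_threshold` (default 0.5),
#' by a deterministic greedy complete-linkage pass in input order: each chain
#' joins the first existing group against whose *every* member it scores at
#' least the threshold, otherwise it opens a new group.  Each group's
#' representative is the member with the highest sum of intra-group Q-scores.
#' Searching then needs one alignment per group rather than per chain.
#'
#' @param library List of [ca_chain()]s with unique `source_id`s.
#' @param q_threshold Grouping threshold in (0, 1); default 0.5.
#' @param mode Alignment mode used throughout the index (default
#'   `"sequential"`, the faster finisher).
#' @param params An [align_params()] bundle.
#' @return An object of class `ca_group_index`: `groups` (each with
#'   `members` and `representative` ids), `q_threshold`, `mode`, `params`,
#'   and the library ids in input order.
#' @examples
#' lib <- lapply(1:3, function(s) make_coil(30, seed = s))
#' idx <- build_index(lib)
#' length(idx$groups)
#' @export
build_index <- function(library, q_threshold = 0.5,
                        mode = c("sequential", "nonsequential"),
                        params = align_params()) {
  mode <- match.arg(mode)
  stopifnot(length(library) >= 1L, q_threshold > 0, q_threshold < 1)
  ids <- vapply(library, source_id, "")
  if (anyDuplicated(ids)) {
    abort("duplicate source_ids in library",
          class = "castalign_error_duplicate_ids")
  }
  qfun <- make_q_cache(library, mode, params)
  groups <- list()          # list of integer index vectors
  for (k in seq_along(library)) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      ok <- TRUE
      for (m in groups[[g]]) {
        if (qfun(m, k) < q_threshold) { ok <- FALSE; break }
      }
      if (ok) {
        groups[[g]] <- c(groups[[g]], k)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups <- c(groups, list(k))
  }
  out_groups <- lapply(groups, function(g) {
    rep_idx <- select_representative_idx(g, qfun)
    list(members = ids[g], representative = ids[rep_idx])
  })
  structure(list(groups = out_groups, q_threshold = q_threshold,
                 mode = mode, params = unclass(params), ids = ids,
                 version = "1"),
            class = "ca_group_index")
}

# Memoized pairwise Q-score; alignments are computed in canonical (i < j)
# order so that the cache is symmetric.
make_q_cache <- function(library, mode, params) {
  cache <- new.env(parent = emptyenv())
  function(i, j) {
    if (i == j) return(1)
    a <- min(i, j); b <- max(i, j)
    key <- paste0(a, "_", b)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- suppressWarnings(pairwise_align(library[[a]], library[[b]],
                                           mode = mode, params = params))
    cache[[key]] <- res$scores$q_score
    cache[[key]]
  }
}

select_representative_idx <- function(group_idx, qfun) {
  if (length(group_idx) == 1L) return(group_idx)
  sums <- vapply(group_idx, function(i) {
    sum(vapply(setdiff(group_idx, i), function(j) qfun(i, j), 1))
  }, 1)
  group_idx[which.max(sums)]   # which.max breaks ties by input order
}

#' Representative of a group of chains
#'
#' Aligns every member against all others and returns the `source_id` of the
#' member with the highest sum of pairwise Q-scores (ties: input order).
#'
#' @param group_members List of [ca_chain()]s (non-empty).
#' @inheritParams build_index
#' @return The representative's `source_id`.
#' @export
select_representative <- function(group_members,
                                  mode = c("sequential", "nonsequential"),
                                  params = align_params()) {
  mode <- match.arg(mode)
  stopifnot(length(group_members) >= 1L)
  qfun <- make_q_cache(group_members, mode, params)
  idx <- select_representative_idx(seq_along(group_members), qfun)
  source_id(group_members[[idx]])
}

#' Query a structure library through its group index
#'
#' Two-phase ranked similarity search.  Phase 1 aligns the query against
#' every group representative (the work is split over `n_workers` contiguous
#' partitions via [partition_work()]; results are merged in representative
#' order, so the hit list is identical for any worker count).  Phase 2 fully
#' aligns the query against all members of the `expand_groups` best groups by
#' representative Q-score.  Hits are ranked by Q-score (ties: `n_mat`
#' descending, then id).
#'
#' @param query_chain A [ca_chain()].
#' @param index A `ca_group_index` built over `library`.
#' @param library The same list of chains the index was built on.
#' @param top_k Maximum number of hits returned (default 10).
#' @param expand_groups Number of groups expanded in phase 2 (default from
#'   the index parameters; 0 disables phase 2).
#' @param n_workers Number of work partitions for phase 1 (default 1).
#' @return Tibble of hits: `rank`, `target_id`, `group`, `n_mat`, `rmsd`,
#'   `q_score`, `sas1`.
#' @export
query_index <- function(query_chain, index, library, top_k = 10L,
                        expand_groups = NULL, n_workers = 1L) {
  if (!inherits(index, "ca_group_index") || length(index$groups) == 0L) {
    abort("empty or invalid index", class = "castalign_error_bad_index")
  }
  ids <- vapply(library, source_id, "")
  if (!all(index$ids %in% ids)) {
    abort("index and library do not match",
          class = "castalign_error_index_mismatch")
  }
  params <- do.call(align_params, index$params)
  expand_groups <- as.integer(expand_groups %||% params$expand_groups)
  align_one <- function(id) {
    res <- suppressWarnings(pairwise_align(query_chain,
                                           library[[match(id, ids)]],
                                           mode = index$mode, params = params))
    glance(res)
  }
  reps <- vapply(index$groups, `[[`, "", "representative")
  work <- partition_work(length(reps), n_workers)
  rep_hits <- dplyr::bind_rows(lapply(seq_len(nrow(work)), function(w) {
    if (work$size[w] == 0L) return(NULL)
    dplyr::bind_rows(lapply(reps[work$start[w]:work$end[w]], align_one))
  }))
  rep_hits$group <- seq_along(reps)
  hits <- rep_hits
  if (expand_groups > 0L) {
    best_groups <- order(-rep_hits$q_score, seq_along(reps))
    best_groups <- head(best_groups, expand_groups)
    extra_ids <- unlist(lapply(best_groups, function(g) {
      setdiff(index$groups[[g]]$members, reps[g])
    }))
    if (length(extra_ids) > 0L) {
      extra <- dplyr::bind_rows(lapply(extra_ids, align_one))
      extra$group <- rep(best_groups, vapply(best_groups, function(g) {
        length(setdiff(index$groups[[g]]$members, reps[g]))
      }, 1L))
      hits <- dplyr::bind_rows(hits, extra)
    }
  }
  hits <- hits[order(-hits$q_score, -hits$n_mat, hits$id2), , drop = FALSE]
  hits <- head(hits, top_k)
  tibble::tibble(rank = seq_len(nrow(hits)), target_id = hits$id2,
                 group = hits$group, n_mat = hits$n_mat, rmsd = hits$rmsd,
                 q_score = hits$q_score, sas1 = hits$sas1)
}

#' Deterministic work partitioning
#'
#' Splits `1..n_items` into `n_workers` contiguous, disjoint, exhaustive
#' ranges whose sizes differ by at most one (the partitioning contract that
#' lets representative alignments run on several machines and merge
#' order-independently).
#'
#' @param n_items Number of items (>= 0).
#' @param n_workers Number of workers (>= 1).
#' @return Tibble with `worker`, `start`, `end`, `size` (`size` 0 means an
#'   empty range, `end < start`).
#' @examples
#' partition_work(10, 3)$size  # 4 3 3
#' @export
partition_work <- function(n_items, n_workers) {
  stopifnot(n_workers >= 1L, n_items >= 0L)
  sizes <- rep(n_items %/% n_workers, n_workers) +
    (seq_len(n_workers) <= n_items %% n_workers)
  ends <- cumsum(sizes)
  tibble::tibble(worker = seq_len(n_workers),
                 start = ends - sizes + 1L, end = ends,
                 size = as.integer(sizes))
}

#' Persist and reload a group index as JSON
#'
#' @param index A `ca_group_index`.
#' @param path JSON file path.
#' @return `path` invisibly (`write`); a `ca_group_index` (`read`).
#' @export
write_index <- function(index, path) {
  jsonlite::write_json(unclass(index), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("index not found: ", path),
          class = "castalign_error_missing_file")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  raw$groups <- lapply(raw$groups, function(g) {
    list(members = as.character(g$members),
         representative = as.character(g$representative))
  })
  structure(raw, class = "ca_group_index")
}

#' @export
print.ca_group_index <- function(x, ...) {
  cat(sprintf("<ca_group_index> %d chains in %d groups (Q >= %.2f, %s)\n",
              length(x$ids), length(x$groups), x$q_threshold, x$mode))
  invisible(x)
}

#' @rdname ca_alignment-methods
#' @method tidy ca_group_index
#' @export
tidy.ca_group_index <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$groups), function(g) {
    tibble::tibble(group = g, member_id = x$groups[[g]]$members,
                   representative =
                     x$groups[[g]]$members == x$groups[[g]]$representative)
  }))
}

#' @rdname ca_alignment-methods
#' @method glance ca_group_index
#' @export
glance.ca_group_index <- function(x, ...) {
  tibble::tibble(n_chains = length(x$ids), n_groups = length(x$groups),
                 q_threshold = x$q_threshold, mode = x$mode)
}
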