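# The complete fragmenter: exhaustive recursive tree search over all
# non-overlapping group placements, organised as an exact-cover search (each
# node branches over the candidates covering the lowest-index unassigned
# atom, so every partition of the heavy atoms is generated exactly once).
# Residual atom sets proven uncoverable are memoized and pruned on
# re-encounter; solutions are ranked and the first is the chosen
# fragmentation.

residual_key <- function(residual) paste(which(residual), collapse = ",")

# Mark a residual atom set as uncoverable in the failure cache. Exposed for
# testing; fragment_complete() drives it.
record_failure <- function(memo, residual) {
  key <- residual_key(residual)
  if (nzchar(key)) assign(key, TRUE, envir = memo)
  memo
}

failure_known <- function(memo, residual) {
  !is.null(memo[[residual_key(residual)]])
}

#' Rank complete-search solutions
#'
#' Solutions are ordered by ascending total number of placed groups (larger
#' groups cover the molecule in fewer pieces, so this prioritizes them), then
#' by ascending number of distinct group ids, then lexicographically by the
#' scheme precedence of the groups used; the sort is stable.
#'
#' @param solutions list of solutions (each a list of candidates).
#' @param scheme the `fragmentation_scheme` searched (precedence source).
#' @param sorted use descriptor-sorted precedence (must match the search).
#' @return the reordered list.
#' @export
rank_solutions <- function(solutions, scheme = default_scheme(),
                           sorted = TRUE) {
  if (length(solutions) <= 1L) return(solutions)
  order_idx <- if (sorted) scheme$sorted_order else seq_along(scheme$groups)
  prec <- integer(length(scheme$groups))
  prec[order_idx] <- seq_along(order_idx)
  names(prec) <- as.character(scheme_group_ids(scheme))

  n_placed <- vapply(solutions, length, integer(1))
  n_distinct <- vapply(solutions, function(s) {
    length(unique(vapply(s, `[[`, integer(1), "group_id")))
  }, integer(1))
  prec_strings <- vapply(solutions, function(s) {
    p <- sort(prec[as.character(vapply(s, `[[`, integer(1), "group_id"))])
    paste(formatC(p, width = 4, flag = "0"), collapse = ".")
  }, character(1))
  solutions[order(n_placed, n_distinct, prec_strings)]
}

#' Fragment a molecule with the complete (exhaustive) algorithm
#'
#' Enumerates every partition of the heavy atoms into scheme-group matches by
#' recursive tree search, deduplicates identical partitions, ranks all
#' solutions ([rank_solutions()]) and reports the first as the chosen
#' fragmentation. The `sorted` flag only affects the order candidates are
#' explored (and therefore solution rank ties broken by precedence), never
#' the solution set. Search cost grows exponentially with molecule size, so
#' molecules above `max_heavy_atoms` are rejected with an error of class
#' `frag_size_error`; callers may fall back to [fragment_simple()].
#'
#' @inheritParams fragment_simple
#' @param max_heavy_atoms size cap (default 20).
#' @param use_failure_cache memoize uncoverable residual atom sets
#'   (default `TRUE`; disabling is for testing the cache's soundness).
#' @return a `fragmentation_result`; on success its `solutions` field holds
#'   the full ranked solution list (each solution a list of candidates).
#' @examples
#' res <- fragment_complete("Cc1ccccc1") # toluene: 2 solutions
#' length(res$solutions)
#' @export
fragment_complete <- function(molecule, scheme = default_scheme(),
                              sorted = TRUE, max_heavy_atoms = 20L,
                              use_failure_cache = TRUE) {
  if (is.character(molecule)) {
    mol <- normalize_structure(molecule)
    if (is_rejection(mol)) {
      return(new_fragmentation_result(molecule, "excluded_input",
                                      algorithm = "complete", scheme = scheme,
                                      reason = paste0(mol$status, ": ",
                                                      mol$reason)))
    }
  } else {
    mol <- as_molecule(molecule)
  }
  if (mol$n_atoms > max_heavy_atoms) {
    stop(structure(class = c("frag_size_error", "error", "condition"),
                   list(message = sprintf(
                     "molecule has %d heavy atoms (cap %d): complete search skipped",
                     mol$n_atoms, max_heavy_atoms),
                     call = sys.call(-1))))
  }

  order_idx <- if (sorted) {
    if (is.null(scheme$sorted_order)) stop("scheme is not sorted",
                                           call. = FALSE)
    scheme$sorted_order
  } else {
    seq_along(scheme$groups)
  }

  # flat candidate list in search order
  cands <- list()
  for (gi in order_idx) {
    for (cand in find_match_candidates(mol, scheme$groups[[gi]])) {
      cands[[length(cands) + 1L]] <- cand
    }
  }
  by_atom <- vector("list", mol$n_atoms)
  for (ci in seq_along(cands)) {
    for (a in cands[[ci]]$atoms) by_atom[[a]] <- c(by_atom[[a]], ci)
  }

  memo <- new.env(parent = emptyenv())
  solutions <- list()
  seen_solutions <- new.env(parent = emptyenv())

  search <- function(residual, chosen) {
    if (!any(residual)) {
      key <- paste(sort(vapply(chosen, function(ci) {
        candidate_key(cands[[ci]])
      }, character(1))), collapse = "|")
      if (is.null(seen_solutions[[key]])) {
        seen_solutions[[key]] <- TRUE
        solutions[[length(solutions) + 1L]] <<- lapply(chosen,
                                                       function(ci) cands[[ci]])
      }
      return(TRUE)
    }
    if (use_failure_cache && failure_known(memo, residual)) return(FALSE)
    a <- which(residual)[1L]
    any_cover <- FALSE
    for (ci in by_atom[[a]]) {
      atoms <- cands[[ci]]$atoms
      if (!all(residual[atoms])) next
      residual[atoms] <- FALSE
      if (search(residual, c(chosen, ci))) any_cover <- TRUE
      residual[atoms] <- TRUE
    }
    if (!any_cover && use_failure_cache) record_failure(memo, residual)
    any_cover
  }
  search(rep(TRUE, mol$n_atoms), integer(0))

  if (!length(solutions)) {
    return(new_fragmentation_result(mol$smiles, "no_solution",
                                    algorithm = "complete", scheme = scheme))
  }
  solutions <- rank_solutions(solutions, scheme, sorted = sorted)
  new_fragmentation_result(mol$smiles, "success", solutions[[1L]],
                           solutions = solutions, algorithm = "complete",
                           scheme = scheme)
}

#' Fragment a molecule (front-end over both algorithms)
#'
#' `algorithm = "combined"` reproduces the large-database protocol: the
#' simple fragmenter runs first and the complete search is the fallback for
#' structures it cannot fragment, provided they are within the size cap.
#'
#' @inheritParams fragment_complete
#' @param algorithm `"simple"`, `"complete"` or `"combined"`.
#' @return a `fragmentation_result`.
#' @export
fragment <- function(molecule, scheme = default_scheme(),
                     algorithm = c("simple", "complete", "combined"),
                     sorted = TRUE, max_heavy_atoms = 20L) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "simple") {
    return(fragment_simple(molecule, scheme, sorted = sorted))
  }
  if (algorithm == "complete") {
    return(fragment_complete(molecule, scheme, sorted = sorted,
                             max_heavy_atoms = max_heavy_atoms))
  }
  res <- fragment_simple(molecule, scheme, sorted = sorted)
  if (res$status != "no_solution") return(res)
  complete_res <- tryCatch(
    fragment_complete(molecule, scheme, sorted = sorted,
                      max_heavy_atoms = max_heavy_atoms),
    frag_size_error = function(e) NULL)
  if (is.null(complete_res)) res else complete_res
}
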