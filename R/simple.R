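# The simple (heuristic) fragmenter: one sequential pass over the
# descriptor-sorted scheme with parent-child prioritization, then
# clearing + adjacency-constrained retry passes.

new_fragmentation_result <- function(smiles, status, placed = list(),
                                     iterations_used = 0L, solutions = NULL,
                                     algorithm = "simple", scheme = NULL,
                                     reason = NULL) {
  counts <- counts_from_placed(placed)
  names_map <- if (!is.null(scheme)) scheme_group_names(scheme) else NULL
  structure(list(
    smiles = smiles, status = status, placed = placed,
    group_counts = counts,
    group_names = if (!is.null(names_map) && length(counts))
      unname(names_map[names(counts)]) else character(0),
    iterations_used = iterations_used, solutions = solutions,
    algorithm = algorithm, reason = reason
  ), class = "fragmentation_result")
}

#' @export
print.fragmentation_result <- function(x, ...) {
  cat("<fragmentation_result> ", x$smiles, " [", x$algorithm, "]: ",
      x$status, "\n", sep = "")
  if (x$status == "success") {
    lab <- if (length(x$group_names)) {
      sprintf("%s %s:%d", x$group_names, names(x$group_counts),
              as.integer(x$group_counts))
    } else {
      sprintf("%s:%d", names(x$group_counts), as.integer(x$group_counts))
    }
    cat("  groups: ", paste(lab, collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$solutions)) {
    cat("  solutions found: ", length(x$solutions), "\n", sep = "")
  }
  if (!is.null(x$reason)) cat("  reason: ", x$reason, "\n", sep = "")
  invisible(x)
}

#' Group counts of a fragmentation result, keyed by group name
#'
#' @param result a `fragmentation_result`.
#' @param scheme the scheme the result was computed with (defaults to the
#'   packaged UNIFAC scheme).
#' @return named integer vector, names are group names such as `"CH3"`.
#' @export
group_counts_by_name <- function(result, scheme = default_scheme()) {
  counts <- result$group_counts
  if (!length(counts)) return(stats::setNames(integer(0), character(0)))
  nm <- scheme_group_names(scheme)
  stats::setNames(as.integer(counts), unname(nm[names(counts)]))
}

#' Placeable candidates of a group under parent-child prioritization
#'
#' Computes the group's candidates that may be placed in the current state:
#' non-overlapping matches of the group's patterns, minus child matches lying
#' on atoms claimed by a live match of a parent pattern (a pattern of the
#' scheme that contains the child pattern and whose own match does not clash
#' with the placed groups). Searching the parent first protects larger
#' groups: a CH2 inside an intact amide CONHCH2 site is not consumed by the
#' plain CH2 group.
#'
#' @param molecule `frag_molecule`.
#' @param group a group entry of `scheme`.
#' @param scheme a prepared `fragmentation_scheme` (with parent-child map).
#' @param state current `assignment_state`.
#' @param cand_cache optional precomputed [candidate_table()]-style cache
#'   (list of per-group candidate lists in scheme order); used internally.
#' @return list of placeable candidates in deterministic order.
#' @export
parent_first_search <- function(molecule, group, scheme, state,
                                cand_cache = NULL) {
  mol <- as_molecule(molecule)
  if (is.null(scheme$parent_child)) {
    stop("scheme has no parent-child map; use load_scheme()", call. = FALSE)
  }
  assigned <- which(!is.na(state$assigned))
  group_cands <- if (!is.null(cand_cache)) {
    idx <- match(group$group_id, scheme_group_ids(scheme))
    cand_cache$by_group[[idx]]
  } else {
    find_match_candidates(mol, group)
  }
  out <- list()
  for (cand in group_cands) {
    if (any(cand$atoms %in% assigned)) next
    parents <- scheme$parent_child[[pattern_key(cand$group_id,
                                                cand$pattern_index)]]
    blocked <- FALSE
    for (par in parents) {
      par_sets <- if (!is.null(cand_cache)) {
        cand_cache$by_pattern[[pattern_key(par$group_id, par$pattern_index)]]
      } else {
        match_atom_sets(par$smarts, mol)
      }
      for (atoms in par_sets) {
        if (any(atoms %in% assigned)) next      # parent site already broken up
        if (all(cand$atoms %in% atoms)) {
          blocked <- TRUE; break
        }
      }
      if (blocked) break
    }
    if (!blocked) out[[length(out) + 1L]] <- cand
  }
  out
}

# Precompute per-group candidates and per-pattern atom sets for one molecule.
build_candidate_cache <- function(mol, scheme) {
  by_pattern <- list()
  by_group <- vector("list", length(scheme$groups))
  for (gi in seq_along(scheme$groups)) {
    g <- scheme$groups[[gi]]
    seen <- character(0)
    cands <- list()
    for (k in seq_along(g$compiled)) {
      sets <- match_atom_sets(g$compiled[[k]], mol)
      by_pattern[[pattern_key(g$group_id, k)]] <- sets
      for (atoms in sets) {
        key <- paste(atoms, collapse = ",")
        if (key %in% seen) next
        seen <- c(seen, key)
        cands[[length(cands) + 1L]] <- new_candidate(g$group_id, k, atoms)
      }
    }
    by_group[[gi]] <- cands
  }
  list(by_group = by_group, by_pattern = by_pattern)
}

simple_sequential_pass <- function(mol, scheme, state, order, cache,
                                   adjacency_required) {
  for (gi in order) {
    g <- scheme$groups[[gi]]
    cands <- parent_first_search(mol, g, scheme, state, cand_cache = cache)
    for (cand in cands) {
      if (state_overlaps(state, cand)) next  # earlier placement in this pass
      if (adjacency_required && !is_adjacent(cand, state, mol)) next
      state <- state_place(state, cand)
      if (state_complete(state)) return(state)
    }
  }
  state
}

#' Fragment a molecule with the simple (heuristic) algorithm
#'
#' Pass 1 walks the scheme in priority order (descending descriptor sort, or
#' file order with `sorted = FALSE`), placing every non-overlapping match of
#' each group after parent-child screening. If atoms remain unassigned, retry
#' passes clear an increasingly large neighbourhood around the stuck atoms
#' and re-run the sequential search with new matches required to be adjacent
#' to the groups already placed. The retry radius is capped at the molecule's
#' graph diameter, at which point the clearing empties the state and the
#' search has had one unconstrained restart.
#'
#' @param molecule SMILES string or `frag_molecule`; strings are normalized
#'   first and may yield an `excluded_input` result.
#' @param scheme a prepared `fragmentation_scheme` (default: packaged UNIFAC).
#' @param sorted use the descriptor sort order (`TRUE`, default) or the
#'   scheme file order.
#' @return a `fragmentation_result` with status `success`, `no_solution` or
#'   `excluded_input`, the group-count multiset and the number of clearing
#'   iterations used.
#' @examples
#' res <- fragment_simple("CCCC")
#' group_counts_by_name(res)
#' @export
fragment_simple <- function(molecule, scheme = default_scheme(),
                            sorted = TRUE) {
  if (is.character(molecule)) {
    mol <- normalize_structure(molecule)
    if (is_rejection(mol)) {
      return(new_fragmentation_result(molecule, "excluded_input",
                                      algorithm = "simple", scheme = scheme,
                                      reason = paste0(mol$status, ": ",
                                                      mol$reason)))
    }
  } else {
    mol <- as_molecule(molecule)
  }
  order <- if (sorted) {
    if (is.null(scheme$sorted_order)) stop("scheme is not sorted",
                                           call. = FALSE)
    scheme$sorted_order
  } else {
    seq_along(scheme$groups)
  }
  cache <- build_candidate_cache(mol, scheme)
  state <- new_assignment_state(mol)
  state <- simple_sequential_pass(mol, scheme, state, order, cache,
                                  adjacency_required = FALSE)
  iterations <- 0L
  cap <- molecule_diameter(mol)
  while (!state_complete(state) && iterations < cap) {
    iterations <- iterations + 1L
    state <- clear_neighborhood(state, mol, iterations)
    state <- simple_sequential_pass(mol, scheme, state, order, cache,
                                    adjacency_required = TRUE)
  }
  if (state_complete(state)) {
    new_fragmentation_result(mol$smiles, "success", state$placed,
                             iterations_used = iterations,
                             algorithm = "simple", scheme = scheme)
  } else {
    new_fragmentation_result(mol$smiles, "no_solution",
                             iterations_used = iterations,
                             algorithm = "simple", scheme = scheme)
  }
}
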