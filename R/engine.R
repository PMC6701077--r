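# Shared matching machinery for both fragmenters: match candidates, the
# mutable (copy-on-modify) assignment state, adjacency tests and neighbourhood
# clearing.

new_candidate <- function(group_id, pattern_index, atoms) {
  list(group_id = group_id, pattern_index = pattern_index,
       atoms = sort(as.integer(atoms)))
}

candidate_key <- function(cand) {
  paste0(cand$group_id, "@", paste(cand$atoms, collapse = "."))
}

#' Find the match candidates of one group on a molecule
#'
#' All symmetry-distinct atom sets matched by any pattern of the group,
#' deduplicated by atom set and ordered by pattern index, then by
#' lexicographically smallest atom tuple. Output order is deterministic for
#' identical input.
#'
#' @param molecule `frag_molecule` or SMILES string.
#' @param group a group entry of a `fragmentation_scheme` (see
#'   [load_scheme()]), or a list with fields `group_id` and `patterns`.
#' @return list of candidates, each with fields `group_id`, `pattern_index`,
#'   `atoms` (sorted integer vector).
#' @examples
#' sch <- default_scheme()
#' find_match_candidates("CCCC", sch$groups[[1]]) # the two CH3 of n-butane
#' @export
find_match_candidates <- function(molecule, group) {
  mol <- as_molecule(molecule)
  compiled <- group$compiled
  if (is.null(compiled)) compiled <- lapply(group$patterns, parse_smarts)
  out <- list()
  seen <- character(0)
  for (k in seq_along(compiled)) {
    for (atoms in match_atom_sets(compiled[[k]], mol)) {
      key <- paste(atoms, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- new_candidate(group$group_id, k, atoms)
    }
  }
  out
}

# Per-run cache of all pattern matches on one molecule: candidates for every
# group computed once, reused by every pass.
candidate_table <- function(mol, scheme) {
  lapply(scheme$groups, function(g) find_match_candidates(mol, g))
}

#' Create an empty assignment state
#'
#' @param molecule `frag_molecule`.
#' @return an `assignment_state`: fields `assigned` (integer vector, the
#'   group id covering each atom or `NA`) and `placed` (list of candidates).
#' @export
new_assignment_state <- function(molecule) {
  mol <- as_molecule(molecule)
  structure(list(assigned = rep(NA_integer_, mol$n_atoms), placed = list()),
            class = "assignment_state")
}

state_overlaps <- function(state, cand) {
  any(!is.na(state$assigned[cand$atoms]))
}

#' Place a candidate into an assignment state
#'
#' Errors if the candidate overlaps atoms already assigned: non-overlap is a
#' hard invariant of every state mutation.
#'
#' @param state an `assignment_state`.
#' @param cand a match candidate.
#' @return the updated state.
#' @export
state_place <- function(state, cand) {
  if (state_overlaps(state, cand)) {
    stop("candidate overlaps already-assigned atoms", call. = FALSE)
  }
  state$assigned[cand$atoms] <- cand$group_id
  state$placed[[length(state$placed) + 1L]] <- cand
  state
}

state_unassigned <- function(state) which(is.na(state$assigned))

state_complete <- function(state) !anyNA(state$assigned)

#' Adjacency of a candidate to the groups already placed
#'
#' True when the state is empty, or when some bond connects a candidate atom
#' to an already-assigned atom. Used by the simple fragmenter's retry passes:
#' subsequent matches must be adjacent to the groups already found.
#'
#' @param cand a match candidate (must not overlap `state`).
#' @param state an `assignment_state`.
#' @param molecule the `frag_molecule` the state refers to.
#' @return logical.
#' @export
is_adjacent <- function(cand, state, molecule) {
  if (!length(state$placed)) return(TRUE)
  assigned <- which(!is.na(state$assigned))
  for (a in cand$atoms) {
    if (any(molecule$order_mat[a, assigned] > 0)) return(TRUE)
  }
  FALSE
}

#' Clear the neighbourhood of the unassigned atoms
#'
#' Removes every placed group having an atom within bond distance
#' `iteration` of any unassigned atom, freeing room around the stuck region;
#' each retry iteration of the simple fragmenter clears a larger portion of
#' the molecule connected to the unassigned atoms.
#'
#' @param state an `assignment_state` with at least one unassigned atom.
#' @param molecule the `frag_molecule` the state refers to.
#' @param iteration positive integer clearing radius.
#' @return the reduced state.
#' @export
clear_neighborhood <- function(state, molecule, iteration) {
  stopifnot(iteration >= 1L)
  un <- state_unassigned(state)
  if (!length(un)) {
    stop("clear_neighborhood() requires at least one unassigned atom",
         call. = FALSE)
  }
  d <- molecule$dist[un, , drop = FALSE]
  zone <- which(apply(d, 2, min) <= iteration)
  keep <- vapply(state$placed, function(c) !any(c$atoms %in% zone),
                 logical(1))
  new_state <- new_assignment_state(molecule)
  for (cand in state$placed[keep]) new_state <- state_place(new_state, cand)
  new_state
}

# --- group-count multisets ---------------------------------------------------

counts_from_placed <- function(placed) {
  if (!length(placed)) return(integer(0))
  ids <- vapply(placed, `[[`, integer(1), "group_id")
  tab <- table(ids)
  stats::setNames(as.integer(tab), names(tab))
}

#' Format a group-count multiset as `id:count` pairs
#'
#' @param counts named integer vector (names are group ids).
#' @return a single string such as `"1:2;2:2"`, ids ascending; empty string
#'   for an empty multiset.
#' @export
format_group_counts <- function(counts) {
  if (!length(counts)) return("")
  ord <- order(as.integer(names(counts)))
  paste(sprintf("%s:%d", names(counts)[ord], as.integer(counts[ord])),
        collapse = ";")
}

#' Parse an `id:count` pair string into a group-count multiset
#'
#' @param text string such as `"1:2;2:2"` (empty gives an empty multiset).
#' @return named integer vector.
#' @export
parse_group_counts <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) return(stats::setNames(integer(0), character(0)))
  parts <- strsplit(text, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  ids <- vapply(kv, `[[`, character(1), 1L)
  cnt <- as.integer(vapply(kv, `[[`, character(1), 2L))
  if (anyNA(cnt) || any(cnt <= 0L)) {
    stop("malformed group-count string: ", text, call. = FALSE)
  }
  stats::setNames(cnt, ids)[order(as.integer(ids))]
}
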