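# Substructure matching of compiled SMARTS patterns onto molecules.
#
# Plain backtracking over the pattern's BFS order. Matches are non-induced
# (only the bonds the pattern writes are required) which is standard SMARTS
# semantics. Recursive environments are evaluated by anchoring the environment
# pattern's first atom on the candidate molecule atom.

eval_atom_expr <- function(expr, mol, a) {
  op <- expr$op
  if (op == "prim") {
    p <- expr$prim
    return(switch(p$kind,
      element = mol$element[a] == p$element &&
        (is.na(p$aromatic) || mol$aromatic[a] == p$aromatic),
      hcount = mol$nH[a] == p$n,
      connectivity = (mol$degree[a] + mol$nH[a]) == p$n,
      degree = mol$degree[a] == p$n,
      ring = mol$in_ring[a] == p$value,
      charge = mol$charge[a] == p$n,
      aromflag = mol$aromatic[a] == p$value,
      any = TRUE,
      recursive = length(match_pattern(p$env, mol, anchor = a,
                                       max_matches = 1L)) > 0L,
      stop("unknown primitive kind: ", p$kind)))
  }
  if (op == "not") return(!eval_atom_expr(expr$arg, mol, a))
  if (op == "and") {
    for (e in expr$args) if (!eval_atom_expr(e, mol, a)) return(FALSE)
    return(TRUE)
  }
  if (op == "or") {
    for (e in expr$args) if (eval_atom_expr(e, mol, a)) return(TRUE)
    return(FALSE)
  }
  stop("unknown expression op: ", op)
}

mol_bond_matches <- function(type, mol, a, b) {
  o <- mol$order_mat[a, b]
  if (o == 0) return(FALSE)
  arom <- mol$arom_mat[a, b]
  switch(type,
    any = arom || (o == 1 && !arom),
    single = o == 1 && !arom,
    double = o == 2 && !arom,
    triple = o == 3,
    aromatic = arom,
    wild = TRUE,
    stop("unknown bond type: ", type))
}

#' Enumerate matches of a pattern on a molecule
#'
#' Returns every embedding of `pattern` into `molecule` as a list of integer
#' vectors; element `k` of a vector is the molecule atom matched by pattern
#' atom `k`. Symmetry-equivalent embeddings onto the same atoms are all
#' returned; deduplication by atom set happens at the candidate level.
#'
#' @param pattern SMARTS string or compiled `frag_pattern`.
#' @param molecule `frag_molecule` or SMILES string.
#' @param anchor optional molecule atom index the pattern's first atom must map
#'   to (used for recursive environments).
#' @param max_matches stop after this many embeddings.
#' @return list of integer vectors (possibly empty).
#' @export
match_pattern <- function(pattern, molecule, anchor = NULL,
                          max_matches = Inf) {
  pat <- as_pattern(pattern)
  mol <- as_molecule(molecule)
  np <- pat$n_atoms
  order <- pat$match_order

  # bonds from each pattern atom to previously-placed pattern atoms
  placed_rank <- integer(np)
  placed_rank[order] <- seq_len(np)
  back_bonds <- vector("list", np)
  for (b in seq_len(nrow(pat$bonds))) {
    i <- pat$bonds$i[b]; j <- pat$bonds$j[b]
    late <- if (placed_rank[i] > placed_rank[j]) i else j
    early <- if (late == i) j else i
    back_bonds[[late]] <- rbind(back_bonds[[late]],
                                c(early, b))
  }

  matches <- list()
  assignment <- integer(np)
  used <- logical(mol$n_atoms)

  extend <- function(step) {
    if (length(matches) >= max_matches) return(invisible())
    if (step > np) {
      matches[[length(matches) + 1L]] <<- assignment
      return(invisible())
    }
    pa <- order[step]
    cands <- if (step == 1L) {
      if (is.null(anchor)) seq_len(mol$n_atoms) else anchor
    } else {
      # any back bond constrains the candidate set to neighbours
      first_back <- back_bonds[[pa]][1L, 1L]
      mol$adjacency[[assignment[first_back]]]
    }
    for (m in cands) {
      if (used[m]) next
      ok <- TRUE
      bb <- back_bonds[[pa]]
      if (!is.null(bb)) {
        for (r in seq_len(nrow(bb))) {
          if (!mol_bond_matches(pat$bonds$type[bb[r, 2L]], mol,
                                assignment[bb[r, 1L]], m)) {
            ok <- FALSE; break
          }
        }
      }
      if (!ok) next
      if (!eval_atom_expr(pat$atoms[[pa]], mol, m)) next
      assignment[pa] <<- m
      used[m] <<- TRUE
      extend(step + 1L)
      used[m] <<- FALSE
      if (length(matches) >= max_matches) return(invisible())
    }
    invisible()
  }
  extend(1L)
  matches
}

#' Distinct matched atom sets of a pattern on a molecule
#'
#' Like [match_pattern()] but reduced to unique, sorted atom-index sets, in
#' deterministic (lexicographically smallest tuple first) order.
#'
#' @inheritParams match_pattern
#' @return list of sorted integer vectors.
#' @export
match_atom_sets <- function(pattern, molecule) {
  ms <- match_pattern(pattern, molecule)
  if (!length(ms)) return(list())
  sets <- lapply(ms, function(x) sort(unique(x)))
  keys <- vapply(sets, paste, character(1), collapse = ",")
  sets <- sets[!duplicated(keys)]
  ord <- order(vapply(sets, function(x) {
    paste(formatC(x, width = 5, flag = "0"), collapse = ",")
  }, character(1)))
  sets[ord]
}
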