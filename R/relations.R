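# Parent-child pattern containment.
#
# A child pattern is contained in a parent pattern when every structure the
# parent matches necessarily holds a match of the child inside the parent's
# atoms. This is decided by matching the child's graph onto the parent's graph
# with conservative constraint comparison, and in particular an explicit
# hydrogen-count check: a toolkit-style raw graph match would claim [CH3][OH]
# is contained in [CH3][O;H0], so declared H-counts are compared atom by atom.
# Constraint comparison rules, atom by atom along the graph embedding:
#   * elements and aromaticity must agree where the child declares them;
#   * declared H-counts are compared explicitly, with an undeclared atom
#     counting as zero explicit hydrogens (the published heuristic: it stops
#     a raw graph match from claiming [CH3][OH] is contained in
#     [CH3][O;H0], and lets [c] stand for a substituted aromatic carbon);
#   * ring constraints must be guaranteed (child R needs a parent ring atom
#     or declaration; child !R needs a parent !R);
#   * a connectivity constraint needs the same declaration on the parent, or
#     a parent atom whose declared hydrogens and written bonds leave at most
#     one valence unit open (that unit can only be one more single bond, so
#     the CH3 of [CH3][OH] guarantees X4 while the CH2 of [CH2]=[C] is X3);
#   * recursive environments must be declared identically on the parent.
# The ring/connectivity/environment guards keep the relation acyclic on
# real schemes (no two patterns mutually contained unless textually equal),
# which the fragmenters' parent-first suppression relies on.

contain_atom_compat <- function(child_prof, parent_prof, parent_in_ring,
                                parent_bond_count) {
  if (!is.na(child_prof$element)) {
    if (is.na(parent_prof$element) ||
        parent_prof$element != child_prof$element) return(FALSE)
    if (!is.na(child_prof$aromatic)) {
      if (is.na(parent_prof$aromatic) ||
          parent_prof$aromatic != child_prof$aromatic) return(FALSE)
    }
  }
  if (!is.na(child_prof$charge)) {
    parent_c <- if (is.na(parent_prof$charge)) 0L else parent_prof$charge
    if (parent_c != child_prof$charge) return(FALSE)
  }
  if (!is.na(child_prof$ring)) {
    if (child_prof$ring) {
      if (!(parent_in_ring || isTRUE(parent_prof$ring))) return(FALSE)
    } else {
      if (!isFALSE(parent_prof$ring)) return(FALSE)
    }
  }
  if (!is.na(child_prof$hcount)) {
    # undeclared counts as zero explicit hydrogens: this is the published
    # heuristic, under which [c] guarantees H0 to its children (so the
    # aromatic-carbon group defers to substituted-aromatic parents) at the
    # price of not being literally sound for every molecule site
    parent_h <- if (is.na(parent_prof$hcount)) 0L else parent_prof$hcount
    if (parent_h != child_prof$hcount) return(FALSE)
  }
  if (!is.na(child_prof$connectivity)) {
    declared_ok <- !is.na(parent_prof$connectivity) &&
      parent_prof$connectivity == child_prof$connectivity
    # connectivity is also guaranteed when at most one valence unit is left
    # open on the parent atom: that unit can only be one more single bond
    guaranteed <- NA_integer_
    if (!is.na(parent_prof$hcount) && !is.na(parent_prof$element)) {
      v <- standard_valence(parent_prof$element)
      rem <- v - parent_prof$hcount - parent_bond_count$order_sum
      if (rem >= 0 && rem <= 1) {
        guaranteed <- parent_prof$hcount + parent_bond_count$n_bonds +
          as.integer(round(rem))
      }
    }
    saturated_ok <- !is.na(guaranteed) &&
      guaranteed == child_prof$connectivity
    if (!declared_ok && !saturated_ok) return(FALSE)
  }
  parent_pos <- vapply(parent_prof$pos_envs, `[[`, character(1), "smarts")
  for (env in child_prof$pos_envs) {
    if (!(env$smarts %in% parent_pos)) return(FALSE)
  }
  parent_neg <- vapply(parent_prof$neg_envs, `[[`, character(1), "smarts")
  for (env in child_prof$neg_envs) {
    if (!(env$smarts %in% parent_neg)) return(FALSE)
  }
  TRUE
}

contain_bond_compat <- function(child_type, parent_type) {
  switch(child_type,
    any = parent_type %in% c("any", "single", "aromatic"),
    wild = TRUE,
    single = parent_type == "single",
    double = parent_type == "double",
    triple = parent_type == "triple",
    aromatic = parent_type == "aromatic",
    FALSE)
}

#' Test whether one pattern contains another
#'
#' @param parent,child SMARTS strings or compiled `frag_pattern`s.
#' @return `TRUE` iff `child` is structurally contained in `parent` with
#'   compatible declared constraints (see the explicit-hydrogen rule above).
#' @examples
#' pattern_contains("C(=O)[NH][CH2]", "[CH2]")     # TRUE
#' pattern_contains("[CH3][O;H0]", "[CH3][OH]")    # FALSE: H0 vs H1
#' @export
pattern_contains <- function(parent, child) {
  pp <- as_pattern(parent)
  cp <- as_pattern(child)
  if (cp$n_atoms > pp$n_atoms) return(FALSE)

  # parent bond lookup
  np <- pp$n_atoms
  ptype <- matrix(NA_character_, np, np)
  for (b in seq_len(nrow(pp$bonds))) {
    ptype[pp$bonds$i[b], pp$bonds$j[b]] <- pp$bonds$type[b]
    ptype[pp$bonds$j[b], pp$bonds$i[b]] <- pp$bonds$type[b]
  }

  order <- cp$match_order
  rank <- integer(cp$n_atoms)
  rank[order] <- seq_along(order)
  back_bonds <- vector("list", cp$n_atoms)
  for (b in seq_len(nrow(cp$bonds))) {
    i <- cp$bonds$i[b]; j <- cp$bonds$j[b]
    late <- if (rank[i] > rank[j]) i else j
    early <- if (late == i) j else i
    back_bonds[[late]] <- rbind(back_bonds[[late]], c(early, b))
  }

  assignment <- integer(cp$n_atoms)
  used <- logical(np)
  found <- FALSE
  extend <- function(step) {
    if (found) return(invisible())
    if (step > cp$n_atoms) { found <<- TRUE; return(invisible()) }
    ca <- order[step]
    for (m in seq_len(np)) {
      if (used[m]) next
      ok <- contain_atom_compat(cp$profile[[ca]], pp$profile[[m]],
                                pp$pattern_ring[m],
                                list(order_sum = pp$bond_order_sum[m],
                                     n_bonds = pp$bond_n[m]))
      if (!ok) next
      bb <- back_bonds[[ca]]
      if (!is.null(bb)) {
        for (r in seq_len(nrow(bb))) {
          pt <- ptype[assignment[bb[r, 1L]], m]
          if (is.na(pt) ||
              !contain_bond_compat(cp$bonds$type[bb[r, 2L]], pt)) {
            ok <- FALSE; break
          }
        }
      }
      if (!ok) next
      assignment[ca] <<- m
      used[m] <<- TRUE
      extend(step + 1L)
      used[m] <<- FALSE
      if (found) return(invisible())
    }
    invisible()
  }
  extend(1L)
  found
}

pattern_key <- function(group_id, pattern_index) {
  sprintf("%d.%d", group_id, pattern_index)
}

flat_patterns <- function(scheme) {
  out <- list()
  for (g in scheme$groups) {
    for (k in seq_along(g$patterns)) {
      out[[length(out) + 1L]] <- list(
        group_id = g$group_id, pattern_index = k,
        smarts = g$patterns[k], compiled = g$compiled[[k]],
        key = pattern_key(g$group_id, k))
    }
  }
  out
}

#' Build the parent-child containment map of a scheme
#'
#' For every pattern of every group, finds all other patterns of the scheme
#' that contain it. The map is irreflexive (per pattern occurrence) and keyed
#' by `"<group_id>.<pattern_index>"`.
#'
#' @param scheme a `fragmentation_scheme`.
#' @return a named list; each element is a list of parent references with
#'   fields `group_id`, `pattern_index`, `smarts`.
#' @export
build_parent_child_map <- function(scheme) {
  pats <- flat_patterns(scheme)
  n <- length(pats)
  # element multiset prefilter
  elems <- lapply(pats, function(p) {
    sort(vapply(p$compiled$profile, function(pr) {
      if (is.na(pr$element)) "*" else pr$element
    }, character(1)))
  })
  sizes <- vapply(pats, function(p) p$compiled$n_atoms, integer(1))
  res <- stats::setNames(vector("list", n),
                         vapply(pats, `[[`, character(1), "key"))
  for (ci in seq_len(n)) {
    parents <- list()
    for (pi in seq_len(n)) {
      if (pi == ci) next
      if (sizes[ci] > sizes[pi]) next
      tc <- table(elems[[ci]][elems[[ci]] != "*"])
      tp <- table(factor(elems[[pi]], levels = names(tc)))
      if (any(tc > tp)) next
      if (pattern_contains(pats[[pi]]$compiled, pats[[ci]]$compiled)) {
        parents[[length(parents) + 1L]] <- list(
          group_id = pats[[pi]]$group_id,
          pattern_index = pats[[pi]]$pattern_index,
          smarts = pats[[pi]]$smarts)
      }
    }
    res[[pats[[ci]]$key]] <- parents
  }
  res
}

#' Parent patterns of a given pattern
#'
#' Convenience lookup into the scheme's parent-child map.
#'
#' @param scheme a prepared `fragmentation_scheme` (see [load_scheme()]).
#' @param group_id,pattern_index identify the child pattern.
#' @return character vector of parent SMARTS (possibly empty).
#' @export
parent_patterns <- function(scheme, group_id, pattern_index = 1L) {
  if (is.null(scheme$parent_child)) {
    stop("scheme has no parent-child map; use load_scheme()", call. = FALSE)
  }
  ps <- scheme$parent_child[[pattern_key(group_id, pattern_index)]]
  vapply(ps, `[[`, character(1), "smarts")
}
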