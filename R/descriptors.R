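# The 8 heuristic pattern descriptors that drive the priority sort.
#
# For each SMARTS pattern the vector is, in sort order:
#   d1 zero free bonds          (boolean)
#   d2 "simple" pattern         (boolean; a lone valence-one atom, or one
#                                carbon plus valence-one atoms bonded to it,
#                                with at least one free bond)
#   d3 number of defining atoms (matched atoms + atoms of positive recursive
#                                environments)
#   d4 exactly one free bond    (boolean)
#   d5 atoms that are neither H nor C
#   d6 pattern includes ring atoms (aromatic or ring-constrained)
#   d7 number of triple bonds
#   d8 number of double bonds
#
# Free bonds are counted per matched atom as the element's standard valence
# minus declared hydrogens minus the bond orders written in the pattern
# (aromatic bonds count 1.5), clamped at zero; the unconsumed ring bonds of a
# lowercase aromatic atom written without its ring therefore count as free.
# Bonds and atoms inside recursive environments never contribute to free-bond,
# double-bond or triple-bond counts; atoms of positive environments do count
# toward the atom total (the environment defines the group's vicinity), atoms
# of negated environments do not.

pattern_free_bonds <- function(pat) {
  free <- 0
  for (a in seq_len(pat$n_atoms)) {
    prof <- pat$profile[[a]]
    el <- prof$element
    if (is.na(el)) next # wildcard atoms contribute no free valence
    allowed <- standard_valence(el)
    h <- if (is.na(prof$hcount)) 0L else prof$hcount
    free <- free + max(0, allowed - h - pat$bond_order_sum[a])
  }
  free
}

pattern_env_atoms <- function(pat) {
  # atoms contributed by positive recursive environments, beyond the anchor
  extra <- character(0)
  for (prof in pat$profile) {
    for (env in prof$pos_envs) {
      if (env$n_atoms > 1L) {
        els <- vapply(env$profile[-1L], function(p) {
          if (is.na(p$element)) "*" else p$element
        }, character(1))
        extra <- c(extra, els)
      }
    }
  }
  extra
}

pattern_is_simple <- function(pat) {
  if (pattern_free_bonds(pat) < 1) return(FALSE)
  els <- vapply(pat$profile, function(p) p$element, character(1))
  if (anyNA(els)) return(FALSE)
  val <- standard_valence(els)
  if (pat$n_atoms == 1L) return(val[1L] == 1)
  centre <- which(val > 1)
  if (length(centre) != 1L || els[centre] != "C") return(FALSE)
  # every valence-one atom must be bonded to the central carbon
  for (b in seq_len(nrow(pat$bonds))) {
    if (pat$bonds$i[b] != centre && pat$bonds$j[b] != centre) return(FALSE)
  }
  all(tabulate(c(pat$bonds$i, pat$bonds$j), pat$n_atoms)[-centre] == 1L)
}

#' Compute the 8-descriptor vector of a SMARTS pattern
#'
#' @param pattern SMARTS string or compiled `frag_pattern`.
#' @return an object of class `descriptor_vector`: a list with elements
#'   `d1_zero_bonds`, `d2_simple`, `d3_n_atoms`, `d4_one_bond`, `d5_n_hetero`,
#'   `d6_in_ring`, `d7_n_triple`, `d8_n_double`.
#' @examples
#' compute_descriptor_vector("[OH2]")       # water: zero free bonds
#' compute_descriptor_vector("[$(Cl[C]=[C])]") # 3 defining atoms
#' @export
compute_descriptor_vector <- function(pattern) {
  pat <- as_pattern(pattern)
  free <- pattern_free_bonds(pat)
  env_els <- pattern_env_atoms(pat)
  matched_els <- vapply(pat$profile, function(p) {
    if (is.na(p$element)) "*" else p$element
  }, character(1))
  all_els <- c(matched_els, env_els)
  hetero <- sum(!(all_els %in% c("C", "H", "*")))
  in_ring <- any(vapply(seq_len(pat$n_atoms), function(a) {
    prof <- pat$profile[[a]]
    isTRUE(prof$aromatic) || isTRUE(prof$ring)
  }, logical(1)))
  structure(list(
    d1_zero_bonds = free == 0,
    d2_simple = pattern_is_simple(pat),
    d3_n_atoms = pat$n_atoms + length(env_els),
    d4_one_bond = free == 1,
    d5_n_hetero = as.integer(hetero),
    d6_in_ring = in_ring,
    d7_n_triple = sum(pat$bonds$type == "triple"),
    d8_n_double = sum(pat$bonds$type == "double")
  ), class = "descriptor_vector")
}

descriptor_numeric <- function(d) {
  c(as.numeric(d$d1_zero_bonds), as.numeric(d$d2_simple), d$d3_n_atoms,
    as.numeric(d$d4_one_bond), d$d5_n_hetero, as.numeric(d$d6_in_ring),
    d$d7_n_triple, d$d8_n_double)
}

#' @export
print.descriptor_vector <- function(x, ...) {
  cat("<descriptor_vector> (",
      paste(descriptor_numeric(x), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Sort a fragmentation scheme by descending descriptor order
#'
#' Groups are ordered by descending lexicographic comparison of their
#' descriptor vectors (booleans as 1/0); the sort is stable, so groups with
#' identical vectors keep their scheme-file order. A group's descriptor
#' vector is that of its first pattern, the pattern used for sorting.
#'
#' @param scheme a `fragmentation_scheme` with descriptors attached (see
#'   [load_scheme()]).
#' @return the scheme with its `sorted_order` permutation set.
#' @export
sort_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "fragmentation_scheme"))
  m <- t(vapply(scheme$groups, function(g) {
    if (is.null(g$descriptor)) {
      stop("group ", g$group_id, " has no descriptor vector; use load_scheme()",
           call. = FALSE)
    }
    descriptor_numeric(g$descriptor)
  }, numeric(8)))
  cols <- lapply(seq_len(8), function(k) -m[, k])
  scheme$sorted_order <- do.call(order, cols)
  scheme
}
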