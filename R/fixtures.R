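# Deterministic test molecules with closed-form expected fragmentations, and
# an independent brute-force exact-cover oracle. The oracle recurses over the
# raw candidate list with plain include/exclude branching - no memoization,
# no cover-directed branching, no ordering heuristics - so it shares no logic
# with either fragmenter and can arbitrate both.

series_families <- c("n-alkane", "1-alkanol", "chloroalkane", "alkylbenzene")

series_member <- function(family, n) {
  chain <- strrep("C", n)
  switch(family,
    "n-alkane" = {
      if (n < 2L) stop("n-alkane series starts at n = 2", call. = FALSE)
      counts <- c("1" = 2L)
      if (n > 2L) counts <- c(counts, "2" = n - 2L)
      list(smiles = chain, counts = counts)
    },
    "1-alkanol" = {
      if (n < 2L) stop("1-alkanol series starts at n = 2", call. = FALSE)
      # the OH group consumes no carbon: CnH(2n+1)OH is CH3 + (n-1) CH2 + OH
      counts <- c("1" = 1L, "2" = n - 1L, "14" = 1L)
      list(smiles = paste0(chain, "O"), counts = counts)
    },
    "chloroalkane" = {
      if (n < 2L) stop("chloroalkane series starts at n = 2", call. = FALSE)
      counts <- c("1" = 1L, "44" = 1L)
      if (n > 2L) counts <- c(counts, "2" = n - 2L)
      list(smiles = paste0(chain, "Cl"), counts = counts)
    },
    "alkylbenzene" = {
      if (n < 1L) stop("alkylbenzene series starts at n = 1", call. = FALSE)
      if (n == 1L) {
        list(smiles = "Cc1ccccc1", counts = c("9" = 5L, "11" = 1L))
      } else {
        counts <- c("1" = 1L, "9" = 5L, "12" = 1L)
        if (n > 2L) counts <- c(counts, "2" = n - 2L)
        list(smiles = paste0(chain, "c1ccccc1"), counts = counts)
      }
    },
    stop("unknown series family: ", family, call. = FALSE))
}

#' Generate members of a homologous series with known fragmentations
#'
#' Emits SMILES with closed-form expected UNIFAC group counts: n-alkanes
#' (2 CH3 + (n-2) CH2), 1-alkanols (CH3 + (n-2) CH2 + OH), terminal
#' chloroalkanes (CH3 + (n-2) CH2 + CH2Cl) and n-alkylbenzenes (5 ACH +
#' ACCH3 for toluene, else ACCH2 + alkyl tail).
#'
#' @param family one of `"n-alkane"`, `"1-alkanol"`, `"chloroalkane"`,
#'   `"alkylbenzene"`.
#' @param n carbon count of the (first) chain; family-specific minimum
#'   (1 for alkylbenzene, else 2).
#' @param count number of consecutive series members to emit (chain lengths
#'   `n, n+1, ...`).
#' @return data.frame with columns `smiles`, `family`, `n`,
#'   `expected_counts` (an `id:count` string, see [format_group_counts()]).
#' @export
generate_series <- function(family, n, count = 1L) {
  family <- match.arg(family, series_families)
  stopifnot(count >= 1L)
  rows <- lapply(seq_len(count) - 1L + n, function(len) {
    m <- series_member(family, len)
    data.frame(smiles = m$smiles, family = family, n = len,
               expected_counts = format_group_counts(m$counts),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Independent brute-force enumeration of all exact covers
#'
#' Enumerates every partition of the molecule's heavy atoms into scheme-group
#' matches by naive recursion over the candidate list. Deliberately
#' independent of [fragment_complete()] (no pruning beyond overlap
#' feasibility, no memoization, no branching heuristic); exponential by
#' design and intended for molecules of about 10 heavy atoms or fewer.
#'
#' @param molecule SMILES string or `frag_molecule`.
#' @param scheme a `fragmentation_scheme`.
#' @return list of covers, each a list of candidates; attribute `keys` holds
#'   the canonical partition keys (sorted, for set comparison).
#' @export
oracle_enumerate_covers <- function(molecule, scheme = default_scheme()) {
  mol <- as_molecule(molecule)
  cands <- list()
  for (g in scheme$groups) {
    for (cand in find_match_candidates(mol, g)) {
      cands[[length(cands) + 1L]] <- cand
    }
  }
  covers <- list()
  n <- mol$n_atoms
  recurse <- function(i, covered, chosen) {
    if (i > length(cands)) {
      if (sum(covered) == n) {
        covers[[length(covers) + 1L]] <<- chosen
      }
      return(invisible())
    }
    recurse(i + 1L, covered, chosen)          # exclude candidate i
    atoms <- cands[[i]]$atoms
    if (!any(covered[atoms])) {               # include candidate i
      covered[atoms] <- TRUE
      recurse(i + 1L, covered, c(chosen, i))
      }
    invisible()
  }
  recurse(1L, logical(n), integer(0))
  covers <- lapply(covers, function(idx) lapply(idx, function(i) cands[[i]]))
  keys <- vapply(covers, solution_key, character(1))
  dup <- duplicated(keys)
  covers <- covers[!dup]
  attr(covers, "keys") <- sort(keys[!dup])
  covers
}

# Canonical key of a partition-with-group-labels, usable across the oracle,
# the complete fragmenter and the simple fragmenter's single solution.
solution_key <- function(solution) {
  paste(sort(vapply(solution, candidate_key, character(1))), collapse = "|")
}

#' Build a reference table from the fixture generators
#'
#' Produces a data.frame usable as a reference database for
#' [run_reference_comparison()]: all four families over the given chain
#' lengths (a self-test loop for the comparison tooling).
#'
#' @param lengths integer vector of chain lengths (intersected with each
#'   family's valid range).
#' @return data.frame with columns `smiles`, `expected_counts`.
#' @export
generate_fixture_reference <- function(lengths = 2:8) {
  rows <- list()
  for (family in series_families) {
    valid <- lengths[lengths >= if (family == "alkylbenzene") 1L else 2L]
    for (n in valid) {
      rows[[length(rows) + 1L]] <- generate_series(family, n)
    }
  }
  df <- do.call(rbind, rows)
  df[!duplicated(df$smiles), c("smiles", "expected_counts")]
}
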