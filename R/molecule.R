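# Molecule model and SMILES parsing.
#
# Molecules are plain heavy-atom graphs: hydrogens are implicit (stored as a
# per-atom count), bond orders are 1/2/3 or aromatic (order 1.5). This is the
# SMILES subset group-contribution work needs: organic-subset atoms, bracket
# atoms with isotope/H-count/charge, branches, ring closures and aromatic
# lowercase notation. Stereo marks (/ \ @) are parsed and ignored.

ELEMENT_VALENCES <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L, Si = 4L
)

STANDARD_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
  F = 1, Cl = 1, Br = 1, I = 1, Si = 4, H = 1
)

standard_valence <- function(element) {
  v <- STANDARD_VALENCE[element]
  v[is.na(v)] <- 4
  unname(v)
}

ORGANIC_SUBSET <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
AROMATIC_SUBSET <- c("b", "c", "n", "o", "p", "s")

# --- tokenizer ---------------------------------------------------------------

# Parse the body of a bracket atom (without the enclosing []) as used in
# SMILES: [isotope][symbol][chirality][Hcount][charge][:map]
parse_bracket_atom <- function(txt, full) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  i <- 1L
  n <- length(chars)
  peek <- function() if (i <= n) chars[i] else ""
  take_digits <- function() {
    s <- ""
    while (i <= n && grepl("[0-9]", chars[i])) {
      s <- paste0(s, chars[i]); i <<- i + 1L
    }
    s
  }
  isotope <- take_digits()
  isotope <- if (nzchar(isotope)) as.integer(isotope) else NA_integer_
  aromatic <- FALSE
  if (peek() %in% c("c", "n", "o", "p", "s", "b")) {
    element <- toupper(peek()); aromatic <- TRUE; i <- i + 1L
    if (element == "S" && peek() == "i") { # aromatic si, not expected but safe
      element <- "Si"; i <- i + 1L
    }
  } else if (grepl("[A-Z]", peek())) {
    element <- peek(); i <- i + 1L
    if (i <= n && grepl("[a-z]", chars[i]) && chars[i] != "h") {
      two <- paste0(element, chars[i])
      # Two-letter symbol unless the lowercase letter starts a valid tail
      # (there is no such ambiguity for the elements supported here).
      element <- two; i <- i + 1L
    }
  } else {
    stop("cannot parse bracket atom [", full, "]", call. = FALSE)
  }
  while (peek() == "@") i <- i + 1L # chirality, ignored
  hcount <- 0L
  if (peek() == "H") {
    i <- i + 1L
    d <- take_digits()
    hcount <- if (nzchar(d)) as.integer(d) else 1L
  }
  charge <- 0L
  if (peek() %in% c("+", "-")) {
    sign <- if (peek() == "+") 1L else -1L
    sym <- peek()
    cnt <- 0L
    while (peek() == sym) { cnt <- cnt + 1L; i <- i + 1L }
    d <- take_digits()
    charge <- if (nzchar(d)) sign * as.integer(d) else sign * cnt
  }
  if (peek() == ":") { i <- i + 1L; take_digits() } # atom map, ignored
  if (i <= n) stop("trailing characters in bracket atom [", full, "]", call. = FALSE)
  list(element = element, aromatic = aromatic, hcount = hcount,
       charge = charge, isotope = isotope)
}

# Tokenize a SMILES string into a raw atom/bond list. Explicit hydrogens and
# isotopes are kept; normalize_structure() folds them away.
parse_smiles_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  s <- trimws(smiles)
  if (!nzchar(s)) stop("empty SMILES", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)

  element <- character(); aromatic <- logical(); charge <- integer()
  hdecl <- integer(); bracket <- logical(); isotope <- integer()
  bi <- integer(); bj <- integer(); bsym <- character()
  prev <- NA_integer_
  stack <- integer()
  pending <- ""
  ring_open <- list()
  multi <- FALSE

  add_atom <- function(el, arom, chg = 0L, h = NA_integer_, brk = FALSE,
                       iso = NA_integer_) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    hdecl[length(hdecl) + 1L] <<- h
    bracket[length(bracket) + 1L] <<- brk
    isotope[length(isotope) + 1L] <<- iso
    idx <- length(element)
    if (!is.na(prev)) {
      bi[length(bi) + 1L] <<- prev
      bj[length(bj) + 1L] <<- idx
      bsym[length(bsym) + 1L] <<- pending
    }
    pending <<- ""
    prev <<- idx
    idx
  }

  close_ring <- function(num) {
    key <- as.character(num)
    if (is.null(ring_open[[key]])) {
      ring_open[[key]] <<- list(atom = prev, sym = pending)
    } else {
      opened <- ring_open[[key]]
      sym <- if (nzchar(pending)) pending else opened$sym
      bi[length(bi) + 1L] <<- opened$atom
      bj[length(bj) + 1L] <<- prev
      bsym[length(bsym) + 1L] <<- sym
      ring_open[[key]] <<- NULL
    }
    pending <<- ""
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":")) {
      pending <- ch; i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      pending <- "-"; i <- i + 1L # stereo bonds treated as single
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES: ", smiles, call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      multi <- TRUE; prev <- NA_integer_; pending <- ""; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("bad ring closure in SMILES: ", smiles, call. = FALSE)
      close_ring(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 3L
    } else if (ch == "[") {
      depth <- 1L; j <- i + 1L
      while (j <= n && depth > 0L) {
        if (chars[j] == "[") depth <- depth + 1L
        if (chars[j] == "]") depth <- depth - 1L
        j <- j + 1L
      }
      if (depth != 0L) stop("unbalanced '[' in SMILES: ", smiles, call. = FALSE)
      body <- substr(s, i + 1L, j - 2L)
      at <- parse_bracket_atom(body, body)
      add_atom(at$element, at$aromatic, at$charge, at$hcount, brk = TRUE,
               iso = at$isotope)
      i <- j
    } else if (ch == "H" && !length(element)) {
      stop("cannot parse SMILES: ", smiles, call. = FALSE)
    } else {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE); i <- i + 2L
      } else if (ch %in% ORGANIC_SUBSET) {
        add_atom(ch, FALSE); i <- i + 1L
      } else if (ch %in% AROMATIC_SUBSET) {
        add_atom(toupper(ch), TRUE); i <- i + 1L
      } else {
        stop("unexpected character '", ch, "' in SMILES: ", smiles, call. = FALSE)
      }
    }
  }
  if (length(ring_open)) stop("unclosed ring bond in SMILES: ", smiles, call. = FALSE)
  if (length(stack)) stop("unbalanced '(' in SMILES: ", smiles, call. = FALSE)
  list(element = element, aromatic = aromatic, charge = charge, hdecl = hdecl,
       bracket = bracket, isotope = isotope,
       bonds = data.frame(i = bi, j = bj, sym = bsym,
                          stringsAsFactors = FALSE),
       multi = multi, smiles = smiles)
}

# --- graph utilities ---------------------------------------------------------

ring_edge_flags <- function(n_atoms, bonds) {
  if (!nrow(bonds)) return(logical(0))
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("i", "j")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < n_atoms) {
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  }
  br <- igraph::bridges(g)
  flags <- rep(TRUE, nrow(bonds))
  flags[as.integer(br)] <- FALSE
  flags
}

# All simple cycles of length 5 or 6, as lists of atom index vectors (in cycle
# order). Molecules here are small, so a direct DFS is adequate.
find_small_rings <- function(n_atoms, bonds, ring_edge) {
  if (!nrow(bonds)) return(list())
  adj <- vector("list", n_atoms)
  for (b in seq_len(nrow(bonds))) {
    if (!ring_edge[b]) next
    i <- bonds$i[b]; j <- bonds$j[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- new.env(parent = emptyenv())
  rings <- list()
  walk <- function(start, path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (nb == start && length(path) >= 5L) {
        key <- paste(sort(path), collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          rings[[length(rings) + 1L]] <<- path
        }
      } else if (!(nb %in% path) && length(path) < 6L && nb > start) {
        walk(start, c(path, nb))
      }
    }
  }
  for (v in seq_len(n_atoms)) walk(v, v)
  rings
}

implicit_h_count <- function(element, order_sum) {
  vals <- ELEMENT_VALENCES[[element]]
  if (is.null(vals)) return(0L)
  need <- ceiling(order_sum - 1e-9)
  ok <- vals[vals >= need]
  if (!length(ok)) return(0L)
  as.integer(ok[1] - need)
}

#' Parse and normalize a SMILES structure
#'
#' Parses a SMILES string into a heavy-atom molecular graph, replacing heavy
#' hydrogen isotopes (deuterium, tritium) by ordinary hydrogens, folding
#' explicit hydrogens into per-atom counts, stripping isotope labels and
#' perceiving aromaticity for Kekule-written rings. Structures that cannot be
#' fragmented meaningfully are rejected rather than parsed: dot-disconnected
#' inputs (salts, mixtures) and radical-bearing structures.
#'
#' @param smiles a single SMILES string.
#' @return An object of class `frag_molecule` on success, or of class
#'   `frag_rejection` with fields `status` (`"parse_error"` or `"excluded"`)
#'   and `reason`. Use [is_rejection()] to discriminate.
#' @examples
#' mol <- normalize_structure("CCO")
#' mol$n_atoms
#' normalize_structure("[Na+].[Cl-]") # exclusion rejection
#' @export
normalize_structure <- function(smiles) {
  raw <- tryCatch(parse_smiles_graph(smiles), error = function(e) e)
  if (inherits(raw, "error")) {
    return(structure(list(status = "parse_error", reason = conditionMessage(raw),
                          smiles = smiles),
                     class = "frag_rejection"))
  }
  if (raw$multi) {
    return(structure(list(status = "excluded",
                          reason = "dot-disconnected structure (salt or mixture)",
                          smiles = smiles),
                     class = "frag_rejection"))
  }

  element <- raw$element; aromatic <- raw$aromatic; charge <- raw$charge
  hdecl <- raw$hdecl; bracket <- raw$bracket
  bonds <- raw$bonds
  n <- length(element)

  # Count explicit-hydrogen neighbours (any isotope), then drop those atoms.
  is_h <- element == "H"
  extra_h <- integer(n)
  if (any(is_h)) {
    keep_bond <- rep(TRUE, nrow(bonds))
    for (b in seq_len(nrow(bonds))) {
      i <- bonds$i[b]; j <- bonds$j[b]
      if (is_h[i] && is_h[j]) {
        return(structure(list(status = "excluded",
                              reason = "hydrogen-only fragment", smiles = smiles),
                         class = "frag_rejection"))
      }
      if (is_h[i] || is_h[j]) {
        heavy <- if (is_h[i]) j else i
        extra_h[heavy] <- extra_h[heavy] + 1L
        keep_bond[b] <- FALSE
      }
    }
    if (any(is_h & (tabulate(c(bonds$i, bonds$j), n) != 1L))) {
      return(structure(list(status = "parse_error",
                            reason = "explicit hydrogen with unexpected bonding",
                            smiles = smiles),
                       class = "frag_rejection"))
    }
    bonds <- bonds[keep_bond, , drop = FALSE]
    old2new <- cumsum(!is_h)
    bonds$i <- old2new[bonds$i]; bonds$j <- old2new[bonds$j]
    keep <- !is_h
    element <- element[keep]; aromatic <- aromatic[keep]
    charge <- charge[keep]; hdecl <- hdecl[keep]; bracket <- bracket[keep]
    extra_h <- extra_h[keep]
    n <- length(element)
  }
  if (n == 0L) {
    return(structure(list(status = "parse_error", reason = "no heavy atoms",
                          smiles = smiles),
                     class = "frag_rejection"))
  }

  ring_edge <- ring_edge_flags(n, bonds)

  # Resolve bond orders; an unwritten bond between two aromatic atoms is
  # aromatic only when it lies on a ring (a biphenyl-type link stays single).
  order <- numeric(nrow(bonds)); arom_bond <- logical(nrow(bonds))
  for (b in seq_len(nrow(bonds))) {
    sym <- bonds$sym[b]
    if (sym == "=") order[b] <- 2
    else if (sym == "#") order[b] <- 3
    else if (sym == ":") { order[b] <- 1.5; arom_bond[b] <- TRUE }
    else if (sym == "" && ring_edge[b] && aromatic[bonds$i[b]] &&
             aromatic[bonds$j[b]]) { order[b] <- 1.5; arom_bond[b] <- TRUE }
    else order[b] <- 1
  }

  order_sum <- numeric(n)
  for (b in seq_len(nrow(bonds))) {
    order_sum[bonds$i[b]] <- order_sum[bonds$i[b]] + order[b]
    order_sum[bonds$j[b]] <- order_sum[bonds$j[b]] + order[b]
  }

  nH <- integer(n)
  for (a in seq_len(n)) {
    if (bracket[a]) {
      nH[a] <- hdecl[a] + extra_h[a]
    } else if (aromatic[a]) {
      # aromatic atoms never promote to a higher valence state
      v <- min(ELEMENT_VALENCES[[element[a]]])
      nH[a] <- max(0L, as.integer(v - ceiling(order_sum[a] + extra_h[a] - 1e-9))) +
        extra_h[a]
    } else {
      nH[a] <- implicit_h_count(element[a], order_sum[a] + extra_h[a]) +
        extra_h[a]
    }
  }

  # Hueckel-style aromatic perception for Kekule-written rings.
  has_triple <- logical(n); has_double <- logical(n)
  for (b in seq_len(nrow(bonds))) {
    if (order[b] == 3) has_triple[bonds$i[b]] <- has_triple[bonds$j[b]] <- TRUE
    if (order[b] == 2) has_double[bonds$i[b]] <- has_double[bonds$j[b]] <- TRUE
  }
  bond_index <- function(i, j) {
    which((bonds$i == i & bonds$j == j) | (bonds$i == j & bonds$j == i))[1]
  }
  for (ring in find_small_rings(n, bonds, ring_edge)) {
    if (all(aromatic[ring])) next
    if (!all(element[ring] %in% c("C", "N", "O", "S"))) next
    if (any(has_triple[ring])) next
    pi_e <- 0L; ok <- TRUE
    for (a in ring) {
      nb_in <- intersect(ring, c(bonds$j[bonds$i == a], bonds$i[bonds$j == a]))
      dbl_in <- any(vapply(nb_in, function(x) {
        order[bond_index(a, x)] == 2
      }, logical(1)))
      if (dbl_in) {
        pi_e <- pi_e + 1L
      } else if (has_double[a]) {
        ok <- FALSE; break # exocyclic double bond: not handled as aromatic
      } else if (element[a] %in% c("N", "O", "S")) {
        pi_e <- pi_e + 2L # lone pair donor (pyrrole-type N, furan O, ...)
      } else {
        ok <- FALSE; break # sp3 ring carbon
      }
    }
    if (ok && pi_e == 6L) {
      aromatic[ring] <- TRUE
      for (k in seq_along(ring)) {
        a <- ring[k]; b2 <- ring[if (k == length(ring)) 1L else k + 1L]
        bi <- bond_index(a, b2)
        order[bi] <- 1.5; arom_bond[bi] <- TRUE
      }
    }
  }

  in_ring <- logical(n)
  for (b in seq_len(nrow(bonds))) {
    if (ring_edge[b]) in_ring[bonds$i[b]] <- in_ring[bonds$j[b]] <- TRUE
  }

  degree <- tabulate(c(bonds$i, bonds$j), n)

  # Radical detection: an uncharged bracket atom whose declared hydrogens plus
  # bonds leave it below the element's minimum standard valence carries an
  # unpaired electron.
  for (a in seq_len(n)) {
    if (!bracket[a] || charge[a] != 0L || aromatic[a]) next
    vals <- ELEMENT_VALENCES[[element[a]]]
    if (is.null(vals)) next
    total <- ceiling(order_sum[a] - 1e-9) + nH[a]
    if (total < min(vals)) {
      return(structure(list(status = "excluded",
                            reason = sprintf("radical centre at atom %d (%s)",
                                             a, element[a]),
                            smiles = smiles),
                       class = "frag_rejection"))
    }
  }

  order_mat <- matrix(0, n, n)
  arom_mat <- matrix(FALSE, n, n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    order_mat[i, j] <- order_mat[j, i] <- order[b]
    arom_mat[i, j] <- arom_mat[j, i] <- arom_bond[b]
  }
  adjacency <- lapply(seq_len(n), function(a) which(order_mat[a, ] > 0))

  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("i", "j")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  dist <- igraph::distances(g)

  structure(list(
    n_atoms = n, element = element, aromatic = aromatic, charge = charge,
    nH = nH, in_ring = in_ring, degree = degree,
    bonds = data.frame(i = bonds$i, j = bonds$j, order = order,
                       aromatic = arom_bond),
    order_mat = order_mat, arom_mat = arom_mat, adjacency = adjacency,
    dist = dist, smiles = smiles
  ), class = "frag_molecule")
}

#' Test whether a structure was rejected
#'
#' @param x result of [normalize_structure()].
#' @return `TRUE` for a `frag_rejection` object.
#' @export
is_rejection <- function(x) inherits(x, "frag_rejection")

as_molecule <- function(x) {
  if (inherits(x, "frag_molecule")) return(x)
  if (is.character(x) && length(x) == 1L) {
    m <- normalize_structure(x)
    if (is_rejection(m)) {
      stop("cannot use rejected structure '", x, "': ", m$reason, call. = FALSE)
    }
    return(m)
  }
  stop("expected a SMILES string or frag_molecule", call. = FALSE)
}

#' @export
print.frag_molecule <- function(x, ...) {
  cat("<frag_molecule> ", x$smiles, "\n", sep = "")
  cat("  heavy atoms: ", x$n_atoms, "; bonds: ", nrow(x$bonds),
      "; aromatic atoms: ", sum(x$aromatic), "\n", sep = "")
  invisible(x)
}

#' @export
print.frag_rejection <- function(x, ...) {
  cat("<frag_rejection> ", x$smiles, " [", x$status, "]: ", x$reason, "\n",
      sep = "")
  invisible(x)
}

# Graph diameter (longest finite shortest path), used to cap the simple
# fragmenter's clearing iterations.
molecule_diameter <- function(mol) {
  d <- mol$dist[is.finite(mol$dist)]
  max(1L, as.integer(max(d)))
}
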