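# SMARTS pattern parsing.
#
# Covers the primitives group-contribution schemes use: element symbols
# (aliphatic and aromatic), H-counts, connectivity X, ring membership R/!R,
# charges, wildcards (* A a), logical operators (! ; & ,) and recursive
# environments $(...) / !$(...). Patterns compile to a small graph of atom
# expression trees plus a per-atom "profile" of the positively declared
# constraints, which descriptor computation and pattern-on-pattern containment
# work from.

smarts_bond_types <- c("-" = "single", "=" = "double", "#" = "triple",
                       ":" = "aromatic", "~" = "wild")

# --- atom expressions --------------------------------------------------------

# Recursive descent over a bracket-atom body. Returns an expression tree of
# nodes list(op = "or"/"and"/"not"/"prim", ...).
parse_atom_expr <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  pos <- 1L
  n <- length(chars)
  peek <- function() if (pos <= n) chars[pos] else ""
  take_digits <- function() {
    s <- ""
    while (pos <= n && grepl("[0-9]", chars[pos])) {
      s <- paste0(s, chars[pos]); pos <<- pos + 1L
    }
    s
  }

  parse_primitive <- function() {
    ch <- peek()
    if (ch == "$") {
      pos <<- pos + 1L
      if (peek() != "(") stop("'$' must be followed by '(' in [", txt, "]",
                              call. = FALSE)
      depth <- 0L; start <- pos
      while (pos <= n) {
        if (chars[pos] == "(") depth <- depth + 1L
        if (chars[pos] == ")") {
          depth <- depth - 1L
          if (depth == 0L) break
        }
        pos <<- pos + 1L
      }
      if (depth != 0L) stop("unbalanced '(' in recursive SMARTS [", txt, "]",
                            call. = FALSE)
      inner <- paste(chars[(start + 1L):(pos - 1L)], collapse = "")
      pos <<- pos + 1L
      return(list(op = "prim",
                  prim = list(kind = "recursive", env = parse_smarts(inner))))
    }
    if (ch == "#") {
      pos <<- pos + 1L
      num <- as.integer(take_digits())
      el <- c("6" = "C", "7" = "N", "8" = "O", "16" = "S", "14" = "Si",
              "9" = "F", "17" = "Cl", "35" = "Br", "53" = "I", "15" = "P",
              "5" = "B", "1" = "H")[as.character(num)]
      if (is.na(el)) stop("unsupported atomic number #", num, call. = FALSE)
      return(list(op = "prim",
                  prim = list(kind = "element", element = unname(el),
                              aromatic = NA)))
    }
    if (ch == "H") {
      pos <<- pos + 1L
      d <- take_digits()
      return(list(op = "prim",
                  prim = list(kind = "hcount",
                              n = if (nzchar(d)) as.integer(d) else 1L)))
    }
    if (ch == "X") {
      pos <<- pos + 1L
      d <- take_digits()
      return(list(op = "prim",
                  prim = list(kind = "connectivity",
                              n = if (nzchar(d)) as.integer(d) else 1L)))
    }
    if (ch == "D") {
      pos <<- pos + 1L
      d <- take_digits()
      return(list(op = "prim",
                  prim = list(kind = "degree",
                              n = if (nzchar(d)) as.integer(d) else 1L)))
    }
    if (ch == "R") {
      pos <<- pos + 1L
      d <- take_digits()
      val <- if (nzchar(d) && as.integer(d) == 0L) FALSE else TRUE
      return(list(op = "prim", prim = list(kind = "ring", value = val)))
    }
    if (ch %in% c("+", "-")) {
      sign <- if (ch == "+") 1L else -1L
      cnt <- 0L
      while (peek() == ch) { cnt <- cnt + 1L; pos <<- pos + 1L }
      d <- take_digits()
      chg <- if (nzchar(d)) sign * as.integer(d) else sign * cnt
      return(list(op = "prim", prim = list(kind = "charge", n = chg)))
    }
    if (ch == "*") {
      pos <<- pos + 1L
      return(list(op = "prim", prim = list(kind = "any")))
    }
    if (ch == "A") {
      pos <<- pos + 1L
      return(list(op = "prim", prim = list(kind = "aromflag", value = FALSE)))
    }
    if (ch == "a") {
      pos <<- pos + 1L
      return(list(op = "prim", prim = list(kind = "aromflag", value = TRUE)))
    }
    if (ch == "@") { # chirality: parse and accept anything
      while (peek() == "@") pos <<- pos + 1L
      return(list(op = "prim", prim = list(kind = "any")))
    }
    if (grepl("[A-Z]", ch)) {
      el <- ch; pos <<- pos + 1L
      if (pos <= n && grepl("[a-z]", chars[pos])) {
        two <- paste0(el, chars[pos])
        if (two %in% c("Cl", "Br", "Si")) { el <- two; pos <<- pos + 1L }
      }
      if (!(el %in% names(STANDARD_VALENCE))) {
        stop("unsupported element '", el, "' in [", txt, "]", call. = FALSE)
      }
      return(list(op = "prim",
                  prim = list(kind = "element", element = el, aromatic = FALSE)))
    }
    if (ch %in% AROMATIC_SUBSET) {
      el <- toupper(ch); pos <<- pos + 1L
      if (ch == "s" && peek() == "i") { el <- "Si"; pos <<- pos + 1L }
      return(list(op = "prim",
                  prim = list(kind = "element", element = el, aromatic = TRUE)))
    }
    stop("unsupported SMARTS primitive at '", ch, "' in [", txt, "]",
         call. = FALSE)
  }

  parse_factor <- function() {
    if (peek() == "!") {
      pos <<- pos + 1L
      return(list(op = "not", arg = parse_factor()))
    }
    parse_primitive()
  }

  parse_and <- function() {
    parts <- list(parse_factor())
    repeat {
      if (peek() %in% c("&", ";")) {
        pos <<- pos + 1L
        parts[[length(parts) + 1L]] <- parse_factor()
      } else if (pos <= n && !(peek() %in% c(",", ""))) {
        parts[[length(parts) + 1L]] <- parse_factor()
      } else break
    }
    if (length(parts) == 1L) parts[[1L]] else list(op = "and", args = parts)
  }

  parse_or <- function() {
    parts <- list(parse_and())
    while (peek() == ",") {
      pos <<- pos + 1L
      parts[[length(parts) + 1L]] <- parse_and()
    }
    if (length(parts) == 1L) parts[[1L]] else list(op = "or", args = parts)
  }

  expr <- parse_or()
  if (pos <= n) stop("trailing characters in atom expression [", txt, "]",
                     call. = FALSE)
  expr
}

# Collect positively declared constraints from an expression tree: these drive
# descriptor computation and pattern-on-pattern containment. Negated and
# OR-alternated constraints are recorded separately or ignored.
atom_profile <- function(expr) {
  prof <- list(element = NA_character_, aromatic = NA, hcount = NA_integer_,
               connectivity = NA_integer_, charge = NA_integer_,
               ring = NA, pos_envs = list(), neg_envs = list())
  walk <- function(node, negated, in_or) {
    if (node$op == "prim") {
      p <- node$prim
      if (negated) {
        if (p$kind == "ring" && isTRUE(p$value)) prof$ring <<- FALSE
        if (p$kind == "recursive") {
          prof$neg_envs[[length(prof$neg_envs) + 1L]] <<- p$env
        }
        return(invisible())
      }
      if (in_or) return(invisible())
      switch(p$kind,
        element = {
          prof$element <<- p$element
          prof$aromatic <<- p$aromatic
        },
        hcount = prof$hcount <<- p$n,
        connectivity = prof$connectivity <<- p$n,
        charge = prof$charge <<- p$n,
        ring = prof$ring <<- p$value,
        aromflag = prof$aromatic <<- p$value,
        recursive = prof$pos_envs[[length(prof$pos_envs) + 1L]] <<- p$env,
        NULL)
      return(invisible())
    }
    if (node$op == "not") return(walk(node$arg, !negated, in_or))
    if (node$op == "or") {
      for (a in node$args) walk(a, negated, in_or = TRUE)
      return(invisible())
    }
    for (a in node$args) walk(a, negated, in_or)
    invisible()
  }
  walk(expr, FALSE, FALSE)
  prof
}

# --- SMARTS tokenizer --------------------------------------------------------

#' Compile a SMARTS pattern
#'
#' Parses a SMARTS string into the pattern-graph representation used by the
#' matching engine. Only connected patterns are supported.
#'
#' @param smarts a single SMARTS string.
#' @return an object of class `frag_pattern`.
#' @examples
#' p <- parse_smarts("[CH3;X4]")
#' p$n_atoms
#' @export
parse_smarts <- function(smarts) {
  stopifnot(is.character(smarts), length(smarts) == 1L)
  s <- trimws(smarts)
  if (!nzchar(s)) stop("empty SMARTS", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)

  exprs <- list()
  bi <- integer(); bj <- integer(); btype <- character()
  prev <- NA_integer_; stack <- integer(); pending <- ""
  ring_open <- list()

  add_atom <- function(expr) {
    exprs[[length(exprs) + 1L]] <<- expr
    idx <- length(exprs)
    if (!is.na(prev)) {
      bi[length(bi) + 1L] <<- prev
      bj[length(bj) + 1L] <<- idx
      btype[length(btype) + 1L] <<- if (nzchar(pending))
        smarts_bond_types[[pending]] else "any"
    }
    pending <<- ""
    prev <<- idx
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
      btype[length(btype) + 1L] <<- if (nzchar(sym))
        smarts_bond_types[[sym]] else "any"
      ring_open[[key]] <<- NULL
    }
    pending <<- ""
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% names(smarts_bond_types)) {
      pending <- ch; i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMARTS: ", smarts,
                               call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("bad ring closure in SMARTS: ", smarts,
                           call. = FALSE)
      close_ring(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 3L
    } else if (ch == "[") {
      depth <- 1L; j <- i + 1L
      while (j <= n && depth > 0L) {
        if (chars[j] == "[") depth <- depth + 1L
        if (chars[j] == "]") depth <- depth - 1L
        j <- j + 1L
      }
      if (depth != 0L) stop("unbalanced '[' in SMARTS: ", smarts,
                            call. = FALSE)
      body <- substr(s, i + 1L, j - 2L)
      add_atom(parse_atom_expr(body))
      i <- j
    } else if (ch == ".") {
      stop("disconnected SMARTS patterns are not supported: ", smarts,
           call. = FALSE)
    } else {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(list(op = "prim",
                      prim = list(kind = "element", element = two,
                                  aromatic = FALSE)))
        i <- i + 2L
      } else if (ch %in% ORGANIC_SUBSET) {
        add_atom(list(op = "prim",
                      prim = list(kind = "element", element = ch,
                                  aromatic = FALSE)))
        i <- i + 1L
      } else if (ch %in% AROMATIC_SUBSET) {
        add_atom(list(op = "prim",
                      prim = list(kind = "element", element = toupper(ch),
                                  aromatic = TRUE)))
        i <- i + 1L
      } else if (ch == "*") {
        add_atom(list(op = "prim", prim = list(kind = "any")))
        i <- i + 1L
      } else {
        stop("unexpected character '", ch, "' in SMARTS: ", smarts,
             call. = FALSE)
      }
    }
  }
  if (length(ring_open)) stop("unclosed ring bond in SMARTS: ", smarts,
                              call. = FALSE)
  if (length(stack)) stop("unbalanced '(' in SMARTS: ", smarts, call. = FALSE)

  n_atoms <- length(exprs)
  bonds <- data.frame(i = bi, j = bj, type = btype, stringsAsFactors = FALSE)

  # connectivity check + match order (BFS from atom 1)
  adj <- vector("list", n_atoms)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds$i[b]]] <- c(adj[[bonds$i[b]]], b)
    adj[[bonds$j[b]]] <- c(adj[[bonds$j[b]]], b)
  }
  visited <- logical(n_atoms)
  order <- integer(0)
  queue <- 1L
  visited[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (b in adj[[v]]) {
      w <- if (bonds$i[b] == v) bonds$j[b] else bonds$i[b]
      if (!visited[w]) { visited[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  if (!all(visited)) stop("disconnected SMARTS pattern: ", smarts,
                          call. = FALSE)

  profile <- lapply(exprs, atom_profile)
  # An atom written purely as a positive recursive environment (e.g. the Cl of
  # [$(Cl[C]=[C])]) takes its identity from the environment's anchor atom.
  for (a in seq_along(profile)) {
    if (is.na(profile[[a]]$element) && length(profile[[a]]$pos_envs)) {
      anchor_prof <- profile[[a]]$pos_envs[[1L]]$profile[[1L]]
      profile[[a]]$element <- anchor_prof$element
      profile[[a]]$aromatic <- anchor_prof$aromatic
      if (is.na(profile[[a]]$hcount)) {
        profile[[a]]$hcount <- anchor_prof$hcount
      }
    }
  }
  pattern_ring <- logical(n_atoms)
  if (nrow(bonds)) {
    redge <- ring_edge_flags(n_atoms, bonds)
    for (b in seq_len(nrow(bonds))) {
      if (redge[b]) pattern_ring[bonds$i[b]] <- pattern_ring[bonds$j[b]] <- TRUE
    }
  }
  bond_order_sum <- numeric(n_atoms)
  bond_n <- integer(n_atoms)
  ordval <- c(any = 1, single = 1, double = 2, triple = 3, aromatic = 1.5,
              wild = 1)
  for (b in seq_len(nrow(bonds))) {
    bond_n[bonds$i[b]] <- bond_n[bonds$i[b]] + 1L
    bond_n[bonds$j[b]] <- bond_n[bonds$j[b]] + 1L
    arom_ends <- isTRUE(profile[[bonds$i[b]]]$aromatic) &&
      isTRUE(profile[[bonds$j[b]]]$aromatic)
    o <- if (bonds$type[b] == "any" && arom_ends) 1.5 else ordval[[bonds$type[b]]]
    bond_order_sum[bonds$i[b]] <- bond_order_sum[bonds$i[b]] + o
    bond_order_sum[bonds$j[b]] <- bond_order_sum[bonds$j[b]] + o
  }

  structure(list(
    n_atoms = n_atoms, atoms = exprs, profile = profile, bonds = bonds,
    match_order = order, pattern_ring = pattern_ring,
    bond_order_sum = bond_order_sum, bond_n = bond_n, smarts = smarts
  ), class = "frag_pattern")
}

as_pattern <- function(x) {
  if (inherits(x, "frag_pattern")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_smarts(x))
  stop("expected a SMARTS string or frag_pattern", call. = FALSE)
}

#' @export
print.frag_pattern <- function(x, ...) {
  cat("<frag_pattern> ", x$smarts, " (", x$n_atoms, " atoms)\n", sep = "")
  invisible(x)
}
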