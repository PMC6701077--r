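# Fragmentation schemes: parsing, validation, packaging.
#
# A scheme file is CSV with header group_id,name,patterns; alternative SMARTS
# for one group are '|'-separated (the published table separates them with
# commas, which would collide with CSV). The packaged default,
# extdata/unifac_table1.csv, encodes the full published UNIFAC scheme.

.groupfrag_env <- new.env(parent = emptyenv())

#' Parse a fragmentation scheme file
#'
#' Reads a scheme CSV into a `fragmentation_scheme`, compiling every SMARTS
#' pattern. File order is preserved; descriptors, the priority sort and the
#' parent-child containment map are attached by [load_scheme()].
#'
#' @param source path to a scheme CSV file, or a character vector of CSV
#'   lines.
#' @param strict error on malformed SMARTS or duplicate group ids (default);
#'   with `strict = FALSE` problems are collected into the `problems`
#'   attribute instead, which [validate_scheme()] reports.
#' @return an object of class `fragmentation_scheme`.
#' @seealso [load_scheme()], [validate_scheme()], [serialize_scheme()]
#' @export
parse_scheme <- function(source, strict = TRUE) {
  if (length(source) == 1L && file.exists(source)) {
    df <- utils::read.csv(source, stringsAsFactors = FALSE,
                          colClasses = "character")
  } else {
    df <- utils::read.csv(text = source, stringsAsFactors = FALSE,
                          colClasses = "character")
  }
  required <- c("group_id", "name", "patterns")
  if (!all(required %in% names(df))) {
    stop("scheme file must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  problems <- character(0)
  groups <- list()
  for (r in seq_len(nrow(df))) {
    gid <- suppressWarnings(as.integer(df$group_id[r]))
    if (is.na(gid) || gid <= 0L) {
      problems <- c(problems,
                    sprintf("row %d: group_id '%s' is not a positive integer",
                            r, df$group_id[r]))
      next
    }
    pats <- strsplit(df$patterns[r], "|", fixed = TRUE)[[1]]
    pats <- trimws(pats)
    pats <- pats[nzchar(pats)]
    if (!length(pats)) {
      problems <- c(problems, sprintf("group %d: no patterns", gid))
      next
    }
    compiled <- vector("list", length(pats))
    bad <- FALSE
    for (k in seq_along(pats)) {
      cp <- tryCatch(parse_smarts(pats[k]), error = function(e) e)
      if (inherits(cp, "error")) {
        problems <- c(problems,
                      sprintf("group %d: pattern '%s' does not parse: %s",
                              gid, pats[k], conditionMessage(cp)))
        bad <- TRUE
      } else {
        compiled[[k]] <- cp
      }
    }
    groups[[length(groups) + 1L]] <- list(
      group_id = gid, name = df$name[r], patterns = pats,
      compiled = if (bad) NULL else compiled, descriptor = NULL
    )
  }
  ids <- vapply(groups, `[[`, integer(1), "group_id")
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) {
    problems <- c(problems, sprintf("duplicate group_id %d", d))
  }
  if (strict && length(problems)) {
    stop("invalid scheme:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  structure(list(groups = groups, sorted_order = NULL, parent_child = NULL),
            class = "fragmentation_scheme", problems = problems)
}

#' Validate a fragmentation scheme
#'
#' Returns human-readable diagnostics rather than raising errors:
#' unparseable SMARTS, non-positive or duplicate group ids, empty pattern
#' lists. Disagreement of descriptor vectors between alternative patterns of
#' one group is reported informationally (the published scheme contains such
#' groups; sorting always uses the first pattern).
#'
#' @param scheme a `fragmentation_scheme`, or a path/text accepted by
#'   [parse_scheme()].
#' @return character vector of diagnostics; empty for a clean scheme.
#' @export
validate_scheme <- function(scheme) {
  if (!inherits(scheme, "fragmentation_scheme")) {
    scheme <- parse_scheme(scheme, strict = FALSE)
  }
  diags <- attr(scheme, "problems")
  if (is.null(diags)) diags <- character(0)
  for (g in scheme$groups) {
    if (is.null(g$compiled)) next
    vecs <- lapply(g$compiled, compute_descriptor_vector)
    nums <- lapply(vecs, descriptor_numeric)
    same <- vapply(nums, identical, logical(1), nums[[1L]])
    if (!all(same)) {
      diags <- c(diags, sprintf(
        "note: group %d (%s): alternative patterns differ in descriptors; the first pattern is used for sorting",
        g$group_id, g$name))
    }
  }
  diags
}

#' Load, sort and index a fragmentation scheme
#'
#' Full scheme preparation: parse, compute descriptor vectors (from each
#' group's first pattern), establish the descending descriptor sort order and
#' build the parent-child pattern containment map.
#'
#' @inheritParams parse_scheme
#' @param build_relations compute the parent-child map (default `TRUE`; it is
#'   the expensive step and only the fragmenters need it).
#' @return a ready-to-use `fragmentation_scheme`.
#' @export
load_scheme <- function(source, build_relations = TRUE) {
  scheme <- parse_scheme(source, strict = TRUE)
  for (k in seq_along(scheme$groups)) {
    scheme$groups[[k]]$descriptor <-
      compute_descriptor_vector(scheme$groups[[k]]$compiled[[1L]])
  }
  scheme <- sort_scheme(scheme)
  if (build_relations) scheme$parent_child <- build_parent_child_map(scheme)
  scheme
}

#' The packaged UNIFAC fragmentation scheme
#'
#' Loads (and caches for the session) the published UNIFAC scheme shipped
#' with the package: 111 groups, ids 1-109 plus 118 and 119.
#'
#' @return a prepared `fragmentation_scheme`.
#' @export
default_scheme <- function() {
  if (is.null(.groupfrag_env$default_scheme)) {
    path <- system.file("extdata", "unifac_table1.csv", package = "groupfrag",
                        mustWork = TRUE)
    .groupfrag_env$default_scheme <- load_scheme(path)
  }
  .groupfrag_env$default_scheme
}

#' Path to the packaged UNIFAC scheme file
#' @return file path of `unifac_table1.csv`.
#' @export
default_scheme_path <- function() {
  system.file("extdata", "unifac_table1.csv", package = "groupfrag",
              mustWork = TRUE)
}

#' Tabulate a scheme
#'
#' @param scheme a `fragmentation_scheme`.
#' @param sorted order rows by the descriptor sort (requires descriptors).
#' @param descriptors append the 8 descriptor columns `d1`..`d8` (booleans as
#'   integers).
#' @return a data.frame with columns `group_id`, `name`, `patterns` and
#'   optionally `d1`..`d8`.
#' @export
scheme_table <- function(scheme, sorted = FALSE, descriptors = FALSE) {
  stopifnot(inherits(scheme, "fragmentation_scheme"))
  idx <- if (sorted) {
    if (is.null(scheme$sorted_order)) stop("scheme is not sorted",
                                           call. = FALSE)
    scheme$sorted_order
  } else {
    seq_along(scheme$groups)
  }
  df <- data.frame(
    group_id = vapply(scheme$groups[idx], `[[`, integer(1), "group_id"),
    name = vapply(scheme$groups[idx], `[[`, character(1), "name"),
    patterns = vapply(scheme$groups[idx], function(g) {
      paste(g$patterns, collapse = "|")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  if (descriptors) {
    m <- t(vapply(scheme$groups[idx], function(g) {
      descriptor_numeric(g$descriptor)
    }, numeric(8)))
    colnames(m) <- paste0("d", 1:8)
    df <- cbind(df, as.data.frame(m))
  }
  df
}

#' Write a scheme back to CSV
#'
#' Serializes group ids, names and '|'-joined pattern lists; parsing the
#' output reproduces them exactly.
#'
#' @inheritParams scheme_table
#' @param path output file path.
#' @export
serialize_scheme <- function(scheme, path, sorted = FALSE,
                             descriptors = FALSE) {
  utils::write.csv(scheme_table(scheme, sorted = sorted,
                                descriptors = descriptors),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

scheme_group_ids <- function(scheme) {
  vapply(scheme$groups, `[[`, integer(1), "group_id")
}

scheme_group_names <- function(scheme) {
  nm <- vapply(scheme$groups, `[[`, character(1), "name")
  names(nm) <- as.character(scheme_group_ids(scheme))
  nm
}

group_by_id <- function(scheme, group_id) {
  ids <- scheme_group_ids(scheme)
  k <- match(group_id, ids)
  if (is.na(k)) stop("no group with id ", group_id, call. = FALSE)
  scheme$groups[[k]]
}

#' @export
print.fragmentation_scheme <- function(x, ...) {
  np <- sum(vapply(x$groups, function(g) length(g$patterns), integer(1)))
  cat("<fragmentation_scheme> ", length(x$groups), " groups, ", np,
      " patterns", sep = "")
  cat(if (!is.null(x$sorted_order)) ", sorted" else "", sep = "")
  cat(if (!is.null(x$parent_child)) ", relations built" else "", "\n",
      sep = "")
  invisible(x)
}
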