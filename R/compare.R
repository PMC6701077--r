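# Comparison of computed fragmentations against a reference database and
# run-level summary statistics (counts and fractions of structures
# fragmented and fragmented identically to the reference).

#' Compare two group-count multisets
#'
#' @param computed,expected named integer vectors (names are group ids).
#' @return `TRUE` iff the multisets are identical: same ids, same counts.
#' @export
compare_counts <- function(computed, expected) {
  computed <- computed[computed > 0]
  expected <- expected[expected > 0]
  if (length(computed) != length(expected)) return(FALSE)
  ord_c <- order(as.integer(names(computed)))
  ord_e <- order(as.integer(names(expected)))
  identical(as.character(names(computed)[ord_c]),
            as.character(names(expected)[ord_e])) &&
    identical(as.integer(computed[ord_c]), as.integer(expected[ord_e]))
}

#' Read a reference-fragmentation file
#'
#' CSV with columns `smiles` and `expected_counts` (`id:count` pairs joined
#' by `;`).
#'
#' @param path file path.
#' @return data.frame with columns `smiles`, `expected_counts`.
#' @export
read_reference <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("smiles", "expected_counts") %in% names(df))) {
    stop("reference file must have columns smiles, expected_counts",
         call. = FALSE)
  }
  df
}

#' Summarize a comparison run
#'
#' Aggregates per-molecule outcomes into the run-level statistics: number of
#' inputs, exclusions, successful fragmentations, and fragmentations
#' identical to the reference. Fractions use the total number of input
#' structures as denominator.
#'
#' @param entries data.frame with columns `smiles`, `expected_counts`
#'   (aligned with `results`).
#' @param results list of `fragmentation_result`s.
#' @return a `run_summary`: fields `n_input`, `n_excluded`, `n_fragmented`,
#'   `n_like_reference`, `frac_fragmented`, `frac_like_reference` and a
#'   per-molecule `verdicts` data.frame.
#' @export
summarize_run <- function(entries, results) {
  stopifnot(nrow(entries) == length(results))
  n_input <- nrow(entries)
  status <- vapply(results, `[[`, character(1), "status")
  match_ref <- vapply(seq_along(results), function(k) {
    if (status[k] != "success") return(FALSE)
    compare_counts(results[[k]]$group_counts,
                   parse_group_counts(entries$expected_counts[k]))
  }, logical(1))
  summary <- structure(list(
    n_input = n_input,
    n_excluded = sum(status == "excluded_input"),
    n_fragmented = sum(status == "success"),
    n_like_reference = sum(match_ref),
    frac_fragmented = if (n_input) sum(status == "success") / n_input else 0,
    frac_like_reference = if (n_input) sum(match_ref) / n_input else 0,
    verdicts = data.frame(
      smiles = if (n_input) entries$smiles else character(0),
      status = if (n_input) status else character(0),
      match = if (n_input) match_ref else logical(0),
      stringsAsFactors = FALSE)
  ), class = "run_summary")
  summary
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary> ", x$n_input, " structures: ",
      x$n_fragmented, " fragmented (", sprintf("%.1f%%",
                                               100 * x$frac_fragmented),
      "), ", x$n_like_reference, " like reference (",
      sprintf("%.1f%%", 100 * x$frac_like_reference), "), ",
      x$n_excluded, " excluded\n", sep = "")
  invisible(x)
}

#' Run a fragmentation algorithm against a reference database
#'
#' @param reference data.frame from [read_reference()] (or path to one).
#' @param scheme a prepared `fragmentation_scheme`.
#' @param algorithm `"simple"`, `"complete"` or `"combined"`.
#' @param sorted use the descriptor sort order.
#' @param max_heavy_atoms size cap for the complete search; with
#'   `algorithm = "complete"`, larger molecules are dropped from the run
#'   (the published evaluation restricted the complete algorithm to
#'   molecules of at most 20 heavy atoms).
#' @return a `run_summary`; its `results` attribute holds the per-molecule
#'   `fragmentation_result`s.
#' @export
run_reference_comparison <- function(reference, scheme = default_scheme(),
                                     algorithm = c("simple", "complete",
                                                   "combined"),
                                     sorted = TRUE, max_heavy_atoms = 20L) {
  algorithm <- match.arg(algorithm)
  if (is.character(reference)) reference <- read_reference(reference)
  if (algorithm == "complete") {
    keep <- vapply(reference$smiles, function(s) {
      m <- normalize_structure(s)
      !is_rejection(m) && m$n_atoms <= max_heavy_atoms
    }, logical(1))
    keep <- keep | vapply(reference$smiles, function(s) {
      is_rejection(normalize_structure(s))   # keep rejections: they count
    }, logical(1))
    reference <- reference[keep, , drop = FALSE]
  }
  results <- lapply(reference$smiles, function(s) {
    fragment(s, scheme, algorithm = algorithm, sorted = sorted,
             max_heavy_atoms = max_heavy_atoms)
  })
  out <- summarize_run(reference, results)
  attr(out, "results") <- results
  out
}
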