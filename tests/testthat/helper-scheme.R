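# The packaged UNIFAC scheme, loaded once per session (default_scheme caches).
unifac <- function() default_scheme()

counts_of <- function(result) format_group_counts(result$group_counts)

solution_keys <- function(result) {
  if (is.null(result$solutions)) return(character(0))
  sort(vapply(result$solutions, solution_key, character(1)))
}

# Fixture molecules small enough for the brute-force oracle.
small_fixture_smiles <- function(max_atoms = 8L) {
  ref <- generate_fixture_reference(2:8)
  extra <- c("O", "ClC=C", "CC(=O)O", "OCCO", "C1=CN=CC#C1", "C1CCCO1",
             "c1ccsc1", "CC(=O)NC", "CCOC", "CN(C)C=O")
  smiles <- unique(c(ref$smiles, extra))
  keep <- vapply(smiles, function(s) {
    m <- normalize_structure(s)
    !is_rejection(m) && m$n_atoms <= max_atoms
  }, logical(1))
  smiles[keep]
}
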