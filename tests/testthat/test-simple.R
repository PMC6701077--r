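test_that("simple fragmentation resolves reference molecules", {
  sch <- unifac()
  # chlorophenol: prioritization must not fall into the ACH-first trap
  r <- fragment_simple("c1c(Cl)c([OH])ccc1", sch)
  expect_equal(r$status, "success")
  expect_equal(counts_of(r), "9:4;17:1;53:1")
  # water: a single zero-free-bond group
  expect_equal(counts_of(fragment_simple("O", sch)), "16:1")
  # butane
  expect_equal(counts_of(fragment_simple("CCCC", sch)), "1:2;2:2")
  # the known uncoverable ring
  expect_equal(fragment_simple("C1=CN=CC#C1", sch)$status, "no_solution")
  # rejected inputs surface as excluded_input, not failures
  expect_equal(fragment_simple("[Na+].[Cl-]", sch)$status, "excluded_input")
  expect_equal(fragment_simple("not-a-smiles", sch)$status, "excluded_input")
})

test_that("success implies a partition of the heavy atoms", {
  sch <- unifac()
  for (s in c("CCCC", "c1c(Cl)c([OH])ccc1", "CC(=O)NC", "C1CCCO1",
              "Cc1ccsc1", "CCOC(=O)C")) {
    r <- fragment_simple(s, sch)
    expect_equal(r$status, "success", label = s)
    atoms <- sort(unlist(lapply(r$placed, `[[`, "atoms")))
    expect_equal(atoms, seq_len(normalize_structure(s)$n_atoms), label = s)
  }
})

test_that("parent-first search suppresses children inside intact parent sites", {
  sch <- unifac()
  mol <- normalize_structure("CC(=O)NCC")     # N-ethylacetamide
  ids <- scheme_group_ids(sch)
  g_ch2 <- sch$groups[[match(2L, ids)]]
  st <- new_assignment_state(mol)
  # the CH2 (atom 5) lies inside the intact CONHCH2 site: suppressed
  cands <- parent_first_search(mol, g_ch2, sch, st)
  expect_length(cands, 0L)
  # ... but raw matching does see it
  expect_length(find_match_candidates(mol, g_ch2), 1L)
  # with only the acetyl placed, the amine parent [CH2][NH] still guards it
  st_acetyl <- state_place(st, list(group_id = 18L, pattern_index = 1L,
                                    atoms = c(1L, 2L, 3L)))
  expect_length(parent_first_search(mol, g_ch2, sch, st_acetyl), 0L)
  # once every parent site is broken up by placements, suppression lifts
  st_broken <- state_place(st, list(group_id = 18L, pattern_index = 1L,
                                    atoms = c(1L, 2L, 3L, 4L)))
  cands <- parent_first_search(mol, g_ch2, sch, st_broken)
  expect_length(cands, 1L)
  expect_equal(cands[[1]]$atoms, 5L)
  # a group with no matching parents returns its plain candidates
  g_ch3 <- sch$groups[[match(1L, ids)]]
  mol2 <- normalize_structure("CCCC")
  st2 <- new_assignment_state(mol2)
  expect_equal(lapply(parent_first_search(mol2, g_ch3, sch, st2), `[[`,
                      "atoms"),
               lapply(find_match_candidates(mol2, g_ch3), `[[`, "atoms"))
})

test_that("the full amide example fragments around the protected site", {
  sch <- unifac()
  r <- fragment_simple("CC(=O)NCC", sch)
  expect_equal(counts_of(r), "1:2;96:1")
  # the carbamate of the order-dependence example
  r2 <- fragment_simple("C[NH]C(=O)OC", sch)
  expect_equal(r2$status, "success")
  expect_equal(counts_of(r2), "24:1;95:1")
})

test_that("simple fragmentation is deterministic", {
  sch <- unifac()
  for (s in c("CCCO", "c1c(Cl)c([OH])ccc1", "Cc1ccccc1")) {
    r1 <- fragment_simple(s, sch)
    r2 <- fragment_simple(s, sch)
    expect_identical(solution_key(r1$placed), solution_key(r2$placed))
    r3 <- fragment_simple(s, sch, sorted = FALSE)
    r4 <- fragment_simple(s, sch, sorted = FALSE)
    expect_identical(solution_key(r3$placed), solution_key(r4$placed))
  }
})

test_that("homologous series follow their closed forms", {
  sch <- unifac()
  for (n in 2:12) {
    alkane <- fragment_simple(strrep("C", n), sch)
    expected <- if (n == 2) c("1" = 2L) else c("1" = 2L, "2" = n - 2L)
    expect_true(compare_counts(alkane$group_counts, expected),
                label = sprintf("n-alkane n=%d", n))
    ol <- fragment_simple(paste0(strrep("C", n), "O"), sch)
    expect_true(compare_counts(ol$group_counts,
                               c("1" = 1L, "2" = n - 1L, "14" = 1L)),
                label = sprintf("1-alkanol n=%d", n))
  }
})

test_that("unsorted search still recovers protected aromatic assignments", {
  sch <- unifac()
  r <- fragment_simple("Cc1ccccc1", sch, sorted = FALSE)
  expect_equal(r$status, "success")
  expect_equal(counts_of(r), "9:5;11:1")
})
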