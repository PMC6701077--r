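test_that("pattern containment respects declared hydrogen counts", {
  # a CH2 is contained in an amide CONHCH2
  expect_true(pattern_contains("C(=O)[NH][CH2]", "[CH2]"))
  # the toolkit-style false positive is corrected: H0 is not H1
  expect_false(pattern_contains("[CH3][O;H0]", "[CH3][OH]"))
  # self-containment of identical patterns
  expect_true(pattern_contains("[CH3;X4]", "[CH3;X4]"))
  # direction matters
  expect_false(pattern_contains("[CH2]", "C(=O)[NH][CH2]"))
  # an undeclared child H-count is compatible with a declared parent one
  expect_true(pattern_contains("[CH](=O)[OH]", "C(=O)[OH]"))
  # aromatic and aliphatic element forms never mix
  expect_false(pattern_contains("[CH3][n]", "[CH3][N]"))
  # a recursive-environment child needs the same declared environment
  expect_false(pattern_contains("[CH]Cl", "[$(Cl[C]=[C])]"))
  expect_true(pattern_contains("[$(Cl[C]=[C])]", "[$(Cl[C]=[C])]"))
})

test_that("the UNIFAC parent-child map has the expected structure", {
  sch <- unifac()
  # parents of CH3 include the aromatic-methyl pattern
  expect_true("[c][CH3;X4]" %in% parent_patterns(sch, 1L))
  # nothing embeds a zero-valence water oxygen
  expect_length(parent_patterns(sch, 16L), 0L)
  # the ring-ether pattern protects its site from the open-chain ether
  expect_true("[CH2;R][OH0]" %in% parent_patterns(sch, 25L))
  # irreflexive
  for (g in sch$groups) {
    for (k in seq_along(g$patterns)) {
      ps <- sch$parent_child[[pattern_key(g$group_id, k)]]
      self <- vapply(ps, function(p) {
        p$group_id == g$group_id && p$pattern_index == k
      }, logical(1))
      expect_false(any(self))
    }
  }
  # single-group scheme: empty map
  mini <- load_scheme(c("group_id,name,patterns", "1,CH3,[CH3;X4]"))
  expect_length(mini$parent_child[["1.1"]], 0L)
})

test_that("containment is anti-symmetric on the scheme (no cycles)", {
  sch <- unifac()
  for (g in sch$groups) {
    for (k in seq_along(g$patterns)) {
      key <- pattern_key(g$group_id, k)
      for (p in sch$parent_child[[key]]) {
        back <- sch$parent_child[[pattern_key(p$group_id, p$pattern_index)]]
        mutual <- vapply(back, function(b) {
          b$group_id == g$group_id && b$pattern_index == k
        }, logical(1))
        expect_false(any(mutual),
                     label = sprintf("mutual containment %s <-> %s",
                                     g$patterns[k], p$smarts))
      }
    }
  }
})

test_that("containment is sound where hydrogen counts are fully declared", {
  # For pattern pairs in which both sides declare an H-count on every atom,
  # containment guarantees a child match inside every parent match site.
  # (Pairs relying on the undeclared-means-zero heuristic, e.g. [cH0] inside
  # [c]Cl, trade this literal guarantee for the prioritization the search
  # needs; they are exercised through the fragmenter tests instead.)
  sch <- unifac()
  mols <- lapply(small_fixture_smiles(10L), normalize_structure)
  fully_declared <- function(pat) {
    all(vapply(pat$profile, function(p) !is.na(p$hcount), logical(1)))
  }
  checked <- 0L
  for (g in sch$groups) {
    for (k in seq_along(g$patterns)) {
      child <- g$compiled[[k]]
      if (!fully_declared(child)) next
      for (p in sch$parent_child[[pattern_key(g$group_id, k)]]) {
        parent <- parse_smarts(p$smarts)
        if (!fully_declared(parent)) next
        for (mol in mols) {
          for (site in match_atom_sets(parent, mol)) {
            hits <- match_atom_sets(child, mol)
            inside <- any(vapply(hits, function(h) all(h %in% site),
                                 logical(1)))
            checked <- checked + 1L
            expect_true(inside,
                        label = sprintf("'%s' inside '%s' site on %s",
                                        child$smarts, p$smarts, mol$smiles))
          }
        }
      }
    }
  }
  expect_gt(checked, 10L) # the fixture set must actually exercise the map
})
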