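test_that("SMILES parse to heavy-atom graphs with correct implicit hydrogens", {
  m <- normalize_structure("CCO")
  expect_s3_class(m, "frag_molecule")
  expect_equal(m$n_atoms, 3L)
  expect_equal(m$element, c("C", "C", "O"))
  expect_equal(m$nH, c(3L, 2L, 1L))

  m <- normalize_structure("CC")
  expect_equal(m$n_atoms, 2L)
  expect_equal(m$nH, c(3L, 3L))

  # branches, ring closures, double/triple bonds
  m <- normalize_structure("CC(C)(C)C")
  expect_equal(m$degree, c(1L, 4L, 1L, 1L, 1L))
  m <- normalize_structure("C#N")
  expect_equal(m$nH, c(1L, 0L))
  m <- normalize_structure("C1CCCCC1")
  expect_true(all(m$in_ring))
  expect_equal(m$nH, rep(2L, 6))
})

test_that("explicit and isotopic hydrogens are folded into H counts", {
  water <- normalize_structure("O")
  heavy_water <- normalize_structure("[2H]O[2H]")
  expect_equal(heavy_water$n_atoms, 1L)
  expect_equal(heavy_water$element, water$element)
  expect_equal(heavy_water$nH, water$nH)

  methane <- normalize_structure("[H]C([H])([H])[H]")
  expect_equal(methane$n_atoms, 1L)
  expect_equal(methane$nH, 4L)
})

test_that("aromaticity: lowercase and Kekule benzene perceive identically", {
  b1 <- normalize_structure("c1ccccc1")
  b2 <- normalize_structure("C1=CC=CC=C1")
  expect_true(all(b1$aromatic))
  expect_true(all(b2$aromatic))
  expect_equal(b1$nH, b2$nH)
  # matching agrees
  expect_equal(length(match_atom_sets("[cH]", b1)),
               length(match_atom_sets("[cH]", b2)))

  # pyridine Kekule; thiophene lowercase S has no H
  p <- normalize_structure("C1=CC=NC=C1")
  expect_true(all(p$aromatic))
  t <- normalize_structure("c1ccsc1")
  expect_equal(t$nH[t$element == "S"], 0L)

  # the biphenyl link bond stays single between two aromatic rings
  bp <- normalize_structure("c1ccc(cc1)c1ccccc1")
  link <- which(bp$degree == 3)
  expect_false(bp$arom_mat[link[1], link[2]])

  # a ring with a triple bond is not aromatic
  f5 <- normalize_structure("C1=CN=CC#C1")
  expect_false(any(f5$aromatic))
})

test_that("salts, radicals and malformed input yield typed rejections", {
  salt <- normalize_structure("[Na+].[Cl-]")
  expect_s3_class(salt, "frag_rejection")
  expect_equal(salt$status, "excluded")

  radical <- normalize_structure("[CH3]")
  expect_equal(radical$status, "excluded")
  expect_match(radical$reason, "radical")

  garbage <- normalize_structure("C1CC")   # unclosed ring
  expect_equal(garbage$status, "parse_error")
  expect_equal(normalize_structure("C(")$status, "parse_error")

  # charged species are not radicals; bracket atoms at full valence are fine
  expect_s3_class(normalize_structure("C[N+](=O)[O-]"), "frag_molecule")
  expect_s3_class(normalize_structure("[OH2]"), "frag_molecule")
})
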