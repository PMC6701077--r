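test_that("descriptor vectors of reference patterns reproduce known values", {
  # water: zero free bonds, one atom, one heteroatom
  d <- compute_descriptor_vector("[OH2]")
  expect_equal(descriptor_numeric(d), c(1, 0, 1, 0, 1, 0, 0, 0))
  # recursive chloride: environment atoms count toward the atom total
  d <- compute_descriptor_vector("[$(Cl[C]=[C])]")
  expect_equal(descriptor_numeric(d), c(0, 1, 3, 1, 1, 0, 0, 0))
  # furfural: ring flag from aromatic atoms, one double bond
  d <- compute_descriptor_vector("O=[CH]c1[cH][cH][cH]o1")
  expect_equal(descriptor_numeric(d), c(1, 0, 7, 0, 2, 1, 0, 1))
  # negated environments contribute no atoms
  d <- compute_descriptor_vector("[OH0;!$(OC=O);!R][CH2;!R][CH2;!R][OH]")
  expect_equal(d$d3_n_atoms, 4L)
  expect_false(d$d6_in_ring)
})

test_that("descriptors regenerate the full published table", {
  sch <- unifac()
  expected <- utils::read.csv(test_path("table1-descriptors.csv"))
  for (g in sch$groups) {
    got <- descriptor_numeric(g$descriptor)
    want <- as.numeric(expected[expected$group_id == g$group_id, -1])
    expect_equal(got, want,
                 label = sprintf("group %d (%s) descriptors", g$group_id,
                                 g$name))
  }
})

test_that("descriptor invariants hold across every scheme pattern", {
  sch <- unifac()
  for (g in sch$groups) {
    for (p in g$compiled) {
      d <- compute_descriptor_vector(p)
      expect_false(d$d1_zero_bonds && d$d4_one_bond)
      expect_gte(d$d3_n_atoms, 1L)
      expect_lte(d$d5_n_hetero, d$d3_n_atoms)
    }
  }
})

test_that("the priority sort is descending, stable and idempotent", {
  # restricted scheme: methanol > water > methyl by lexicographic descent
  mini <- load_scheme(c("group_id,name,patterns",
                        "1,CH3,[CH3;X4]",
                        "16,H2O,[OH2]",
                        "15,CH3OH,[CH3][OH]"),
                      build_relations = FALSE)
  expect_equal(vapply(mini$groups[mini$sorted_order], `[[`, character(1),
                      "name"),
               c("CH3OH", "H2O", "CH3"))

  # singleton scheme unchanged
  single <- load_scheme(c("group_id,name,patterns", "1,CH3,[CH3;X4]"),
                        build_relations = FALSE)
  expect_equal(single$sorted_order, 1L)

  sch <- unifac()
  ids <- scheme_group_ids(sch)
  # permutation
  expect_setequal(sch$sorted_order, seq_along(sch$groups))
  # stability: CH2 and CH print identical vectors and keep file order
  expect_lt(which(sch$sorted_order == match(2L, ids)),
            which(sch$sorted_order == match(3L, ids)))
  # idempotence
  expect_identical(sort_scheme(sch)$sorted_order, sch$sorted_order)
  # descending order of the numeric descriptor rows
  rows <- vapply(sch$groups[sch$sorted_order], function(g) {
    paste(sprintf("%03d", descriptor_numeric(g$descriptor) + 100),
          collapse = "")
  }, character(1))
  expect_identical(rows, sort(rows, decreasing = TRUE))
})

test_that("sorting is input-order independent up to descriptor ties", {
  sch <- unifac()
  tab <- scheme_table(sch)
  rev_scheme <- load_scheme(
    c("group_id,name,patterns",
      sprintf("%d,%s,%s", rev(tab$group_id), rev(tab$name),
              rev(tab$patterns))),
    build_relations = FALSE)
  fwd <- vapply(sch$groups[sch$sorted_order], function(g) {
    paste(descriptor_numeric(g$descriptor), collapse = ",")
  }, character(1))
  bwd <- vapply(rev_scheme$groups[rev_scheme$sorted_order], function(g) {
    paste(descriptor_numeric(g$descriptor), collapse = ",")
  }, character(1))
  expect_identical(fwd, bwd)
})
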