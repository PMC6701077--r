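test_that("complete search enumerates and ranks all solutions", {
  sch <- unifac()
  r <- fragment_complete("Cc1ccccc1", sch)
  expect_equal(r$status, "success")
  expect_length(r$solutions, 2L)
  # the 6-group solution outranks the 7-group one
  expect_equal(counts_of(r), "9:5;11:1")
  expect_equal(format_group_counts(counts_from_placed(r$solutions[[2]])),
               "1:1;9:5;10:1")

  r <- fragment_complete("O", sch)
  expect_length(r$solutions, 1L)
  expect_equal(counts_of(r), "16:1")

  expect_equal(fragment_complete("C1=CN=CC#C1", sch)$status, "no_solution")
})

test_that("molecules above the size cap raise a typed size error", {
  sch <- unifac()
  expect_error(fragment_complete(strrep("C", 21), sch),
               class = "frag_size_error")
  expect_s3_class(fragment_complete(strrep("C", 21), sch,
                                    max_heavy_atoms = 30L),
                  "fragmentation_result")
})

test_that("solution sets equal the brute-force oracle on small molecules", {
  sch <- unifac()
  for (s in small_fixture_smiles(8L)) {
    rc <- fragment_complete(s, sch)
    oc <- oracle_enumerate_covers(s, sch)
    ks_o <- attr(oc, "keys")
    if (is.null(ks_o)) ks_o <- character(0)
    expect_equal(solution_keys(rc), ks_o, label = s)
  }
})

test_that("failure memoization never changes the solution set", {
  sch <- unifac()
  for (s in c("CCCCCC", "Cc1ccccc1", "C1=CN=CC#C1", "OCCOC", "CC(=O)NC")) {
    with_memo <- fragment_complete(s, sch, use_failure_cache = TRUE)
    without <- fragment_complete(s, sch, use_failure_cache = FALSE)
    expect_identical(solution_keys(with_memo), solution_keys(without),
                     label = s)
  }
})

test_that("the sorted flag changes discovery order, never the solution set", {
  sch <- unifac()
  for (s in c("Cc1ccccc1", "CCCO", "c1ccsc1", "ClC=C")) {
    expect_identical(solution_keys(fragment_complete(s, sch, sorted = TRUE)),
                     solution_keys(fragment_complete(s, sch, sorted = FALSE)),
                     label = s)
  }
})

test_that("a simple-fragmenter solution is always among the complete set", {
  sch <- unifac()
  for (s in small_fixture_smiles(8L)) {
    rs <- fragment_simple(s, sch)
    if (rs$status != "success") next
    rc <- fragment_complete(s, sch)
    expect_true(solution_key(rs$placed) %in% solution_keys(rc), label = s)
  }
})

test_that("ranking breaks count ties by distinct groups then precedence", {
  # two interchangeable 2-atom groups: the earlier-precedence homogeneous
  # solution must rank first
  toy <- load_scheme(c("group_id,name,patterns",
                       "1,A,[CH3][CH2]",
                       "2,B,[CH2][CH3]"))
  r <- fragment_complete("CCCC", toy)
  expect_length(r$solutions, 4L)
  n_distinct <- vapply(r$solutions, function(s) {
    length(unique(vapply(s, `[[`, integer(1), "group_id")))
  }, integer(1))
  expect_equal(n_distinct, c(1L, 1L, 2L, 2L))
  # precedence tie-break among the homogeneous solutions: group 1 first
  expect_equal(unique(vapply(r$solutions[[1]], `[[`, integer(1), "group_id")),
               1L)
  # stability / single solution unchanged
  one <- rank_solutions(r$solutions[1], toy)
  expect_identical(one, r$solutions[1])
})

test_that("the combined front-end falls back from simple to complete", {
  sch <- unifac()
  r <- fragment("CCO", sch, algorithm = "combined")
  expect_equal(r$algorithm, "simple")
  # uncoverable stays uncoverable under the fallback
  r2 <- fragment("C1=CN=CC#C1", sch, algorithm = "combined")
  expect_equal(r2$status, "no_solution")
  # oversized no-solution inputs fall back to the simple verdict
  r3 <- fragment(paste0("C1=CN=CC#C1", strrep("C", 0)), sch,
                 algorithm = "combined", max_heavy_atoms = 3L)
  expect_equal(r3$status, "no_solution")
  expect_equal(r3$algorithm, "simple")
})
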