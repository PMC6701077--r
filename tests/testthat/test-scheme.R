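test_that("scheme files parse with patterns split on '|'", {
  sch <- parse_scheme(c("group_id,name,patterns",
                        "1,CH3,[CH3;X4]",
                        "34,CH3N,[CH3][N]|[CH3][n]"))
  expect_length(sch$groups, 2L)
  expect_equal(sch$groups[[1]]$group_id, 1L)
  expect_equal(sch$groups[[1]]$name, "CH3")
  expect_equal(sch$groups[[1]]$patterns, "[CH3;X4]")
  expect_equal(sch$groups[[2]]$patterns, c("[CH3][N]", "[CH3][n]"))

  # empty scheme: header only, no error
  empty <- parse_scheme("group_id,name,patterns")
  expect_length(empty$groups, 0L)
})

test_that("parse errors name the offending group and pattern", {
  expect_error(parse_scheme(c("group_id,name,patterns", "7,bad,[C(")),
               "group 7.*\\[C\\(")
  expect_error(parse_scheme(c("group_id,name,patterns",
                              "7,a,[CH3]", "7,b,[CH2]")),
               "duplicate group_id 7")
})

test_that("validate_scheme reports diagnostics without raising", {
  expect_length(setdiff(validate_scheme(default_scheme_path()),
                        grep("^note:", validate_scheme(default_scheme_path()),
                             value = TRUE)), 0L)
  diags <- validate_scheme(c("group_id,name,patterns", "7,bad,[C("))
  expect_length(diags, 1L)
  expect_match(diags, "does not parse")
  diags <- validate_scheme(c("group_id,name,patterns",
                             "7,a,[CH3]", "7,b,[CH2]"))
  expect_match(diags, "duplicate")
})

test_that("the packaged UNIFAC scheme is complete", {
  sch <- unifac()
  ids <- scheme_group_ids(sch)
  expect_length(ids, 111L)
  expect_setequal(ids, c(1:109, 118L, 119L))
  # every multi-pattern group of the published table
  multi <- ids[vapply(sch$groups, function(g) length(g$patterns) > 1,
                      logical(1))]
  expect_setequal(multi, c(4L, 7L, 8L, 34L, 38L, 39L, 73L, 77L, 101L, 107L,
                           108L))
  expect_length(sch$groups[[match(39L, ids)]]$patterns, 6L)
  # all SMARTS compiled and descriptors attached
  expect_true(all(vapply(sch$groups, function(g) !is.null(g$compiled),
                         logical(1))))
  expect_true(all(vapply(sch$groups, function(g) !is.null(g$descriptor),
                         logical(1))))
})

test_that("serialize/parse round-trips ids, names and patterns exactly", {
  sch <- unifac()
  tmp <- withr::local_tempfile(fileext = ".csv")
  serialize_scheme(sch, tmp)
  back <- parse_scheme(tmp)
  expect_identical(scheme_table(back), scheme_table(sch))

  # sorted serialization with descriptor columns (the sorted-scheme artifact)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  serialize_scheme(sch, tmp2, sorted = TRUE, descriptors = TRUE)
  tab <- utils::read.csv(tmp2)
  expect_equal(nrow(tab), 111L)
  expect_true(all(paste0("d", 1:8) %in% names(tab)))
  expect_equal(tab$group_id[1:2],
               scheme_group_ids(sch)[sch$sorted_order][1:2])
})
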