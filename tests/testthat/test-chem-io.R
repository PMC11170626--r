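test_that("canonicalization maps equivalent SMILES together and is idempotent", {
  expect_identical(canonicalize_smiles("C1=CC=CC=C1"),
                   canonicalize_smiles("c1ccccc1"))
  can <- canonicalize_smiles("CC(=O)Oc1ccccc1C(=O)O")
  expect_identical(canonicalize_smiles(can), can)
  expect_error(canonicalize_smiles("not_a_smiles"), "unparseable")
  expect_false(is_valid_smiles("C1CC"))  # unclosed ring
})

test_that("reader validates rows, maps the absent sentinel, and is total", {
  path <- write_fixture_csv(list(
    c("phenol", "Oc1ccccc1", "", "", "tea", "FDB000001", "", "doi:x",
      "1", "0", "0", "0"),
    c("general-only", "c1ccccc1", "", "", "bread", "Not in database", "", "",
      "0", "0", "0", "1"),
    c("badsmiles", "xx!!", "", "", "", "", "", "", "1", "0", "0", "0"),
    c("badcell", "CCO", "", "", "", "", "", "", "2", "0", "0", "0"),
    c("emptycells", "CCCO", "", "", "", "", "", "", "1", "", "", "0")))
  lib <- read_compound_db(path)
  v <- attr(lib, "validation")

  # totality: every row is either a record or a reported error
  expect_equal(v$n_valid + nrow(v$errors), v$n_rows)
  expect_equal(nrow(lib$compounds), 3)

  # sentinel maps to NA; real IDs survive
  expect_identical(lib$compounds$foodb_id,
                   c("FDB000001", NA_character_, NA_character_))

  # a compound with all-zero specific profile but a family flag is valid
  # and not profile-incomplete
  expect_false(lib$compounds$profile_incomplete[2])
  expect_equal(unname(lib$general[2, "DNMT family"]), 1L)

  # rejected rows carry row number and reason
  expect_setequal(v$errors$row, c(3, 4))
  expect_match(v$errors$reason[v$errors$row == 4], "not in \\{0, 1")
  expect_identical(v$errors$column[v$errors$row == 4], "DNMT1")

  # empty activity cells read as 0 but counted separately
  expect_equal(v$n_empty_activity_cells, 2)
  expect_equal(unname(lib$profile[3, "DNMT1"]), 1)
})

test_that("missing mandatory column is a configuration error", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("Name,DNMT1", "x,1"), path)
  expect_error(read_compound_db(path), "mandatory column")
})

test_that("malformed InChIKeys warn but do not reject the row", {
  path <- write_fixture_csv(list(
    c("ok", "CCO", "", "LFQSCWFLJHTTHZ-UHFFFAOYSA-N", "", "", "", "",
      "1", "0", "0", "0"),
    c("bad", "CCC", "", "NOT-A-KEY", "", "", "", "", "1", "0", "0", "0")))
  expect_warning(lib <- read_compound_db(path), "14-10-1")
  expect_equal(nrow(lib$compounds), 2)
})

test_that("write then read round-trips a library field for field", {
  lib <- generate_library(synthetic_spec(12, 4, seed = 11))
  path <- tempfile(fileext = ".csv")
  write_compound_db(lib, path)
  back <- read_compound_db(path)
  expect_identical(back$compounds$smiles, lib$compounds$smiles)
  expect_identical(back$compounds$name, lib$compounds$name)
  expect_identical(unname(back$profile), unname(lib$profile))
  expect_identical(back$compounds$foodb_id, lib$compounds$foodb_id)
})

test_that("write_report emits one file per table per format", {
  tabs <- list(a = data.frame(x = 1:3, y = letters[1:3]),
               empty = data.frame(x = integer(0)))
  out <- tempfile()
  man <- write_report(tabs, out, formats = "csv")
  expect_equal(nrow(man), 2)
  expect_true(all(file.exists(man$path)))
  # empty table -> header row only
  expect_equal(length(readLines(man$path[man$table == "empty"])), 1)

  man2 <- write_report(tabs["a"], out, formats = c("csv", "json"))
  expect_equal(nrow(man2), 2)
  expect_setequal(man2$format, c("csv", "json"))
  expect_equal(man2$n_rows, c(3, 3))
})
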