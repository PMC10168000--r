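test_that("registration enforces unique names and compiling templates", {
  reg <- id_registry()
  reg <- register_pattern(reg, id_pattern_spec("ChEMBL", "^CHEMBL\\d+$"))
  expect_length(reg, 1L)
  expect_error(
    register_pattern(reg, id_pattern_spec("ChEMBL", "^x$")),
    "already registered"
  )
  expect_error(id_pattern_spec("bad", "^[unclosed$"), "does not compile")
})

test_that("matching returns every full match in registry order", {
  reg <- id_registry()
  reg <- register_pattern(reg, id_pattern_spec("COSMIC-like", "^[A-Z0-9]+$"))
  reg <- register_pattern(reg, id_pattern_spec("ChEMBL", "^CHEMBL\\d+$"))
  expect_identical(match_patterns(reg, "CHEMBL25"), c("COSMIC-like", "ChEMBL"))
  expect_identical(match_patterns(reg, ""), character(0))
  expect_identical(match_patterns(reg, "chembl25"), character(0))
  expect_error(match_patterns(id_registry(), "x"), "empty")
})

test_that("the built-in registry resolves canonical example identifiers", {
  reg <- builtin_registry()
  expect_length(reg, 39L)
  expect_true("Ensembl gene" %in% match_patterns(reg, "ENSG00000164197"))
  expect_true("ChEMBL" %in% match_patterns(reg, "CHEMBL25"))
  expect_true("HGNC" %in% match_patterns(reg, "HGNC:27752"))
})

test_that("generation is seeded, distinct and template-consistent", {
  reg <- builtin_registry()
  a <- generate_ids(reg, "Ensembl gene", 25, seed = 7)
  b <- generate_ids(reg, "Ensembl gene", 25, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_ids(reg, "Ensembl gene", 25, seed = 8)))
  expect_length(unique(a), 25L)
  expect_true(all(grepl("^ENSG\\d{11}$", a)))
  expect_error(generate_ids(reg, "nope", 1, seed = 1), "unknown class")
})

test_that("generation refuses requests beyond a template's capacity", {
  reg <- register_pattern(
    id_registry(),
    id_pattern_spec("tiny", "^T\\d{2}$",
      generator_hint = list(hint_seg("T", literal = TRUE), hint_seg(DIGITS, 2))
    )
  )
  expect_length(generate_ids(reg, "tiny", 100, seed = 1), 100L)
  expect_error(generate_ids(reg, "tiny", 101, seed = 1), "capacity")
})

test_that("every generated identifier matches back to its own class", {
  reg <- builtin_registry()
  for (cl in names(reg$specs)) {
    ids <- generate_ids(reg, cl, 10, seed = 11)
    hits <- vapply(ids, function(q) cl %in% match_patterns(reg, q), logical(1))
    expect_true(all(hits), label = paste("round-trip for", cl))
  }
})

test_that("dataset generation conserves the requested profile exactly", {
  reg <- builtin_registry()
  profile <- c("Rfam" = 17, "ChEMBL" = 5, "Entrez Gene Database" = 9)
  tab <- generate_dataset(reg, profile, seed = 3)
  expect_identical(nrow(tab), 31L)
  counts <- table(tab$class)
  expect_identical(as.integer(counts[names(profile)]), c(17L, 5L, 9L))
  by_class <- split(tab$id, tab$class)
  expect_true(all(vapply(by_class, function(x) !anyDuplicated(x), logical(1))))
  expect_error(generate_dataset(reg, c(bogus = 3), seed = 1), "unknown class")
  single <- generate_dataset(reg, c(Rfam = 5), seed = 1)
  expect_identical(dim(single), c(5L, 2L))
})

test_that("a class's draw does not depend on the rest of the profile", {
  reg <- builtin_registry()
  small <- generate_dataset(reg, c("Rfam" = 6), seed = 5)
  big <- generate_dataset(reg, c("ChEMBL" = 4, "Rfam" = 6), seed = 5)
  expect_identical(small$id, big$id[big$class == "Rfam"])
})

test_that("a registry survives the TSV round trip", {
  reg <- builtin_registry()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_registry(reg, path)
  reg2 <- read_registry(path)
  expect_identical(names(reg2$specs), names(reg$specs))
  expect_identical(
    match_patterns(reg2, "CHEMBL25"),
    match_patterns(reg, "CHEMBL25")
  )
  expect_identical(
    generate_ids(reg2, "Rfam", 8, seed = 2),
    generate_ids(reg, "Rfam", 8, seed = 2)
  )
})
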