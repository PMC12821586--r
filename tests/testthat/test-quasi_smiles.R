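test_that("tokenizer splits element symbols, brackets, rings and branches", {
  expect_equal(tokenize_smiles("CCO"), c("C", "C", "O"))
  expect_equal(tokenize_smiles("ClC(=O)N"),
               c("Cl", "C", "(", "=", "O", ")", "N"))
  expect_equal(tokenize_smiles("c1ccccc1"),
               c("c", "1", "c", "c", "c", "c", "c", "1"))
  expect_equal(tokenize_smiles("C[nH]1C%12"),
               c("C", "[nH]", "1", "C", "%12"))
  expect_equal(tokenize_smiles("BrC#N"), c("Br", "C", "#", "N"))
  expect_equal(tokenize_smiles("C/C=C\\C"),
               c("C", "/", "C", "=", "C", "\\", "C"))
})

test_that("tokenizer rejects unknown characters and unbalanced brackets", {
  expect_error(tokenize_smiles("CC?O"), "position 3")
  expect_error(tokenize_smiles("C[NH"), "unbalanced")
  expect_error(tokenize_smiles("C]N"), "unbalanced")
  expect_error(tokenize_smiles("C(C"), "unbalanced")
  expect_error(tokenize_smiles("C)C"), "unbalanced")
  expect_error(tokenize_smiles(""), "non-empty")
  expect_error(tokenize_smiles("C%1N"), "ring label")
})

test_that("tokenize-then-concatenate is the identity on generated strings", {
  g <- generate_dataset(generator_spec(n_records = 60, seed = 42))
  for (s in g$dataset$smiles) {
    expect_identical(paste(tokenize_smiles(s), collapse = ""), s)
  }
})

test_that("attribute rendering is width-12, dot-padded and invertible", {
  expect_identical(render_attribute("C", "single"), "C...........")
  expect_identical(render_attribute(c("Cl", "("), "pair"), "Cl..(.......")
  expect_identical(render_attribute(c("1", "("), "pair"), "1...(.......")
  expect_identical(render_attribute("SP3", "condition"), "SP3.........")
  for (kind in c("single", "condition")) {
    for (tok in c("C", "Cl", "[nH]", "%12", "WT4")) {
      expect_identical(parse_attribute(render_attribute(tok, kind), kind),
                       tok)
    }
  }
  for (p in list(c("C", "("), c("Cl", "Br"), c("1", "c"))) {
    expect_identical(parse_attribute(render_attribute(p, "pair"), "pair"), p)
  }
  # distinct token lists never collide within a kind
  toks <- c("C", "c", "Cl", "N", "1", "(", "=")
  singles <- vapply(toks, render_attribute, "", kind = "single")
  expect_false(anyDuplicated(singles) > 0)
})

test_that("rendering rejects overlong or malformed tokens", {
  expect_error(render_attribute("0123456789ABC", "single"), "width")
  expect_error(render_attribute(c("[NH3+]", "C"), "pair"), "width")
  expect_error(render_attribute("a.b", "single"), "'.'")
  expect_error(render_attribute(c("C"), "pair"), "two tokens")
})

test_that("extract_attributes counts singles, adjacent pairs and conditions", {
  out <- extract_attributes("CCO", fix_conds())
  singles <- out[out$kind == "single", ]
  expect_equal(
    stats::setNames(singles$count, singles$attribute)[
      c("C...........", "O...........")],
    c(C........... = 2L, O........... = 1L))
  pairs <- out[out$kind == "pair", ]
  expect_setequal(pairs$attribute, c("C...C.......", "O...C......."))
  expect_true(all(pairs$count == 1L))
  expect_equal(sum(out$kind == "condition"), 6L)
  # pair counts accumulate: ClCCl has the (C, Cl) pair twice
  out2 <- extract_attributes("ClCCl", fix_conds())
  expect_equal(out2$count[out2$attribute == "Cl..C......."], 2L)
  # a branch-open pair renders with the paren in the second field
  out3 <- extract_attributes("C(N)O", fix_conds())
  expect_true("C...(......." %in% out3$attribute)
})

test_that("a string of n tokens yields n singles and n-1 pairs by total", {
  g <- generate_dataset(generator_spec(n_records = 25, seed = 9))
  for (s in g$dataset$smiles[1:10]) {
    n <- length(tokenize_smiles(s))
    out <- extract_attributes(s)
    expect_equal(sum(out$count[out$kind == "single"]), n)
    expect_equal(sum(out$count[out$kind == "pair"]), n - 1L)
  }
})

test_that("extraction is deterministic and condition-order invariant", {
  c1 <- fix_conds()
  c2 <- c1[c("OB", "SP", "WT", "LS", "SS", "SO")]
  a <- extract_attributes("ClC(=O)N", c1)
  b <- extract_attributes("ClC(=O)N", c2)
  expect_identical(a[order(a$attribute), ], b[order(b$attribute), ])
})

test_that("condition validation rejects malformed levels", {
  expect_error(extract_attributes("C", c(WT = "1")), "six features")
  bad <- fix_conds(); bad["SP"] <- "a b"
  expect_error(extract_attributes("C", bad), "whitespace")
})
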