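test_that("PDB reading converts Angstrom to nm and honours the model policy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeMiniPDB(f, list(miniAtoms()))
  s <- readStructures(f)
  expect_s4_class(s, "Structure")
  expect_equal(nrow(s@atoms), 4L)
  expect_equal(s@atoms$x, (1:4) * 1.5 / 10)   # file is Angstrom, memory is nm
  expect_equal(s@atoms$y, rep(0.2, 4))

  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeMiniPDB(f3, list(miniAtoms(), miniAtoms(), miniAtoms()))
  all3 <- readStructures(f3, model = "all")
  expect_length(all3, 3L)
  expect_equal(readStructures(f3, model = "first")@atoms, all3[[1L]]@atoms)
})

test_that("HETATM-only files raise an empty-structure error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeMiniPDB(f, list(miniAtoms(elety = "O")), type = "HETATM")
  expect_error(readStructures(f), "empty-structure|format")
})

test_that("PDB write/read round-trips coordinates to PDB precision", {
  syn <- syntheticEnsemble(tinySpec(M = 3L, seed = 8L))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePDB(syn$ensemble, f)
  back <- readEnsemblePDB(f, ranges = list(A = tinySpec()$helixRanges,
                                           B = tinySpec()$helixRanges))
  expect_equal(nFrames(back), 3L)
  # 3-decimal Angstrom precision = 5e-5 nm half-width
  expect_lt(max(abs(frameMatrix(back) - frameMatrix(syn$ensemble))), 5.1e-5)
})

test_that("C-alpha selection counts match the inclusive range arithmetic", {
  syn <- makeTemplate(tinySpec())
  f <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePDB(syn, f)
  s <- readStructures(f)
  sel <- selectCalpha(s, tarHelixRanges())
  # 2 x (32 + 25 + 27 + 30) sites on the Tar helix ranges
  expect_equal(nSites(sel), 228L)
  expect_equal(nSites(selectCalpha(s, list(A = c(44L, 44L)))), 1L)
  lab <- siteLabels(sel)
  expect_true(!is.unsorted(order(lab$chain, lab$resno)))
  expect_error(selectCalpha(s, list(C = c(44L, 75L))), "selection error")
})

test_that("missing residues inside a range are skipped with a warning", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeMiniPDB(f, list(miniAtoms(resno = c(1:3, 5:6))))
  s <- readStructures(f)
  expect_warning(sel <- selectCalpha(s, list(A = c(1L, 6L))), "missing")
  expect_equal(nSites(sel), 5L)
  expect_equal(sel@selection$skipped$resno, 4L)
})

test_that("chain swapping is an involution preserving coordinate multisets", {
  syn <- syntheticEnsemble(tinySpec(M = 4L, seed = 9L))
  e <- syn$ensemble
  sw <- swapChains(e)
  expect_equal(frameMatrix(swapChains(sw)), frameMatrix(e))
  for (m in 1:4) {
    a <- sort(frameMatrix(e)[m, ])
    b <- sort(frameMatrix(sw)[m, ])
    expect_equal(a, b)
  }
})

test_that("a C2-symmetric frame superposes exactly onto its chain swap", {
  tmpl <- makeTemplate(tinySpec())
  expect_lt(calcRMSD(swapChains(tmpl), tmpl), 1e-10)
})

test_that("heterodimer labels cannot be swapped", {
  lab <- data.frame(chain = c("A", "A", "B", "B", "B"),
                    resno = c(1L, 2L, 1L, 2L, 3L))
  e <- makeEnsemble(lab, matrix(rnorm(15), 1L))
  expect_error(swapChains(e), "swap error")
})

test_that("ensemble readers reject models with differing site sets", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeMiniPDB(f, list(miniAtoms(), miniAtoms(resno = 1:3)))
  expect_error(readStructures(f, model = "all"), "model 2")
  expect_error(readEnsemblePDB(f, ranges = list(A = c(1L, 4L))),
               "inconsistent-ensemble|model")
})

test_that("TSV coordinate tables round-trip an ensemble", {
  syn <- syntheticEnsemble(tinySpec(M = 6L, seed = 10L))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEnsembleTSV(syn$ensemble, f, header = "provenance line")
  back <- readEnsembleTSV(f)
  expect_equal(nFrames(back), 6L)
  expect_equal(siteLabels(back), siteLabels(syn$ensemble))
  expect_lt(max(abs(frameMatrix(back) - frameMatrix(syn$ensemble))), 1e-9)
})
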