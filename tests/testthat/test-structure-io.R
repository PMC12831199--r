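test_that("a hand-written two-residue PDB parses to the forced counts", {
  m <- read_structure(two_residue_pdb())
  expect_s3_class(m, "structure_model")
  expect_length(chain_ids(m), 1)
  expect_equal(nrow(chain_residues(m)), 2)
  expect_equal(nrow(m$atoms), 8)
  expect_equal(extract_sequence(m), "AG")
})

test_that("PDB and mmCIF round-trips preserve sequence, numbering and coordinates", {
  m <- helix_model(20)
  for (fmt in c("PDB", "mmCIF")) {
    f <- tempfile(fileext = if (fmt == "PDB") ".pdb" else ".cif")
    write_structure(m, f, format = fmt)
    m2 <- read_structure(f, model_id = m$model_id)
    expect_equal(extract_sequence(m2), extract_sequence(m))
    expect_equal(chain_residues(m2)$resno, chain_residues(m)$resno)
    expect_lt(max(abs(as.matrix(m2$atoms[, c("x", "y", "z")]) -
                        as.matrix(m$atoms[, c("x", "y", "z")]))), 1e-3)
  }
})

test_that("write-read-write is byte-stable at fixed precision", {
  m <- helix_model(12)
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_structure(m, f1)
  write_structure(read_structure(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("altloc selection, water exclusion and MSE mapping follow the rules", {
  m <- read_structure(altloc_mse_pdb())
  # only the A copy of the CA survives, water gone
  expect_equal(sum(m$atoms$elety == "CA"), 1)
  expect_equal(m$atoms$x[m$atoms$elety == "CA"], 1.458)
  expect_false(any(m$atoms$resid == "HOH"))
  expect_equal(extract_sequence(m), "M")
})

test_that("unknown polymer residues become X in the sequence", {
  m <- read_structure(two_residue_pdb())
  m$atoms$resid[m$atoms$resno == 2] <- "LIG"
  expect_equal(extract_sequence(m), "AX")
})

test_that("empty models are rejected", {
  m <- helix_model(5)
  expect_error(structure_model(m$atoms[0, ], "x"), "nrow")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "no such file")
})

test_that("a proteome directory is iterated deterministically with skips logged", {
  dir <- tempfile("prot_")
  dir.create(dir)
  for (id in c("bbb", "aaa", "ccc"))
    write_structure(helix_model(8, id = id), file.path(dir, paste0(id, ".pdb")))
  writeLines("this is not a structure", file.path(dir, "zzz.pdb"))
  models <- suppressWarnings(iterate_proteome(dir))
  expect_equal(names(models), c("aaa", "bbb", "ccc"))  # lexicographic
  expect_equal(attr(models, "n_total"), 4)
  expect_equal(attr(models, "n_ok"), 3)
  expect_equal(attr(models, "n_skipped"), 1)
  expect_match(names(attr(models, "skipped")), "zzz")
})

test_that("AlphaFold-DB style names yield the accession as model id", {
  dir <- tempfile("prot_")
  dir.create(dir)
  write_structure(helix_model(8), file.path(dir, "AF-P00000-F1-model_v4.pdb"))
  models <- iterate_proteome(dir)
  expect_equal(names(models), "P00000")
})

test_that("tar.gz archives iterate to the same models as the directory", {
  dir <- tempfile("prot_")
  dir.create(dir)
  for (id in c("m1", "m2"))
    write_structure(helix_model(8, id = id), file.path(dir, paste0(id, ".pdb")))
  tarball <- tempfile(fileext = ".tar.gz")
  withr::with_dir(dir, utils::tar(tarball, files = ".", compression = "gzip"))
  m_dir <- iterate_proteome(dir)
  m_tar <- iterate_proteome(tarball)
  expect_equal(names(m_tar), names(m_dir))
  expect_equal(extract_sequence(m_tar$m1), extract_sequence(m_dir$m1))
})

test_that("empty sources and all-failed sources raise distinct errors", {
  dir <- tempfile("prot_")
  dir.create(dir)
  expect_error(iterate_proteome(dir), "no structure files")
  writeLines("garbage", file.path(dir, "a.pdb"))
  expect_error(suppressWarnings(iterate_proteome(dir)), "failed to parse")
})
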