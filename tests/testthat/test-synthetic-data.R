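test_that("ideal helices have the expected backbone geometry", {
  m <- build_backbone(strrep("A", 15), dihedrals_preset(15, "helix"))
  bb <- backbone_coords(m)
  dca <- vapply(2:15, function(i) sqrt(sum((bb$CA[i, ] - bb$CA[i - 1, ])^2)),
                numeric(1))
  expect_true(all(abs(dca - 3.80) < 0.01))
  # helical O(i)..N(i+4) within hydrogen-bond acceptance range
  don <- vapply(1:11, function(i) sqrt(sum((bb$O[i, ] - bb$N[i + 4, ])^2)),
                numeric(1))
  expect_true(all(don < 3.5))
})

test_that("degenerate builder inputs behave as specified", {
  one <- build_backbone("A", data.frame(phi = -57, psi = -47))
  expect_equal(nrow(chain_residues(one)), 1)
  expect_error(build_backbone("AAA", data.frame(phi = -57, psi = -47)),
               "one row per residue")
  expect_error(build_backbone("AZB", dihedrals_preset(3, "helix")),
               "non-standard")
})

test_that("toy proteomes are recovered exactly by the scanner", {
  dir <- tempfile("toy_")
  out <- generate_toy_proteome(dir, n_helix = 4, n_coil = 3, n_strand = 2,
                               n_empty = 3, seed = 7)
  models <- iterate_proteome(dir)
  expect_length(models, 12)
  scan <- scan_proteome(models, frm_pattern("relaxed"))
  truth_hits <- out$truth[!is.na(out$truth$motif_start), ]
  got <- scan$matches[order(scan$matches$model_id), ]
  want <- truth_hits[order(truth_hits$id), ]
  expect_equal(got$model_id, want$id)
  expect_equal(got$start, want$motif_start)
  expect_equal(got$residues, want$residues)
})

test_that("generation is a pure function of parameters and seed", {
  d1 <- tempfile("toy_"); d2 <- tempfile("toy_")
  generate_toy_proteome(d1, n_helix = 2, n_coil = 1, n_strand = 1,
                        n_empty = 1, seed = 99)
  generate_toy_proteome(d2, n_helix = 2, n_coil = 1, n_strand = 1,
                        n_empty = 1, seed = 99)
  f1 <- list.files(d1, full.names = TRUE); f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (k in seq_along(f1))
    expect_identical(readLines(f1[k]), readLines(f2[k]))
  b1 <- tempfile("cx_"); b2 <- tempfile("cx_")
  generate_synthetic_complex(b1, "c", "VIDLY", binder = TRUE, seed = 5)
  generate_synthetic_complex(b2, "c", "VIDLY", binder = TRUE, seed = 5)
  for (f in c("model.pdb", "pae.json", "summary.json"))
    expect_identical(readLines(file.path(b1, f)), readLines(file.path(b2, f)))
})

test_that("planted contexts receive the intended simplified labels", {
  dir <- tempfile("toy_")
  out <- generate_toy_proteome(dir, n_helix = 3, n_coil = 2, n_strand = 3,
                               n_empty = 0, seed = 17)
  models <- iterate_proteome(dir)
  truth <- out$truth[out$truth$planted, ]
  for (k in seq_len(nrow(truth))) {
    m <- models[[truth$id[k]]]
    ss <- assign_secondary_structure(m)
    win <- truth$motif_start[k]:(truth$motif_start[k] + 4)
    labs <- ss_labels(ss, "A", win)
    if (truth$context[k] == "strand") {
      expect_true(any(labs == "E"))
      expect_false(ss_context_filter(labs))  # discarded by the context rule
    } else {
      expect_false(any(labs == "E"))
      expect_true(ss_context_filter(labs))
    }
    if (truth$context[k] == "helix")
      expect_true(all(labs == "H"))
  }
  # regular generated elements label as intended for >= 90% of interior
  helix <- build_backbone(strrep("A", 20), dihedrals_preset(20, "helix"))
  lab_h <- assign_secondary_structure(helix)$table$label[3:18]
  expect_gte(mean(lab_h == "H"), 0.9)
  hp <- hairpin_model(6)
  core <- assign_secondary_structure(hp)$table$label[c(3:5, 10:12)]
  expect_gte(mean(core == "E"), 0.9)
})

test_that("localization tables honour the cytosolic fraction and seed", {
  ids <- sprintf("P%02d", 1:10)
  f_all <- tempfile(fileext = ".tsv")
  generate_localization_table(f_all, ids, cytosolic_fraction = 1, seed = 1)
  tab <- read_localization_table(f_all)
  expect_true(all(vapply(ids, function(i) localization_filter(i, tab)$keep,
                         logical(1))))
  f_none <- tempfile(fileext = ".tsv")
  generate_localization_table(f_none, ids, cytosolic_fraction = 0, seed = 1)
  tab0 <- read_localization_table(f_none)
  expect_false(any(vapply(ids, function(i) localization_filter(i, tab0)$keep,
                          logical(1))))
  fa <- tempfile(fileext = ".tsv"); fb <- tempfile(fileext = ".tsv")
  generate_localization_table(fa, ids, cytosolic_fraction = 0.5, seed = 3)
  generate_localization_table(fb, ids, cytosolic_fraction = 0.5, seed = 3)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("contradictory complex specifications are rejected", {
  expect_error(generate_synthetic_complex(tempfile(), "c", "VIDLY",
                                          binder = TRUE,
                                          failure_stage = "iptm"),
               "cannot")
  expect_error(generate_synthetic_complex(tempfile(), "c", "VIDLF",
                                          binder = TRUE),
               "Tyr")
})

test_that("the mock receptor carries every groove residue with usable atoms", {
  rec <- build_mock_receptor()
  g <- groove_definition()
  at <- rec$atoms
  for (r in g$hydrophobic)
    expect_true(any(at$resno == r & at$resid == "LEU"))
  for (r in c(g$asp_canonical, g$asp_flipped))
    expect_setequal(intersect(at$elety[at$resno == r], c("OD1", "OD2")),
                    c("OD1", "OD2"))
  expect_true(any(at$resno == g$lysine & at$elety == "NZ"))
})
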