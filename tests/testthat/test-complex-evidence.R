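write_pae_json <- function(mat, boundary = NULL, dialect = "flat") {
  f <- tempfile(fileext = ".json")
  if (dialect == "flat") {
    obj <- list(predicted_aligned_error = mat)
    if (!is.null(boundary)) obj$chain_boundary <- boundary
  } else {
    idx <- which(mat >= 0, arr.ind = TRUE)
    obj <- list(residue1 = idx[, 1], residue2 = idx[, 2],
                distance = mat[idx])
    if (!is.null(boundary)) obj$chain_boundary <- boundary
  }
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
  f
}

test_that("PAE matrices parse from both dialects to identical values", {
  set.seed(5)
  mat <- matrix(round(runif(100, 0.5, 30), 2), 10, 10)
  p1 <- read_pae_matrix(write_pae_json(mat, boundary = 6))
  p2 <- read_pae_matrix(write_pae_json(mat, boundary = 6, dialect = "paired"))
  expect_equal(p1$n, 10)
  expect_equal(p1$boundary, 6L)
  expect_equal(p1$matrix, p2$matrix, ignore_attr = TRUE)
})

test_that("ragged, negative and boundary-less PAE inputs are rejected", {
  f <- tempfile(fileext = ".json")
  writeLines('{"predicted_aligned_error": [[1,2,3],[1,2],[1,2,3]],
               "chain_boundary": 2}', f)
  expect_error(read_pae_matrix(f), "ragged|square")
  mat <- matrix(1, 4, 4); mat[2, 3] <- -1
  expect_error(read_pae_matrix(write_pae_json(mat, boundary = 2)), "negative")
  mat2 <- matrix(1, 4, 4)
  expect_error(read_pae_matrix(write_pae_json(mat2)), "boundary")
  expect_error(read_pae_matrix(write_pae_json(mat2, boundary = 9)),
               "outside")
})

test_that("interface PAE summaries average both off-diagonal blocks", {
  mat <- matrix(5, 10, 10)
  pae <- read_pae_matrix(write_pae_json(mat, boundary = 7))
  s <- interface_pae_summary(pae, motif_idx = 7:9, receptor_idx = 1:6)
  expect_equal(s$mean, 5); expect_equal(s$min, 5)
  # asymmetric random matrix against an explicit loop
  set.seed(9)
  mat <- matrix(runif(100, 1, 25), 10, 10)
  pae <- read_pae_matrix(write_pae_json(mat, boundary = 7))
  mi <- 8:10; ri <- 2:5
  vals <- c()
  for (i in mi) for (j in ri) vals <- c(vals, mat[i, j], mat[j, i])
  s <- interface_pae_summary(pae, mi, ri)
  expect_equal(s$mean, mean(vals))
  expect_equal(s$min, min(vals))
  expect_true(s$mean >= s$min && s$mean <= max(vals))
  # windows must straddle the boundary
  expect_error(interface_pae_summary(pae, 1:3, 4:6), "opposite sides")
  expect_error(interface_pae_summary(pae, integer(0), ri), "empty")
})

test_that("groove contacts are found for a docked motif and absent for separated chains", {
  b <- generate_synthetic_complex(tempfile("cx_"), "cand", "VIDLY",
                                  binder = TRUE, seed = 21)
  pred <- read_complex_bundle(b$dir, "cand")
  g <- groove_definition()
  ct <- interchain_contacts(pred$model, g, b$motif_start)
  expect_true(ct$groove_contact)
  expect_gte(ct$n_contact_pairs, 1)
  expect_true(all(ct$pairs$dist <= g$contact_cutoff))
  # brute-force all-pairs check of the contact count
  at <- pred$model$atoms
  lig <- at[at$chain == "B" & at$resno %in% b$motif_start:(b$motif_start + 4) &
              at$elesy != "H", ]
  rec <- at[at$chain == "A" & at$resno %in% g$hydrophobic & at$elesy != "H", ]
  n_bf <- 0
  for (i in seq_len(nrow(lig))) for (j in seq_len(nrow(rec))) {
    d <- sqrt(sum((as.numeric(lig[i, c("x", "y", "z")]) -
                     as.numeric(rec[j, c("x", "y", "z")]))^2))
    if (d <= g$contact_cutoff) n_bf <- n_bf + 1
  }
  expect_equal(ct$n_contact_pairs, n_bf)
  # translate the ligand far away: no contacts, min distance still reported
  far <- pred$model
  sel <- far$atoms$chain == "B"
  far$atoms$y[sel] <- far$atoms$y[sel] + 100
  ct2 <- interchain_contacts(far, g, b$motif_start)
  expect_false(ct2$groove_contact)
  expect_equal(ct2$n_contact_pairs, 0)
  expect_gt(ct2$min_dist, 50)
})

test_that("missing groove residues are reported by number", {
  b <- generate_synthetic_complex(tempfile("cx_"), "cand", "VIDLY",
                                  binder = TRUE, seed = 22)
  pred <- read_complex_bundle(b$dir, "cand")
  m <- pred$model
  m$atoms <- m$atoms[!(m$atoms$chain == "A" & m$atoms$resno == 51), ]
  expect_error(interchain_contacts(m, groove_definition(), b$motif_start),
               "51")
})

test_that("motif helicity in the complex distinguishes helical from extended ligands", {
  bh <- generate_synthetic_complex(tempfile("cx_"), "h", "VIDLY",
                                   binder = TRUE, seed = 23)
  predh <- read_complex_bundle(bh$dir, "h")
  expect_true(motif_helicity_in_complex(predh$model, bh$motif_start))
  be <- generate_synthetic_complex(tempfile("cx_"), "e", "VIDLY",
                                   binder = FALSE, failure_stage = "extended",
                                   seed = 23)
  prede <- read_complex_bundle(be$dir, "e")
  expect_false(motif_helicity_in_complex(prede$model, be$motif_start))
  # a 3-residue ligand fragment is not evaluable
  frag <- predh$model
  keep <- frag$atoms$chain == "A" |
    frag$atoms$resno %in% bh$motif_start:(bh$motif_start + 2)
  frag$atoms <- frag$atoms[keep, ]
  expect_true(is.na(motif_helicity_in_complex(frag, bh$motif_start)))
})

test_that("orientation classification keys on the Tyr(+2) hydrogen-bond partner", {
  g <- groove_definition()
  bc <- generate_synthetic_complex(tempfile("cx_"), "c", "VIDLY",
                                   binder = TRUE,
                                   orientation = "canonical_D112", seed = 31)
  mc <- read_complex_bundle(bc$dir, "c")$model
  expect_equal(classify_orientation(mc, bc$motif_start, g), "canonical_D112")
  # brute-force distance check on the generated coordinates
  at <- mc$atoms
  oh <- as.numeric(at[at$chain == "B" & at$resno == bc$motif_start + 4 &
                        at$elety == "OH", c("x", "y", "z")])
  d112 <- min(apply(at[at$chain == "A" & at$resno == 112 &
                         at$elety %in% c("OD1", "OD2"), c("x", "y", "z")], 1,
                    function(p) sqrt(sum((as.numeric(p) - oh)^2))))
  d62 <- min(apply(at[at$chain == "A" & at$resno == 62 &
                        at$elety %in% c("OD1", "OD2"), c("x", "y", "z")], 1,
                   function(p) sqrt(sum((as.numeric(p) - oh)^2))))
  expect_lte(d112, g$hbond_cutoff)
  expect_lt(d112, d62)
  bf <- generate_synthetic_complex(tempfile("cx_"), "f", "VIDLY",
                                   binder = TRUE,
                                   orientation = "flipped_D62", seed = 31)
  mf <- read_complex_bundle(bf$dir, "f")$model
  expect_equal(classify_orientation(mf, bf$motif_start, g), "flipped_D62")
  # both acceptors out of range -> indeterminate
  sep <- mc
  sel <- sep$atoms$chain == "B"
  sep$atoms$y[sel] <- sep$atoms$y[sel] + 100
  expect_equal(classify_orientation(sep, bc$motif_start, g), "indeterminate")
  # non-Tyr at +2 -> not applicable (distinct from indeterminate)
  mut <- mc
  mut$atoms$resid[mut$atoms$chain == "B" &
                    mut$atoms$resno == bc$motif_start + 4] <- "PHE"
  expect_equal(classify_orientation(mut, bc$motif_start, g), "not_applicable")
})

test_that("geometric evidence is invariant under rigid motions of the whole complex", {
  set.seed(41)
  b <- generate_synthetic_complex(tempfile("cx_"), "cand", "ILDAY",
                                  binder = TRUE, seed = 41)
  pred <- read_complex_bundle(b$dir, "cand")
  g <- groove_definition()
  ref_ct <- interchain_contacts(pred$model, g, b$motif_start)
  ref_or <- classify_orientation(pred$model, b$motif_start, g)
  ref_ss <- assign_secondary_structure(pred$model)$table$label
  for (k in 1:4) {
    mt <- transform_model(pred$model, random_rigid_motion())
    ct <- interchain_contacts(mt, g, b$motif_start)
    expect_equal(ct$n_contact_pairs, ref_ct$n_contact_pairs)
    expect_lt(abs(ct$min_dist - ref_ct$min_dist), 1e-6)
    expect_identical(classify_orientation(mt, b$motif_start, g), ref_or)
    expect_identical(assign_secondary_structure(mt)$table$label, ref_ss)
  }
})

test_that("bundle reading wires model, PAE and ipTM together", {
  b <- generate_synthetic_complex(tempfile("cx_"), "cand", "VISLY",
                                  binder = TRUE, seed = 51)
  pred <- read_complex_bundle(b$dir, "cand")
  expect_s3_class(pred, "complex_prediction")
  expect_equal(pred$iptm, b$iptm)
  expect_length(chain_ids(pred$model), 2)
  ev <- evaluate_complex(pred, motif_start = b$motif_start)
  expect_true(ev$groove_contact)
  expect_true(ev$motif_helical)
  expect_true(is.finite(ev$mean_interface_pae))
  expect_gte(ev$mean_interface_pae, ev$min_interface_pae)
})
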