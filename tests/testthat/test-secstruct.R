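test_that("the hydrogen-bond energy reproduces a direct evaluation of the formula", {
  # independent arithmetic on the stated distances
  expected <- 0.084 * 332 * (1 / 2.9 + 1 / 3.5 - 1 / 1.9 - 1 / 3.9)
  e <- hbond_energy_distances(2.9, 3.5, 1.9, 3.9)
  expect_equal(e, expected)
  expect_equal(round(e, 2), -4.24)
  expect_lt(e, -0.5)  # accepted
  # the energy vanishes as all distances grow
  expect_gt(hbond_energy_distances(290, 350, 190, 390), -0.5)
  expect_lt(abs(hbond_energy_distances(29000, 35000, 19000, 39000)), 1e-3)
})

test_that("missing atoms make a bond not evaluable, never silently zero", {
  r <- hydrogen_bond_energy(list(N = c(0, 0, 0), H = NULL),
                            list(C = c(3, 0, 0), O = c(3, 1, 0)))
  expect_true(is.na(r$energy))
  expect_true(is.na(r$accepted))
})

test_that("amide hydrogens follow the carbonyl direction at 1.01 A", {
  m <- helix_model(10, seq = "AAAPAAAAAA")
  bb <- place_amide_hydrogens(m)
  for (i in 2:10) {
    if (bb$code1[i] == "P") {
      expect_true(any(!is.finite(bb$H[i, ])))
    } else {
      expect_equal(sqrt(sum((bb$H[i, ] - bb$N[i, ])^2)), 1.01,
                   tolerance = 1e-8)
      # anti-parallel to the preceding C->O bond
      co <- bb$O[i - 1, ] - bb$C[i - 1, ]
      nh <- bb$H[i, ] - bb$N[i, ]
      cosang <- sum(co * nh) / sqrt(sum(co^2) * sum(nh^2))
      expect_equal(cosang, -1, tolerance = 1e-8)
    }
  }
  expect_true(any(!is.finite(bb$H[1, ])))  # chain-initial residue
})

test_that("a residue whose predecessor lacks the carbonyl gets no hydrogen", {
  m <- helix_model(6)
  m$atoms <- m$atoms[!(m$atoms$resno == 3 & m$atoms$elety == "C"), ]
  bb <- place_amide_hydrogens(m)
  expect_true(any(!is.finite(bb$H[4, ])))
})

test_that("ideal poly-Ala helices are labelled helix in the interior", {
  for (L in c(10, 15, 25)) {
    m <- helix_model(L)
    lab <- assign_secondary_structure(m)$table$label
    expect_gte(sum(lab == "H"), L - 4)
    expect_false(any(lab == "E"))
  }
})

test_that("an antiparallel hairpin yields strand labels backed by bridge bonds", {
  m <- hairpin_model(6)
  lab <- assign_secondary_structure(m)$table$label
  expect_true(all(lab[3:5] == "E"))
  expect_true(all(lab[10:12] == "E"))
  expect_false(any(lab == "H"))
  # no 'E' without at least one accepted cross-strand bond
  hb <- list_hbonds(m)
  expect_gt(nrow(hb[abs(hb$donor - hb$acceptor) > 2, ]), 0)
})

test_that("chains without accepted bonds are all loop, and tiny chains default to loop", {
  m5 <- build_backbone("AAAAA",
                       data.frame(phi = c(-60, 140, -75, 60, -100),
                                  psi = c(150, -40, 80, 20, -60)))
  expect_equal(paste(assign_secondary_structure(m5)$table$label,
                     collapse = ""), "CCCCC")
  m2 <- build_backbone("AA", data.frame(phi = c(-57, -57), psi = c(-47, -47)))
  expect_equal(assign_secondary_structure(m2)$table$label, c("C", "C"))
})

test_that("simplified labels map the 8-class alphabet onto {H,E,C}", {
  expect_equal(simplify_label(c("G", "B", "T", "H", "I", "E", "S", "C", "-")),
               c("H", "E", "C", "H", "H", "E", "C", "C", "C"))
  expect_error(simplify_label("Q"), "unknown")
})

test_that("assignments are invariant under rigid motions", {
  set.seed(101)
  models <- list(helix_model(18), hairpin_model(6),
                 build_backbone(random_seq(20),
                                data.frame(phi = runif(20, -140, -60),
                                           psi = runif(20, -50, 110))))
  for (m in models) {
    ref <- assign_secondary_structure(m)$table$label
    for (k in 1:3) {
      mt <- transform_model(m, random_rigid_motion())
      expect_identical(assign_secondary_structure(mt)$table$label, ref)
    }
  }
})

test_that("labels agree with the brute-force oracle on short synthetic chains", {
  set.seed(7)
  cases <- list(helix_model(12), helix_model(30), hairpin_model(5),
                hairpin_model(8))
  for (k in 1:6) {
    n <- sample(8:30, 1)
    cases[[length(cases) + 1]] <- build_backbone(
      random_seq(n),
      data.frame(phi = runif(n, -150, -50), psi = runif(n, -60, 140)))
  }
  # mixed helix/coil chains exercise boundaries
  for (k in 1:3) {
    n <- 24
    dh <- dihedrals_preset(n, "helix")
    coil <- sample(seq_len(n), 10)
    dh$phi[coil] <- runif(10, -140, -60); dh$psi[coil] <- runif(10, -50, 110)
    cases[[length(cases) + 1]] <- build_backbone(random_seq(n), dh)
  }
  for (m in cases) {
    expect_identical(assign_secondary_structure(m)$table$label,
                     oracle_ss(m), info = m$model_id)
  }
})
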