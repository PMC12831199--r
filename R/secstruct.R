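# Secondary-structure assignment from backbone hydrogen bonding.
#
# Kabsch-Sander electrostatic H-bond energies with the standard turn and
# bridge rules, simplified to the three-class alphabet {H, E, C} used by the
# structural-context filter. Helix covers alpha/3-10/pi; strand covers
# bridges and ladders; everything else (turns, bends, coil) is loop.

HB_CUTOFF <- -0.5       # kcal/mol, bond accepted below this energy
HB_FACTOR <- 0.084 * 332
CHAIN_BREAK_CA <- 4.5   # Angstrom, CA-CA distance defining a chain break

#' Kabsch-Sander hydrogen-bond energy from the four distances
#'
#' E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol, where the
#' donor contributes N and its amide H and the acceptor contributes the
#' carbonyl C and O.
#'
#' @param r_on,r_ch,r_oh,r_cn distances in Angstrom
#' @return energy in kcal/mol
#' @export
hbond_energy_distances <- function(r_on, r_ch, r_oh, r_cn) {
  HB_FACTOR * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

#' Hydrogen-bond energy between a donor and an acceptor residue
#'
#' @param donor list with 3-vectors `N` and `H`
#' @param acceptor list with 3-vectors `C` and `O`
#' @return list with `energy` (kcal/mol) and `accepted`; if any required atom
#'   is missing, `energy` is NA and `accepted` is NA ("not evaluable")
#' @export
hydrogen_bond_energy <- function(donor, acceptor) {
  atoms <- c(donor["N"], donor["H"], acceptor["C"], acceptor["O"])
  if (any(vapply(atoms, function(p) is.null(p) || any(!is.finite(p)),
                 logical(1))))
    return(list(energy = NA_real_, accepted = NA))
  e <- hbond_energy_distances(
    point_dist(acceptor$O, donor$N),
    point_dist(acceptor$C, donor$H),
    point_dist(acceptor$O, donor$H),
    point_dist(acceptor$C, donor$N))
  list(energy = e, accepted = e < HB_CUTOFF)
}

# segment ids within a chain: a new segment starts wherever consecutive CA
# atoms are missing or further apart than CHAIN_BREAK_CA
chain_segments <- function(CA) {
  n <- nrow(CA)
  seg <- integer(n)
  cur <- 1L
  seg[1] <- 1L
  if (n > 1) for (i in 2:n) {
    brk <- any(!is.finite(CA[i - 1, ])) || any(!is.finite(CA[i, ])) ||
      vnorm(CA[i, ] - CA[i - 1, ]) > CHAIN_BREAK_CA
    if (brk) cur <- cur + 1L
    seg[i] <- cur
  }
  seg
}

#' Place backbone amide hydrogens on a chain
#'
#' For residue i > 1 the H sits on N, 1.01 Angstrom along the direction
#' opposite the preceding carbonyl C -> O bond (the DSSP convention). Prolines,
#' chain-initial residues, residues following a chain break, and residues
#' whose predecessor lacks C or O receive no H.
#'
#' @param model a `structure_model`
#' @param chain chain id; default first chain
#' @return the [backbone_coords()] list augmented with an n x 3 matrix `H`
#'   and an integer vector `segment`
#' @export
place_amide_hydrogens <- function(model, chain = chain_ids(model)[1]) {
  bb <- backbone_coords(model, chain)
  n <- length(bb$resno)
  seg <- chain_segments(bb$CA)
  H <- matrix(NA_real_, n, 3)
  if (n > 1) for (i in 2:n) {
    if (bb$code1[i] == "P") next
    if (seg[i] != seg[i - 1]) next
    Cp <- bb$C[i - 1, ]; Op <- bb$O[i - 1, ]; Ni <- bb$N[i, ]
    if (any(!is.finite(c(Cp, Op, Ni)))) next
    H[i, ] <- Ni + 1.01 * unit(Cp - Op)
  }
  bb$H <- H
  bb$segment <- seg
  bb
}

cross_dist <- function(A, B) {
  # pairwise distances between rows of A and rows of B
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * (A %*% t(B))
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# accepted-bond matrix: bond[i, j] is TRUE when residue i's amide donates to
# residue j's carbonyl; pairs closer than 2 in chain order or spanning a
# chain break are never evaluated
hbond_matrix <- function(bb) {
  n <- length(bb$resno)
  E <- matrix(NA_real_, n, n)
  ok_don <- apply(is.finite(bb$N) & is.finite(bb$H), 1, all)
  ok_acc <- apply(is.finite(bb$C) & is.finite(bb$O), 1, all)
  if (any(ok_don) && any(ok_acc)) {
    r_on <- cross_dist(bb$N, bb$O)
    r_ch <- cross_dist(bb$H, bb$C)
    r_oh <- cross_dist(bb$H, bb$O)
    r_cn <- cross_dist(bb$N, bb$C)
    E <- HB_FACTOR * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
    E[!ok_don, ] <- NA
    E[, !ok_acc] <- NA
  }
  idx <- seq_len(n)
  near <- abs(outer(idx, idx, "-")) < 2
  E[near] <- NA
  segdiff <- outer(bb$segment, bb$segment, "!=")
  E[segdiff] <- NA
  list(energy = E, bond = !is.na(E) & E < HB_CUTOFF)
}

#' Accepted backbone hydrogen bonds of a chain
#'
#' @inheritParams place_amide_hydrogens
#' @return data.frame with columns `donor`, `acceptor` (1-based residue
#'   indices along the chain) and `energy` (kcal/mol)
#' @export
list_hbonds <- function(model, chain = chain_ids(model)[1]) {
  bb <- place_amide_hydrogens(model, chain)
  hb <- hbond_matrix(bb)
  w <- which(hb$bond, arr.ind = TRUE)
  data.frame(donor = w[, 1], acceptor = w[, 2],
             energy = hb$energy[hb$bond])[order(w[, 1], w[, 2]), ]
}

# raw 8-class-style labels for one chain from its bond matrix
assign_chain_raw <- function(bb) {
  n <- length(bb$resno)
  raw <- rep("C", n)
  if (n < 3) return(raw)
  bond <- hbond_matrix(bb)$bond
  bnd <- function(a, b) {
    a >= 1 && b >= 1 && a <= n && b <= n && bond[a, b]
  }
  # n-turns: H-bond from i+n back to i
  turn <- list()
  for (k in 3:5) {
    t <- rep(FALSE, n)
    for (i in seq_len(n - k)) if (bond[i + k, i]) t[i] <- TRUE
    turn[[as.character(k)]] <- t
  }
  # turn interiors marked T (may be overwritten by stronger classes)
  for (k in 3:5) for (i in which(turn[[as.character(k)]]))
    for (j in (i + 1):(i + k - 1)) if (raw[j] == "C") raw[j] <- "T"
  # bridges: parallel / antiparallel patterns, |i - j| >= 3
  bridge <- rep(FALSE, n)
  partner <- vector("list", n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < 3) next
    par <- (bnd(i - 1, j) && bnd(j, i + 1)) || (bnd(j - 1, i) && bnd(i, j + 1))
    anti <- (bnd(i, j) && bnd(j, i)) || (bnd(i - 1, j + 1) && bnd(j - 1, i + 1))
    if (par || anti) {
      bridge[i] <- TRUE; bridge[j] <- TRUE
      partner[[i]] <- c(partner[[i]], j)
      partner[[j]] <- c(partner[[j]], i)
    }
  }
  # ladders (adjacent bridged residues) become E, isolated bridges B
  for (i in which(bridge)) {
    ladder <- (i > 1 && bridge[i - 1]) || (i < n && bridge[i + 1])
    raw[i] <- if (ladder) "E" else "B"
  }
  # helices: two consecutive n-turns start an n-helix at i (residues i..i+n-1)
  mark_helix <- function(t, k, sym) {
    for (i in 2:n) if (i <= length(t) && t[i] && t[i - 1])
      for (j in i:min(i + k - 1, n))
        raw[j] <<- sym
  }
  mark_helix(turn[["5"]], 5, "I")
  mark_helix(turn[["3"]], 3, "G")
  mark_helix(turn[["4"]], 4, "H")
  raw
}

#' Simplify a DSSP-style label to the three-class alphabet
#'
#' Maps H/G/I to 'H' (helix), E/B to 'E' (strand/bridge) and T/S/C/'-'/' '
#' to 'C' (loop). Vectorised.
#'
#' @param raw character vector of raw labels
#' @return character vector over {H, E, C}
#' @export
simplify_label <- function(raw) {
  map <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
           T = "C", S = "C", C = "C", "-" = "C", " " = "C")
  out <- map[raw]
  if (any(is.na(out)))
    stop("unknown secondary-structure symbol: ",
         paste(unique(raw[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Assign per-residue secondary structure to a model
#'
#' Hydrogen bonds are detected with the Kabsch-Sander energy (acceptance
#' below -0.5 kcal/mol); two consecutive n-turns define helices (n = 3, 4, 5,
#' all reported as 'H'), bridge patterns define strand ('E'), and everything
#' else, including turns and bends, is loop ('C'). Deterministic for fixed
#' input and invariant under rigid motions.
#'
#' @param model a `structure_model`
#' @return an object of class `ss_annotation`: list with `model_id`, `method`
#'   and `table` (columns `chain`, `resno`, `aa`, `raw`, `label`)
#' @export
assign_secondary_structure <- function(model) {
  tabs <- lapply(chain_ids(model), function(ch) {
    bb <- place_amide_hydrogens(model, ch)
    raw <- assign_chain_raw(bb)
    data.frame(chain = ch, resno = bb$resno, aa = bb$code1,
               raw = raw, label = simplify_label(raw),
               stringsAsFactors = FALSE)
  })
  structure(list(model_id = model$model_id,
                 method = "kabsch-sander-3class (turns/bends as loop)",
                 table = do.call(rbind, tabs)),
            class = "ss_annotation")
}

#' @export
print.ss_annotation <- function(x, ...) {
  cat("<ss_annotation>", x$model_id, "-", x$method, "\n")
  for (ch in unique(x$table$chain))
    cat("  ", ch, ": ",
        paste(x$table$label[x$table$chain == ch], collapse = ""), "\n",
        sep = "")
  invisible(x)
}

#' Labels of a residue window
#'
#' @param ss an `ss_annotation`
#' @param chain chain id
#' @param resno_window integer vector of author residue numbers
#' @return character vector of labels (NA where unannotated)
#' @export
ss_labels <- function(ss, chain, resno_window) {
  tab <- ss$table[ss$table$chain == chain, ]
  tab$label[match(resno_window, tab$resno)]
}
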