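# Ground-truth synthetic inputs for every pipeline stage, with no downloads:
# ideal-geometry backbones, toy proteomes with planted motifs in known
# secondary-structure context, localization tables, and binder/non-binder
# complex bundles with constructed PAE and ipTM.
#
# All generators are pure functions of (parameters, seed).

# turn dihedrals connecting two antiparallel ideal strands into a hairpin
# whose five residues flanking the turn register as strand ('E'); derived
# once by numerical optimisation of the Kabsch-Sander bond energies over the
# turn torsions under ideal geometry, then frozen
HAIRPIN_TURN <- c(psi_pre = 133.2, phi_t1 = 63.7, psi_t1 = -72.2,
                  phi_t2 = -153.3, psi_t2 = 4.7, phi_post = -109.2)

# background residue alphabet for generated sequences: the 19 standard
# letters without Tyr, so that every motif occurrence in a toy proteome is a
# planted one (the motif requires Tyr at +2) and the truth table is exhaustive
BACKGROUND_AA <- setdiff(unname(AA_321[1:20]), "Y")

sample_background_seq <- function(n) {
  paste(sample(BACKGROUND_AA, n, replace = TRUE), collapse = "")
}

# coil torsions: uniform draws from a broad left-half window that avoids the
# narrow strand/polyproline band, with enough spread that no regular
# hydrogen-bond ladder can form
sample_coil_dihedrals <- function(n) {
  data.frame(phi = stats::runif(n, -140, -60),
             psi = stats::runif(n, -50, 110))
}

#' Dihedral table for a two-strand beta-hairpin
#'
#' Two ideal antiparallel strands of `strand_len` residues joined by a
#' frozen two-residue turn whose torsions were pre-optimised so that the
#' strand cores hydrogen-bond into a ladder under ideal geometry.
#'
#' @param strand_len residues per strand (>= 4)
#' @return data.frame with `phi`, `psi` for `2 * strand_len + 2` residues
#' @export
dihedrals_hairpin <- function(strand_len = 6) {
  stopifnot(strand_len >= 4)
  n <- 2L * strand_len + 2L
  dh <- dihedrals_preset(n, "strand")
  L <- strand_len
  dh$psi[L] <- HAIRPIN_TURN["psi_pre"]
  dh$phi[L + 1] <- HAIRPIN_TURN["phi_t1"]; dh$psi[L + 1] <- HAIRPIN_TURN["psi_t1"]
  dh$phi[L + 2] <- HAIRPIN_TURN["phi_t2"]; dh$psi[L + 2] <- HAIRPIN_TURN["psi_t2"]
  dh$phi[L + 3] <- HAIRPIN_TURN["phi_post"]
  dh
}

# one toy protein: coil flanks around a context segment carrying the motif;
# returns the model plus the motif window start (author numbering from 1)
build_context_protein <- function(id, motif_residues,
                                  context = c("helix", "coil", "strand"),
                                  flank_range = c(8L, 20L), max_tries = 25L) {
  context <- match.arg(context)
  for (try in seq_len(max_tries)) {
    pre <- sample.int(flank_range[2] - flank_range[1] + 1L, 1L) +
      flank_range[1] - 1L
    post <- sample.int(flank_range[2] - flank_range[1] + 1L, 1L) +
      flank_range[1] - 1L
    if (context == "helix") {
      # 13-residue helix with the motif at interior positions 5..9
      seg_seq <- paste0(substr(sample_background_seq(4), 1, 4),
                        motif_residues,
                        substr(sample_background_seq(4), 1, 4))
      seg_dh <- dihedrals_preset(13, "helix")
      motif_at <- 5L
    } else if (context == "strand") {
      # hairpin, motif on the five residues entering the turn (2..6)
      seg_core <- paste0(substr(sample_background_seq(1), 1, 1),
                         motif_residues,
                         sample_background_seq(8))
      seg_seq <- seg_core
      seg_dh <- dihedrals_hairpin(6)
      motif_at <- 2L
    } else {
      seg_seq <- paste0(motif_residues, sample_background_seq(2))
      seg_dh <- sample_coil_dihedrals(7)
      motif_at <- 1L
    }
    sq <- paste0(sample_background_seq(pre), seg_seq,
                 sample_background_seq(post))
    dh <- rbind(sample_coil_dihedrals(pre), seg_dh,
                sample_coil_dihedrals(post))
    model <- build_backbone(sq, dh, model_id = id)
    start <- pre + motif_at
    labs <- ss_labels(assign_secondary_structure(model), "A",
                      start:(start + 4L))
    ok <- if (context == "strand") any(labs == "E") else all(labs != "E")
    if (ok) return(list(model = model, start = start,
                        labels = paste(labs, collapse = "")))
  }
  stop("could not realise ", context, " context for ", id, " in ",
       max_tries, " tries")
}

build_plain_protein <- function(id, len) {
  build_backbone(sample_background_seq(len), sample_coil_dihedrals(len),
                 model_id = id)
}

#' Generate a toy proteome with planted motifs
#'
#' Writes AlphaFold-DB-style PDB files (`AF-<id>-F1-model_v4.pdb`) into
#' `dir`. Planted motifs are placed in the requested secondary-structure
#' contexts; background sequences cannot match the pattern (they carry no
#' Tyr), and an internal oracle scan nevertheless records any accidental
#' match in the truth table. Deterministic for a fixed seed.
#'
#' @param dir output directory (created)
#' @param pattern a `motif_pattern` the planted motifs are drawn from
#' @param n_helix,n_coil,n_strand number of proteins with one planted motif
#'   in each context
#' @param n_empty number of motif-free proteins
#' @param length_range residue-count range for motif-free proteins
#' @param seed integer seed
#' @return list with `dir`, `files` and `truth` (data.frame: `id`, `context`,
#'   `motif_start`, `residues`, `ss_window`, `planted`)
#' @export
generate_toy_proteome <- function(dir, pattern = frm_pattern("relaxed"),
                                  n_helix = 3, n_coil = 3, n_strand = 2,
                                  n_empty = 4, length_range = c(40L, 90L),
                                  seed = 1L) {
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  specs <- data.frame(
    context = c(rep("helix", n_helix), rep("coil", n_coil),
                rep("strand", n_strand), rep("none", n_empty)))
  truth <- list()
  files <- character()
  for (i in seq_len(nrow(specs))) {
    id <- sprintf("SYN%04d", i)
    ctx <- specs$context[i]
    if (ctx == "none") {
      len <- sample(seq(length_range[1], length_range[2]), 1)
      model <- build_plain_protein(id, len)
      start <- NA_integer_; res <- NA_character_; win <- NA_character_
    } else {
      res <- paste(vapply(pattern$positions, function(s)
        sample(s, 1), character(1)), collapse = "")
      built <- build_context_protein(id, res, ctx)
      model <- built$model; start <- built$start; win <- built$labels
    }
    f <- file.path(dir, sprintf("AF-%s-F1-model_v4.pdb", id))
    write_structure(model, f, format = "PDB")
    files <- c(files, f)
    # oracle re-scan of the written sequence: records planted and any
    # accidental occurrence
    hits <- scan_sequence(extract_sequence(model), pattern,
                          model_id = id, chain = "A")
    for (k in seq_len(nrow(hits))) {
      truth[[length(truth) + 1]] <- data.frame(
        id = id, context = ctx, motif_start = hits$start[k],
        residues = hits$residues[k],
        ss_window = if (!is.na(start) && hits$start[k] == start) win
                    else NA_character_,
        planted = !is.na(start) && hits$start[k] == start)
    }
    if (ctx == "none" && nrow(hits) == 0)
      truth[[length(truth) + 1]] <- data.frame(
        id = id, context = "none", motif_start = NA_integer_,
        residues = NA_character_, ss_window = NA_character_,
        planted = FALSE)
  }
  list(dir = dir, files = files, truth = do.call(rbind, truth))
}

# ---------------------------------------------------------------------------
# mock receptor and complex bundles

# extend built backbones with coarse side-chain stubs along the CA->CB
# direction so that groove contacts, the K97 rim and the Asp carboxylate /
# Tyr hydroxyl hydrogen-bond geometry can all be evaluated; synthetic
# geometry, not a rotamer model
add_sidechain_stubs <- function(model) {
  at <- model$atoms
  extra <- list()
  keys <- unique(at[at$resid %in% c("ASP", "TYR", "LYS", "LEU"),
                    c("chain", "resno", "resid")])
  for (r in seq_len(nrow(keys))) {
    sel <- at$chain == keys$chain[r] & at$resno == keys$resno[r]
    ca <- at[sel & at$elety == "CA", c("x", "y", "z")]
    cb <- at[sel & at$elety == "CB", c("x", "y", "z")]
    nn <- at[sel & at$elety == "N", c("x", "y", "z")]
    if (nrow(ca) != 1 || nrow(cb) != 1) next
    ca <- as.numeric(ca); cb <- as.numeric(cb); nn <- as.numeric(nn)
    dir <- unit(cb - ca)
    perp <- nn - ca
    perp <- perp - sum(perp * dir) * dir
    perp <- if (vnorm(perp) < 1e-6) unit(vcross(dir, c(0, 0, 1))) else unit(perp)
    resid <- keys$resid[r]
    stub <- function(elety, elesy, pos)
      data.frame(chain = keys$chain[r], resno = keys$resno[r], inscode = "",
                 resid = resid, elety = elety, elesy = elesy,
                 x = pos[1], y = pos[2], z = pos[3], b = 90, alt = "",
                 stringsAsFactors = FALSE)
    cg <- cb + 1.52 * dir
    if (resid == "ASP") {
      od1 <- cg + 1.25 * unit(0.5 * dir + 0.87 * perp)
      od2 <- cg + 1.25 * unit(0.5 * dir - 0.87 * perp)
      extra <- c(extra, list(stub("CG", "C", cg), stub("OD1", "O", od1),
                             stub("OD2", "O", od2)))
    } else if (resid == "LEU") {
      cd1 <- cg + 1.53 * unit(0.5 * dir + 0.87 * perp)
      cd2 <- cg + 1.53 * unit(0.5 * dir - 0.87 * perp)
      extra <- c(extra, list(stub("CG", "C", cg), stub("CD1", "C", cd1),
                             stub("CD2", "C", cd2)))
    } else if (resid == "TYR") {
      extra <- c(extra, list(stub("CG", "C", cg),
                             stub("OH", "O", cb + 4.0 * dir)))
    } else if (resid == "LYS") {
      extra <- c(extra, list(stub("CG", "C", cg),
                             stub("NZ", "N", cb + 3.9 * dir)))
    }
  }
  if (length(extra) > 0) {
    model$atoms <- rbind(at, do.call(rbind, extra))
    ord <- order(match(model$atoms$chain, unique(model$atoms$chain)),
                 model$atoms$resno)
    model$atoms <- model$atoms[ord, ]
    rownames(model$atoms) <- NULL
  }
  model
}

# place a built helix so its axis runs along `axis_dir` through `center`
place_segment <- function(model, center, axis_dir) {
  bb <- backbone_coords(model)
  ax <- helix_axis(bb$CA)
  R <- rotation_between(ax$axis, axis_dir)
  motion <- list(R = R, t = center - as.numeric(R %*% ax$center))
  transform_model(model, motion)
}

receptor_segment_plan <- function() {
  data.frame(
    from = c(16L, 44L, 70L, 96L, 122L),
    to = c(39L, 67L, 93L, 119L, 145L),
    x = c(-10, -4.5, 0, 4.5, 10),
    y = c(-9, 0, -10.5, 0, -9),
    flip = c(FALSE, TRUE, FALSE, FALSE, TRUE))
}

#' Build the mock SHD1 receptor
#'
#' A five-helix bundle on chain A whose author numbering is chosen so that
#' the groove residues of [groove_definition()] exist with the expected
#' side-chain atom names: Leu at 48, 51, 59, 98, 101 and 109 (hydrophobic
#' patch), Lys97, and the two symmetric aspartates 62 and 112. A synthetic
#' stand-in for the real domain that lets all groove logic run without any
#' downloaded structure.
#'
#' @return a `structure_model` with one chain "A"
#' @export
build_mock_receptor <- function() {
  plan <- receptor_segment_plan()
  special <- c("48" = "L", "51" = "L", "59" = "L", "62" = "D",
               "97" = "K", "98" = "L", "101" = "L", "109" = "L",
               "112" = "D")
  parts <- list()
  for (s in seq_len(nrow(plan))) {
    resnos <- plan$from[s]:plan$to[s]
    aa <- ifelse(as.character(resnos) %in% names(special),
                 special[as.character(resnos)], "A")
    seg <- build_backbone(paste(aa, collapse = ""),
                          dihedrals_preset(length(resnos), "helix"),
                          chain = "A", model_id = "SHD1MOCK",
                          resno_start = plan$from[s])
    dirv <- if (plan$flip[s]) c(0, 0, -1) else c(0, 0, 1)
    parts[[s]] <- place_segment(seg, c(plan$x[s], plan$y[s], 0), dirv)$atoms
  }
  m <- structure_model(do.call(rbind, parts), model_id = "SHD1MOCK",
                       source_format = "built")
  add_sidechain_stubs(m)
}

# rigidly place a built ligand so that the hydroxyl of its motif Tyr(+2)
# points at, and sits `hb_dist` short of, the chosen receptor carboxylate
place_ligand_at_asp <- function(ligand, receptor, motif_start, asp_resno,
                                axis_dir, hb_dist = 2.8) {
  at <- receptor$atoms
  od <- at[at$resno == asp_resno & at$elety == "OD1", c("x", "y", "z")]
  od <- as.numeric(od[1, ])
  groove_center <- c(0, 1.5, od[3])
  w <- unit(od - groove_center)
  # align ligand helix axis with the groove axis
  bb <- backbone_coords(ligand)
  ax <- helix_axis(bb$CA)
  R1 <- rotation_between(ax$axis, axis_dir)
  lig <- transform_model(ligand, list(R = R1, t = -as.numeric(R1 %*% ax$center)))
  # roll about the axis so the Tyr hydroxyl points along +w
  la <- lig$atoms
  oh <- as.numeric(la[la$resno == motif_start + 4L & la$elety == "OH",
                      c("x", "y", "z")][1, ])
  ca <- as.numeric(la[la$resno == motif_start + 4L & la$elety == "CA",
                      c("x", "y", "z")][1, ])
  v <- oh - ca
  v_perp <- v - sum(v * axis_dir) * axis_dir
  w_perp <- w - sum(w * axis_dir) * axis_dir
  if (vnorm(v_perp) > 1e-6 && vnorm(w_perp) > 1e-6) {
    ang <- atan2(sum(vcross(unit(v_perp), unit(w_perp)) * axis_dir),
                 sum(unit(v_perp) * unit(w_perp))) * 180 / pi
    R2 <- rotation_about_axis(axis_dir, ang)
    lig <- transform_model(lig, list(R = R2, t = c(0, 0, 0)))
  }
  # translate the hydroxyl onto its target point
  la <- lig$atoms
  oh <- as.numeric(la[la$resno == motif_start + 4L & la$elety == "OH",
                      c("x", "y", "z")][1, ])
  transform_model(lig, list(R = diag(3), t = (od - hb_dist * w) - oh))
}

# synthetic PAE: square matrix with small within-chain error and cross-chain
# blocks drawn from a truncated normal around `cross_mean`
synth_pae <- function(n_rec, n_lig, cross_mean, cross_sd = 1.0) {
  n <- n_rec + n_lig
  ij <- abs(outer(seq_len(n), seq_len(n), "-"))
  mat <- 1.0 + 0.03 * ij
  cross <- outer(seq_len(n) > n_rec, seq_len(n) > n_rec, "!=")
  k <- sum(cross)
  vals <- pmin(pmax(stats::rnorm(k, cross_mean, cross_sd), 0.2), 31.75)
  mat[cross] <- vals
  round(mat, 2)
}

#' Generate a synthetic complex-prediction bundle
#'
#' Writes `model.pdb` (chain A = mock SHD1 receptor, chain B = motif
#' peptide), `pae.json` (flat dialect with a `chain_boundary` field) and
#' `summary.json` (with `iptm`) into `dir`, emulating the on-disk shape of a
#' structure-prediction output. Binders place the helical motif in the
#' groove with low cross-chain PAE and an ipTM above the reference;
#' non-binders violate exactly their designed failure criterion.
#'
#' @param dir bundle directory (created)
#' @param candidate_id identifier written into the bundle
#' @param motif_residues the 5 motif letters (position +2 must be Y for an
#'   orientation to be requested)
#' @param binder logical; TRUE for a complex that passes stages 4 and 5
#' @param orientation "canonical_D112" or "flipped_D62"
#' @param failure_stage for non-binders: "separated" (no groove contact),
#'   "extended" (motif not helical) or "iptm" (geometry fine, score below
#'   reference)
#' @param reference_iptm the stage-5 threshold the scores are generated
#'   against
#' @param iptm optional explicit ipTM (e.g. exactly the reference, for the
#'   reference candidate itself)
#' @param seed integer seed
#' @return list with `dir`, `iptm`, `motif_start` (ligand author numbering)
#' @export
generate_synthetic_complex <- function(dir, candidate_id, motif_residues,
                                       binder = TRUE,
                                       orientation = c("canonical_D112",
                                                       "flipped_D62"),
                                       failure_stage = NULL,
                                       reference_iptm = 0.50,
                                       iptm = NULL, seed = 1L) {
  orientation <- match.arg(orientation)
  if (binder && !is.null(failure_stage))
    stop("a binder cannot have a designed failure stage")
  if (!binder && is.null(failure_stage))
    stop("non-binders need failure_stage: separated, extended or iptm")
  if (substr(motif_residues, 5, 5) != "Y")
    stop("orientation placement requires Tyr at motif position +2")
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  receptor <- build_mock_receptor()
  extended <- !is.null(failure_stage) && failure_stage == "extended"
  flank1 <- sample_background_seq(4)
  flank2 <- sample_background_seq(4)
  lig_seq <- paste0(flank1, motif_residues, flank2)
  dih <- if (extended) dihedrals_preset(13, "strand")
         else dihedrals_preset(13, "helix")
  motif_start <- 5L
  ligand <- build_backbone(lig_seq, dih, chain = "B", model_id = "ligand")
  ligand <- add_sidechain_stubs(ligand)
  asp <- if (orientation == "canonical_D112") 112L else 62L
  axis <- if (orientation == "canonical_D112") c(0, 0, 1) else c(0, 0, -1)
  ligand <- place_ligand_at_asp(ligand, receptor, motif_start, asp, axis)
  if (!is.null(failure_stage) && failure_stage == "separated")
    ligand <- transform_model(ligand,
                              list(R = diag(3), t = c(0, 100, 0)))
  complex <- merge_models(receptor, ligand, model_id = candidate_id)
  write_structure(complex, file.path(dir, "model.pdb"), format = "PDB")
  n_rec <- nrow(chain_residues(complex, "A"))
  n_lig <- nrow(chain_residues(complex, "B"))
  good_geometry <- binder || failure_stage == "iptm"
  pae <- synth_pae(n_rec, n_lig,
                   cross_mean = if (good_geometry) 4.5 else 18)
  if (is.null(iptm)) {
    iptm <- if (binder) reference_iptm + stats::runif(1, 0.10, 0.30)
    else if (failure_stage == "iptm")
      reference_iptm - stats::runif(1, 0.05, 0.20)
    else stats::runif(1, 0.10, 0.25)
  }
  iptm <- round(min(max(iptm, 0), 1), 2)
  jsonlite::write_json(list(predicted_aligned_error = pae,
                            chain_boundary = n_rec + 1L),
                       file.path(dir, "pae.json"), digits = NA,
                       auto_unbox = TRUE)
  jsonlite::write_json(list(candidate_id = candidate_id, iptm = iptm,
                            chain_boundary = n_rec + 1L),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA)
  list(dir = dir, iptm = iptm, motif_start = motif_start)
}

#' Generate a localization table
#'
#' @param path output TSV path
#' @param ids protein identifiers
#' @param cytosolic_fraction fraction of ids labelled cytosolic
#' @param seed integer seed
#' @param force_cytosolic,force_noncytosolic ids whose label is fixed
#' @return `path`, invisibly; the table has columns `id`, `labels`
#' @export
generate_localization_table <- function(path, ids, cytosolic_fraction = 0.6,
                                        seed = 1L,
                                        force_cytosolic = character(),
                                        force_noncytosolic = character()) {
  stopifnot(cytosolic_fraction >= 0, cytosolic_fraction <= 1)
  set.seed(seed)
  other <- c("nucleus", "mitochondrion", "endoplasmic reticulum", "vacuole",
             "plasma membrane")
  n <- length(ids)
  cyto <- stats::runif(n) < cytosolic_fraction
  cyto[ids %in% force_cytosolic] <- TRUE
  cyto[ids %in% force_noncytosolic] <- FALSE
  labels <- vapply(seq_len(n), function(i) {
    extra <- sample(other, sample(0:1, 1))
    base <- if (cyto[i]) "cytosol" else sample(other, 1)
    paste(unique(c(base, extra)), collapse = ";")
  }, character(1))
  utils::write.table(data.frame(id = ids, labels = labels), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate the full funnel benchmark
#'
#' Builds, under one directory, a toy proteome with planted motifs, a
#' localization table and complex-prediction bundles, such that every
#' candidate either survives the whole funnel or fails at exactly one
#' designed stage. The reference candidate (the weak-binder analog whose
#' ipTM defines the stage-5 threshold) is planted with an ipTM exactly equal
#' to the reference value and, by the inclusive comparison, survives.
#'
#' @param dir output directory (created; subdirectories `proteome/`,
#'   `bundles/`, files `localization.tsv`, `truth.json`)
#' @param seed integer seed
#' @param reference_iptm the stage-5 threshold
#' @return list with `paths` (proteome, localization, bundles, truth),
#'   `truth` (data.frame: `id`, `context`, `failure_stage`, `last_stage`,
#'   `motif_start`, `residues`, `iptm`), `expected_counts` (stages 1-5) and
#'   `reference_id`
#' @export
generate_funnel_benchmark <- function(dir, seed = 1L,
                                      reference_iptm = 0.50) {
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pattern <- frm_pattern("relaxed")
  plan <- data.frame(
    role = c(rep("binder", 4), "reference",
             rep("fail2", 4), rep("fail3", 3),
             rep("fail4_separated", 2), rep("fail4_extended", 2),
             rep("fail5", 3), rep("none", 6)),
    context = c("helix", "helix", "coil", "coil", "helix",
                rep("strand", 4), rep("coil", 3),
                rep("helix", 2), rep("coil", 2),
                rep("helix", 3), rep("none", 6)),
    stringsAsFactors = FALSE)
  plan$id <- sprintf("SYN%04d", seq_len(nrow(plan)))
  last_stage_of <- c(binder = 5L, reference = 5L, fail2 = 1L, fail3 = 2L,
                     fail4_separated = 3L, fail4_extended = 3L, fail5 = 4L,
                     none = 0L)
  plan$last_stage <- unname(last_stage_of[plan$role])

  # proteome
  proteome_dir <- file.path(dir, "proteome")
  dir.create(proteome_dir, showWarnings = FALSE)
  plan$motif_start <- NA_integer_
  plan$residues <- NA_character_
  for (i in seq_len(nrow(plan))) {
    id <- plan$id[i]
    if (plan$role[i] == "none") {
      model <- build_plain_protein(id, sample(40:80, 1))
    } else {
      res <- paste(vapply(pattern$positions, function(s) sample(s, 1),
                          character(1)), collapse = "")
      built <- build_context_protein(id, res, plan$context[i])
      model <- built$model
      plan$motif_start[i] <- built$start
      plan$residues[i] <- res
    }
    write_structure(model,
                    file.path(proteome_dir,
                              sprintf("AF-%s-F1-model_v4.pdb", id)),
                    format = "PDB")
  }

  # localization: fail3 candidates are non-cytosolic, all other motif
  # carriers cytosolic, motif-free proteins random
  loc_path <- file.path(dir, "localization.tsv")
  generate_localization_table(
    loc_path, plan$id, cytosolic_fraction = 0.6,
    seed = seed + 1L,
    force_cytosolic = plan$id[plan$role %in%
      c("binder", "reference", "fail2", "fail4_separated",
        "fail4_extended", "fail5")],
    force_noncytosolic = plan$id[plan$role == "fail3"])

  # complex bundles for every candidate that reaches stage 4
  bundles_dir <- file.path(dir, "bundles")
  dir.create(bundles_dir, showWarnings = FALSE)
  plan$iptm <- NA_real_
  needs_bundle <- plan$role %in% c("binder", "reference", "fail4_separated",
                                   "fail4_extended", "fail5")
  for (i in which(needs_bundle)) {
    role <- plan$role[i]
    bdir <- file.path(bundles_dir,
                      paste0(plan$id[i], "_", plan$motif_start[i]))
    out <- generate_synthetic_complex(
      bdir, candidate_id = plan$id[i], motif_residues = plan$residues[i],
      binder = role %in% c("binder", "reference"),
      orientation = if (i %% 2 == 0) "canonical_D112" else "flipped_D62",
      failure_stage = switch(role, fail4_separated = "separated",
                             fail4_extended = "extended", fail5 = "iptm",
                             NULL),
      reference_iptm = reference_iptm,
      iptm = if (role == "reference") reference_iptm else NULL,
      seed = seed + 100L + i)
    plan$iptm[i] <- out$iptm
  }

  truth <- plan[, c("id", "role", "context", "last_stage", "motif_start",
                    "residues", "iptm")]
  expected_counts <- vapply(1:5, function(k) sum(truth$last_stage >= k),
                            integer(1))
  names(expected_counts) <- paste0("stage", 1:5)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(seed = seed, reference_iptm = reference_iptm,
         reference_id = plan$id[plan$role == "reference"],
         expected_counts = as.list(expected_counts), truth = truth),
    truth_path, auto_unbox = TRUE, digits = NA, na = "null")
  list(paths = list(proteome = proteome_dir, localization = loc_path,
                    bundles = bundles_dir, truth = truth_path),
       truth = truth, expected_counts = expected_counts,
       reference_id = plan$id[plan$role == "reference"],
       reference_iptm = reference_iptm)
}
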