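# Evidence extraction from two-chain complex predictions: predicted aligned
# error (PAE) matrices, ipTM scores, motif-groove contacts, motif helicity in
# the complex, and the hydrogen-bond orientation of the motif Tyr(+2).

#' Default groove definition for the SHD1 receptor
#'
#' Hydrophobic-patch residues {48, 51, 59, 98, 101, 109}, the charged rim
#' residue K97 and the two symmetric hydrogen-bond acceptors D112 (canonical
#' helix orientation) and D62 (flipped orientation), in full-length Spa2
#' numbering. Cutoffs follow standard structural-biology conventions:
#' 4.5 Angstrom heavy-atom contacts, 3.5 Angstrom donor-acceptor H-bonds.
#'
#' @param contact_cutoff heavy-atom contact distance (Angstrom)
#' @param hbond_cutoff hydroxyl-carboxylate H-bond distance (Angstrom)
#' @param numbering_offset added to the groove residue numbers to map
#'   full-length numbering onto an SHD1 fragment chain (0 for full length)
#' @return object of class `groove_definition`
#' @export
groove_definition <- function(contact_cutoff = 4.5, hbond_cutoff = 3.5,
                              numbering_offset = 0L) {
  stopifnot(contact_cutoff > 0, hbond_cutoff > 0)
  structure(list(
    hydrophobic = c(48L, 51L, 59L, 98L, 101L, 109L) + numbering_offset,
    lysine = 97L + numbering_offset,
    asp_canonical = 112L + numbering_offset,
    asp_flipped = 62L + numbering_offset,
    contact_cutoff = contact_cutoff,
    hbond_cutoff = hbond_cutoff),
    class = "groove_definition")
}

#' Read a PAE matrix from JSON
#'
#' Supports the flat dialect (a square list-of-lists under
#' `predicted_aligned_error` or `pae`) and the paired-array dialect
#' (`residue1` / `residue2` / `distance`). The chain boundary (1-based index
#' of the first residue of chain B) is taken from a `chain_boundary` field or
#' the explicit argument.
#'
#' @param path JSON file path
#' @param chain_boundary first residue index of chain B; overrides metadata
#' @return object of class `pae_matrix`: list with `n`, `matrix`, `boundary`
#' @export
read_pae_matrix <- function(path, chain_boundary = NULL) {
  j <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.data.frame(j) || (is.list(j) && is.null(names(j)) && length(j) == 1))
    j <- as.list(if (is.data.frame(j)) j else j[[1]])
  mat <- NULL
  if (!is.null(j$predicted_aligned_error)) mat <- j$predicted_aligned_error
  else if (!is.null(j$pae)) mat <- j$pae
  else if (!is.null(j$residue1) && !is.null(j$residue2) &&
           !is.null(j$distance)) {
    n <- max(j$residue1, j$residue2)
    mat <- matrix(NA_real_, n, n)
    mat[cbind(j$residue1, j$residue2)] <- j$distance
    if (any(is.na(mat))) stop("paired-array PAE does not cover all pairs")
  } else stop("no recognised PAE field in '", path, "'")
  if (is.list(mat) && !is.matrix(mat)) {
    lens <- lengths(mat)
    if (length(unique(lens)) != 1)
      stop("ragged PAE rows: lengths ", paste(unique(lens), collapse = ", "))
    mat <- do.call(rbind, mat)
  }
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat))
    stop("PAE matrix is not square: ", nrow(mat), " x ", ncol(mat))
  if (any(mat < 0)) stop("negative PAE entries")
  boundary <- chain_boundary
  if (is.null(boundary)) boundary <- j$chain_boundary
  if (is.null(boundary))
    stop("chain boundary not in metadata; pass chain_boundary explicitly")
  boundary <- as.integer(boundary)
  if (boundary <= 1 || boundary > nrow(mat))
    stop("chain boundary ", boundary, " outside (1, n]")
  structure(list(n = nrow(mat), matrix = mat, boundary = boundary),
            class = "pae_matrix")
}

#' Mean and minimum cross-chain PAE over an index block
#'
#' PAE matrices are not symmetric, so both off-diagonal blocks
#' (motif -> receptor and receptor -> motif) are averaged.
#'
#' @param pae a `pae_matrix`
#' @param motif_idx residue indices of the motif window (ligand side)
#' @param receptor_idx residue indices on the receptor side
#' @return list with `mean` and `min` (Angstrom)
#' @export
interface_pae_summary <- function(pae, motif_idx, receptor_idx) {
  stopifnot(inherits(pae, "pae_matrix"))
  if (length(motif_idx) == 0 || length(receptor_idx) == 0)
    stop("empty index set")
  if (any(c(motif_idx, receptor_idx) < 1) ||
      any(c(motif_idx, receptor_idx) > pae$n))
    stop("indices outside the PAE matrix")
  b <- pae$boundary
  side <- function(ix) ifelse(ix >= b, "B", "A")
  if (length(unique(side(motif_idx))) > 1 ||
      length(unique(side(receptor_idx))) > 1 ||
      side(motif_idx[1]) == side(receptor_idx[1]))
    stop("motif and receptor windows must lie on opposite sides of the ",
         "chain boundary")
  blocks <- c(pae$matrix[motif_idx, receptor_idx, drop = FALSE],
              pae$matrix[receptor_idx, motif_idx, drop = FALSE])
  list(mean = mean(blocks), min = min(blocks))
}

heavy_atoms <- function(atoms) atoms[atoms$elesy != "H", , drop = FALSE]

#' Heavy-atom contacts between a motif window and the groove
#'
#' All heavy-atom pairs between the motif residues on the ligand chain and
#' the hydrophobic-patch residues on the receptor chain within the contact
#' cutoff. The minimum distance is reported even when there is no contact.
#'
#' @param model two-chain `structure_model`
#' @param groove a `groove_definition`
#' @param motif_start author number of motif position -2 on the ligand chain
#' @param receptor_chain,ligand_chain chain ids (defaults: first and second)
#' @return list with `groove_contact`, `n_contact_pairs`, `min_dist`, and
#'   `pairs` (data.frame of contacting atom pairs)
#' @export
interchain_contacts <- function(model, groove, motif_start,
                                receptor_chain = chain_ids(model)[1],
                                ligand_chain = chain_ids(model)[2]) {
  stopifnot(inherits(groove, "groove_definition"))
  at <- model$atoms
  rec <- heavy_atoms(at[at$chain == receptor_chain &
                          at$resno %in% groove$hydrophobic, , drop = FALSE])
  missing <- setdiff(groove$hydrophobic,
                     unique(at$resno[at$chain == receptor_chain]))
  if (length(missing) > 0)
    stop("groove residues absent from receptor chain: ",
         paste(missing, collapse = ", "))
  win <- motif_start:(motif_start + 4L)
  lig <- heavy_atoms(at[at$chain == ligand_chain & at$resno %in% win, ,
                        drop = FALSE])
  if (nrow(lig) == 0) stop("motif window not present on ligand chain")
  D <- cross_dist(as.matrix(lig[, c("x", "y", "z")]),
                  as.matrix(rec[, c("x", "y", "z")]))
  hit <- which(D <= groove$contact_cutoff, arr.ind = TRUE)
  pairs <- data.frame(
    lig_resno = lig$resno[hit[, 1]], lig_atom = lig$elety[hit[, 1]],
    rec_resno = rec$resno[hit[, 2]], rec_atom = rec$elety[hit[, 2]],
    dist = D[hit], stringsAsFactors = FALSE)
  list(groove_contact = nrow(pairs) > 0,
       n_contact_pairs = nrow(pairs),
       min_dist = min(D),
       pairs = pairs[order(pairs$dist), ])
}

#' Is the motif helical in the complex?
#'
#' TRUE iff at least 4 of the 5 motif residues are labelled 'H' by
#' [assign_secondary_structure()] run on the ligand chain in its complex
#' conformation.
#'
#' @inheritParams interchain_contacts
#' @return TRUE/FALSE, or NA ("not evaluable") when backbone atoms are
#'   missing or the window is incomplete
#' @export
motif_helicity_in_complex <- function(model, motif_start,
                                      ligand_chain = chain_ids(model)[2]) {
  win <- motif_start:(motif_start + 4L)
  bb <- tryCatch(backbone_coords(model, ligand_chain),
                 error = function(e) NULL)
  if (is.null(bb) || !all(win %in% bb$resno)) return(NA)
  idx <- match(win, bb$resno)
  if (any(!is.finite(bb$N[idx, ])) || any(!is.finite(bb$CA[idx, ])) ||
      any(!is.finite(bb$C[idx, ])) || any(!is.finite(bb$O[idx, ])))
    return(NA)
  ss <- assign_secondary_structure(model)
  lab <- ss_labels(ss, ligand_chain, win)
  if (any(is.na(lab))) return(NA)
  sum(lab == "H") >= 4
}

carboxylate_oxygens <- function(atoms, chain, resno) {
  sel <- atoms$chain == chain & atoms$resno == resno &
    atoms$elety %in% c("OD1", "OD2", "OE1", "OE2")
  atoms[sel, , drop = FALSE]
}

#' Classify the motif helix orientation in the groove
#'
#' Uses the hydrogen-bond partner of the motif Tyr(+2) hydroxyl: the
#' canonical orientation bonds to the receptor's Asp112 carboxylate, the
#' flipped orientation to Asp62. Returns "not_applicable" when position +2
#' is not a tyrosine.
#'
#' @inheritParams interchain_contacts
#' @return one of "canonical_D112", "flipped_D62", "indeterminate",
#'   "not_applicable"
#' @export
classify_orientation <- function(model, motif_start, groove,
                                 receptor_chain = chain_ids(model)[1],
                                 ligand_chain = chain_ids(model)[2]) {
  at <- model$atoms
  tyr_resno <- motif_start + 4L
  tyr <- at[at$chain == ligand_chain & at$resno == tyr_resno, , drop = FALSE]
  if (nrow(tyr) == 0 || tyr$resid[1] != "TYR") return("not_applicable")
  oh <- tyr[tyr$elety == "OH", , drop = FALSE]
  if (nrow(oh) == 0) return("not_applicable")
  p_oh <- as.numeric(oh[1, c("x", "y", "z")])
  d_to <- function(resno) {
    ox <- carboxylate_oxygens(at, receptor_chain, resno)
    if (nrow(ox) == 0) return(Inf)
    min(apply(as.matrix(ox[, c("x", "y", "z")]), 1,
              function(p) vnorm(p - p_oh)))
  }
  d112 <- d_to(groove$asp_canonical)
  d62 <- d_to(groove$asp_flipped)
  if (d112 <= groove$hbond_cutoff && d112 < d62) "canonical_D112"
  else if (d62 <= groove$hbond_cutoff && d62 < d112) "flipped_D62"
  else "indeterminate"
}

#' Read a complex-prediction bundle
#'
#' A bundle is a directory holding `model.pdb` (or `model.cif`), optionally
#' `pae.json` and `summary.json` (with fields `iptm` and optionally
#' `chain_boundary`). Structure prediction itself is never run; its outputs
#' are consumed.
#'
#' @param dir bundle directory
#' @param candidate_id identifier; default the directory name
#' @return object of class `complex_prediction`: list with `candidate_id`,
#'   `model`, `pae` (or NULL), `iptm` (or NA)
#' @export
read_complex_bundle <- function(dir, candidate_id = basename(dir)) {
  if (!dir.exists(dir)) stop("no such bundle directory: '", dir, "'")
  mfile <- list.files(dir, pattern = "^model\\.(pdb|cif)$", full.names = TRUE)
  if (length(mfile) != 1) stop("bundle must contain exactly one model.pdb ",
                               "or model.cif")
  model <- read_structure(mfile, model_id = candidate_id)
  if (length(chain_ids(model)) != 2)
    stop("complex model must have exactly 2 chains, found ",
         length(chain_ids(model)))
  iptm <- NA_real_
  boundary <- NULL
  sfile <- file.path(dir, "summary.json")
  if (file.exists(sfile)) {
    s <- jsonlite::fromJSON(sfile)
    if (!is.null(s$iptm)) iptm <- as.numeric(s$iptm)
    if (!is.null(s$chain_boundary)) boundary <- s$chain_boundary
  }
  if (!is.na(iptm) && (iptm < 0 || iptm > 1))
    stop("iptm outside [0, 1]: ", iptm)
  pfile <- file.path(dir, "pae.json")
  pae <- if (file.exists(pfile)) read_pae_matrix(pfile, boundary) else NULL
  structure(list(candidate_id = candidate_id, model = model, pae = pae,
                 iptm = iptm),
            class = "complex_prediction")
}

#' Full interface evidence for a candidate complex
#'
#' @param prediction a `complex_prediction`
#' @param groove a `groove_definition`
#' @param motif_start author number of motif position -2 on the ligand chain
#' @return object of class `interface_evidence`: list with `groove_contact`,
#'   `n_contact_pairs`, `min_dist`, `motif_helical`, `orientation`,
#'   `mean_interface_pae`, `min_interface_pae`, `iptm`
#' @export
evaluate_complex <- function(prediction, groove = groove_definition(),
                             motif_start) {
  stopifnot(inherits(prediction, "complex_prediction"))
  m <- prediction$model
  contacts <- interchain_contacts(m, groove, motif_start)
  helical <- motif_helicity_in_complex(m, motif_start)
  orient <- classify_orientation(m, motif_start, groove)
  if (!isTRUE(contacts$groove_contact) &&
      orient %in% c("canonical_D112", "flipped_D62"))
    orient <- "indeterminate"   # orientation claims require groove contact
  mean_pae <- NA_real_; min_pae <- NA_real_
  if (!is.null(prediction$pae)) {
    b <- prediction$pae$boundary
    rec_chain <- chain_ids(m)[1]
    n_rec <- nrow(chain_residues(m, rec_chain))
    lig_res <- chain_residues(m, chain_ids(m)[2])
    w <- match(motif_start:(motif_start + 4L), lig_res$resno)
    if (!any(is.na(w))) {
      s <- interface_pae_summary(prediction$pae,
                                 motif_idx = b - 1L + w,
                                 receptor_idx = seq_len(n_rec))
      mean_pae <- s$mean; min_pae <- s$min
    }
  }
  structure(list(candidate_id = prediction$candidate_id,
                 groove_contact = contacts$groove_contact,
                 n_contact_pairs = contacts$n_contact_pairs,
                 min_dist = contacts$min_dist,
                 motif_helical = helical,
                 orientation = orient,
                 mean_interface_pae = mean_pae,
                 min_interface_pae = min_pae,
                 iptm = prediction$iptm),
            class = "interface_evidence")
}
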