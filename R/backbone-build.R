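# Ideal backbone geometry (Engh-Huber-style averages)
#' Default backbone geometry for the structure builder
#'
#' Bond lengths, bond angles and named dihedral presets used by
#' [build_backbone()]. Helix preset (-57, -47); strand preset (-139, 135);
#' the trans peptide bond (omega = 180) is fixed.
#'
#' @return list of geometric constants
#' @export
backbone_geometry <- function() {
  list(
    b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
    b_c_o = 1.231, b_ca_cb = 1.521,
    a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
    a_ca_c_o = 120.5, a_n_ca_cb = 110.4,
    omega = 180,
    presets = list(helix = c(phi = -57, psi = -47),
                   strand = c(phi = -139, psi = 135)))
}

#' Dihedral table for a preset conformation
#'
#' @param n number of residues
#' @param preset "helix" or "strand"
#' @return data.frame with columns `phi`, `psi`
#' @export
dihedrals_preset <- function(n, preset = c("helix", "strand")) {
  preset <- match.arg(preset)
  p <- backbone_geometry()$presets[[preset]]
  data.frame(phi = rep(p["phi"], n), psi = rep(p["psi"], n))
}

#' Build a backbone structure from sequence and dihedrals
#'
#' NeRF-style internal-to-Cartesian chain extension with ideal bond lengths
#' and angles. Places N, CA, C, carbonyl O (in the peptide plane) and a
#' tetrahedral C-beta for non-glycine residues. `phi[1]` and the chain is
#' extended with trans peptide bonds (omega = 180).
#'
#' @param sequence one-letter amino-acid sequence
#' @param dihedrals data.frame with columns `phi`, `psi` (degrees), one row
#'   per residue; `psi` of the last residue only orients its carbonyl
#' @param geometry list from [backbone_geometry()]
#' @param chain chain identifier
#' @param model_id model identifier
#' @param resno_start author number of the first residue
#' @return a `structure_model`
#' @export
build_backbone <- function(sequence, dihedrals,
                           geometry = backbone_geometry(),
                           chain = "A", model_id = "built",
                           resno_start = 1L) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n == 0) stop("empty sequence")
  if (!is.data.frame(dihedrals) || nrow(dihedrals) != n)
    stop("dihedral table must have one row per residue (", n, " needed, got ",
         nrow(dihedrals), ")")
  bad <- setdiff(aa, names(AA_123))
  if (length(bad) > 0)
    stop("sequence contains non-standard letters: ",
         paste(unique(bad), collapse = ""))
  g <- geometry
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N; CB <- N
  # first residue in a canonical frame
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$b_c_n, g$a_ca_c_n, dihedrals$psi[i - 1])
      CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca, g$omega)
      C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                           g$b_ca_c, g$a_n_ca_c, dihedrals$phi[i])
    }
    # carbonyl O in the peptide plane, anti to the next N
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, dihedrals$psi[i] + 180)
    if (aa[i] != "G")
      CB[i, ] <- nerf_place(C[i, ], N[i, ], CA[i, ],
                            g$b_ca_cb, g$a_n_ca_cb, -122.6)
  }
  rows <- list()
  for (i in seq_len(n)) {
    resid3 <- unname(AA_123[aa[i]])
    atom_names <- c("N", "CA", "C", "O")
    coords <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    elems <- c("N", "C", "C", "O")
    if (aa[i] != "G") {
      atom_names <- c(atom_names, "CB")
      coords <- rbind(coords, CB[i, ])
      elems <- c(elems, "C")
    }
    rows[[i]] <- data.frame(
      chain = chain, resno = resno_start + i - 1L, inscode = "",
      resid = resid3, elety = atom_names, elesy = elems,
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      b = 90, alt = "", stringsAsFactors = FALSE)
  }
  structure_model(do.call(rbind, rows), model_id = model_id,
                  source_format = "built",
                  metadata = list(builder = "nerf-ideal-geometry"))
}

#' Merge several models into one multi-chain model
#' @param ... `structure_model` objects with distinct chain ids
#' @param model_id identifier for the merged model
#' @return a `structure_model`
#' @export
merge_models <- function(..., model_id = "complex") {
  parts <- list(...)
  atoms <- do.call(rbind, lapply(parts, function(m) m$atoms))
  structure_model(atoms, model_id = model_id, source_format = "built")
}

#' Apply a rigid motion to a whole model
#' @param model a `structure_model`
#' @param motion list with `R` and `t` (see [random_rigid_motion()])
#' @return transformed `structure_model`
#' @export
transform_model <- function(model, motion) {
  xyz <- apply_rigid_motion(as.matrix(model$atoms[, c("x", "y", "z")]), motion)
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# least-squares axis of a helix from its CA coordinates: first principal
# component of the centred coordinates, oriented N- to C-terminus
helix_axis <- function(ca) {
  ctr <- colMeans(ca)
  s <- svd(sweep(ca, 2, ctr))
  ax <- s$v[, 1]
  if (sum((ca[nrow(ca), ] - ca[1, ]) * ax) < 0) ax <- -ax
  list(center = ctr, axis = ax)
}
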