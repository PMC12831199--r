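#' @importFrom utils head tail
NULL

#' Construct a structure model from an atom table
#'
#' The atom table is the single source of truth for a model: one row per atom
#' with columns `chain`, `resno` (author numbering), `inscode`, `resid`
#' (three-letter code), `elety` (atom name), `elesy` (element), `x`, `y`, `z`,
#' `b` (B-factor / per-residue confidence) and `alt`.
#'
#' @param atoms data.frame as described above
#' @param model_id protein identifier (e.g. a UniProt accession)
#' @param source_format "PDB", "mmCIF" or "built"
#' @param metadata free-form provenance list
#' @return an object of class `structure_model`
#' @export
structure_model <- function(atoms, model_id, source_format = "built",
                            metadata = list()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  needed <- c("chain", "resno", "inscode", "resid", "elety", "elesy",
              "x", "y", "z", "b", "alt")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0)
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (is.null(model_id) || !nzchar(model_id)) stop("model_id must be non-empty")
  rownames(atoms) <- NULL
  structure(list(model_id = model_id, atoms = atoms,
                 source_format = source_format, metadata = metadata),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model>", x$model_id, "\n")
  cat("  chains:", paste(chain_ids(x), collapse = ", "),
      " atoms:", nrow(x$atoms),
      " source:", x$source_format, "\n")
  invisible(x)
}

#' Chain identifiers of a model
#' @param model a `structure_model`
#' @return character vector in order of first appearance
#' @export
chain_ids <- function(model) unique(model$atoms$chain)

#' Residue-level view of one chain
#'
#' Collapses the atom table of a chain to one row per residue, ordered as in
#' the file, with the one-letter code attached.
#'
#' @param model a `structure_model`
#' @param chain chain identifier; default first chain
#' @return data.frame with columns `resno`, `inscode`, `resid`, `code1`
#' @export
chain_residues <- function(model, chain = chain_ids(model)[1]) {
  at <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("chain '", chain, "' not present in model")
  key <- paste(at$resno, at$inscode, sep = "|")
  first <- !duplicated(key)
  res <- at[first, c("resno", "inscode", "resid")]
  res$code1 <- unname(ifelse(res$resid %in% names(AA_321),
                             AA_321[res$resid], "X"))
  rownames(res) <- NULL
  res
}

#' One-letter sequence of a chain
#'
#' Length equals the number of polymer residues; residues without a standard
#' parent become 'X' (MSE maps to M).
#'
#' @inheritParams chain_residues
#' @return single character string
#' @export
extract_sequence <- function(model, chain = chain_ids(model)[1]) {
  paste(chain_residues(model, chain)$code1, collapse = "")
}

#' Backbone coordinates of a chain
#'
#' @inheritParams chain_residues
#' @return list with `resno`, `code1`, and n x 3 matrices `N`, `CA`, `C`, `O`
#'   (rows of missing atoms are NA)
#' @export
backbone_coords <- function(model, chain = chain_ids(model)[1]) {
  at <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  res <- chain_residues(model, chain)
  n <- nrow(res)
  key_at <- paste(at$resno, at$inscode, sep = "|")
  key_res <- paste(res$resno, res$inscode, sep = "|")
  out <- list(resno = res$resno, code1 = res$code1)
  for (nm in c("N", "CA", "C", "O")) {
    m <- matrix(NA_real_, n, 3)
    sel <- at$elety == nm
    idx <- match(key_at[sel], key_res)
    m[idx, ] <- as.matrix(at[sel, c("x", "y", "z")])
    out[[nm]] <- m
  }
  out
}

detect_format <- function(path) {
  p <- sub("\\.gz$", "", tolower(path))
  if (grepl("\\.(cif|mmcif)$", p)) "mmCIF"
  else if (grepl("\\.(pdb|ent)$", p)) "PDB"
  else stop("cannot auto-detect structure format of '", path, "'")
}

# decompress a .gz structure file to a temp copy bio3d can read
maybe_gunzip <- function(path) {
  if (!grepl("\\.gz$", path)) return(path)
  tmp <- tempfile(fileext = paste0(".", tools::file_ext(sub("\\.gz$", "", path))))
  writeLines(readLines(gzfile(path)), tmp)
  tmp
}

#' Read a protein structure from PDB or mmCIF
#'
#' Keeps ATOM/HETATM records with blank or 'A' altloc, drops water, and for
#' multi-model PDB files keeps the first model only. Parsing is delegated to
#' bio3d.
#'
#' @param path file path (optionally gzipped)
#' @param format "PDB", "mmCIF" or "auto" (from the file extension)
#' @param model_id identifier to assign; default is parsed from the filename
#'   (AlphaFold-DB style `AF-<acc>-F1-model_vN` yields `<acc>`, otherwise the
#'   file stem)
#' @return a `structure_model`
#' @export
read_structure <- function(path, format = c("auto", "PDB", "mmCIF"),
                           model_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: '", path, "'")
  if (format == "auto") format <- detect_format(path)
  if (is.null(model_id)) model_id <- model_id_from_filename(path)
  fp <- maybe_gunzip(path)
  parsed <- tryCatch(
    if (format == "PDB") bio3d::read.pdb(fp, multi = FALSE, verbose = FALSE)
    # minimal files lack optional helix/sheet categories; not an error
    else suppressWarnings(bio3d::read.cif(fp, verbose = FALSE)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  a <- parsed$atom
  if (nrow(a) == 0) stop("empty model in '", path, "'")
  keep <- (is.na(a$alt) | a$alt %in% c("", "A")) &
    !(a$resid %in% WATER_RESIDUES)
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms left after altloc/water filtering in '",
                         path, "'")
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno,
    inscode = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid,
    elety = a$elety,
    elesy = ifelse(is.na(a$elesy) | a$elesy == "",
                   substr(gsub("[0-9']", "", a$elety), 1, 1), a$elesy),
    x = a$x, y = a$y, z = a$z,
    b = ifelse(is.na(a$b), 0, a$b),
    alt = ifelse(is.na(a$alt), "", a$alt),
    stringsAsFactors = FALSE)
  structure_model(atoms, model_id = model_id, source_format = format,
                  metadata = list(path = path))
}

model_id_from_filename <- function(path) {
  stem <- sub("\\.gz$", "", basename(path))
  stem <- tools::file_path_sans_ext(stem)
  m <- regmatches(stem, regexec("^AF-([A-Za-z0-9]+)-F[0-9]+-model", stem))[[1]]
  if (length(m) == 2) m[2] else stem
}

#' Write a structure model to PDB or mmCIF
#'
#' Coordinates are written with three decimals; the output is re-readable by
#' [read_structure()].
#'
#' @param model a `structure_model`
#' @param path output file path
#' @param format "PDB", "mmCIF" or "auto" (from the extension)
#' @return `path`, invisibly
#' @export
write_structure <- function(model, path, format = c("auto", "PDB", "mmCIF")) {
  format <- match.arg(format)
  if (!inherits(model, "structure_model")) stop("not a structure_model")
  if (format == "auto") format <- detect_format(path)
  at <- model$atoms
  if (nrow(at) == 0) stop("refusing to write an empty model")
  if (format == "PDB") {
    xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
    bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                     resno = at$resno, resid = at$resid,
                     eleno = seq_len(nrow(at)), elety = at$elety,
                     chain = at$chain, insert = ifelse(at$inscode == "",
                                                       NA, at$inscode),
                     alt = ifelse(at$alt == "", NA, at$alt),
                     o = rep(1, nrow(at)), b = at$b,
                     elesy = at$elesy)
  } else {
    write_mmcif(model, path)
  }
  invisible(path)
}

# minimal mmCIF writer: a single atom_site loop, enough for round-tripping
# backbone models (bio3d provides no mmCIF writer)
write_mmcif <- function(model, path) {
  at <- model$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("data_", model$model_id),
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"), con)
  lines <- sprintf(
    "ATOM %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f 1.00 %.2f %d %s %s %s 1",
    seq_len(nrow(at)), at$elesy, at$elety,
    ifelse(at$alt == "", ".", at$alt),
    at$resid, at$chain, at$resno,
    ifelse(at$inscode == "", "?", at$inscode),
    at$x, at$y, at$z, at$b, at$resno, at$resid, at$chain, at$elety)
  writeLines(lines, con)
  writeLines("#", con)
}

#' Iterate a proteome of structure files
#'
#' Reads every structure in a directory or a (optionally gzipped) tar archive,
#' in lexicographic order of entry name. Unparseable entries are skipped with
#' a warning, not fatal.
#'
#' @param source directory, or `.tar` / `.tar.gz` archive of PDB/mmCIF files
#' @param format format filter passed to [read_structure()]
#' @return list of `structure_model`; attributes `n_total`, `n_ok`,
#'   `n_skipped`, and `skipped` (named reasons)
#' @export
iterate_proteome <- function(source, format = c("auto", "PDB", "mmCIF")) {
  format <- match.arg(format)
  if (!file.exists(source)) stop("no such source: '", source, "'")
  if (dir.exists(source)) {
    files <- list.files(source, pattern = "\\.(pdb|ent|cif|mmcif)(\\.gz)?$",
                        full.names = TRUE, ignore.case = TRUE)
  } else if (grepl("\\.tar(\\.gz)?$|\\.tgz$", source)) {
    exdir <- tempfile("proteome_")
    dir.create(exdir)
    utils::untar(source, exdir = exdir)
    files <- list.files(exdir, pattern = "\\.(pdb|ent|cif|mmcif)(\\.gz)?$",
                        full.names = TRUE, recursive = TRUE,
                        ignore.case = TRUE)
  } else {
    stop("source must be a directory or a tar/tar.gz archive")
  }
  files <- files[order(basename(files))]
  if (length(files) == 0) stop("no structure files found in '", source, "'")
  models <- list()
  skipped <- character()
  for (f in files) {
    m <- tryCatch(read_structure(f, format = format), error = function(e) e)
    if (inherits(m, "error")) {
      skipped[basename(f)] <- conditionMessage(m)
      warning("skipping '", basename(f), "': ", conditionMessage(m),
              call. = FALSE)
    } else {
      models[[m$model_id]] <- m
    }
  }
  if (length(models) == 0)
    stop("all ", length(files), " entries failed to parse in '", source, "'")
  attr(models, "n_total") <- length(files)
  attr(models, "n_ok") <- length(models)
  attr(models, "n_skipped") <- length(skipped)
  attr(models, "skipped") <- skipped
  models
}
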