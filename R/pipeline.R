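# The staged candidate funnel: motif scan -> structural context ->
# localization -> groove binding -> ipTM threshold. Stage 6 of the underlying
# study (an in-vivo competition assay) is experimental and only echoed as a
# "pending" column, never computed.

CYTOSOLIC_LABELS <- c("cytosol", "cytoplasm", "cytosolic")

#' Read a protein localization table
#'
#' Two-column TSV: protein id, semicolon-separated compartment labels.
#' Lookups are case-insensitive on ids.
#'
#' @param path TSV file path
#' @param cytosolic_labels labels counted as cytosolic
#' @return object of class `localization_table`
#' @export
read_localization_table <- function(path,
                                    cytosolic_labels = CYTOSOLIC_LABELS) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           col.names = c("id", "labels"))
  lab <- strsplit(tolower(tab$labels), ";")
  names(lab) <- tolower(tab$id)
  structure(list(labels = lab,
                 cytosolic_labels = tolower(cytosolic_labels)),
            class = "localization_table")
}

#' Structural-context filter for a motif window
#'
#' A candidate survives iff none of its five motif residues is labelled 'E'
#' (strand): the motif must lie in unfolded or helical regions, mixtures of
#' helix and loop included.
#'
#' @param labels character vector of 5 three-class labels
#' @return TRUE (keep), FALSE (discard) or NA (unannotated)
#' @export
ss_context_filter <- function(labels) {
  if (length(labels) != 5 || any(is.na(labels))) return(NA)
  !any(labels == "E")
}

#' Localization filter
#'
#' Keeps a protein iff its compartment labels intersect the cytosolic label
#' set. Proteins absent from the table are kept and flagged by default
#' ("keep" policy) or dropped under the "strict" policy.
#'
#' @param id protein identifier
#' @param table a `localization_table`
#' @param unknown_policy "keep" or "strict"
#' @return list with `keep` and `flag`
#' @export
localization_filter <- function(id, table, unknown_policy = c("keep",
                                                              "strict")) {
  unknown_policy <- match.arg(unknown_policy)
  stopifnot(inherits(table, "localization_table"))
  labs <- table$labels[[tolower(id)]]
  if (is.null(labs))
    return(list(keep = unknown_policy == "keep", flag = "unknown-localization"))
  list(keep = length(intersect(labs, table$cytosolic_labels)) > 0, flag = "")
}

#' ipTM threshold filter
#'
#' Inclusive comparison: a candidate survives iff its ipTM is greater than or
#' equal to the reference complex's ipTM.
#'
#' @param iptm candidate score in [0, 1]
#' @param reference_iptm reference complex score
#' @return TRUE or FALSE
#' @export
iptm_filter <- function(iptm, reference_iptm) {
  if (is.null(reference_iptm) || is.na(reference_iptm))
    stop("reference ipTM is required for the threshold stage")
  if (is.na(iptm)) return(FALSE)
  iptm >= reference_iptm
}

#' Pipeline configuration
#'
#' @param pattern a `motif_pattern`
#' @param proteome_source directory or tar archive of structures
#' @param localization_path localization TSV, or NULL to skip stage 3
#' @param bundle_dir directory of per-candidate complex bundles (named
#'   `<protein_id>` or `<protein_id>_<start>`), or NULL to skip stages 4-5
#' @param reference_id candidate id whose ipTM is the stage-5 threshold (the
#'   weakest validated binder's role); alternatively set `reference_iptm`
#' @param reference_iptm explicit stage-5 threshold
#' @param groove a `groove_definition`
#' @param unknown_policy stage-3 policy for unannotated proteins
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(pattern, proteome_source,
                            localization_path = NULL, bundle_dir = NULL,
                            reference_id = NULL, reference_iptm = NULL,
                            groove = groove_definition(),
                            unknown_policy = "keep") {
  structure(list(pattern = pattern, proteome_source = proteome_source,
                 localization_path = localization_path,
                 bundle_dir = bundle_dir, reference_id = reference_id,
                 reference_iptm = reference_iptm, groove = groove,
                 unknown_policy = unknown_policy),
            class = "pipeline_config")
}

candidate_bundle_dir <- function(bundle_dir, id, start) {
  for (cand in file.path(bundle_dir, c(paste0(id, "_", start), id)))
    if (dir.exists(cand)) return(cand)
  NA_character_
}

#' Run the candidate-filtering funnel
#'
#' Stages: (1) motif scan over the proteome; (2) structural context (no
#' strand residue in the motif); (3) cytosolic localization; (4) groove
#' binding through the helical motif conformation in the predicted complex;
#' (5) ipTM at least that of the reference complex. Stages 3-5 are skipped
#' (survivors copied forward and marked) when their inputs are absent.
#' Protein-level counts deduplicate proteins with several motif occurrences.
#'
#' @param config a `pipeline_config`
#' @return object of class `filter_report`: list with `stages` (data.frame
#'   `stage`, `description`, `n_proteins`, `skipped`), `survivors` (list of
#'   protein-id sets per stage), `candidates` (per-match table with stage
#'   flags and exclusion reasons) and `config`
#' @export
run_search <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  models <- iterate_proteome(config$proteome_source)
  scan <- scan_proteome(models, config$pattern)
  cand <- scan$matches
  n <- nrow(cand)
  if (n == 0) {
    cand <- data.frame(model_id = character(), chain = character(),
                       start = integer(), residues = character())
  }
  cand$ss_labels <- NA_character_
  cand$passed1 <- rep(TRUE, n)
  for (k in 2:5) cand[[paste0("passed", k)]] <- rep(FALSE, n)
  cand$reason <- rep("", n)
  cand$flag <- rep("", n)
  cand$iptm <- rep(NA_real_, n)
  cand$orientation <- rep(NA_character_, n)
  cand$experimental_validation <- rep("pending", n)

  # stage 2: structural context of the motif in the monomer
  ss_cache <- list()
  for (i in seq_len(n)) {
    id <- cand$model_id[i]
    if (is.null(ss_cache[[id]]))
      ss_cache[[id]] <- assign_secondary_structure(models[[id]])
    labs <- ss_labels(ss_cache[[id]], cand$chain[i],
                      cand$start[i]:(cand$start[i] + 4L))
    cand$ss_labels[i] <- paste(ifelse(is.na(labs), "?", labs), collapse = "")
    keep <- ss_context_filter(labs)
    if (is.na(keep)) {
      cand$reason[i] <- "unannotated"
    } else if (keep) {
      cand$passed2[i] <- TRUE
    } else {
      cand$reason[i] <- "strand-context"
    }
  }

  # stage 3: localization
  skip3 <- is.null(config$localization_path)
  if (skip3) {
    cand$passed3 <- cand$passed2
  } else {
    loctab <- read_localization_table(config$localization_path)
    for (i in which(cand$passed2)) {
      r <- localization_filter(cand$model_id[i], loctab,
                               config$unknown_policy)
      cand$flag[i] <- r$flag
      if (r$keep) cand$passed3[i] <- TRUE
      else cand$reason[i] <- "non-cytosolic"
    }
  }

  # stage 4: groove binding via the helical motif in the predicted complex
  skip4 <- is.null(config$bundle_dir)
  if (skip4) {
    cand$passed4 <- cand$passed3
  } else {
    for (i in which(cand$passed3)) {
      bdir <- candidate_bundle_dir(config$bundle_dir, cand$model_id[i],
                                   cand$start[i])
      if (is.na(bdir)) { cand$reason[i] <- "no-complex-prediction"; next }
      pred <- read_complex_bundle(bdir)
      lig_start <- ligand_motif_start(pred$model, cand$residues[i])
      if (is.na(lig_start)) { cand$reason[i] <- "motif-absent-in-complex"; next }
      ev <- evaluate_complex(pred, config$groove, lig_start)
      cand$iptm[i] <- ev$iptm
      cand$orientation[i] <- ev$orientation
      if (isTRUE(ev$groove_contact) && isTRUE(ev$motif_helical))
        cand$passed4[i] <- TRUE
      else cand$reason[i] <-
          if (!isTRUE(ev$groove_contact)) "no-groove-contact"
          else "motif-not-helical"
    }
  }

  # stage 5: ipTM threshold
  skip5 <- skip4 ||
    (is.null(config$reference_iptm) && is.null(config$reference_id))
  if (skip5) {
    cand$passed5 <- cand$passed4
  } else {
    ref <- config$reference_iptm
    if (is.null(ref)) {
      sel <- cand$model_id == config$reference_id & !is.na(cand$iptm)
      if (!any(sel))
        stop("reference candidate '", config$reference_id,
             "' has no ipTM available")
      ref <- max(cand$iptm[sel])
    }
    for (i in which(cand$passed4)) {
      if (iptm_filter(cand$iptm[i], ref)) cand$passed5[i] <- TRUE
      else cand$reason[i] <- "iptm-below-reference"
    }
  }

  survivors <- lapply(1:5, function(k)
    sort(unique(cand$model_id[cand[[paste0("passed", k)]]])))
  names(survivors) <- paste0("stage", 1:5)
  stages <- data.frame(
    stage = 1:5,
    description = c("motif match", "helix/loop context", "cytosolic",
                    "groove binding (helical motif)", "ipTM >= reference"),
    n_proteins = vapply(survivors, length, integer(1)),
    skipped = c(FALSE, FALSE, skip3, skip4, skip5),
    row.names = NULL)
  structure(list(stages = stages, survivors = survivors, candidates = cand,
                 config = list(pattern = config$pattern$source,
                               contact_cutoff = config$groove$contact_cutoff,
                               hbond_cutoff = config$groove$hbond_cutoff,
                               reference_id = config$reference_id,
                               reference_iptm = config$reference_iptm,
                               unknown_policy = config$unknown_policy,
                               proteome = attr(models, "n_ok"))),
            class = "filter_report")
}

# locate the motif window on the ligand chain of a complex by its residues
ligand_motif_start <- function(model, residues) {
  lig <- chain_ids(model)[2]
  res <- chain_residues(model, lig)
  seq1 <- paste(res$code1, collapse = "")
  pos <- regexpr(residues, seq1, fixed = TRUE)[1]
  if (pos < 0) NA_integer_ else res$resno[pos]
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Write a filter report to JSON or TSV
#'
#' JSON round-trips the full report (stage counts, survivor id sets,
#' candidate table); TSV writes the one-row-per-stage funnel table.
#'
#' @param report a `filter_report`
#' @param path output path
#' @param format "JSON" or "TSV"
#' @return `path`, invisibly
#' @export
write_report <- function(report, path, format = c("JSON", "TSV")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "filter_report"))
  if (format == "JSON") {
    jsonlite::write_json(
      list(stages = report$stages, survivors = report$survivors,
           candidates = report$candidates, config = report$config),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.table(report$stages, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON filter report
#' @param path JSON file written by [write_report()]
#' @return list with `stages`, `survivors`, `candidates`, `config`
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
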