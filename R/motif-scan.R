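# Degenerate five-position motif patterns and proteome scanning.
#
# Patterns use bracket notation ("[VI][IL]D[LA]Y"): one single letter or one
# bracketed set per position, exactly five positions. Positions carry the
# field's -2..+2 labels with the anchor (Asp/Ser) at position 0, i.e. the
# third position of the window.

#' The built-in motif patterns
#'
#' `strict` is the consensus (V/I)-(I/L)-D-(L/A)-Y; `relaxed` additionally
#' allows Ser at position 0, (V/I)-(I/L)-(D/S)-(L/A)-Y.
#'
#' @param name "strict" or "relaxed"
#' @return a `motif_pattern`
#' @export
frm_pattern <- function(name = c("strict", "relaxed")) {
  name <- match.arg(name)
  spec <- switch(name, strict = "[VI][IL]D[LA]Y",
                 relaxed = "[VI][IL][DS][LA]Y")
  compile_pattern(spec, name = paste0("frm_", name))
}

#' Compile a bracket-notation motif pattern
#'
#' @param spec pattern string: five positions, each a single residue letter or
#'   a bracketed set, e.g. `"[VI][IL]D[LA]Y"`
#' @param name pattern name carried into match tables
#' @return object of class `motif_pattern`: list with `name`, `source`,
#'   `positions` (list of 5 character vectors) and `labels` (-2..+2)
#' @export
compile_pattern <- function(spec, name = spec) {
  toks <- regmatches(spec, gregexpr("\\[[A-Za-z]+\\]|[A-Za-z]", spec))[[1]]
  if (paste(toks, collapse = "") != spec)
    stop("cannot parse pattern '", spec, "'")
  if (length(toks) != 5)
    stop("pattern must have exactly 5 positions, got ", length(toks))
  labels <- c(-2L, -1L, 0L, 1L, 2L)
  positions <- lapply(seq_along(toks), function(i) {
    set <- strsplit(gsub("\\[|\\]", "", toks[i]), "")[[1]]
    set <- toupper(set)
    bad <- setdiff(set, STANDARD_AA)
    if (length(bad) > 0)
      stop("illegal residue letter(s) ", paste(bad, collapse = ""),
           " at position ", labels[i])
    if (length(set) == 0) stop("empty set at position ", labels[i])
    unique(set)
  })
  names(positions) <- as.character(labels)
  structure(list(name = name, source = spec, positions = positions,
                 labels = labels),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern>", x$name, ":", x$source, "\n")
  invisible(x)
}

#' Scan a sequence for motif occurrences
#'
#' Reports every (possibly overlapping) window in which each residue belongs
#' to the allowed set of its position. 'X' matches nothing.
#'
#' @param sequence one-letter sequence (may contain 'X')
#' @param pattern a `motif_pattern`
#' @param offset author number of the first sequence position (default 1), so
#'   reported coordinates are author numbering
#' @param model_id,chain identifiers carried into the match table
#' @return data.frame with one row per match: `model_id`, `chain`, `start`
#'   (author number of position -2), `end` (= start + 4), `residues`, and
#'   columns `p_m2`, `p_m1`, `p_0`, `p_p1`, `p_p2` for the residue at each
#'   motif position; sorted by `start`
#' @export
scan_sequence <- function(sequence, pattern, offset = 1L,
                          model_id = NA_character_, chain = NA_character_) {
  stopifnot(inherits(pattern, "motif_pattern"))
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  empty <- data.frame(model_id = character(), chain = character(),
                      start = integer(), end = integer(),
                      residues = character(),
                      p_m2 = character(), p_m1 = character(),
                      p_0 = character(), p_p1 = character(),
                      p_p2 = character(), stringsAsFactors = FALSE)
  if (n < 5) return(empty)
  # per-position membership vectors, combined over the 5-residue window
  ok <- rep(TRUE, n - 4)
  for (k in 1:5) {
    memb <- aa[k:(n - 5 + k)] %in% pattern$positions[[k]]
    ok <- ok & memb
  }
  starts <- which(ok)
  if (length(starts) == 0) return(empty)
  data.frame(
    model_id = model_id, chain = chain,
    start = as.integer(starts + offset - 1L),
    end = as.integer(starts + offset + 3L),
    residues = vapply(starts, function(s) paste(aa[s:(s + 4)], collapse = ""),
                      character(1)),
    p_m2 = aa[starts], p_m1 = aa[starts + 1], p_0 = aa[starts + 2],
    p_p1 = aa[starts + 3], p_p2 = aa[starts + 4],
    stringsAsFactors = FALSE)
}

#' Scan a proteome of structure models for a motif
#'
#' Sequences are extracted from the structure files themselves. Every match
#' is retained with coordinates; the protein-level count deduplicates
#' proteins with several occurrences.
#'
#' @param models list of `structure_model` (e.g. from [iterate_proteome()])
#' @param pattern a `motif_pattern`
#' @return list with `matches` (combined match table), `by_protein` (named
#'   list of match tables), and `n_proteins_matched`
#' @export
scan_proteome <- function(models, pattern) {
  if (length(models) == 0) stop("empty proteome")
  per <- lapply(models, function(m) {
    tabs <- lapply(chain_ids(m), function(ch) {
      res <- chain_residues(m, ch)
      scan_sequence(paste(res$code1, collapse = ""), pattern,
                    offset = res$resno[1], model_id = m$model_id, chain = ch)
    })
    do.call(rbind, tabs)
  })
  matches <- do.call(rbind, per)
  rownames(matches) <- NULL
  keep <- vapply(per, nrow, integer(1)) > 0
  list(matches = matches,
       by_protein = per[keep],
       n_proteins_matched = sum(keep))
}
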