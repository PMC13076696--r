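# SMILES standardization: the curation entry point every molecule passes
# through before it may touch a vocabulary, a model, or a similarity filter.

# Strip stereo bond markers and bracket-atom chirality/isotope annotations at
# string level; the subsequent canonicalization normalizes whatever remains
# (e.g. "[CH3]" back to "C").
.strip_stereo_isotopes <- function(smiles) {
  s <- gsub("[/\\\\]", "", smiles)
  s <- gsub("@{1,2}", "", s)     # only ever occurs inside brackets
  gsub("\\[([0-9]+)", "[", s)    # leading isotope mass inside brackets
}

# Largest organic fragment by heavy-atom count; ties broken by the longer
# SMILES (proxy for molecular weight at string level, refined later), then
# lexicographically for determinism. Returns NA when no fragment contains
# carbon.
.largest_organic_fragment <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  has_carbon <- vapply(frags, function(f) {
    toks <- .scan_smiles(f)
    if (is.null(toks)) return(FALSE)
    any(toks %in% c("C", "c") |
          grepl("^\\[[0-9]*[Cc](?![alroudsemf])", toks, perl = TRUE))
  }, logical(1))
  organic <- frags[has_carbon]
  if (!length(organic)) return(NA_character_)
  heavy <- vapply(organic, function(f) {
    toks <- .scan_smiles(f)
    if (is.null(toks)) return(-1L)
    sum(.is_atom_token(toks))
  }, integer(1))
  if (all(heavy < 0L)) return(NA_character_)
  ord <- order(-heavy, -nchar(organic), organic)
  organic[ord[1]]
}

#' Standardize raw SMILES into curated molecule records
#'
#' Applies, in order: stereo and isotope removal, a strict syntactic parse,
#' salt stripping (largest organic fragment, ties by size then lexicographic),
#' neutralization of ionizable groups (permanently charged atoms such as
#' quaternary nitrogen are kept), canonicalization, and the molecular-weight
#' and token-length gates. Rejections are never exceptions: each input row
#' reports a machine-readable reason.
#'
#' @param raw Character vector of SMILES strings.
#' @param max_mw Maximum molecular weight in Da (strictly greater is
#'   rejected). Default 1000.
#' @param max_tokens Maximum token count of the canonical form (strictly
#'   greater is rejected). Default 140.
#' @return A data.frame with columns `raw`, `smiles` (canonical, NA when
#'   rejected), `mw`, `n_tokens`, `accepted`, `reason`
#'   (`unparsable`, `empty-after-salt-strip`, `overweight`, `overlong`, or NA).
#' @examples
#' standardize_smiles(c("C[C@@H](O)c1ccccc1", "CC(=O)[O-].[Na+]"))
#' @export
standardize_smiles <- function(raw, max_mw = 1000, max_tokens = 140) {
  n <- length(raw)
  out <- data.frame(
    raw = as.character(raw),
    smiles = NA_character_, mw = NA_real_, n_tokens = NA_integer_,
    accepted = FALSE, reason = NA_character_,
    stringsAsFactors = FALSE
  )
  if (!n) return(out)

  bad_input <- is.na(raw) | !nzchar(trimws(raw))
  out$reason[bad_input] <- "unparsable"
  work <- which(!bad_input)
  if (!length(work)) return(out)

  stripped <- .strip_stereo_isotopes(trimws(raw[work]))
  syntax_ok <- vapply(stripped, function(s) {
    a <- .analyze_smiles(s)
    !is.null(a) && a$valence_ok
  }, logical(1), USE.NAMES = FALSE)
  out$reason[work[!syntax_ok]] <- "unparsable"
  work <- work[syntax_ok]
  stripped <- stripped[syntax_ok]
  if (!length(work)) return(out)

  frag <- vapply(stripped, .largest_organic_fragment, character(1), USE.NAMES = FALSE)
  no_frag <- is.na(frag)
  out$reason[work[no_frag]] <- "empty-after-salt-strip"
  work <- work[!no_frag]
  frag <- frag[!no_frag]
  if (!length(work)) return(out)

  can <- ob_convert_smiles(frag, ops = "--neutralize")
  # canonical output can reintroduce nothing we stripped, but guard anyway
  can <- ifelse(is.na(can), NA, .strip_stereo_isotopes(can))
  analysis <- lapply(can, function(x) if (is.na(x)) NULL else .analyze_smiles(x))
  failed <- vapply(analysis, is.null, logical(1))
  out$reason[work[failed]] <- "unparsable"
  work <- work[!failed]
  can <- can[!failed]
  analysis <- analysis[!failed]
  if (!length(work)) return(out)

  mw <- vapply(analysis, function(a) a$mw, numeric(1))
  ntok <- vapply(analysis, function(a) a$n_tokens, integer(1))
  out$smiles[work] <- can
  out$mw[work] <- mw
  out$n_tokens[work] <- ntok

  over_w <- mw > max_mw
  over_l <- !over_w & ntok > max_tokens
  out$reason[work[over_w]] <- "overweight"
  out$reason[work[over_l]] <- "overlong"
  out$accepted[work[!(over_w | over_l)]] <- TRUE
  out$smiles[work[over_w | over_l]] <- NA_character_
  out
}

#' Read an activity table into a standardized molecule table
#'
#' Reads a delimited text file with a SMILES column and (optionally) an
#' activity value and unit column, standardizes every row, converts activities
#' to potency on the negative decadic log molar scale, and collapses duplicate
#' canonical SMILES keeping the best (highest) potency.
#'
#' @param path Path to a CSV/TSV file (delimiter inferred from the extension,
#'   or set `sep`).
#' @param column_map Named list mapping roles to column names:
#'   `smiles` (required), and optionally `value`, `unit`, `potency`
#'   (already on the -log10 molar scale), `series_id`, `target`.
#' @param sep Field separator; default `","` (`"\t"` for `.tsv`/`.smi`).
#' @param max_mw,max_tokens Passed to [standardize_smiles()].
#' @return A data.frame with columns `smiles`, `potency`, `series_id`,
#'   `target`; attribute `"rejections"` holds the rejected rows with reasons.
#' @export
read_activity_table <- function(path, column_map = list(smiles = "smiles"),
                                sep = NULL, max_mw = 1000, max_tokens = 140) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|smi|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "")
  if (is.null(column_map$smiles) || !column_map$smiles %in% names(tab)) {
    stop("missing SMILES column: ", column_map$smiles %||% "smiles")
  }
  raw <- as.character(tab[[column_map$smiles]])
  std <- standardize_smiles(raw, max_mw = max_mw, max_tokens = max_tokens)

  potency <- rep(NA_real_, nrow(tab))
  reason_unit <- rep(NA_character_, nrow(tab))
  if (!is.null(column_map$potency) && column_map$potency %in% names(tab)) {
    potency <- as.numeric(tab[[column_map$potency]])
  } else if (!is.null(column_map$value) && column_map$value %in% names(tab)) {
    value <- as.numeric(tab[[column_map$value]])
    unit <- if (!is.null(column_map$unit) && column_map$unit %in% names(tab)) {
      as.character(tab[[column_map$unit]])
    } else {
      rep("M", nrow(tab))
    }
    molar <- molar_value(value, unit)
    reason_unit[!is.na(value) & is.na(molar)] <- "unparsable-unit"
    potency <- -log10(molar)
  }

  keep <- std$accepted & is.na(reason_unit)
  rejections <- data.frame(
    row = which(!keep),
    raw = raw[!keep],
    reason = ifelse(is.na(reason_unit[!keep]), std$reason[!keep], reason_unit[!keep]),
    stringsAsFactors = FALSE
  )

  res <- data.frame(
    smiles = std$smiles[keep],
    potency = potency[keep],
    series_id = if (!is.null(column_map$series_id) && column_map$series_id %in% names(tab)) {
      as.character(tab[[column_map$series_id]])[keep]
    } else NA_character_,
    target = if (!is.null(column_map$target) && column_map$target %in% names(tab)) {
      as.character(tab[[column_map$target]])[keep]
    } else NA_character_,
    stringsAsFactors = FALSE
  )
  # duplicates collapse to one record, best (highest) potency kept
  ord <- order(res$smiles, -xtfrm(ifelse(is.na(res$potency), -Inf, res$potency)))
  res <- res[ord, , drop = FALSE]
  res <- res[!duplicated(res$smiles), , drop = FALSE]
  res <- res[order(res$smiles), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "rejections") <- rejections
  res
}

#' Convert an activity value with unit to molar concentration
#'
#' @param value Numeric activity values.
#' @param unit Character units: one of M, mM, uM (or µM), nM, pM, fM.
#' @return Numeric molar values; NA for unknown units.
#' @export
molar_value <- function(value, unit) {
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9,
             pM = 1e-12, fM = 1e-15)
  fac <- scale[trimws(unit)]
  unname(value * fac)
}

#' Write a rejection log as JSON lines
#'
#' @param rejections Data frame as attached by [read_activity_table()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_rejection_log <- function(rejections, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(rejections))) {
    writeLines(jsonlite::toJSON(as.list(rejections[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
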