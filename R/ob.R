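# Cheminformatics backend. Batch operations go through the OpenBabel CLI
# (one process per batch, input/output aligned via integer title tags, since
# OpenBabel silently drops molecules it cannot read); SMARTS matching uses
# the in-process ChemmineOB bindings. A token-level analyzer provides strict
# syntax checking, a valence audit and molecular weights without a backend
# round trip.

.ob_run <- function(smiles, args) {
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste0(smiles, " idx", seq_along(smiles)), fin)
  status <- suppressWarnings(
    system2("obabel", c(fin, args, "-O", fout), stdout = FALSE, stderr = FALSE)
  )
  if (!file.exists(fout)) return(character(0))
  readLines(fout, warn = FALSE)
}

# Canonical SMILES for a character vector; NA where conversion failed.
# ops: additional obabel transforms, e.g. "--neutralize".
ob_convert_smiles <- function(smiles, ops = NULL) {
  n <- length(smiles)
  if (!n) return(character(0))
  lines <- .ob_run(smiles, c("-ocan", ops))
  res <- rep(NA_character_, n)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) >= 2 && nzchar(p[1])) {
      idx <- suppressWarnings(as.integer(sub("^idx", "", trimws(p[2]))))
      if (!is.na(idx)) res[idx] <- p[1]
    }
  }
  res
}

# OpenBabel property table (MW, logP, TPSA, HBA, HBD, formula), aligned.
ob_props <- function(smiles) {
  n <- length(smiles)
  out <- data.frame(MW = rep(NA_real_, n), logP = NA_real_, TPSA = NA_real_,
                    HBA2 = NA_integer_, HBD = NA_integer_,
                    formula = NA_character_, stringsAsFactors = FALSE)
  if (!n) return(out)
  lines <- .ob_run(smiles, c("-otxt", "--append", "MW logP TPSA HBA2 HBD formula"))
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) != 7) next
    idx <- suppressWarnings(as.integer(sub("^idx", "", f[1])))
    if (is.na(idx)) next
    out$MW[idx] <- as.numeric(f[2])
    out$logP[idx] <- as.numeric(f[3])
    out$TPSA[idx] <- as.numeric(f[4])
    out$HBA2[idx] <- as.integer(f[5])
    out$HBD[idx] <- as.integer(f[6])
    out$formula[idx] <- f[7]
  }
  out
}

# SDF text (V2000 molblocks, kekule bond orders) for valid SMILES; explicit
# hydrogens on request (needed to recover H counts for the SMILES writer).
ob_sdf_text <- function(smiles, explicit_h = FALSE) {
  src <- paste0(smiles, "\t", seq_along(smiles), collapse = "\n")
  ops <- if (explicit_h) "h" else character(0)
  opts <- data.frame(names = ops, args = rep("", length(ops)))
  ChemmineOB::convertFormat("SMI", "SDF", source = src, options = opts)
}

# OBMol references and SMARTS match counts (unique matches) per molecule.
ob_mols <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), identity)
}

ob_smarts_count <- function(smiles, pattern) {
  if (!length(smiles)) return(integer(0))
  as.integer(ChemmineOB::smartsSearch_OB(ob_mols(smiles), pattern, uniqueMatches = TRUE))
}

# ---------------------------------------------------------------------------
# Token-level analysis: syntax, valence audit, molecular weight
# ---------------------------------------------------------------------------

.atomic_masses <- c(
  H = 1.00794, B = 10.811, C = 12.0107, N = 14.0067, O = 15.9994,
  F = 18.9984032, Na = 22.98977, Mg = 24.305, Al = 26.9815386, Si = 28.0855,
  P = 30.973762, S = 32.065, Cl = 35.453, K = 39.0983, Ca = 40.078,
  Fe = 55.845, Cu = 63.546, Zn = 65.409, Se = 78.96, Br = 79.904,
  Ag = 107.8682, I = 126.90447, Li = 6.941
)

# smallest standard valence >= bond sum; aromatic atoms reserve one unit
.implicit_h <- function(element, aromatic, bondsum) {
  if (aromatic) {
    allow <- switch(tolower(element), c = 3, n = 3, b = 3, p = 3, o = 2, s = 2, 0)
    return(max(0, allow - bondsum))
  }
  vals <- .default_valences[[element]]
  if (is.null(vals)) return(0)
  v <- vals[vals >= bondsum]
  if (length(v)) v[1] - bondsum else 0
}

# maximum plausible explicit connections for the neutral organic subset
.valence_ok <- function(element, aromatic, bondsum, has_multiple) {
  if (aromatic) {
    limit <- switch(tolower(element), c = 3, n = 3, b = 3, p = 3, o = 2, s = 3, 99)
    return(bondsum <= limit)
  }
  switch(element,
    C = bondsum <= 4,
    N = bondsum <= 3 || (has_multiple && bondsum <= 5),
    O = bondsum <= 2,
    S = bondsum <= 6,
    P = bondsum <= 5,
    B = bondsum <= 3,
    F = , Cl = , Br = , I = bondsum <= 1,
    TRUE
  )
}

.is_atom_token <- function(tok) {
  grepl("^\\[", tok) |
    tok %in% c("B", "C", "N", "O", "P", "S", "F", "I", "Cl", "Br",
               "b", "c", "n", "o", "p", "s")
}

.is_bond_token <- function(tok) tok %in% c("=", "#", "-", "/", "\\", ":", "~")

.bond_order_of <- function(tok) switch(tok, "=" = 2L, "#" = 3L, 1L)

# Parse a bracket token: list(element, aromatic, h, charge, mass_known) or
# NULL when malformed.
.parse_bracket <- function(tok) {
  m <- regmatches(tok, regexec(
    "^\\[([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H([0-9]*))?(([+-])([0-9]*)|(\\+{2,})|(-{2,}))?\\]$",
    tok))[[1]]
  if (!length(m)) return(NULL)
  el <- m[3]
  aromatic <- el %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  h <- if (nzchar(m[5])) {
    if (nzchar(m[6])) as.integer(m[6]) else 1L
  } else 0L
  charge <- 0L
  if (nzchar(m[8])) {
    mag <- if (nzchar(m[9])) as.integer(m[9]) else 1L
    charge <- if (m[8] == "+") mag else -mag
  } else if (nzchar(m[10])) {
    charge <- nchar(m[10])
  } else if (nzchar(m[11])) {
    charge <- -nchar(m[11])
  }
  list(element = el, aromatic = aromatic, h = h, charge = charge)
}

# Single pass over the token stream: grammar check, connectivity accounting,
# molecular weight. Returns NULL on a syntax error, otherwise a list with
# n_atoms, mw, valence_ok.
.analyze_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles)) {
    return(NULL)
  }
  toks <- .scan_smiles(smiles)
  if (is.null(toks)) return(NULL)

  n_atoms <- 0L
  element <- character(0); aromatic <- logical(0)
  hexp <- integer(0); charge <- integer(0); bracket <- logical(0)
  conn <- numeric(0); multiple <- logical(0)

  prev_atom <- 0L
  pending <- 0L # 0 = unset (default single)
  depth <- 0L
  stack <- integer(0)
  ring_atom <- list(); ring_order <- list()
  prev_tok <- ""

  add_bond <- function(a, b, order) {
    conn[a] <<- conn[a] + order
    conn[b] <<- conn[b] + order
    if (order > 1) { multiple[a] <<- TRUE; multiple[b] <<- TRUE }
  }

  for (k in seq_along(toks)) {
    tok <- toks[k]
    if (.is_atom_token(tok)) {
      n_atoms <- n_atoms + 1L
      if (startsWith(tok, "[")) {
        info <- .parse_bracket(tok)
        if (is.null(info)) return(NULL)
        element <- c(element, info$element)
        aromatic <- c(aromatic, info$aromatic)
        hexp <- c(hexp, info$h)
        charge <- c(charge, info$charge)
        bracket <- c(bracket, TRUE)
      } else {
        element <- c(element, tok)
        aromatic <- c(aromatic, tok %in% c("b", "c", "n", "o", "p", "s"))
        hexp <- c(hexp, NA_integer_)
        charge <- c(charge, 0L)
        bracket <- c(bracket, FALSE)
      }
      conn <- c(conn, 0)
      multiple <- c(multiple, FALSE)
      if (prev_atom > 0L) add_bond(prev_atom, n_atoms, if (pending > 0L) pending else 1L)
      prev_atom <- n_atoms
      pending <- 0L
    } else if (tok == "(") {
      if (prev_atom == 0L || .is_bond_token(prev_tok) || prev_tok == "(") return(NULL)
      stack <- c(stack, prev_atom)
      depth <- depth + 1L
    } else if (tok == ")") {
      if (depth == 0L || .is_bond_token(prev_tok) || prev_tok == "(") return(NULL)
      prev_atom <- stack[length(stack)]
      stack <- stack[-length(stack)]
      depth <- depth - 1L
    } else if (grepl("^[0-9]$", tok) || grepl("^%", tok)) {
      if (prev_atom == 0L) return(NULL)
      if (!(.is_atom_token(prev_tok) || grepl("^[0-9]$|^%", prev_tok) ||
            .is_bond_token(prev_tok))) return(NULL)
      lab <- sub("^%", "", tok)
      if (!is.null(ring_atom[[lab]])) {
        order <- max(ring_order[[lab]], if (pending > 0L) pending else 0L, 1L)
        if (ring_atom[[lab]] == prev_atom) return(NULL) # self ring bond
        add_bond(ring_atom[[lab]], prev_atom, order)
        ring_atom[[lab]] <- NULL
        ring_order[[lab]] <- NULL
      } else {
        ring_atom[[lab]] <- prev_atom
        ring_order[[lab]] <- if (pending > 0L) pending else 0L
      }
      pending <- 0L
    } else if (.is_bond_token(tok)) {
      if (prev_atom == 0L || .is_bond_token(prev_tok)) return(NULL)
      pending <- .bond_order_of(tok)
    } else if (tok == ".") {
      if (prev_atom == 0L || .is_bond_token(prev_tok) || prev_tok %in% c("(", ".")) return(NULL)
      prev_atom <- 0L
      pending <- 0L
    } else {
      return(NULL) # "*", stray "%", ":" handled as bond, anything else: no
    }
    prev_tok <- tok
  }
  if (n_atoms == 0L) return(NULL)
  if (depth != 0L || length(ring_atom)) return(NULL)
  if (.is_bond_token(prev_tok) || prev_tok %in% c("(", ".")) return(NULL)

  valence_ok <- TRUE
  mw <- 0
  for (a in seq_len(n_atoms)) {
    el_sym <- if (aromatic[a] && !bracket[a]) toupper(element[a]) else element[a]
    el_sym <- paste0(toupper(substr(el_sym, 1, 1)), substr(el_sym, 2, 10))
    h <- if (bracket[a]) {
      if (charge[a] == 0L &&
          !.valence_ok(el_sym, aromatic[a], conn[a] + hexp[a], multiple[a])) {
        valence_ok <- FALSE
      }
      hexp[a]
    } else {
      if (!.valence_ok(element[a], aromatic[a], conn[a], multiple[a])) {
        valence_ok <- FALSE
      }
      .implicit_h(element[a], aromatic[a], conn[a])
    }
    mass <- .atomic_masses[el_sym]
    if (is.na(mass)) mass <- 0
    mw <- mw + mass + h * .atomic_masses[["H"]]
  }
  list(n_atoms = n_atoms, mw = unname(mw), valence_ok = valence_ok,
       n_tokens = length(toks))
}

# Syntactic well-formedness (grammar only; no valence audit) -- deliberately
# stricter than the OpenBabel reader, which silently repairs some malformed
# strings.
smiles_syntax_ok <- function(smiles) {
  !is.null(.analyze_smiles(smiles))
}

# A chargeless bracket atom over an organic-subset element (other than [nH])
# in a canonical SMILES marks a radical or valence-damaged atom, e.g. the
# OpenBabel reading of "c1cc1" as "C1=C[CH]1".
.has_damaged_bracket <- function(canonical) {
  brackets <- regmatches(canonical, gregexpr("\\[[^][]*\\]", canonical))[[1]]
  if (!length(brackets)) return(FALSE)
  ok <- grepl("[+-]", brackets) | brackets == "[nH]"
  any(!ok)
}

#' Validity of SMILES strings
#'
#' A string is valid when it passes a strict syntactic scan (token grammar,
#' balanced parentheses, paired ring closures, no dangling bonds) and a
#' valence audit, is parsed by the cheminformatics backend, and its canonical
#' form shows no radical or valence-damaged atoms. Used by the sampling
#' statistics.
#'
#' @param smiles Character vector of raw strings.
#' @return Logical vector; attribute `"canonical"` carries the canonical
#'   SMILES (NA where invalid).
#' @export
smiles_validity <- function(smiles) {
  n <- length(smiles)
  ok <- vapply(smiles, function(s) {
    a <- .analyze_smiles(s)
    !is.null(a) && a$valence_ok
  }, logical(1), USE.NAMES = FALSE)
  canonical <- rep(NA_character_, n)
  if (any(ok)) {
    can <- ob_convert_smiles(smiles[ok])
    damaged <- !is.na(can) & vapply(can, function(x) {
      isTRUE(.has_damaged_bracket(x))
    }, logical(1), USE.NAMES = FALSE)
    can[damaged] <- NA_character_
    canonical[ok] <- can
    ok[ok] <- !is.na(can)
  }
  structure(ok, canonical = canonical)
}
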