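# Circular (Morgan-type / extended-connectivity) fingerprints and Tanimoto
# similarity. Fingerprints are computed by the OpenBabel ECFP implementation
# (radius 2 -> ECFP4, radius 3 -> ECFP6) at its native 4096-bit width and
# folded by OR to the requested width.

# Expand one 8-hex-digit word into 32 bits (little chunks first; the bit
# order only needs to be consistent across molecules).
.hex_word_bits <- function(words) {
  uw <- unique(words)
  tab <- vapply(uw, function(w) {
    hi <- strtoi(substr(w, 1, 4), 16L)
    lo <- strtoi(substr(w, 5, 8), 16L)
    as.logical(c(bitwAnd(bitwShiftR(lo, 0:15), 1L), bitwAnd(bitwShiftR(hi, 0:15), 1L)))
  }, logical(32))
  tab[, match(words, uw), drop = FALSE]
}

#' Morgan-type fingerprints for a set of molecules
#'
#' @param smiles Character vector of valid (standardized) SMILES.
#' @param radius Circular radius, 2 or 3.
#' @param nbits Folded fingerprint width; must divide 4096. Default 2048.
#' @return Logical matrix (molecules x nbits), rows named by SMILES.
#' @export
morgan_fp <- function(smiles, radius = 2, nbits = 2048) {
  stopifnot(radius %in% c(2, 3), 4096 %% nbits == 0)
  if (!length(smiles)) return(matrix(logical(0), 0, nbits))
  lines <- .ob_run(smiles, c("-ofpt", paste0("-xfECFP", 2 * radius), "-xh"))
  heads <- grep("^>", lines)
  if (!length(heads)) stop("fingerprint generation failed")
  bounds <- c(heads, length(lines) + 1L)
  raw <- matrix(FALSE, length(smiles), 4096)
  for (k in seq_along(heads)) {
    idx <- suppressWarnings(as.integer(
      sub("^>idx([0-9]+).*$", "\\1", lines[heads[k]])
    ))
    if (is.na(idx)) next
    body <- lines[seq(heads[k] + 1L, length.out = bounds[k + 1L] - heads[k] - 1L)]
    words <- unlist(regmatches(body, gregexpr("\\b[0-9a-f]{8}\\b", body)))
    if (length(words) != 128) {
      stop("unexpected fingerprint width for molecule: ", smiles[idx])
    }
    raw[idx, ] <- as.vector(.hex_word_bits(words))
  }
  folds <- 4096 %/% nbits
  out <- matrix(FALSE, nrow(raw), nbits)
  for (f in seq_len(folds)) {
    out <- out | raw[, ((f - 1) * nbits + 1):(f * nbits), drop = FALSE]
  }
  rownames(out) <- smiles
  out
}

# Tanimoto similarity between two fingerprint matrices (rows = molecules).
.tanimoto_cross <- function(fa, fb) {
  inter <- tcrossprod(fa * 1, fb * 1)
  ca <- rowSums(fa)
  cb <- rowSums(fb)
  denom <- outer(ca, cb, "+") - inter
  sim <- ifelse(denom == 0, 0, inter / denom)
  # two empty fingerprints are identical by convention
  if (any(denom == 0)) sim[outer(ca == 0, cb == 0, "&")] <- 1
  sim
}

#' Tanimoto similarity between two molecules
#'
#' Symmetric, reflexive (identical molecules score 1), bounded in \[0, 1\].
#'
#' @param a,b Valid SMILES strings.
#' @param radius Circular radius (2 or 3).
#' @param nbits Fingerprint width. Default 2048.
#' @return Similarity in \[0, 1\].
#' @export
fingerprint_similarity <- function(a, b, radius = 2, nbits = 2048) {
  fp <- morgan_fp(c(a, b), radius = radius, nbits = nbits)
  .tanimoto_cross(fp[1, , drop = FALSE], fp[2, , drop = FALSE])[1, 1]
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param smiles Character vector of valid SMILES.
#' @param radius Circular radius. @param nbits Width.
#' @return Symmetric similarity matrix.
#' @export
tanimoto_matrix <- function(smiles, radius = 2, nbits = 2048) {
  fp <- morgan_fp(smiles, radius = radius, nbits = nbits)
  .tanimoto_cross(fp, fp)
}

# Max similarity of each row molecule to any column molecule (matrix inputs
# are fingerprint matrices so callers can cache them).
.max_sim_to_set <- function(fp_query, fp_ref) {
  if (!nrow(fp_ref)) return(rep(0, nrow(fp_query)))
  apply(.tanimoto_cross(fp_query, fp_ref), 1, max)
}
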