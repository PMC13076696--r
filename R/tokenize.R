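#' @useDynLib increclm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Sentinel tokens delimiting every training sequence. They are multi-character
# strings, so they can never collide with a chemical token.
TOK_START <- "<s>"
TOK_END <- "</s>"
TOK_PAD <- "<pad>"

# Single-character SMILES tokens accepted by the scanner.
.smiles_single_chars <- c(
  "B", "C", "N", "O", "P", "S", "F", "I",
  "b", "c", "n", "o", "p", "s",
  as.character(0:9),
  "(", ")", "=", "#", "-", "+", "/", "\\", ".", "%", "*", "~", ":"
)

#' Tokenize a SMILES string
#'
#' Deterministic atom-level segmentation: bracket atoms (`[...]`), the
#' two-letter halogens `Cl` and `Br`, and two-digit ring closures (`%nn`) are
#' single tokens; every other character is its own token. This segmentation is
#' used consistently for model training and for perplexity, so the sequence
#' length entering the perplexity exponent is the token count produced here.
#'
#' @param smiles A single non-empty SMILES string.
#' @param vocab Optional [build_vocabulary()] result. When given, every token
#'   must be a member; an unknown token raises an error naming the offender.
#' @return Character vector of tokens (no sentinels).
#' @examples
#' tokenize_smiles("Clc1ccccc1")
#' @export
tokenize_smiles <- function(smiles, vocab = NULL) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles)) {
    stop("`smiles` must be a single non-empty string")
  }
  toks <- .scan_smiles(smiles)
  if (is.null(toks)) {
    stop("cannot tokenize SMILES: ", smiles)
  }
  if (!is.null(vocab)) {
    unknown <- setdiff(unique(toks), vocab$tokens)
    if (length(unknown)) {
      stop("unknown token(s) not in vocabulary: ", paste(unknown, collapse = ", "))
    }
  }
  toks
}

# Scanner core; returns NULL on untokenizable input instead of erroring so it
# can double as a syntax predicate for generated strings.
.scan_smiles <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) return(NULL) # unclosed bracket
      toks <- c(toks, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "C" && i < n && chars[i + 1L] == "l") {
      toks <- c(toks, "Cl")
      i <- i + 2L
    } else if (ch == "B" && i < n && chars[i + 1L] == "r") {
      toks <- c(toks, "Br")
      i <- i + 2L
    } else if (ch == "%") {
      if (i + 2L > n || !all(grepl("^[0-9]$", chars[(i + 1L):(i + 2L)]))) return(NULL)
      toks <- c(toks, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch %in% .smiles_single_chars) {
      toks <- c(toks, ch)
      i <- i + 1L
    } else {
      return(NULL)
    }
  }
  if (!length(toks)) NULL else toks
}

#' Reassemble a SMILES string from its tokens
#'
#' Inverse of [tokenize_smiles()]: concatenation reproduces the source string
#' exactly.
#'
#' @param tokens Character vector of tokens.
#' @return A single SMILES string.
#' @export
untokenize_smiles <- function(tokens) {
  paste(tokens, collapse = "")
}

#' Build a token vocabulary from a corpus
#'
#' The vocabulary is the sorted union of all tokens occurring in the corpus
#' plus the three sentinel tokens (pad, start, end). Indexing is a bijection
#' onto `0..V-1` with the pad token fixed at index 0.
#'
#' @param corpus Character vector of standardized SMILES (or a molecule table
#'   with a `smiles` column).
#' @return An object of class `token_vocabulary` with elements `tokens`
#'   (character vector, pad/start/end first) and `index` (named integer map,
#'   0-based).
#' @export
build_vocabulary <- function(corpus) {
  if (is.data.frame(corpus)) corpus <- corpus$smiles
  corpus <- corpus[!is.na(corpus)]
  if (!length(corpus)) stop("empty corpus")
  chem <- sort(unique(unlist(lapply(unique(corpus), tokenize_smiles))))
  tokens <- c(TOK_PAD, TOK_START, TOK_END, chem)
  index <- stats::setNames(seq_along(tokens) - 1L, tokens)
  structure(
    list(tokens = tokens, index = index,
         pad_id = 0L, start_id = 1L, end_id = 2L),
    class = "token_vocabulary"
  )
}

#' @export
print.token_vocabulary <- function(x, ...) {
  cat("<token_vocabulary> V =", length(x$tokens), "tokens\n")
  cat("  chemical:", paste(utils::head(x$tokens[-(1:3)], 25), collapse = " "),
      if (length(x$tokens) > 28) "..." else "", "\n")
  invisible(x)
}

#' Encode a SMILES string as sentinel-wrapped token indices
#'
#' @param smiles SMILES string.
#' @param vocab A `token_vocabulary`.
#' @return Integer vector `start, tokens..., end` of 0-based indices.
#' @export
encode_smiles <- function(smiles, vocab) {
  toks <- tokenize_smiles(smiles, vocab)
  c(vocab$start_id, unname(vocab$index[toks]), vocab$end_id)
}

#' Decode token indices back to a SMILES string
#'
#' Sentinels and padding are dropped.
#'
#' @param ids Integer vector of 0-based token indices.
#' @param vocab A `token_vocabulary`.
#' @return SMILES string.
#' @export
decode_ids <- function(ids, vocab) {
  ids <- ids[ids > 2L]
  paste(vocab$tokens[ids + 1L], collapse = "")
}

# Count of chemical tokens (the sequence length N that enters perplexity,
# excluding sentinels).
smiles_token_count <- function(smiles) {
  length(tokenize_smiles(smiles))
}
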