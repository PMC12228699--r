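# Regex SMILES tokenizer with token-to-atom mapping. Atom-bearing tokens
# (element symbols including two-letter ones, aromatic atoms, bracket
# atoms) receive sequential atom indices matching the atom order of the
# parsed molecular graph; structural tokens (bonds, ring digits,
# parentheses) map to no atom.

.SMILES_TOKEN_RE <- paste0(
  "(\\[[^\\]]+\\]",            # bracket atoms, one token each
  "|Br|Cl|Si|Se|As",           # two-letter elements
  "|se|as",                    # two-letter aromatic
  "|B|C|N|O|P|S|F|I",          # organic subset
  "|b|c|n|o|p|s",              # aromatic subset
  "|%[0-9]{2}|[0-9]",          # ring closures
  "|\\(|\\)|\\.|=|#|\\$|:|/|\\\\|-|\\+|@@|@|~|\\*)"
)

.ATOM_TOKEN_RE <- "^(\\[[^\\]]+\\]|Br|Cl|Si|Se|As|se|as|B|C|N|O|P|S|F|I|b|c|n|o|p|s)$"

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into its lexical tokens and maps each atom-bearing
#' token to its atom index (1-based, in order of appearance, matching the
#' atom order of the molecular graph). The concatenation of the tokens
#' reproduces the input exactly; a character that cannot start a token is an
#' error.
#'
#' @param smiles A single SMILES string.
#' @return Tibble with columns `token` (character) and `atom` (integer atom
#'   index, `NA` for non-atom tokens).
#' @export
#' @examples
#' tokenize_smiles("ClCCl")
tokenize_smiles <- function(smiles) {
  stopifnot(length(smiles) == 1)
  m <- gregexpr(.SMILES_TOKEN_RE, smiles, perl = TRUE)[[1]]
  toks <- if (m[1] == -1) character(0) else regmatches(smiles, list(m))[[1]]
  if (paste(toks, collapse = "") != smiles) {
    # locate the first untokenizable character
    covered <- rep(FALSE, nchar(smiles))
    if (m[1] != -1) {
      for (i in seq_along(m)) {
        covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1)] <- TRUE
      }
    }
    pos <- which(!covered)[1]
    abort(paste0(
      "untokenizable character ",
      encodeString(substr(smiles, pos, pos), quote = "\""),
      " at position ", pos, " in ", encodeString(smiles, quote = "\"")
    ), class = "tastekit_tokenize_error")
  }
  is_atom <- grepl(.ATOM_TOKEN_RE, toks, perl = TRUE)
  atom <- rep(NA_integer_, length(toks))
  atom[is_atom] <- seq_len(sum(is_atom))
  tibble(token = toks, atom = atom)
}
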