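# Tokenization of SMILES strings and extraction of correlation-weight-bearing
# attributes (single tokens, adjacent token pairs, condition codes).

#' Condition features of a quasi-SMILES record
#'
#' The six categorical experimental/environmental features that augment the
#' molecular structure: persistence in water (`WT`), sediment (`SS`) and soil
#' (`SO`), pollinator species (`SP`), life stage (`LS`) and observation
#' duration (`OB`). Every record carries exactly one level for each feature.
#'
#' @return Character vector of the six feature codes, in canonical order.
#' @export
#' @examples
#' qs_features()
qs_features <- function() {
  c("WT", "SS", "SO", "SP", "LS", "OB")
}

# Width of the rendered attribute string and of each token field in a pair.
.ATTR_WIDTH <- 12L
.PAIR_FIELD <- 4L

# Two-character element symbols recognized outside brackets.
.TWO_CHAR <- c("Cl", "Br")

# Single characters legal outside bracket atoms.
.SINGLE_CHARS <- c(
  "B", "C", "N", "O", "S", "P", "F", "I", "H",
  "b", "c", "n", "o", "s", "p",
  "-", "=", "#", "$", ":", "/", "\\", "@",
  "(", ")", ".", "*", as.character(0:9)
)

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into the symbol tokens that carry correlation
#' weights. Two-character element symbols (`Cl`, `Br`) and whole bracket-atom
#' blocks (`[nH]`, `[N+]`) are single tokens; aromatic lowercase atoms, bond
#' symbols, branch parentheses, ring-closure digits and `%nn` ring labels are
#' single tokens. Stereo markers (`/`, `\`, `@`) tokenize as themselves.
#' No chemical validity is checked beyond this grammar.
#'
#' @param smiles A single non-empty SMILES string.
#' @return Character vector of tokens; concatenating them reproduces `smiles`.
#' @export
#' @examples
#' tokenize_smiles("ClC(=O)N")
#' tokenize_smiles("c1ccccc1")
tokenize_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("'smiles' must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  depth <- 0L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") {
        if (chars[j] == "[") {
          stop(sprintf("nested '[' at position %d in '%s'", j, smiles),
               call. = FALSE)
        }
        j <- j + 1L
      }
      if (j > n) {
        stop(sprintf("unbalanced '[' at position %d in '%s'", i, smiles),
             call. = FALSE)
      }
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "]") {
      stop(sprintf("unbalanced ']' at position %d in '%s'", i, smiles),
           call. = FALSE)
    } else if (ch == "%") {
      if (i + 2L > n || !all(grepl("^[0-9]$", chars[(i + 1L):(i + 2L)]))) {
        stop(sprintf("malformed '%%nn' ring label at position %d in '%s'",
                     i, smiles), call. = FALSE)
      }
      tokens <- c(tokens, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% .TWO_CHAR) {
      tokens <- c(tokens, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else if (ch %in% .SINGLE_CHARS) {
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") {
        depth <- depth - 1L
        if (depth < 0L) {
          stop(sprintf("unbalanced ')' at position %d in '%s'", i, smiles),
               call. = FALSE)
        }
      }
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else {
      stop(sprintf("unknown character '%s' at position %d in '%s'",
                   ch, i, smiles), call. = FALSE)
    }
  }
  if (depth != 0L) {
    stop(sprintf("unbalanced '(' in '%s'", smiles), call. = FALSE)
  }
  tokens
}

pad_field <- function(token, width) {
  if (nchar(token) > width) {
    stop(sprintf("token '%s' exceeds field width %d", token, width),
         call. = FALSE)
  }
  paste0(token, strrep(".", width - nchar(token)))
}

#' Render an attribute as a fixed-width dotted string
#'
#' Attributes are rendered as 12-character strings padded with `'.'`, the
#' convention used in correlation-weight tables. A single-token attribute
#' occupies the leading positions (`"C..........."`); a pair occupies two
#' 4-character fields (`"Cl..(......."`); a condition attribute is its
#' feature code plus level (`"SP3........."`). Pair tokens are expected in
#' canonical (ASCII-sorted) order; see [canonical_pair()].
#'
#' @param tokens Character vector: one token for `kind = "single"` or
#'   `"condition"`, two tokens for `kind = "pair"`.
#' @param kind One of `"single"`, `"pair"`, `"condition"`.
#' @return The 12-character rendering.
#' @seealso [parse_attribute()] for the inverse.
#' @export
#' @examples
#' render_attribute("C", "single")
#' render_attribute(c("Cl", "("), "pair")
render_attribute <- function(tokens, kind = c("single", "pair", "condition")) {
  kind <- match.arg(kind)
  if (any(!nzchar(tokens)) || any(grepl("[[:space:]]", tokens)) ||
      any(grepl(".", tokens, fixed = TRUE))) {
    stop("attribute tokens must be non-empty, without whitespace or '.'",
         call. = FALSE)
  }
  if (kind == "pair") {
    if (length(tokens) != 2L) {
      stop("a pair attribute needs exactly two tokens", call. = FALSE)
    }
    body <- paste0(pad_field(tokens[1], .PAIR_FIELD),
                   pad_field(tokens[2], .PAIR_FIELD))
    pad_field(body, .ATTR_WIDTH)
  } else {
    if (length(tokens) != 1L) {
      stop(sprintf("a %s attribute needs exactly one token", kind),
           call. = FALSE)
    }
    pad_field(tokens, .ATTR_WIDTH)
  }
}

#' Parse a rendered attribute back into its tokens
#'
#' Inverse of [render_attribute()] given the attribute kind.
#'
#' @param text A 12-character rendered attribute.
#' @param kind One of `"single"`, `"pair"`, `"condition"`.
#' @return Character vector of tokens.
#' @export
parse_attribute <- function(text, kind = c("single", "pair", "condition")) {
  kind <- match.arg(kind)
  if (!is.character(text) || length(text) != 1L || nchar(text) != .ATTR_WIDTH) {
    stop(sprintf("'text' must be a single %d-character string", .ATTR_WIDTH),
         call. = FALSE)
  }
  strip <- function(x) sub("\\.*$", "", x)
  if (kind == "pair") {
    c(strip(substr(text, 1L, .PAIR_FIELD)),
      strip(substr(text, .PAIR_FIELD + 1L, 2L * .PAIR_FIELD)))
  } else {
    strip(text)
  }
}

#' Canonical ordering of a token pair
#'
#' Adjacent token pairs are order-canonicalized before rendering, so
#' `("(", "Cl")` and `("Cl", "(")` denote the same attribute. Tokens are
#' sorted in descending C-locale (ASCII) order, which puts atoms before
#' branch/bond punctuation and aromatic atoms before their aliphatic
#' counterparts — the convention visible in published correlation-weight
#' tables (`"C...(......."`, `"N...C......."`, `"c...C......."`).
#'
#' @param a,b The two adjacent tokens.
#' @return Character vector of the two tokens in canonical order.
#' @export
canonical_pair <- function(a, b) {
  # C-locale comparison keeps the rendering stable across platforms
  sort(c(a, b), method = "radix", decreasing = TRUE)
}

#' Extract the correlation-weight attributes of one quasi-SMILES record
#'
#' Produces the attribute multiset of a record: one `single` attribute per
#' SMILES token, one `pair` attribute per adjacent token pair (tokens sorted
#' canonically), and one `condition` attribute per condition code. Counts
#' accumulate duplicates, so a string of *n* tokens contributes *n* single
#' instances and *n − 1* pair instances.
#'
#' @param smiles A SMILES string.
#' @param conditions Named character vector of condition levels; names must
#'   be exactly the six features of [qs_features()]. Levels are combined with
#'   the feature code, so level `"3"` of `SP` becomes attribute token `SP3`.
#'   May be `NULL` to extract structural attributes only.
#' @return A data frame with columns `attribute` (12-character rendering),
#'   `kind` and `count`.
#' @export
#' @examples
#' extract_attributes("CCO",
#'   c(WT = "1", SS = "2", SO = "1", SP = "Apis", LS = "A", OB = "2"))
extract_attributes <- function(smiles, conditions = NULL) {
  tokens <- tokenize_smiles(smiles)
  singles <- vapply(tokens, render_attribute, "", kind = "single",
                    USE.NAMES = FALSE)
  pairs <- character(0)
  if (length(tokens) > 1L) {
    pairs <- vapply(seq_len(length(tokens) - 1L), function(i) {
      render_attribute(canonical_pair(tokens[i], tokens[i + 1L]), "pair")
    }, "")
  }
  conds <- character(0)
  if (!is.null(conditions)) {
    conditions <- validate_conditions(conditions)
    conds <- vapply(qs_features(), function(f) {
      render_attribute(paste0(f, conditions[[f]]), "condition")
    }, "", USE.NAMES = FALSE)
  }
  tab <- function(x, kind) {
    if (length(x) == 0L) {
      return(data.frame(attribute = character(0), kind = character(0),
                        count = integer(0)))
    }
    t <- table(x)
    data.frame(attribute = names(t), kind = kind,
               count = as.integer(t), row.names = NULL)
  }
  out <- rbind(tab(singles, "single"), tab(pairs, "pair"),
               tab(conds, "condition"))
  rownames(out) <- NULL
  out
}

validate_conditions <- function(conditions) {
  if (is.list(conditions)) conditions <- unlist(conditions)
  feats <- qs_features()
  if (!is.character(conditions) || is.null(names(conditions)) ||
      !setequal(names(conditions), feats) ||
      anyDuplicated(names(conditions)) > 0L) {
    stop("'conditions' must be a character vector named by the six features ",
         paste(feats, collapse = ", "), call. = FALSE)
  }
  bad <- !nzchar(conditions) | grepl("[[:space:].]", conditions)
  if (any(bad)) {
    stop("condition levels must be non-empty tokens without whitespace ",
         "or '.': ", paste(names(conditions)[bad], collapse = ", "),
         call. = FALSE)
  }
  conditions[feats]
}
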