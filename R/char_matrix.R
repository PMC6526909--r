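#' Discrete morphological character matrix
#'
#' A `char_matrix` stores a taxa-by-characters table of state-sets.
#' Each cell is a non-empty subset of that character's alphabet, held as a
#' bitmask; missing (`?`) and inapplicable (`-`) cells carry the full
#' alphabet with a missing flag, polymorphic cells carry two or more states
#' with the flag unset. Characters have non-negative weights (default 1).
#'
#' @param cells character matrix of cell strings, one row per taxon. Each
#'   cell is a single state symbol, `"?"`/`"-"` for missing, or several
#'   symbols wrapped in `{}`, `()` or `[]` for polymorphism/ambiguity.
#' @param taxa taxon labels; defaults to `rownames(cells)`.
#' @param weights per-character non-negative weights, recycled.
#' @param symbols optional list of per-character alphabets (character
#'   vectors); defaults to the symbols observed in each column.
#' @param allowed optional character vector of permitted symbols (e.g. a
#'   declared NEXUS SYMBOLS list): observed symbols outside it are an
#'   error, but each column's alphabet stays the set it actually uses.
#' @return an object of class `char_matrix` with fields `taxa`, `bits`
#'   (integer bitmask matrix), `missing` (logical matrix), `symbols`
#'   (list of per-character alphabets) and `weights`.
#' @examples
#' m <- char_matrix(rbind(A = c("0", "1"), B = c("0", "?"), C = c("1", "{01}")))
#' m
#' @export
char_matrix <- function(cells, taxa = rownames(cells), weights = 1,
                        symbols = NULL, allowed = NULL) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "character"
  if (is.null(taxa)) stop_labeled("taxon labels are required")
  taxa <- normalize_taxon(taxa)
  nt <- nrow(cells); nc <- ncol(cells)
  if (length(taxa) != nt) stop_labeled("one label per row required")
  parsed <- lapply(seq_len(nc), function(j)
    parse_column(cells[, j], symbols[[j]] %||% NULL, col = j,
                 allowed = allowed))
  bits <- vapply(parsed, `[[`, integer(nt), "bits")
  miss <- vapply(parsed, `[[`, logical(nt), "missing")
  bits <- matrix(bits, nrow = nt); miss <- matrix(miss, nrow = nt)
  new_char_matrix(taxa, bits, miss, lapply(parsed, `[[`, "symbols"),
                  rep_len(weights, nc))
}

new_char_matrix <- function(taxa, bits, missing, symbols, weights) {
  obj <- structure(list(taxa = taxa, bits = bits, missing = missing,
                        symbols = symbols, weights = as.numeric(weights)),
                   class = "char_matrix")
  validate_char_matrix(obj)
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("Morphological character matrix:", n_taxa(x), "taxa x", n_chars(x),
      "characters\n")
  k <- lengths(x$symbols)
  cat("  states per character:", min(k), "-", max(k),
      "; missing cells:",
      sprintf("%.1f%%", 100 * mean(x$missing)), "\n")
  if (any(x$weights != 1))
    cat("  non-unit character weights present\n")
  invisible(x)
}

#' @rdname char_matrix
#' @param m a `char_matrix`.
#' @export
n_taxa <- function(m) length(m$taxa)

#' @rdname char_matrix
#' @export
n_chars <- function(m) ncol(m$bits)

#' @export
dim.char_matrix <- function(x) c(n_taxa(x), n_chars(x))

validate_char_matrix <- function(m) {
  nt <- length(m$taxa); nc <- ncol(m$bits)
  if (anyDuplicated(m$taxa)) stop_labeled("duplicate taxon labels")
  if (any(!nzchar(m$taxa))) stop_labeled("empty taxon label")
  if (nrow(m$bits) != nt || !identical(dim(m$bits), dim(m$missing)))
    stop_labeled("matrix field dimensions disagree")
  if (length(m$symbols) != nc || length(m$weights) != nc)
    stop_labeled("per-character fields must match the character count")
  if (any(m$weights < 0)) stop_labeled("negative character weight")
  for (j in seq_len(nc)) {
    k <- length(m$symbols[[j]])
    if (k < 1 || k > 31) stop_labeled("character ", j, ": alphabet size ", k,
                                      " unsupported")
    full <- bitwShiftL(1L, k) - 1L
    col <- m$bits[, j]
    if (any(col <= 0L | bitwAnd(col, bitwNot(full)) != 0L))
      stop_labeled("character ", j, ": cell state-set outside alphabet")
    if (any(m$missing[, j] & col != full))
      stop_labeled("character ", j, ": missing cell must carry full state-set")
  }
  m
}

## symbols of one cell as a character vector
#' Decode one cell of a character matrix
#'
#' @param m a [char_matrix].
#' @param taxon taxon label or row index.
#' @param char character (column) index.
#' @return character vector of state symbols in the cell's state-set.
#' @export
cell_states <- function(m, taxon, char) {
  i <- if (is.character(taxon)) match(taxon, m$taxa) else taxon
  if (is.na(i)) stop_labeled("unknown taxon: ", taxon)
  mask <- m$bits[i, char]
  m$symbols[[char]][bit_positions(mask)]
}

bit_positions <- function(mask) which(bitwAnd(mask, bitwShiftL(1L, 0:30)) != 0L)

full_mask <- function(k) bitwShiftL(1L, as.integer(k)) - 1L

normalize_taxon <- function(x) gsub("[ \t]+", "_", trimws(x))

## ---- cell-string parsing ----------------------------------------------

split_cell_tokens <- function(s) {
  # split a row's state string into per-cell tokens; {..} (..) [..] groups
  # stay wrapped (normalized to {..}) so each token is one cell
  s <- gsub("[ \t]", "", s)
  chars <- strsplit(s, "")[[1]]
  out <- character(0); i <- 1
  closers <- c("{" = "}", "(" = ")", "[" = "]")
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% names(closers)) {
      j <- i + 1
      while (j <= length(chars) && chars[j] != closers[[ch]]) j <- j + 1
      if (j > length(chars)) stop_labeled("unterminated '", ch, "' group")
      out <- c(out, paste0("{", paste(chars[(i + 1):(j - 1)], collapse = ""),
                           "}"))
      i <- j + 1
    } else {
      out <- c(out, ch)
      i <- i + 1
    }
  }
  out
}

## parse one column of cell tokens into bitmasks. The column's alphabet is
## `symbols` if given, else the observed symbols (digits ordered
## numerically, letters in order of appearance); `allowed` is a validation
## set (e.g. a declared NEXUS SYMBOLS list) that observed symbols must
## belong to without forcing the column alphabet to its full extent.
parse_column <- function(tokens, symbols = NULL, col = NA, allowed = NULL,
                         missing_chars = c("?", "-")) {
  pieces <- lapply(tokens, function(tok) {
    if (tok %in% missing_chars) return(NA_character_)
    first <- substr(tok, 1, 1)
    if (first %in% c("{", "(", "[")) # optional group wrapper
      tok <- substr(tok, 2, nchar(tok) - 1)
    strsplit(tok, "")[[1]]
  })
  observed <- unique(unlist(pieces[!is.na(pieces)]))
  if (!is.null(allowed)) {
    bad <- setdiff(observed, allowed)
    if (length(bad))
      stop_labeled("character ", col,
                   ": symbol(s) outside declared alphabet: ",
                   paste(bad, collapse = " "))
  }
  if (is.null(symbols)) {
    dig <- observed[grepl("^[0-9]$", observed)]
    symbols <- c(sort(dig), setdiff(observed, dig))
    if (!is.null(allowed))   # keep the declared ordering where available
      symbols <- c(intersect(allowed, symbols), setdiff(symbols, allowed))
  }
  if (length(symbols) == 0) symbols <- "0"   # entirely missing column
  bad <- setdiff(observed, symbols)
  if (length(bad))
    stop_labeled("character ", col, ": symbol(s) outside declared alphabet: ",
                 paste(bad, collapse = " "))
  k <- length(symbols)
  bits <- vapply(pieces, function(p) {
    if (length(p) == 1L && is.na(p)) return(full_mask(k))
    idx <- match(p, symbols)
    as.integer(sum(bitwShiftL(1L, idx - 1L)))
  }, integer(1))
  miss <- vapply(pieces, function(p) length(p) == 1L && is.na(p), logical(1))
  list(bits = bits, missing = miss, symbols = symbols)
}

## render one cell back to text
render_cell <- function(m, i, j, missing_char = "?") {
  if (m$missing[i, j]) return(missing_char)
  st <- cell_states(m, i, j)
  if (length(st) == 1) st else paste0("{", paste(st, collapse = ""), "}")
}

## full text rendering (taxa x chars character matrix)
render_cells <- function(m, missing_char = "?") {
  out <- matrix("", n_taxa(m), n_chars(m), dimnames = list(m$taxa, NULL))
  for (i in seq_len(n_taxa(m)))
    for (j in seq_len(n_chars(m)))
      out[i, j] <- render_cell(m, i, j, missing_char)
  out
}

#' @export
`[.char_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_taxa(x))
  if (missing(j)) j <- seq_len(n_chars(x))
  if (is.character(i)) i <- match(i, x$taxa)
  new_char_matrix(x$taxa[i], x$bits[i, j, drop = FALSE],
                  x$missing[i, j, drop = FALSE],
                  x$symbols[j], x$weights[j])
}
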