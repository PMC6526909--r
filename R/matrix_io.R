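#' Read a morphological character matrix
#'
#' Reads NEXUS (DATA/CHARACTERS block) or TNT `xread` files into a
#' [char_matrix]. `?` and `-` are both scored as missing (full state-set);
#' `{..}`, `(..)` and `[..]` denote polymorphic/ambiguous state-sets.
#' Character weights default to 1; a NEXUS `ASSUMPTIONS` block with a
#' `WTSET` command (`value: characters` pairs) is honoured.
#'
#' @param path file path.
#' @param format `"nexus"`, `"tnt"`, or `"auto"` (sniff the header).
#' @return a [char_matrix]. Dimensions are checked against the declared
#'   NTAX/NCHAR and a parse error names the offending line.
#' @export
read_char_matrix <- function(path, format = c("auto", "nexus", "tnt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_labeled("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    head_txt <- toupper(paste(head(lines, 5), collapse = " "))
    format <- if (grepl("#NEXUS", head_txt)) "nexus"
              else if (grepl("XREAD", head_txt)) "tnt"
              else stop_labeled("cannot determine matrix format of ", path)
  }
  switch(format,
         nexus = parse_nexus_matrix(lines),
         tnt   = parse_tnt_matrix(lines))
}

parse_err <- function(line, ...) stop_labeled("parse error (line ", line, "): ", ...)

strip_nexus_comments <- function(lines) {
  # remove [...] comments but NOT inside a MATRIX block where [] marks
  # polymorphism; we only strip comments containing non-state characters
  gsub("\\[[^][]*[^][0-9A-Za-z][^][]*\\]", "", lines)
}

parse_nexus_matrix <- function(lines) {
  lines <- strip_nexus_comments(lines)
  up <- toupper(lines)
  ntax <- nchar_decl <- NA_integer_
  missing_char <- "?"; gap_char <- "-"; symbols_decl <- NULL
  in_matrix <- FALSE; in_data_block <- FALSE
  rows <- list(); order <- character(0)
  matrix_done <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i]); lnu <- trimws(up[i])
    if (!nzchar(ln)) next
    if (grepl("^BEGIN\\s+(DATA|CHARACTERS)", lnu)) { in_data_block <- TRUE; next }
    if (!in_data_block) next
    if (!in_matrix) {
      if (grepl("NTAX", lnu)) {
        v <- regmatches(lnu, regexpr("NTAX\\s*=\\s*[0-9]+", lnu))
        if (length(v)) ntax <- as.integer(sub(".*=\\s*", "", v))
      }
      if (grepl("NCHAR", lnu)) {
        v <- regmatches(lnu, regexpr("NCHAR\\s*=\\s*[0-9]+", lnu))
        if (length(v)) nchar_decl <- as.integer(sub(".*=\\s*", "", v))
      }
      if (grepl("^FORMAT", lnu)) {
        v <- regmatches(ln, regexpr('SYMBOLS\\s*=\\s*"[^"]*"', ln, ignore.case = TRUE))
        if (length(v)) {
          sym <- sub('.*"(.*)"', "\\1", v)
          symbols_decl <- strsplit(gsub("\\s", "", sym), "")[[1]]
        }
        v <- regmatches(lnu, regexpr("MISSING\\s*=\\s*\\S", lnu))
        if (length(v)) missing_char <- substr(sub(".*=\\s*", "", v), 1, 1)
        v <- regmatches(lnu, regexpr("GAP\\s*=\\s*\\S", lnu))
        if (length(v)) gap_char <- substr(sub(".*=\\s*", "", v), 1, 1)
      }
      if (grepl("^MATRIX", lnu)) in_matrix <- TRUE
      next
    }
    if (grepl("^;", ln) || grepl(";\\s*$", ln)) {
      ln <- sub(";\\s*$", "", ln)
      matrix_done <- TRUE
    }
    ln <- trimws(ln)
    if (nzchar(ln)) {
      toks <- strsplit(ln, "\\s+")[[1]]
      taxon <- normalize_taxon(gsub("^'|'$", "", toks[1]))
      states <- paste(toks[-1], collapse = "")
      if (!nzchar(states)) parse_err(i, "row without character states")
      cells <- tryCatch(split_cell_tokens(states),
                        error = function(e) parse_err(i, conditionMessage(e)))
      if (taxon %in% names(rows)) {
        rows[[taxon]] <- c(rows[[taxon]], cells)   # interleaved continuation
      } else {
        rows[[taxon]] <- cells
        order <- c(order, taxon)
      }
    }
    if (matrix_done) { in_matrix <- FALSE; in_data_block <- FALSE }
  }
  if (!length(rows)) stop_labeled("no MATRIX block found")
  build_matrix_from_rows(rows, order, ntax, nchar_decl, symbols_decl,
                         weights = parse_nexus_wtset(lines,
                                                     length(rows[[order[1]]])))
}

## ASSUMPTIONS ... WTSET * name = w1: chars, w2: chars ... ;
parse_nexus_wtset <- function(lines, nchar) {
  txt <- paste(lines, collapse = "\n")
  m <- regmatches(txt, regexpr("WTSET[^;]*;", txt, ignore.case = TRUE))
  w <- rep(1, nchar)
  if (!length(m)) return(w)
  body <- sub(";$", "", sub(".*?=", "", m))
  for (grp in strsplit(body, ",")[[1]]) {
    parts <- strsplit(grp, ":")[[1]]
    if (length(parts) != 2) next
    val <- as.numeric(trimws(parts[1]))
    for (tok in strsplit(trimws(parts[2]), "\\s+")[[1]]) {
      if (grepl("-", tok)) {
        ab <- as.integer(strsplit(tok, "-")[[1]])
        w[ab[1]:ab[2]] <- val
      } else w[as.integer(tok)] <- val
    }
  }
  w
}

parse_tnt_matrix <- function(lines) {
  # xread ['title'] nchar ntax  then rows "taxon states", & for interleave
  txt_lines <- lines
  start <- grep("xread", txt_lines, ignore.case = TRUE)[1]
  if (is.na(start)) stop_labeled("no xread statement found")
  body <- paste(txt_lines[start:length(txt_lines)], collapse = "\n")
  body <- sub(".*?xread", "", body, ignore.case = TRUE, perl = TRUE)
  body <- gsub("'[^']*'", "", body)               # quoted title
  semi <- regexpr(";", body, fixed = TRUE)
  if (semi < 0) stop_labeled("xread block not terminated by ';'")
  body <- substr(body, 1, semi - 1)
  toks <- strsplit(trimws(body), "\\s+")[[1]]
  if (length(toks) < 2 || !grepl("^[0-9]+$", toks[1]) || !grepl("^[0-9]+$", toks[2]))
    stop_labeled("xread requires 'nchar ntax' counts")
  nchar_decl <- as.integer(toks[1]); ntax <- as.integer(toks[2])
  toks <- toks[-(1:2)]
  toks <- toks[toks != "&"]
  if (length(toks) %% 2 != 0)
    stop_labeled("xread rows must alternate taxon and states")
  rows <- list(); order <- character(0)
  for (k in seq(1, length(toks), by = 2)) {
    taxon <- normalize_taxon(toks[k])
    cells <- split_cell_tokens(toks[k + 1])
    if (taxon %in% names(rows)) rows[[taxon]] <- c(rows[[taxon]], cells)
    else { rows[[taxon]] <- cells; order <- c(order, taxon) }
  }
  build_matrix_from_rows(rows, order, ntax, nchar_decl, NULL,
                         weights = rep(1, nchar_decl))
}

build_matrix_from_rows <- function(rows, order, ntax, nchar_decl,
                                   symbols_decl, weights) {
  if (anyDuplicated(order)) stop_labeled("duplicate taxon: ",
                                         order[duplicated(order)][1])
  nc <- length(rows[[order[1]]])
  for (tx in order)
    if (length(rows[[tx]]) != nc)
      stop_labeled("taxon ", tx, " has ", length(rows[[tx]]),
                   " characters, expected ", nc)
  if (!is.na(ntax) && length(order) != ntax)
    stop_labeled("declared NTAX ", ntax, " but found ", length(order), " taxa")
  if (!is.na(nchar_decl) && nc != nchar_decl)
    stop_labeled("declared NCHAR ", nchar_decl, " but found ", nc)
  cells <- do.call(rbind, rows[order])
  rownames(cells) <- order
  ## the declared SYMBOLS list validates; each column's alphabet is the
  ## set it actually uses (per-character state counts, as in Mesquite)
  char_matrix(cells, taxa = order, weights = rep_len(weights, nc),
              allowed = symbols_decl)
}

#' Write a character matrix
#'
#' Symmetric writer for [read_char_matrix]. NEXUS output records the
#' observed per-matrix symbol set and, when any weight differs from 1,
#' an `ASSUMPTIONS` block with a `WTSET` command. TNT output ignores
#' weights (the `xread` dialect carries none here).
#'
#' @param m a [char_matrix].
#' @param path output file.
#' @param format `"nexus"` or `"tnt"`.
#' @return `path`, invisibly.
#' @export
write_char_matrix <- function(m, path, format = c("nexus", "tnt")) {
  format <- match.arg(format)
  cells <- render_cells(m)
  rows <- apply(cells, 1, paste, collapse = "")
  name_w <- max(nchar(m$taxa)) + 2
  body <- sprintf(paste0("%-", name_w, "s%s"), m$taxa, rows)
  if (format == "nexus") {
    syms <- sort(unique(unlist(m$symbols)))
    out <- c("#NEXUS", "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", n_taxa(m), n_chars(m)),
             sprintf('  FORMAT SYMBOLS="%s" MISSING=? GAP=-;',
                     paste(syms, collapse = "")),
             "  MATRIX", paste0("    ", body), "  ;", "END;")
    if (any(m$weights != 1)) {
      grp <- split(seq_len(n_chars(m)), m$weights)
      wt <- paste(vapply(names(grp), function(v)
        paste0(v, ": ", paste(grp[[v]], collapse = " ")), character(1)),
        collapse = ", ")
      out <- c(out, "BEGIN ASSUMPTIONS;",
               paste0("  WTSET * w = ", wt, ";"), "END;")
    }
  } else {
    out <- c("xread", sprintf("%d %d", n_chars(m), n_taxa(m)), body, ";")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read phylogenetic trees
#'
#' Reads Newick files or NEXUS TREES blocks (via ape), returning a list of
#' rooted trees with polytomies preserved and whitespace-normalized labels.
#'
#' @param path file path.
#' @return a `multiPhylo` list of trees.
#' @export
read_trees <- function(path) {
  if (!file.exists(path)) stop_labeled("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop_labeled("empty tree file: ", path)
  is_nexus <- grepl("#NEXUS", toupper(lines[1]), fixed = TRUE)
  trees <- if (is_nexus) ape::read.nexus(path) else ape::read.tree(path)
  if (is.null(trees)) stop_labeled("could not parse trees in ", path)
  if (inherits(trees, "phylo")) trees <- structure(list(trees),
                                                   class = "multiPhylo")
  for (i in seq_along(trees))
    trees[[i]]$tip.label <- normalize_taxon(trees[[i]]$tip.label)
  trees
}

#' Write phylogenetic trees
#'
#' @param trees a `phylo` or list of trees.
#' @param path output file.
#' @param format `"newick"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (inherits(trees, "phylo")) trees <- structure(list(trees),
                                                   class = "multiPhylo")
  class(trees) <- "multiPhylo"
  if (format == "newick") {
    ape::write.tree(trees, file = path)
  } else {
    ape::write.nexus(trees, file = path)
    ## drop ape's timestamp comment so identical trees give identical files
    lines <- readLines(path, warn = FALSE)
    writeLines(lines[!grepl("^\\[R-package APE", lines)], path)
  }
  invisible(path)
}

#' Read a stratigraphic age table
#'
#' CSV with header `taxon,fad,lad`: first- and last-appearance dates in Ma
#' (million years before present; larger = older). Validates `fad >= lad >= 0`.
#'
#' @param path CSV file path.
#' @return data.frame of class `age_table`.
#' @export
read_ages <- function(path) {
  if (!file.exists(path)) stop_labeled("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  age_table(df)
}

#' Construct/validate an age table
#'
#' @param df data.frame with columns `taxon`, `fad`, `lad`.
#' @return data.frame of class `age_table`.
#' @export
age_table <- function(df) {
  need <- c("taxon", "fad", "lad")
  names(df) <- tolower(names(df))
  if (!all(need %in% names(df)))
    stop_labeled("age table needs columns taxon, fad, lad")
  df <- df[, need]
  df$taxon <- normalize_taxon(df$taxon)
  for (cl in c("fad", "lad")) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v)) stop_labeled("non-numeric ", cl, " for taxon ",
                               df$taxon[which(is.na(v))[1]])
    df[[cl]] <- v
  }
  bad <- df$lad > df$fad | df$lad < 0
  if (any(bad))
    stop_labeled("invalid age range (lad > fad or negative) for taxon ",
                 df$taxon[which(bad)[1]])
  if (anyDuplicated(df$taxon))
    stop_labeled("duplicate taxon in age table: ",
                 df$taxon[duplicated(df$taxon)][1])
  class(df) <- c("age_table", "data.frame")
  df
}

#' @rdname read_ages
#' @param ages an `age_table`.
#' @export
write_ages <- function(ages, path) {
  write.csv(as.data.frame(ages), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## fetch fad/lad vectors aligned with tip labels
ages_for_tips <- function(phy, ages) {
  idx <- match(phy$tip.label, ages$taxon)
  if (anyNA(idx))
    stop_labeled("taxa missing from age table: ",
                 paste(phy$tip.label[is.na(idx)], collapse = ", "))
  list(fad = ages$fad[idx], lad = ages$lad[idx])
}
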