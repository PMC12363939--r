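# Minimal mmCIF/CCD category reader and writer.
#
# Covers the subset of the PDBx/CIF syntax needed for the categories this
# package consumes (atom_site, struct_conn, entity_poly_seq, chem_comp_atom,
# chem_comp_bond): data_ blocks, loop_ tables, single key-value items,
# quoted values and comments. Multi-line ;-delimited text fields are read as
# opaque values. Everything else in a file is ignored.

cif_tokenize_line <- function(line) {
  out <- character()
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "#") break
    if (ch == "'" || ch == "\"") {
      # quote ends at matching quote followed by whitespace/EOL
      j <- i + 1L
      repeat {
        k <- regexpr(ch, substr(line, j, n), fixed = TRUE)[1]
        if (k < 0) { j <- n + 1L; break }
        j <- j + k - 1L
        if (j == n || substr(line, j + 1L, j + 1L) %in% c(" ", "\t")) break
        j <- j + 1L
      }
      out <- c(out, substr(line, i + 1L, min(j, n) - if (j > n) 0L else 1L))
      i <- j + 1L
    } else {
      m <- regexpr("[ \t]", substr(line, i, n))[1]
      j <- if (m < 0) n else i + m - 2L
      out <- c(out, substr(line, i, j))
      i <- j + 1L
    }
  }
  out
}

#' Read CIF categories from a file
#'
#' Parses a CIF/mmCIF file into one data.frame per category (all columns
#' character; `.` and `?` become `NA`). Multiple data blocks are merged; for
#' CCD-style dictionaries the per-block comp_id lives in the category rows
#' themselves so no information is lost.
#'
#' @param path file path.
#' @return named list of data.frames, names are category names without the
#'   leading underscore (e.g. `"atom_site"`).
#' @export
read_cif_categories <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cats <- list()
  add_rows <- function(cat, df) {
    cats[[cat]] <<- if (is.null(cats[[cat]])) df else {
      both <- union(names(cats[[cat]]), names(df))
      for (nm in setdiff(both, names(df))) df[[nm]] <- NA_character_
      for (nm in setdiff(both, names(cats[[cat]]))) cats[[cat]][[nm]] <- NA_character_
      rbind(cats[[cat]][both], df[both])
    }
  }
  i <- 1L; n <- length(lines)
  read_value_tokens <- function() {
    # collect tokens from current position; handles ;-delimited text blocks
    toks <- character()
    while (i <= n) {
      ln <- lines[i]
      if (startsWith(ln, ";")) {
        txt <- sub("^;", "", ln); i <<- i + 1L
        while (i <= n && !startsWith(lines[i], ";")) {
          txt <- paste(txt, lines[i], sep = "\n"); i <<- i + 1L
        }
        i <<- i + 1L
        return(c(toks, txt))
      }
      t <- cif_tokenize_line(ln)
      i <<- i + 1L
      if (length(t)) return(c(toks, t))
    }
    toks
  }
  while (i <= n) {
    ln <- lines[i]
    toks <- cif_tokenize_line(ln)
    if (!length(toks)) { i <- i + 1L; next }
    first <- toks[1]
    if (startsWith(first, "data_") || first == "#") { i <- i + 1L; next }
    if (first == "loop_") {
      i <- i + 1L
      hdr <- character()
      while (i <= n) {
        t <- cif_tokenize_line(lines[i])
        if (length(t) == 1L && startsWith(t, "_")) { hdr <- c(hdr, t); i <- i + 1L }
        else break
      }
      if (!length(hdr)) next
      vals <- character()
      while (i <= n) {
        ln2 <- lines[i]
        t2 <- cif_tokenize_line(ln2)
        if (length(t2) && (startsWith(t2[1], "_") || t2[1] %in% c("loop_", "stop_") ||
                           startsWith(t2[1], "data_"))) break
        if (!length(t2) && !startsWith(ln2, ";")) { i <- i + 1L; next }
        vals <- c(vals, read_value_tokens())
      }
      if (length(vals) %% length(hdr) != 0L)
        stop("CIF parse error: ragged loop for ", hdr[1], " in ", path)
      cat_name <- sub("^_([^.]+)\\..*$", "\\1", hdr[1])
      cols <- sub("^_[^.]+\\.", "", hdr)
      m <- matrix(vals, ncol = length(hdr), byrow = TRUE)
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- cols
      df[df == "." | df == "?"] <- NA
      add_rows(cat_name, df)
    } else if (startsWith(first, "_")) {
      # single key-value item
      cat_name <- sub("^_([^.]+)\\..*$", "\\1", first)
      col <- sub("^_[^.]+\\.", "", first)
      if (length(toks) >= 2L) { val <- toks[2]; i <- i + 1L }
      else { i <- i + 1L; val <- read_value_tokens()[1] }
      if (is.na(val) || val %in% c(".", "?")) val <- NA_character_
      df <- stats::setNames(data.frame(v = val, stringsAsFactors = FALSE), col)
      if (!is.null(cats[[cat_name]]) && nrow(cats[[cat_name]]) == 1L &&
          !col %in% names(cats[[cat_name]])) {
        cats[[cat_name]][[col]] <- val
      } else add_rows(cat_name, df)
    } else i <- i + 1L
  }
  cats
}

cif_quote <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "."
  needs <- grepl("[ \t']", x) | x %in% c(".", "?") & FALSE
  x[needs] <- paste0('"', x[needs], '"')
  x
}

#' Write CIF categories to a file
#'
#' Emits one `loop_` per category (single-row categories are still written as
#' loops; readers accept both). Column order follows the data.frame.
#'
#' @param categories named list of data.frames.
#' @param path output file path.
#' @param block data block name.
#' @return `path`, invisibly.
#' @export
write_cif_categories <- function(categories, path, block = "structforge") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("data_", block), con)
  writeLines("#", con)
  for (cat in names(categories)) {
    df <- categories[[cat]]
    if (!nrow(df)) next
    writeLines("loop_", con)
    writeLines(paste0("_", cat, ".", names(df)), con)
    cols <- lapply(df, cif_quote)
    widths <- vapply(cols, function(cc) max(nchar(cc)), 1L)
    rows <- do.call(paste, c(mapply(formatC, cols, width = -widths,
                                    SIMPLIFY = FALSE), sep = " "))
    writeLines(rows, con)
    writeLines("#", con)
  }
  invisible(path)
}
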