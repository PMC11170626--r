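#' Default column mapping for the database CSV dialect
#'
#' The curated database ships as a UTF-8 comma-separated file with ten
#' general-information columns followed by the binary activity columns.
#' Header text may evolve between releases, so the reader takes an
#' explicit mapping from roles to header names; this function supplies
#' the defaults. Any column not named in the map is treated as an
#' activity column: if its header matches a panel target it contributes
#' to the specific profile, otherwise it is read as a family-level
#' general flag.
#'
#' @param absent_sentinel cell value marking a missing cross-reference ID.
#' @return named list of header names by role.
#' @export
default_column_map <- function(absent_sentinel = "Not in database") {
  list(name = "Name",
       smiles = "SMILES",
       inchi = "InChI",
       inchikey = "InChIKey",
       food_sources = "Food source",
       foodb_id = "FooDB ID",
       coconut_id = "COCONUT ID",
       doi = "DOI",
       absent_sentinel = absent_sentinel)
}

#' Read and validate a compound database CSV
#'
#' Every input row either becomes a validated record or is reported with
#' its row number and the reason it was rejected; the run always
#' continues past bad rows. SMILES are canonicalized on the way in.
#' Activity cells may be 0, 1 or empty; empty cells are read as 0 (in
#' this dialect 0 means "no reported activity", not "inactive") and
#' counted separately in the data-quality summary. The FooDB/COCONUT
#' sentinel string maps to \code{NA}. InChIKeys that fail the 14-10-1
#' pattern, or that disagree with nothing else (structures are compared
#' by canonical SMILES), produce warnings, not rejections.
#'
#' @param path CSV file path.
#' @param column_map see [default_column_map()].
#' @param panel a [target_panel()]; activity headers are matched against
#'   its target names.
#' @return A [compound_library()] with a \code{validation} attribute:
#'   a list with \code{errors} (data.frame of row, column, reason),
#'   \code{n_rows}, \code{n_valid}, \code{n_empty_activity_cells}.
#' @export
read_compound_db <- function(path, column_map = default_column_map(),
                             panel = default_target_panel()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = character(0))
  for (role in c("name", "smiles")) {
    if (!(column_map[[role]] %in% names(raw))) {
      stop("mandatory column '", column_map[[role]], "' (role: ", role,
           ") missing from ", path)
    }
  }
  meta_cols <- unlist(column_map[setdiff(names(column_map), "absent_sentinel")])
  act_cols <- setdiff(names(raw), meta_cols)
  spec_cols <- intersect(panel$targets, act_cols)
  gen_cols <- setdiff(act_cols, spec_cols)
  sentinel <- column_map$absent_sentinel

  get <- function(role, i) {
    col <- column_map[[role]]
    if (is.null(col) || !(col %in% names(raw))) return(NA_character_)
    v <- trimws(raw[[col]][i])
    if (!nzchar(v)) NA_character_ else v
  }

  errors <- data.frame(row = integer(0), column = character(0),
                       reason = character(0), stringsAsFactors = FALSE)
  add_error <- function(i, column, reason) {
    errors[nrow(errors) + 1L, ] <<- list(i, column, reason)
  }

  n_empty <- 0L
  rows <- vector("list", nrow(raw))
  profs <- vector("list", nrow(raw))
  gens <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    smi <- get("smiles", i)
    if (is.na(smi) || !is_valid_smiles(smi)) {
      add_error(i, column_map$smiles, "unparseable SMILES")
      next
    }
    cells <- trimws(unlist(raw[i, act_cols, drop = FALSE]))
    bad <- act_cols[!(cells %in% c("0", "1", ""))]
    if (length(bad) > 0) {
      add_error(i, bad[1],
                paste0("activity cell '", cells[match(bad[1], act_cols)],
                       "' not in {0, 1, empty}"))
      next
    }
    n_empty <- n_empty + sum(cells == "")
    vals <- ifelse(cells == "1", 1L, 0L)
    names(vals) <- act_cols
    prof <- integer(length(panel$targets))
    prof[match(spec_cols, panel$targets)] <- vals[spec_cols]
    ik <- get("inchikey", i)
    if (!is.na(ik) && !.inchikey_ok(ik)) {
      warning("row ", i, ": InChIKey '", ik, "' does not match the 14-10-1 pattern",
              call. = FALSE)
    }
    fdb <- get("foodb_id", i)
    if (!is.na(fdb) && identical(fdb, sentinel)) fdb <- NA_character_
    ccn <- get("coconut_id", i)
    if (!is.na(ccn) && identical(ccn, sentinel)) ccn <- NA_character_
    rows[[i]] <- data.frame(
      compound_id = i,
      name = if (is.na(get("name", i))) paste0("compound_", i) else get("name", i),
      smiles = canonicalize_smiles(smi),
      inchi = get("inchi", i),
      inchikey = ik,
      food_sources = get("food_sources", i),
      foodb_id = fdb,
      coconut_id = ccn,
      doi = get("doi", i),
      stringsAsFactors = FALSE
    )
    profs[[i]] <- prof
    gens[[i]] <- if (length(gen_cols)) vals[gen_cols] else integer(0)
  }

  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("no valid rows in ", path)
  compounds <- do.call(rbind, rows[keep])
  profile <- do.call(rbind, profs[keep])
  general <- do.call(rbind, gens[keep])
  if (length(gen_cols)) colnames(general) <- gen_cols
  lib <- compound_library(compounds, profile,
                          general = if (length(gen_cols)) general else NULL,
                          panel = panel, provenance = path)
  attr(lib, "validation") <- list(errors = errors,
                                  n_rows = nrow(raw),
                                  n_valid = sum(keep),
                                  n_empty_activity_cells = n_empty)
  lib
}

#' Write a compound library in the database CSV dialect
#'
#' Inverse of [read_compound_db()]: writing then reading reproduces the
#' records field for field (structures compared as canonical SMILES).
#'
#' @param library a [compound_library()].
#' @param path output CSV path.
#' @param column_map header names, see [default_column_map()].
#' @return \code{path}, invisibly.
#' @export
write_compound_db <- function(library, path,
                              column_map = default_column_map()) {
  stopifnot(inherits(library, "compound_library"))
  cm <- column_map
  co <- library$compounds
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    a = co$name, b = co$smiles, c = co$inchi, d = co$inchikey,
    e = co$food_sources,
    f = ifelse(is.na(co$foodb_id), cm$absent_sentinel, co$foodb_id),
    g = ifelse(is.na(co$coconut_id), cm$absent_sentinel, co$coconut_id),
    h = co$doi)
  names(out) <- unlist(cm[c("name", "smiles", "inchi", "inchikey",
                            "food_sources", "foodb_id", "coconut_id", "doi")])
  out[is.na(out)] <- ""
  prof <- as.data.frame(library$profile, check.names = FALSE)
  gen <- as.data.frame(library$general, check.names = FALSE)
  utils::write.csv(cbind(out, prof, gen), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a plain SMILES file
#'
#' One molecule per line, optionally followed by a tab-separated
#' identifier. Unparseable lines are dropped with a warning.
#'
#' @param path file path.
#' @return data.frame with columns \code{id} and \code{smiles} (canonical).
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[`, character(1), 1)
  id <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) > 1) parts[[i]][2] else paste0("mol_", i)
  }, character(1))
  ok <- is_valid_smiles(smi)
  if (any(!ok)) {
    warning(sum(!ok), " line(s) with unparseable SMILES dropped", call. = FALSE)
  }
  data.frame(id = id[ok], smiles = canonicalize_smiles(smi[ok]),
             stringsAsFactors = FALSE)
}

#' Write result tables to disk
#'
#' One file per table per requested format, with deterministic column
#' order (as given). Empty tables produce a header-only file.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param formats subset of \code{c("csv", "json", "html")}.
#' @return manifest data.frame: table, format, path, n_rows.
#' @export
write_report <- function(tables, out_dir, formats = "csv") {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  formats <- match.arg(formats, c("csv", "json", "html"), several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(table = character(0), format = character(0),
                         path = character(0), n_rows = integer(0),
                         stringsAsFactors = FALSE)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    for (fmt in formats) {
      p <- file.path(out_dir, paste0(nm, ".", fmt))
      switch(fmt,
        csv = utils::write.csv(tab, p, row.names = FALSE),
        json = jsonlite::write_json(tab, p, dataframe = "rows", digits = NA),
        html = .write_html_table(tab, p, title = nm))
      manifest[nrow(manifest) + 1L, ] <- list(nm, fmt, p, nrow(tab))
    }
  }
  manifest
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.write_html_table <- function(tab, path, title = "table") {
  head_row <- paste0("<tr>", paste0("<th>", .html_escape(names(tab)), "</th>",
                                    collapse = ""), "</tr>")
  body <- apply(tab, 1, function(r) {
    paste0("<tr>", paste0("<td>", .html_escape(as.character(r)), "</td>",
                          collapse = ""), "</tr>")
  })
  writeLines(c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
               paste0("<title>", .html_escape(title), "</title></head><body>"),
               paste0("<h1>", .html_escape(title), "</h1><table border='1'>"),
               head_row, body, "</table></body></html>"), path)
  invisible(path)
}
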