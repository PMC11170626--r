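# Internal molecular-graph helpers built on the OpenBabel backend
# (ChemmineOB). Molecules are handled as parsed V2000 connection tables:
# list(elem, chg, bonds, n) with bonds as an (i, j, order) integer matrix.
# Aromatic rings arrive kekulized (orders 1/2), which keeps graph surgery
# (scaffold pruning, decoration) order-exact.

#' Canonicalize SMILES strings
#'
#' Maps every SMILES to the backend's canonical form, so that two encodings
#' of the same molecule compare equal and downstream fingerprint and
#' scaffold results are deterministic. Canonicalization is idempotent.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' canonicalize_smiles(c("C1=CC=CC=C1", "c1ccccc1"))
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  vapply(smiles, function(s) {
    out <- .ob_quiet(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n")))
    out <- trimws(sub("\t.*", "", out))
    if (!nzchar(out)) {
      stop("unparseable SMILES: '", s, "'", call. = FALSE)
    }
    out
  }, character(1), USE.NAMES = FALSE)
}

#' Check whether SMILES strings parse
#'
#' @param smiles character vector.
#' @return logical vector, TRUE where the backend accepts the string.
#' @export
is_valid_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(
      .ob_quiet(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))),
      error = function(e) ""
    )
    nzchar(trimws(sub("\t.*", "", out)))
  }, logical(1), USE.NAMES = FALSE)
}

# OpenBabel reports parse problems on stderr; silence them so per-row
# validation can report its own, structured errors.
.ob_quiet <- function(expr) {
  nul <- if (.Platform$OS.type == "windows") "NUL" else "/dev/null"
  con <- file(nul, open = "w")
  sink(con, type = "message")
  on.exit({ sink(type = "message"); close(con) }, add = TRUE)
  force(expr)
}

# SMILES -> parsed connection table (single molecule).
.smiles_to_mol <- function(smiles) {
  txt <- .ob_quiet(ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n")))
  if (!nzchar(trimws(txt))) stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  .parse_molfile(txt)
}

.parse_molfile <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  elem <- character(0)
  if (na > 0) {
    at <- lines[5:(4 + na)]
    elem <- trimws(substr(at, 32, 34))
  }
  bonds <- matrix(integer(0), ncol = 3)
  if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    bonds <- cbind(as.integer(substr(bl, 1, 3)),
                   as.integer(substr(bl, 4, 6)),
                   as.integer(substr(bl, 7, 9)))
  }
  chg <- integer(na)
  for (l in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substr(l, 7, nchar(l))), "\\s+")[[1]])
    for (k in seq_len(f[1])) chg[f[2 * k]] <- f[2 * k + 1]
  }
  list(elem = elem, chg = chg, bonds = bonds, n = na)
}

# Connection table -> V2000 text (coordinates are irrelevant downstream:
# the only consumer re-perceives the molecule from connectivity).
.write_molfile <- function(elem, chg, bonds) {
  na <- length(elem)
  nb <- nrow(bonds)
  hdr <- c("", " epichem", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  at <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                elem)
  bl <- character(0)
  if (nb > 0) {
    bl <- sprintf("%3d%3d%3d  0  0  0  0", bonds[, 1], bonds[, 2], bonds[, 3])
  }
  chgl <- character(0)
  w <- which(chg != 0)
  if (length(w)) {
    chgl <- sprintf("M  CHG%3d%s", length(w),
                    paste0(sprintf("%4d%4d", w, chg[w]), collapse = ""))
  }
  paste(c(hdr, at, bl, chgl, "M  END", "$$$$", ""), collapse = "\n")
}

# Connection table -> canonical SMILES via the backend.
.mol_to_smiles <- function(mol) {
  txt <- .write_molfile(mol$elem, mol$chg, mol$bonds)
  out <- .ob_quiet(ChemmineOB::convertFormat("SDF", "CAN", txt))
  trimws(sub("\t.*", "", out))
}

# Sum of explicit bond orders per atom (kekulized), used as a valence
# proxy when decorating ring templates.
.bond_order_sums <- function(mol) {
  s <- numeric(mol$n)
  if (nrow(mol$bonds) > 0) {
    for (r in seq_len(nrow(mol$bonds))) {
      s[mol$bonds[r, 1]] <- s[mol$bonds[r, 1]] + mol$bonds[r, 3]
      s[mol$bonds[r, 2]] <- s[mol$bonds[r, 2]] + mol$bonds[r, 3]
    }
  }
  s
}
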