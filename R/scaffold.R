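# Bemis-Murcko scaffold extraction and scaffold-diversity statistics.
# A scaffold is the molecule's ring systems plus the linkers connecting
# them, with all side chains removed; atoms multiply bonded to the
# framework (e.g. the flavone carbonyl) are retained. No installed R
# package exposes this decomposition, so the pruning is implemented here
# on the kekulized connection table and validated against reference
# scaffolds in the tests.

#' Bemis-Murcko scaffold of a molecule
#'
#' Iteratively prunes terminal atoms until only rings and the linkers
#' between them remain, then restores atoms attached to that framework
#' by double or triple bonds, and returns the canonical SMILES of the
#' result. Acyclic molecules have no scaffold and return \code{""}.
#' The result is invariant to the input SMILES form.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical scaffold SMILES ("" = acyclic).
#' @export
bemis_murcko <- function(smiles) {
  vapply(smiles, function(s) {
    mol <- .smiles_to_mol(s)
    if (nrow(mol$bonds) == 0) return("")
    # strip terminal atoms to a fixpoint: what survives is every atom on
    # a cycle or on a path between cycles
    core <- rep(TRUE, mol$n)
    repeat {
      deg <- integer(mol$n)
      for (r in seq_len(nrow(mol$bonds))) {
        i <- mol$bonds[r, 1]; j <- mol$bonds[r, 2]
        if (core[i] && core[j]) { deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L }
      }
      drop <- core & deg <= 1L
      if (!any(drop)) break
      core[drop] <- FALSE
    }
    if (!any(core)) return("")
    keep <- core
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[r, 1]; j <- mol$bonds[r, 2]
      if (mol$bonds[r, 3] >= 2) {
        if (core[i] && !core[j]) keep[j] <- TRUE
        if (core[j] && !core[i]) keep[i] <- TRUE
      }
    }
    idx <- which(keep)
    remap <- integer(mol$n)
    remap[idx] <- seq_along(idx)
    sel <- keep[mol$bonds[, 1]] & keep[mol$bonds[, 2]]
    bonds <- mol$bonds[sel, , drop = FALSE]
    bonds[, 1] <- remap[bonds[, 1]]
    bonds[, 2] <- remap[bonds[, 2]]
    .mol_to_smiles(list(elem = mol$elem[idx], chg = mol$chg[idx],
                        bonds = bonds, n = length(idx)))
  }, character(1), USE.NAMES = FALSE)
}

#' Scaffold frequency table
#'
#' Counts compounds per Bemis-Murcko scaffold. Acyclic compounds (empty
#' scaffold) are tallied but excluded from \code{n_unique_scaffolds},
#' and by default from the fraction denominator: the default
#' \code{ring_bearing_only} convention reports each scaffold's share of
#' the ring-bearing population. Rows are sorted by descending count,
#' ties by ascending scaffold SMILES, so tables and the CSR curve built
#' from them are deterministic.
#'
#' @param library a [compound_library()].
#' @param denominator \code{"ring_bearing_only"} (default) or
#'   \code{"all_compounds"}.
#' @return object of class \code{scaffold_table}: a data.frame
#'   (\code{scaffold}, \code{count}, \code{fraction}) with attributes
#'   \code{n_unique_scaffolds}, \code{n_compounds}, \code{n_acyclic},
#'   \code{denominator}.
#' @export
scaffold_table <- function(library,
                           denominator = c("ring_bearing_only", "all_compounds")) {
  stopifnot(inherits(library, "compound_library"),
            nrow(library$compounds) >= 1)
  denominator <- match.arg(denominator)
  sc <- bemis_murcko(library$compounds$smiles)
  n <- length(sc)
  n_acyclic <- sum(sc == "")
  cyc <- sc[sc != ""]
  counts <- table(cyc)
  denom <- if (denominator == "ring_bearing_only") length(cyc) else n
  tab <- data.frame(scaffold = names(counts),
                    count = as.integer(counts),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$count, tab$scaffold), , drop = FALSE]
  rownames(tab) <- NULL
  tab$fraction <- tab$count / denom
  structure(tab,
            n_unique_scaffolds = length(counts),
            n_compounds = n,
            n_acyclic = n_acyclic,
            denominator = denominator,
            class = c("scaffold_table", "data.frame"))
}

#' Top-k scaffold coverage
#'
#' @param table a [scaffold_table()].
#' @param k number of most frequent scaffolds.
#' @return summed fraction of the top \code{k} scaffolds.
#' @export
top_k_coverage <- function(table, k = 10) {
  stopifnot(inherits(table, "scaffold_table"))
  sum(utils::head(table$fraction, k))
}

#' Cyclic system recovery (CSR) curve and its AUC
#'
#' Scaffolds are added in descending frequency order; the curve plots
#' the cumulative fraction of compounds recovered (y) against the
#' fraction of scaffolds used (x), from (0, 0) to (1, 1). The AUC
#' (trapezoidal rule) summarizes scaffold diversity: a maximally diverse
#' set where every compound has its own scaffold gives the diagonal and
#' AUC = 0.5; concentration onto few scaffolds bends the curve upward.
#' The degenerate single-scaffold table is reported as AUC = 1.0, the
#' limiting "vertical line" convention, although the two-point trapezoid
#' alone would integrate to 0.5.
#'
#' @param table a [scaffold_table()] with >= 1 ring-bearing scaffold.
#' @return object of class \code{csr_curve}: list with \code{points}
#'   (data.frame \code{scaffold_fraction}, \code{compound_fraction}) and
#'   \code{auc}.
#' @export
csr_curve <- function(table) {
  stopifnot(inherits(table, "scaffold_table"))
  counts <- table$count      # already sorted desc, ties by SMILES asc
  m <- length(counts)
  if (m == 0) stop("undefined curve: no ring-bearing compounds")
  total <- sum(counts)
  x <- c(0, seq_len(m) / m)
  y <- c(0, cumsum(counts) / total)
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  if (m == 1) auc <- 1.0
  structure(list(points = data.frame(scaffold_fraction = x,
                                     compound_fraction = y),
                 auc = auc),
            class = "csr_curve")
}

#' @export
print.csr_curve <- function(x, ...) {
  cat(sprintf("csr_curve: %d scaffolds, AUC = %.4f\n",
              nrow(x$points) - 1L, x$auc))
  invisible(x)
}
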