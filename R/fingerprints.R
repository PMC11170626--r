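# Structural fingerprints and all-pairs Jaccard-Tanimoto similarity.
# Four fingerprint kinds mirror common practice for diversity analysis:
# the 166-key MACCS dictionary, extended-connectivity fingerprints of
# radius 2 and 3 (ECFP4/ECFP6), and a path-based topological fingerprint
# (linear fragments up to 7 atoms). All are computed by the OpenBabel
# backend at its native widths.

.fp_kinds <- c(MACCS_166 = "MACCS", ECFP_r2 = "ECFP4", ECFP_r3 = "ECFP6",
               PATH_TOPOLOGICAL = "FP2")

#' Fingerprint kinds
#'
#' @return character vector of the supported fingerprint kind names.
#' @export
fingerprint_kinds <- function() names(.fp_kinds)

#' Compute structural fingerprints for a library
#'
#' @param library a [compound_library()] (all SMILES canonical and valid).
#' @param kind one of [fingerprint_kinds()]: \code{MACCS_166} (166
#'   dictionary keys), \code{ECFP_r2} / \code{ECFP_r3}
#'   (extended-connectivity, radius 2 / 3), \code{PATH_TOPOLOGICAL}
#'   (linear paths up to 7 atoms).
#' @return object of class \code{fingerprint_set}: list with \code{kind},
#'   \code{bits} (n x n_bits 0/1 matrix, rownames = compound_id) and
#'   \code{n_bits}.
#' @export
compute_fingerprints <- function(library, kind = fingerprint_kinds()) {
  stopifnot(inherits(library, "compound_library"))
  kind <- match.arg(kind)
  smi <- paste(library$compounds$smiles, collapse = "\n")
  refs <- .ob_quiet(ChemmineOB::forEachMol("SMILES", smi, identity))
  bits <- .ob_quiet(ChemmineOB::fingerprint_OB(refs, .fp_kinds[[kind]]))
  bits <- matrix(as.integer(bits), nrow = nrow(bits))
  if (kind == "MACCS_166") bits <- bits[, seq_len(166), drop = FALSE]
  rownames(bits) <- library$compounds$compound_id
  structure(list(kind = kind, bits = bits, n_bits = ncol(bits)),
            class = "fingerprint_set")
}

#' Jaccard-Tanimoto similarity of two bit vectors
#'
#' \eqn{|a \cap b| / |a \cup b|} on the set bits. For two all-zero
#' vectors the similarity is undefined; by convention it is 0 and the
#' value carries the attribute \code{undefined_similarity = TRUE}. The
#' same implementation serves structural fingerprints and binary
#' activity profiles.
#'
#' @param a,b equal-length 0/1 vectors.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("bit vectors differ in length (", length(a), " vs ", length(b), ")")
  }
  u <- sum(a | b)
  if (u == 0) return(structure(0, undefined_similarity = TRUE))
  sum(a & b) / u
}

#' Pairwise comparison counts
#'
#' For a library of \code{n} compounds the number of unordered pairs is
#' \eqn{n(n+1)/2} when self-comparisons are included and
#' \eqn{n(n-1)/2} when excluded.
#'
#' @param n library size, >= 1.
#' @return named list \code{with_self}, \code{without_self}.
#' @export
count_pairs <- function(n) {
  if (length(n) != 1 || is.na(n) || n < 1) stop("n must be a single integer >= 1")
  n <- as.numeric(n)
  list(with_self = n * (n + 1) / 2, without_self = n * (n - 1) / 2)
}

#' All-pairs Tanimoto similarity for a fingerprint set
#'
#' Computes the similarity for every unordered pair \code{i < j}
#' (self-pairs excluded; their value is 1 by identity). Vectorized as a
#' bit-matrix cross-product, so the full 4096-bit, few-hundred-compound
#' case stays fast.
#'
#' @param fps a \code{fingerprint_set} from [compute_fingerprints()], or
#'   any n x bits 0/1 matrix with rownames.
#' @return data.frame \code{id_i}, \code{id_j}, \code{similarity},
#'   \code{undefined} (TRUE where both vectors were empty).
#' @export
all_pairs_tanimoto <- function(fps) {
  bits <- if (inherits(fps, "fingerprint_set")) fps$bits else as.matrix(fps)
  n <- nrow(bits)
  if (n < 2) stop("need at least 2 compounds")
  inter <- tcrossprod(bits)
  pop <- diag(inter)
  union <- outer(pop, pop, "+") - inter
  sim <- ifelse(union == 0, 0, inter / union)
  und <- union == 0
  iu <- which(upper.tri(sim), arr.ind = TRUE)
  ids <- rownames(bits)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  data.frame(id_i = ids[iu[, 1]], id_j = ids[iu[, 2]],
             similarity = sim[iu], undefined = und[iu],
             stringsAsFactors = FALSE)
}

#' All-pairs structural and activity-profile similarity table
#'
#' The backbone of the SAS analysis: one row per unordered compound pair
#' (\code{n(n-1)/2} rows), one structural-similarity column per
#' fingerprint kind, plus the activity-profile Jaccard similarity over
#' the panel's specific targets. Pairs in which either profile is
#' all-zero get activity similarity 0 and are flagged
#' \code{activity_undefined}: their zeros may mean "untested".
#'
#' @param library a [compound_library()] with >= 2 compounds.
#' @param kinds fingerprint kinds to compute (default all four).
#' @return data.frame with columns \code{id_i}, \code{id_j},
#'   \code{name_i}, \code{name_j}, one column per kind,
#'   \code{activity_similarity}, \code{activity_undefined}.
#' @export
pairwise_similarity <- function(library, kinds = fingerprint_kinds()) {
  stopifnot(inherits(library, "compound_library"),
            nrow(library$compounds) >= 2)
  base <- NULL
  for (k in kinds) {
    fp <- compute_fingerprints(library, k)
    tab <- all_pairs_tanimoto(fp)
    if (is.null(base)) {
      base <- tab[, c("id_i", "id_j")]
    }
    base[[k]] <- tab$similarity
  }
  act <- all_pairs_tanimoto(library$profile |>
                              `rownames<-`(library$compounds$compound_id))
  base$activity_similarity <- act$similarity
  base$activity_undefined <- act$undefined
  nm <- library$compounds$name[match(base$id_i, library$compounds$compound_id)]
  base <- cbind(base[, 1:2],
                name_i = nm,
                name_j = library$compounds$name[
                  match(base$id_j, library$compounds$compound_id)],
                base[, -(1:2)])
  base
}
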