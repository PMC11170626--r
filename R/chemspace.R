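# Chemical-space embedding: physicochemical descriptors, z-scoring, and
# a seeded exact t-SNE. With library sizes in the hundreds the O(n^2)
# exact algorithm is both fast and free of approximation parameters.

#' Physicochemical descriptors for a set of molecules
#'
#' Computes the backend's property panel (molecular weight, logP, molar
#' refractivity, TPSA, H-bond donor/acceptor counts, fluorine count)
#' extended with connection-table descriptors: heavy-atom, bond, ring
#' (cyclomatic), heteroatom, halogen and per-element counts, and the
#' aromatic-atom fraction. The descriptor names and count are recorded
#' so a run's summary can report the panel actually used. Compounds
#' whose descriptor computation fails are returned as NA rows and
#' reported via the \code{failures} attribute.
#'
#' @param smiles character vector of valid SMILES.
#' @return numeric matrix, one row per molecule, with attribute
#'   \code{failures} (integer indices).
#' @export
compute_descriptors <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  refs <- .ob_quiet(ChemmineOB::forEachMol("SMILES",
                                           paste(smiles, collapse = "\n"),
                                           identity))
  props <- .ob_quiet(ChemmineOB::prop_OB(refs))
  num_cols <- c("MW", "logP", "MR", "TPSA", "HBD", "HBA1", "HBA2", "nF")
  num_cols <- intersect(num_cols, names(props))
  backend <- as.matrix(props[, num_cols, drop = FALSE])

  graph <- t(vapply(smiles, function(s) {
    ok <- tryCatch({
      mol <- .smiles_to_mol(s)
      # canonical SMILES writes aromatic atoms lowercase
      arom <- sum(strsplit(gsub("\\[[^]]*\\]", "", s), "")[[1]] %in%
                    c("c", "n", "o", "s", "p"))
      hetero <- sum(!(mol$elem %in% c("C", "H")))
      halogen <- sum(mol$elem %in% c("F", "Cl", "Br", "I"))
      comp <- .n_components(mol)
      c(n_heavy = mol$n,
        n_bonds = nrow(mol$bonds),
        n_rings = nrow(mol$bonds) - mol$n + comp,
        n_hetero = hetero,
        n_halogen = halogen,
        n_N = sum(mol$elem == "N"),
        n_O = sum(mol$elem == "O"),
        n_S = sum(mol$elem == "S"),
        frac_aromatic = if (mol$n > 0) arom / mol$n else 0)
    }, error = function(e) rep(NA_real_, 9))
    ok
  }, numeric(9)))
  rownames(graph) <- NULL

  m <- cbind(backend, graph)
  failures <- which(apply(m, 1, function(r) all(is.na(r))))
  if (length(failures) == nrow(m)) stop("descriptor computation failed for every molecule")
  attr(m, "failures") <- failures
  m
}

# connected components of the molecular graph
.n_components <- function(mol) {
  if (mol$n == 0) return(0L)
  parent <- seq_len(mol$n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      a <- find(mol$bonds[r, 1]); b <- find(mol$bonds[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  length(unique(vapply(seq_len(mol$n), find, integer(1))))
}

#' Standardize a descriptor matrix
#'
#' Imputes missing values by the column median (with a warning naming
#' the affected rows), drops constant and all-missing columns (logged in
#' the \code{dropped} attribute) and z-scores the remainder, so that no
#' descriptor dominates the embedding distances through its units.
#'
#' @param m numeric descriptor matrix.
#' @return standardized matrix with attributes \code{center},
#'   \code{scale}, \code{dropped}.
#' @export
standardize_descriptors <- function(m) {
  m <- as.matrix(m)
  na_rows <- which(apply(m, 1, anyNA))
  if (length(na_rows)) {
    warning("descriptor values imputed by column median for row(s): ",
            paste(na_rows, collapse = ", "), call. = FALSE)
    for (j in seq_len(ncol(m))) {
      bad <- is.na(m[, j])
      if (any(bad)) m[bad, j] <- stats::median(m[, j], na.rm = TRUE)
    }
  }
  sds <- apply(m, 2, stats::sd)
  drop <- which(is.na(sds) | sds == 0)
  out <- if (length(drop)) m[, -drop, drop = FALSE] else m
  ctr <- colMeans(out)
  scl <- apply(out, 2, stats::sd)
  out <- scale(out, center = ctr, scale = scl)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  attr(out, "dropped") <- colnames(m)[drop]
  out
}

#' Seeded 2-D t-SNE embedding
#'
#' Exact (non-approximate) t-distributed stochastic neighbor embedding:
#' Gaussian input affinities calibrated per point to the requested
#' perplexity by bisection, Student-t output affinities, and gradient
#' descent on the Kullback-Leibler divergence with early exaggeration,
#' momentum and adaptive gains. Identical input, seed and parameters
#' give identical coordinates.
#'
#' @param x numeric matrix (rows = items), typically
#'   [standardize_descriptors()] output.
#' @param perplexity effective neighbor count; must be < nrow(x).
#' @param max_iter gradient-descent iterations.
#' @param seed RNG seed for the initial layout.
#' @param eta learning rate.
#' @return object of class \code{tsne_embedding}: list with
#'   \code{coordinates} (n x 2), \code{params}, \code{kl_divergence}.
#' @export
embed_tsne <- function(x, perplexity = 30, max_iter = 1000, seed = 42,
                       eta = 200) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 rows to embed")
  if (perplexity >= n) {
    stop("perplexity (", perplexity, ") must be smaller than the number of rows (",
         n, ")")
  }
  d2 <- as.matrix(stats::dist(x))^2
  P <- .perplexity_affinities(d2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P / sum(P), .Machine$double.eps)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), ncol = 2)

  gain <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  exagg <- 12
  stop_exagg <- min(100, max_iter %/% 4)
  Pe <- P * exagg
  kl <- NA_real_
  for (it in seq_len(max_iter)) {
    if (it == stop_exagg + 1) Pe <- P
    yd2 <- as.matrix(stats::dist(Y))^2
    num <- 1 / (1 + yd2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.eps)
    PQ <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(PQ)) - PQ) %*% Y
    mom <- if (it < 250) 0.5 else 0.8
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- mom * inc - eta * gain * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  kl <- sum(P * log(P / Q))
  structure(list(coordinates = Y,
                 params = list(perplexity = perplexity, max_iter = max_iter,
                               seed = seed, eta = eta),
                 kl_divergence = kl),
            class = "tsne_embedding")
}

# Bisection for per-row Gaussian bandwidths hitting the target perplexity.
.perplexity_affinities <- function(d2, perplexity, tol = 1e-5, max_tries = 50) {
  n <- nrow(d2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (tr in seq_len(max_tries)) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { p <- rep(1 / length(di), length(di)); break }
      H <- log(sp) + beta * sum(di * p) / sp
      p <- p / sp
      if (abs(H - target) < tol) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P
}

#' k-nearest-neighbor label purity of an embedding
#'
#' Mean fraction of each point's k nearest embedded neighbors
#' (excluding itself) that carry the same label; 1 means perfectly
#' separated groups.
#'
#' @param coordinates n x 2 matrix.
#' @param labels length-n grouping.
#' @param k neighbors to inspect.
#' @return purity in [0, 1].
#' @export
knn_purity <- function(coordinates, labels, k = 10) {
  d <- as.matrix(stats::dist(coordinates))
  diag(d) <- Inf
  mean(vapply(seq_len(nrow(d)), function(i) {
    nb <- order(d[i, ])[seq_len(k)]
    mean(labels[nb] == labels[i])
  }, numeric(1)))
}

#' Descriptor-space map of a library, optionally over a reference set
#'
#' Convenience wrapper: descriptors for the library (and, if given, a
#' reference SMILES collection), standardization fitted on the union,
#' and a seeded t-SNE. The set label ("library" / "reference") is
#' carried into the output for two-color plotting.
#'
#' @param library a [compound_library()].
#' @param reference optional data.frame from [read_smiles()].
#' @param perplexity,max_iter,seed passed to [embed_tsne()].
#' @return data.frame \code{id}, \code{set_label}, \code{x}, \code{y};
#'   attribute \code{n_descriptors} records the panel size used.
#' @export
chem_space_map <- function(library, reference = NULL, perplexity = 30,
                           max_iter = 1000, seed = 42) {
  stopifnot(inherits(library, "compound_library"))
  smi <- library$compounds$smiles
  ids <- as.character(library$compounds$compound_id)
  lab <- rep("library", length(smi))
  if (!is.null(reference)) {
    smi <- c(smi, reference$smiles)
    ids <- c(ids, reference$id)
    lab <- c(lab, rep("reference", nrow(reference)))
  }
  m <- compute_descriptors(smi)
  z <- standardize_descriptors(m)
  emb <- embed_tsne(z, perplexity = min(perplexity, nrow(z) - 1),
                    max_iter = max_iter, seed = seed)
  out <- data.frame(id = ids, set_label = lab,
                    x = emb$coordinates[, 1], y = emb$coordinates[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "n_descriptors") <- ncol(z)
  out
}
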