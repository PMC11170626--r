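# Synthetic compound libraries with controlled scaffold-frequency
# distributions and activity profiles statistically coupled to scaffold
# membership. Structures are built by decorating ring-system templates
# with small inert substituents, so Bemis-Murcko extraction provably
# recovers the template and every SMILES is valid by construction.

#' Specification of a synthetic library
#'
#' @param n_compounds number of compounds to generate.
#' @param n_scaffolds number of distinct scaffolds, \code{<= n_compounds}.
#' @param scaffold_concentration Zipf exponent of the scaffold-size
#'   distribution: 0 gives equal-sized scaffolds, larger values
#'   concentrate compounds onto the first scaffolds.
#' @param n_targets length of the binary activity profile (default 46,
#'   matching [default_target_panel()]).
#' @param base_profile_density probability that a bit of a scaffold's
#'   base activity profile is 1. The default 0.4 keeps the generator in
#'   the regime where same-scaffold profile similarity decays
#'   monotonically over the whole noise range: for sparse profiles
#'   (density below 0.3), heavy noise reintroduces chance overlap and
#'   the expected Jaccard similarity rises again towards its
#'   random-vector value of 1/3 (see [expected_profile_similarity()]).
#' @param noise_rate per-bit flip probability applied independently to
#'   each compound's copy of its scaffold's base profile. 0 makes
#'   same-scaffold profiles identical; 0.5 destroys the coupling.
#'   Flips are realized by thresholding one shared uniform draw per
#'   compound and bit, so libraries generated from the same seed at
#'   different noise rates have nested flip sets (common random
#'   numbers), which makes fixed-seed noise sweeps directly comparable.
#' @param seed integer seed; generation is a pure function of it.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_compounds, n_scaffolds,
                           scaffold_concentration = 1,
                           n_targets = 46,
                           base_profile_density = 0.4,
                           noise_rate = 0.05,
                           seed = 1) {
  stopifnot(n_compounds >= 1, n_scaffolds >= 1, n_scaffolds <= n_compounds,
            scaffold_concentration >= 0, n_targets >= 1,
            base_profile_density >= 0, base_profile_density <= 1,
            noise_rate >= 0, noise_rate <= 1)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_scaffolds = as.integer(n_scaffolds),
                 scaffold_concentration = scaffold_concentration,
                 n_targets = as.integer(n_targets),
                 base_profile_density = base_profile_density,
                 noise_rate = noise_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Ring-system templates: SMILES whose Bemis-Murcko scaffold is the
# template itself (rings, linkers, and exocyclic carbonyls only).
.ring_templates <- function() {
  c("c1ccccc1",                       # benzene
    "c1ccncc1",                       # pyridine
    "c1ccc2ccccc2c1",                 # naphthalene
    "C1CCCCC1",                       # cyclohexane
    "C1CCCC1",                        # cyclopentane
    "c1ccoc1",                        # furan
    "c1ccsc1",                        # thiophene
    "c1cc[nH]c1",                     # pyrrole
    "c1ccc2[nH]ccc2c1",               # indole
    "c1ccc2ncccc2c1",                 # quinoline
    "c1cncnc1",                       # pyrimidine
    "c1c[nH]cn1",                     # imidazole
    "C1CCNCC1",                       # piperidine
    "C1CNCCN1",                       # piperazine
    "C1COCCN1",                       # morpholine
    "C1CCOC1",                        # tetrahydrofuran
    "C1CCOCC1",                       # tetrahydropyran
    "c1cnccn1",                       # pyrazine
    "O=c1ccoc2ccccc12",               # chromone
    "O=c1cc(-c2ccccc2)oc2ccccc12",    # flavone
    "c1ccc(-c2ccccc2)cc1",            # biphenyl
    "C(c1ccccc1)c1ccccc1",            # diphenylmethane
    "c1ccc2occc2c1",                  # benzofuran
    "c1ccc2sccc2c1",                  # benzothiophene
    "C1CC1",                          # cyclopropane
    "C1CCC1")                         # cyclobutane
}

# Decoration slots: carbon atoms with spare valence in the kekulized
# connection table, listed once per free unit of valence.
.decoration_slots <- function(mol) {
  free <- pmax(0, 4 - .bond_order_sums(mol) - abs(mol$chg))
  free[mol$elem != "C"] <- 0
  rep(seq_len(mol$n), times = free)
}

# Link two templates with a single C-C bond (first free-valence carbon of
# each), extending the template set with fused/linked ring systems.
.link_templates <- function(mol_a, mol_b) {
  sa <- .decoration_slots(mol_a)
  sb <- .decoration_slots(mol_b)
  if (!length(sa) || !length(sb)) return(NULL)
  elem <- c(mol_a$elem, mol_b$elem)
  chg <- c(mol_a$chg, mol_b$chg)
  off <- mol_a$n
  bonds_b <- mol_b$bonds
  if (nrow(bonds_b)) bonds_b[, 1:2] <- bonds_b[, 1:2] + off
  bonds <- rbind(mol_a$bonds, bonds_b,
                 c(sa[1], sb[1] + off, 1L))
  list(elem = elem, chg = chg, bonds = bonds, n = length(elem))
}

# Deterministic largest-remainder apportionment of n compounds over k
# scaffolds with Zipf weights i^(-s); every scaffold receives at least
# one compound, the rest follow the quotas exactly.
#' Scaffold-size allocation
#'
#' Deterministic largest-remainder apportionment of \code{n} compounds
#' over \code{k} scaffolds with Zipf weights \eqn{i^{-s}}. Counts are
#' assigned, not sampled, so the empirical scaffold distribution of a
#' generated library matches the request exactly.
#'
#' @param n total compounds.
#' @param k number of scaffolds.
#' @param concentration Zipf exponent \code{s} (0 = uniform).
#' @return integer vector of length \code{k}, non-increasing, summing to
#'   \code{n}, all entries >= 1.
#' @export
scaffold_allocation <- function(n, k, concentration = 1) {
  stopifnot(n >= k, k >= 1)
  w <- seq_len(k)^(-concentration)
  w <- w / sum(w)
  extra <- n - k
  quota <- extra * w
  counts <- floor(quota)
  rem <- extra - sum(counts)
  if (rem > 0) {
    ord <- order(quota - counts, seq_len(k), decreasing = c(TRUE, FALSE),
                 method = "radix")
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts + 1L)
}

#' Generate a synthetic compound library
#'
#' Builds exactly \code{n_compounds} valid molecules by decorating
#' \code{n_scaffolds} ring-system templates (an internal set of 26,
#' extended with linked-ring variants when more are needed) with small
#' inert substituents: methyl, hydroxyl, fluoro, methoxy. Substituents
#' attach by single bonds at ring carbons, so Bemis-Murcko extraction on
#' the output returns the template. Scaffold sizes follow
#' [scaffold_allocation()]; each compound's activity profile is its
#' scaffold's base profile (i.i.d. Bernoulli bits at
#' \code{base_profile_density}) with independent per-bit flips at
#' \code{noise_rate}. A single seed drives two derived RNG streams, one
#' for structures and one for profiles.
#'
#' @param spec a [synthetic_spec()].
#' @return A [compound_library()]; the \code{compounds} table carries a
#'   \code{scaffold_index} column with the generator's ground-truth
#'   scaffold assignment.
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)

  set.seed(spec$seed)
  streams <- sample.int(.Machine$integer.max - 1L, 2)

  base <- lapply(.ring_templates(), .smiles_to_mol)
  mols <- base
  if (spec$n_scaffolds > length(mols)) {
    pairs <- utils::combn(length(base), 2)
    for (p in seq_len(ncol(pairs))) {
      if (length(mols) >= spec$n_scaffolds) break
      linked <- .link_templates(base[[pairs[1, p]]], base[[pairs[2, p]]])
      if (!is.null(linked)) mols <- c(mols, list(linked))
    }
    if (spec$n_scaffolds > length(mols)) {
      stop("capacity error: only ", length(mols),
           " distinct scaffold templates available, ", spec$n_scaffolds,
           " requested")
    }
  }
  mols <- mols[seq_len(spec$n_scaffolds)]
  counts <- scaffold_allocation(spec$n_compounds, spec$n_scaffolds,
                                spec$scaffold_concentration)

  # structure stream: substituent positions and types
  set.seed(streams[1])
  subst <- list(methyl = list(elem = "C", bonds = 1L),
                hydroxyl = list(elem = "O", bonds = 1L),
                fluoro = list(elem = "F", bonds = 1L),
                methoxy = list(elem = c("O", "C"), bonds = c(1L, 2L)))
  smiles <- character(spec$n_compounds)
  scaffold_index <- integer(spec$n_compounds)
  idx <- 0L
  for (m in seq_len(spec$n_scaffolds)) {
    tmpl <- mols[[m]]
    slots <- .decoration_slots(tmpl)
    for (k in seq_len(counts[m])) {
      idx <- idx + 1L
      scaffold_index[idx] <- m
      n_sub <- if (length(slots)) 1L + (k - 1L) %% min(3L, length(slots)) else 0L
      elem <- tmpl$elem; chg <- tmpl$chg; bonds <- tmpl$bonds
      pos <- if (n_sub) sample(seq_along(slots), n_sub) else integer(0)
      for (p in slots[pos]) {
        s <- subst[[sample.int(length(subst), 1)]]
        at0 <- length(elem)
        elem <- c(elem, s$elem)
        chg <- c(chg, integer(length(s$elem)))
        anchor <- c(p, at0 + seq_along(s$elem))  # chain attachment
        for (q in seq_along(s$elem)) {
          bonds <- rbind(bonds, c(anchor[s$bonds[q]], at0 + q, 1L))
        }
      }
      smi <- .mol_to_smiles(list(elem = elem, chg = chg, bonds = bonds,
                                 n = length(elem)))
      if (!nzchar(smi)) stop("internal error: decoration produced invalid molecule")
      smiles[idx] <- smi
    }
  }

  # profile stream: scaffold base profiles, then per-compound bit flips
  set.seed(streams[2])
  base_prof <- matrix(stats::rbinom(spec$n_scaffolds * spec$n_targets, 1,
                                    spec$base_profile_density),
                      nrow = spec$n_scaffolds)
  # flips by thresholding shared uniforms: same seed, larger noise_rate
  # => superset of flipped bits (common random numbers across sweeps)
  flips <- matrix(as.integer(stats::runif(spec$n_compounds * spec$n_targets) <
                               spec$noise_rate),
                  nrow = spec$n_compounds)
  profile <- (base_prof[scaffold_index, , drop = FALSE] + flips) %% 2L
  storage.mode(profile) <- "integer"

  panel <- if (spec$n_targets == 46) default_target_panel() else {
    target_panel(sprintf("T%02d", seq_len(spec$n_targets)),
                 rep("eraser", spec$n_targets))
  }
  compounds <- data.frame(
    compound_id = seq_len(spec$n_compounds),
    name = sprintf("synthetic_%03d", seq_len(spec$n_compounds)),
    smiles = smiles,
    inchi = NA_character_, inchikey = NA_character_,
    food_sources = NA_character_, foodb_id = NA_character_,
    coconut_id = NA_character_, doi = NA_character_,
    scaffold_index = scaffold_index,
    stringsAsFactors = FALSE
  )
  compound_library(compounds, profile, general = NULL, panel = panel,
                   provenance = sprintf("synthetic(seed=%d)", spec$seed))
}

#' Expected activity-profile similarity under the generative model
#'
#' Exact expectation of the Jaccard similarity between two generated
#' profiles. Per bit, the joint law of the two compounds' bits follows
#' from the shared (same scaffold) or independent (different scaffolds)
#' base bit and the two independent flips; across the \code{n_targets}
#' i.i.d. bits the (both-1, exactly-one-1) counts are multinomial, and
#' the expectation of intersection/union is summed over that multinomial
#' exactly. The expectation is conditional on the pair being defined
#' (non-empty union): an all-zero/all-zero pair has no Jaccard value
#' under the model, mirroring the \code{undefined_similarity} flag that
#' the library attaches to such pairs. With \code{noise_rate = 0} the
#' same-scaffold expectation is therefore exactly 1.
#'
#' @param spec a [synthetic_spec()].
#' @param same_scaffold do the two compounds share a scaffold?
#' @return expected Jaccard similarity in [0, 1].
#' @export
expected_profile_similarity <- function(spec, same_scaffold = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  d <- spec$base_profile_density
  e <- spec$noise_rate
  if (same_scaffold) {
    p11 <- d * (1 - e)^2 + (1 - d) * e^2
    p10 <- e * (1 - e)             # one copy flipped relative to the base
  } else {
    m <- d * (1 - e) + (1 - d) * e # marginal bit probability
    p11 <- m^2
    p10 <- m * (1 - m)
  }
  pd <- 2 * p10                    # exactly one of the two bits set
  n <- spec$n_targets
  if (p11 >= 1) return(1)          # degenerate: every bit is 1 in both
  if (p11 + pd == 0) {
    warning("profiles are almost surely empty; similarity undefined",
            call. = FALSE)
    return(NaN)
  }
  total <- 0
  for (a in 0:n) {
    pa <- stats::dbinom(a, n, p11)
    if (pa == 0) next
    for (b in 0:(n - a)) {
      if (a + b == 0) next         # empty union: excluded by conditioning
      pb <- stats::dbinom(b, n - a, pd / (1 - p11))
      total <- total + pa * pb * a / (a + b)
    }
  }
  total / (1 - (1 - p11 - pd)^n)   # condition on a defined pair
}

#' Monte-Carlo profile-pair similarity under the generative model
#'
#' Simulates profile pairs directly from the generative model (no
#' molecule construction) and returns their Jaccard similarities; used
#' to check the generator and [expected_profile_similarity()] against
#' each other.
#'
#' @param spec a [synthetic_spec()].
#' @param same_scaffold share a base profile?
#' @param n_pairs number of simulated pairs.
#' @param seed RNG seed.
#' @return numeric vector of \code{n_pairs} similarities; \code{NA}
#'   marks undefined pairs (both profiles empty), so a \code{na.rm}
#'   mean estimates the conditional expectation of
#'   [expected_profile_similarity()].
#' @export
simulate_profile_pairs <- function(spec, same_scaffold = TRUE,
                                   n_pairs = 10000, seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  n <- spec$n_targets
  vapply(seq_len(n_pairs), function(i) {
    b1 <- stats::rbinom(n, 1, spec$base_profile_density)
    b2 <- if (same_scaffold) b1 else stats::rbinom(n, 1, spec$base_profile_density)
    x <- (b1 + stats::rbinom(n, 1, spec$noise_rate)) %% 2
    y <- (b2 + stats::rbinom(n, 1, spec$noise_rate)) %% 2
    if (sum(x | y) == 0) NA_real_ else tanimoto(x, y)
  }, numeric(1))
}
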