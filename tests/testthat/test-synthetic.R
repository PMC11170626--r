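# exhaustive-enumeration oracle for the expected profile similarity:
# sums Jaccard over every (base, flip, flip) combination, weighted by
# its probability under the generative model, conditioning on pairs
# with a non-empty union (undefined pairs carry no similarity)
enum_expected_similarity <- function(n, density, eps, same_scaffold) {
  bits <- expand.grid(rep(list(0:1), n))
  pvec <- function(v, p) prod(ifelse(v == 1, p, 1 - p))
  total <- 0
  mass <- 0
  for (i in seq_len(nrow(bits))) {
    b1 <- as.integer(bits[i, ])
    pb1 <- pvec(b1, density)
    b2set <- if (same_scaffold) i else seq_len(nrow(bits))
    for (j in b2set) {
      b2 <- as.integer(bits[j, ])
      pb2 <- if (same_scaffold) 1 else pvec(b2, density)
      for (k in seq_len(nrow(bits))) {
        f1 <- as.integer(bits[k, ])
        for (l in seq_len(nrow(bits))) {
          f2 <- as.integer(bits[l, ])
          p <- pb1 * pb2 * pvec(f1, eps) * pvec(f2, eps)
          if (p == 0) next
          x <- (b1 + f1) %% 2; y <- (b2 + f2) %% 2
          u <- sum(x | y)
          if (u > 0) { total <- total + p * sum(x & y) / u; mass <- mass + p }
        }
      }
    }
  }
  total / mass
}

test_that("generation is a pure function of the seed", {
  spec <- synthetic_spec(20, 5, seed = 7)
  a <- generate_library(spec)
  b <- generate_library(spec)
  expect_identical(a$compounds, b$compounds)
  expect_identical(a$profile, b$profile)
  c <- generate_library(synthetic_spec(20, 5, seed = 8))
  expect_false(identical(a$profile, c$profile))
})

test_that("every generated SMILES is valid and already canonical", {
  lib <- test_lib()
  smi <- lib$compounds$smiles
  expect_true(all(is_valid_smiles(smi)))
  expect_identical(canonicalize_smiles(smi), smi)
})

test_that("scaffold extraction on the output recovers the requested scaffolds", {
  # maximally diverse: one scaffold per compound
  lib <- generate_library(synthetic_spec(12, 12, scaffold_concentration = 0,
                                         seed = 3))
  sc <- bemis_murcko(lib$compounds$smiles)
  expect_equal(length(unique(sc[sc != ""])), 12)

  # general case: extracted scaffold identity matches the ground-truth index
  lib2 <- test_lib()
  sc2 <- bemis_murcko(lib2$compounds$smiles)
  expect_equal(length(unique(sc2)), 6)
  expect_true(all(tapply(sc2, lib2$compounds$scaffold_index,
                         function(x) length(unique(x))) == 1))
})

test_that("scaffold counts are assigned, not sampled, and match the request", {
  counts <- scaffold_allocation(100, 7, concentration = 1.2)
  expect_equal(sum(counts), 100)
  expect_true(all(counts >= 1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(scaffold_allocation(50, 50, 0), rep(1L, 50))
  expect_equal(scaffold_allocation(40, 4, 0), rep(10L, 4))

  lib <- generate_library(synthetic_spec(60, 5, scaffold_concentration = 1.5,
                                         seed = 2))
  expect_equal(as.integer(table(lib$compounds$scaffold_index)),
               scaffold_allocation(60, 5, 1.5))
})

test_that("capacity error when more scaffolds than templates are requested", {
  expect_error(generate_library(synthetic_spec(400, 400, seed = 1)),
               "capacity")
})

test_that("zero flip noise makes same-scaffold profiles identical", {
  lib <- generate_library(synthetic_spec(24, 4, noise_rate = 0, seed = 5))
  for (m in unique(lib$compounds$scaffold_index)) {
    rows <- lib$profile[lib$compounds$scaffold_index == m, , drop = FALSE]
    expect_equal(nrow(unique(rows)), 1)
    if (sum(rows[1, ]) > 0) {
      expect_equal(profile_similarity(rows[1, ], rows[nrow(rows), ]), 1.0)
    }
  }
  expect_equal(expected_profile_similarity(
    synthetic_spec(10, 2, noise_rate = 0, base_profile_density = 0.3,
                   seed = 1), same_scaffold = TRUE), 1.0)
})

test_that("closed-form expected similarity matches exhaustive enumeration", {
  for (case in list(list(d = 0, e = 0.2, same = TRUE),
                    list(d = 0.4, e = 0.1, same = TRUE),
                    list(d = 0.4, e = 0.1, same = FALSE))) {
    spec <- synthetic_spec(10, 2, n_targets = 4,
                           base_profile_density = case$d,
                           noise_rate = case$e, seed = 1)
    expect_equal(expected_profile_similarity(spec, case$same),
                 enum_expected_similarity(4, case$d, case$e, case$same),
                 tolerance = 1e-10)
  }
})

test_that("Monte-Carlo profile similarity agrees with the closed form", {
  spec <- synthetic_spec(10, 2, base_profile_density = 0.2, noise_rate = 0.1,
                         seed = 1)
  sims <- simulate_profile_pairs(spec, same_scaffold = TRUE,
                                 n_pairs = 4000, seed = 42)
  sims <- sims[!is.na(sims)]
  se <- stats::sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - expected_profile_similarity(spec, TRUE)), 3 * se)
})

test_that("same-scaffold profile similarity decays with the noise rate", {
  means <- vapply(c(0, 0.1, 0.3, 0.5), function(eps) {
    lib <- generate_library(synthetic_spec(24, 4, noise_rate = eps, seed = 9))
    idx <- lib$compounds$scaffold_index
    sims <- c()
    for (m in unique(idx)) {
      rows <- which(idx == m)
      for (a in rows) for (b in rows) if (a < b) {
        if (sum(lib$profile[a, ] | lib$profile[b, ]) == 0) next  # undefined
        sims <- c(sims, profile_similarity(lib$profile[a, ], lib$profile[b, ]))
      }
    }
    mean(sims)
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
  expect_equal(means[1], 1.0)
})
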