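test_that("scaffold extraction removes side chains and keeps frameworks", {
  expect_equal(bemis_murcko("Cc1ccccc1"), canonicalize_smiles("c1ccccc1"))
  expect_equal(bemis_murcko("CCCCCC"), "")
  # acetyl side chain goes entirely, even though it carries a double bond
  expect_equal(bemis_murcko("CC(=O)c1ccccc1"), canonicalize_smiles("c1ccccc1"))
  # exocyclic carbonyl on a ring atom stays: apigenin -> flavone
  apigenin <- "c1cc(ccc1-c1cc(=O)c2c(o1)cc(cc2O)O)O"
  flavone <- "O=c1cc(-c2ccccc2)oc2ccccc12"
  expect_equal(bemis_murcko(apigenin), canonicalize_smiles(flavone))
  # linkers between rings survive, with their multiply-bonded decorations
  expect_equal(bemis_murcko("Cc1ccc(C(=O)Nc2ccccc2)cc1"),
               canonicalize_smiles("O=C(c1ccccc1)Nc1ccccc1"))
})

test_that("scaffold extraction is invariant to the input SMILES form", {
  forms <- c("C1=CC=CC=C1CC(C)O", "OC(C)Cc1ccccc1")
  expect_equal(bemis_murcko(forms[1]), bemis_murcko(forms[2]))
  can <- canonicalize_smiles(forms[1])
  expect_equal(bemis_murcko(can), bemis_murcko(forms[1]))
})

test_that("scaffold table counts, fractions and ordering are consistent", {
  lib <- test_lib()
  tab <- scaffold_table(lib)
  expect_equal(sum(tab$count), length(lib) - attr(tab, "n_acyclic"))
  expect_equal(sum(tab$fraction), 1.0)
  expect_true(all(diff(tab$count) <= 0))
  # ties broken by ascending scaffold SMILES
  ties <- tab$scaffold[tab$count == tab$count[duplicated(tab$count)][1]]
  expect_equal(ties, sort(ties))
  expect_equal(attr(tab, "n_unique_scaffolds"), 6)
  expect_equal(top_k_coverage(tab, 2),
               sum(tab$fraction[1:2]))

  # all decorated benzenes -> one scaffold covering everything
  lib1 <- generate_library(synthetic_spec(5, 1, seed = 4))
  tab1 <- scaffold_table(lib1)
  expect_equal(nrow(tab1), 1)
  expect_equal(tab1$fraction, 1.0)
})

test_that("denominator convention splits ring-bearing from all compounds", {
  lib <- test_lib()
  co <- lib$compounds
  co <- rbind(co, transform(co[1, ], compound_id = 999, smiles = "CCCC"))
  lib2 <- compound_library(co, rbind(lib$profile, lib$profile[1, ]),
                           panel = lib$panel)
  rb <- scaffold_table(lib2, "ring_bearing_only")
  ac <- scaffold_table(lib2, "all_compounds")
  expect_equal(attr(rb, "n_acyclic"), 1)
  expect_equal(sum(rb$fraction), 1.0)
  expect_equal(sum(ac$fraction), nrow(rb) * 0 + sum(ac$count) / length(lib2))
  expect_true(all(ac$fraction < rb$fraction))
})

test_that("CSR curve matches trapezoid arithmetic and stated conventions", {
  mk <- function(counts) {
    structure(data.frame(scaffold = paste0("s", seq_along(counts)),
                         count = as.integer(sort(counts, decreasing = TRUE)),
                         fraction = counts / sum(counts)),
              n_unique_scaffolds = length(counts), n_compounds = sum(counts),
              n_acyclic = 0L, denominator = "ring_bearing_only",
              class = c("scaffold_table", "data.frame"))
  }
  cv <- csr_curve(mk(c(4, 1)))
  expect_equal(cv$points$scaffold_fraction, c(0, 0.5, 1))
  expect_equal(cv$points$compound_fraction, c(0, 0.8, 1))
  expect_equal(cv$auc, 0.65)

  # every compound its own scaffold -> the diagonal
  expect_equal(csr_curve(mk(rep(1, 20)))$auc, 0.5)
  # single scaffold -> 1.0 by the limiting convention
  expect_equal(csr_curve(mk(7))$auc, 1.0)

  set.seed(5)
  for (i in 1:25) {
    counts <- sample(1:9, sample(2:8, 1), replace = TRUE)
    cv <- csr_curve(mk(counts))
    expect_equal(cv$auc, csr_auc_oracle(counts))
    expect_gte(cv$auc, 0.5)
    expect_lte(cv$auc, 1.0)
    expect_true(all(diff(cv$points$compound_fraction) >= 0))
    # the diagonal (AUC exactly 0.5) arises iff all scaffold sizes are equal
    if (length(unique(counts)) == 1) expect_equal(cv$auc, 0.5)
    else expect_gt(cv$auc, 0.5)
  }
})

test_that("concentrating compounds onto larger scaffolds never decreases AUC", {
  # majorization step at fixed scaffold count: move one compound from a
  # smaller scaffold to a larger one (both staying non-empty)
  mk <- function(counts) {
    structure(data.frame(scaffold = paste0("s", seq_along(counts)),
                         count = as.integer(sort(counts, decreasing = TRUE)),
                         fraction = counts / sum(counts)),
              n_unique_scaffolds = length(counts), n_compounds = sum(counts),
              n_acyclic = 0L, denominator = "ring_bearing_only",
              class = c("scaffold_table", "data.frame"))
  }
  set.seed(6)
  for (i in 1:25) {
    counts <- sort(sample(2:9, sample(3:8, 1), replace = TRUE),
                   decreasing = TRUE)
    auc0 <- csr_auc_oracle(counts)
    j <- length(counts)                    # smallest, count >= 2
    shifted <- counts
    shifted[1] <- shifted[1] + 1L
    shifted[j] <- shifted[j] - 1L
    expect_gte(csr_curve(mk(shifted))$auc, auc0 - 1e-12)
  }
})
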