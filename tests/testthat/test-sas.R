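# build a bare pairs table without touching molecules, so threshold and
# region logic can be exercised on exact hand-made values
mk_pairs <- function(structural, activity, kind = "MACCS_166") {
  df <- data.frame(id_i = as.character(seq_along(structural)),
                   id_j = as.character(seq_along(structural) + 1000),
                   stringsAsFactors = FALSE)
  df[[kind]] <- structural
  df$activity_similarity <- activity
  df$activity_undefined <- FALSE
  df
}

test_that("structural threshold is mean plus two sample SDs, capped at 1", {
  v <- c(0.2, 0.2, 0.2, 0.2, 0.8)
  thr <- sas_thresholds(v)
  expect_equal(unname(thr$mean), 0.32)
  expect_equal(unname(thr$sd), sqrt(0.072), tolerance = 1e-12)
  expect_equal(unname(thr$structural), 0.32 + 2 * sqrt(0.072),
               tolerance = 1e-12)

  expect_error(sas_thresholds(rep(0.4, 10)), "degenerate")

  expect_warning(thr2 <- sas_thresholds(c(0, 1)), "capped")
  expect_equal(unname(thr2$structural), 1.0)
})

test_that("region assignment follows the strict/inclusive boundary rules", {
  pairs <- mk_pairs(structural = c(0.95, 0.95, 0.10, 0.86),
                    activity = c(1.0, 0.05, 0.0, 0.5))
  thr <- sas_thresholds(c(rep(0.2, 10), 0.9))  # threshold 0.86... > 0.86
  cls <- classify_sas(pairs, structure(list(
    structural = c(MACCS_166 = 0.86), activity = 0.1,
    mean = c(MACCS_166 = NA), sd = c(MACCS_166 = NA)),
    class = "sas_thresholds"))
  expect_equal(as.character(cls$region_MACCS_166), c("II", "IV", "III", "I"))
  # structural exactly at threshold is NOT "greater": pair 4 is region I
})

test_that("regions partition all pairs for every fingerprint", {
  pairs <- test_pairs()
  thr <- sas_thresholds(pairs)
  cls <- classify_sas(pairs, thr)
  counts <- sas_region_counts(cls)
  n <- length(test_lib())
  expect_true(all(rowSums(counts) == n * (n - 1) / 2))
})

test_that("raising the activity threshold only moves pairs II->IV and I->III", {
  set.seed(12)
  pairs <- mk_pairs(structural = runif(400), activity = runif(400))
  thr_fun <- function(a) {
    structure(list(structural = c(MACCS_166 = 0.7), activity = a,
                   mean = c(MACCS_166 = NA), sd = c(MACCS_166 = NA)),
              class = "sas_thresholds")
  }
  lo <- classify_sas(pairs, thr_fun(0.1))$region_MACCS_166
  hi <- classify_sas(pairs, thr_fun(0.4))$region_MACCS_166
  moved <- which(lo != hi)
  expect_true(all(paste(lo[moved], hi[moved]) %in% c("II IV", "I III")))
  expect_equal(length(lo), 400)
  expect_equal(sum(table(hi)), 400)
})

test_that("consensus requires the region under every fingerprint", {
  kinds <- fingerprint_kinds()
  df <- data.frame(id_i = c("1", "2"), id_j = c("9", "8"),
                   stringsAsFactors = FALSE)
  # pair 1: region II under all four; pair 2: II under three, I under one
  for (k in kinds) df[[k]] <- c(0.95, 0.95)
  df[[kinds[4]]][2] <- 0.10
  df$activity_similarity <- c(0.9, 0.9)
  df$activity_undefined <- FALSE
  thr <- structure(list(
    structural = stats::setNames(rep(0.8, 4), kinds), activity = 0.1,
    mean = stats::setNames(rep(NA_real_, 4), kinds),
    sd = stats::setNames(rep(NA_real_, 4), kinds)),
    class = "sas_thresholds")
  cls <- classify_sas(df, thr)
  cons <- consensus_pairs(cls, "II")
  expect_equal(cons$id_i, "1")
  expect_equal(nrow(consensus_pairs(cls, "IV")), 0)
})

test_that("consensus pairs sort by mean structural similarity", {
  pairs <- test_pairs()
  cls <- classify_sas(pairs, sas_thresholds(pairs))
  cons <- consensus_pairs(cls, "II")
  if (nrow(cons) >= 2) {
    expect_true(all(diff(cons$mean_structural_similarity) <= 0))
  }
  # every consensus-II pair is II under each fingerprint individually
  for (k in fingerprint_kinds()) {
    expect_true(all(cons[[paste0("region_", k)]] == "II"))
  }
})

test_that("sas_points exports one labelled point per pair", {
  pairs <- test_pairs()
  cls <- classify_sas(pairs, sas_thresholds(pairs))
  pts <- sas_points(cls, "ECFP_r2")
  expect_equal(nrow(pts), nrow(pairs))
  expect_true(all(levels(pts$region) == c("I", "II", "III", "IV")))
  p <- tempfile(fileext = ".html")
  write_sas_html(pts, p)
  expect_true(file.exists(p))
  expect_gt(length(grep("circle", readLines(p))), 0)
})

test_that("without noise, same-scaffold pairs cannot be consensus cliffs", {
  lib <- generate_library(synthetic_spec(20, 4, noise_rate = 0, seed = 13))
  pairs <- pairwise_similarity(lib)
  cls <- classify_sas(pairs, sas_thresholds(pairs))
  cons4 <- consensus_pairs(cls, "IV")
  idx <- lib$compounds$scaffold_index
  same <- idx[match(cons4$id_i, lib$compounds$compound_id)] ==
    idx[match(cons4$id_j, lib$compounds$compound_id)]
  expect_equal(sum(same), 0)
})
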