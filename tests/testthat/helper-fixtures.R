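# Shared fixtures, built once per test run. Libraries are small so the
# OpenBabel round-trips stay cheap.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_cache)) assign(name, build(), .fixture_cache)
  get(name, .fixture_cache)
}

# 30 compounds over 6 scaffolds, moderate profile noise
test_lib <- function() {
  fixture("lib30", function() generate_library(synthetic_spec(30, 6, seed = 7)))
}

test_pairs <- function() {
  fixture("pairs30", function() pairwise_similarity(test_lib()))
}

# a tiny database CSV in the curated dialect, written to a temp file
write_fixture_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- c("Name", "SMILES", "InChI", "InChIKey", "Food source",
              "FooDB ID", "COCONUT ID", "DOI",
              "DNMT1", "HDAC1", "HDAC6", "DNMT family")
  writeLines(c(paste(header, collapse = ","),
               vapply(rows, paste, character(1), collapse = ",")), path)
  path
}

random_bits <- function(n, p = 0.3) as.integer(stats::runif(n) < p)

# independent set-operation oracle for Jaccard similarity
jaccard_oracle <- function(a, b) {
  ia <- which(a == 1); ib <- which(b == 1)
  u <- union(ia, ib)
  if (length(u) == 0) return(0)
  length(intersect(ia, ib)) / length(u)
}

# independent trapezoid integration of a CSR curve from raw counts
csr_auc_oracle <- function(counts) {
  counts <- sort(counts, decreasing = TRUE)
  m <- length(counts)
  x <- c(0, seq_len(m) / m)
  y <- c(0, cumsum(counts) / sum(counts))
  a <- 0
  for (i in seq_len(m)) a <- a + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  a
}
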