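---
title: "Methods: diversity and structure-activity landscapes of epigenetically annotated chemical libraries"
author: "epichem"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epichem)
```

# The problem

Food chemicals and other natural products are increasingly annotated with
*epigenetic* activity: reported inhibition or modulation of the enzymes
that write (DNA methyltransferases, histone acetyltransferases, EZH2,
PRMT1), erase (HDACs, sirtuins, lysine demethylases) or read (BET/BRD4
bromodomains) chemical marks on DNA and histones. A curated library of
such compounds is only useful if one can ask quantitative questions of
it: how structurally diverse is it, which targets dominate the
annotations, and — most importantly for prioritizing experiments — which
pairs of compounds are structurally almost identical yet carry very
different activity profiles, suggesting untested activities.

`epichem` implements that analysis pipeline for any compound library
annotated with binary multi-target activity profiles, plus a synthetic
library generator so the entire pipeline is exercised and validated
without any external data.

# The data model

A `compound_library` holds one record per compound (canonical SMILES,
name, provenance metadata, cross-reference IDs with an explicit
"absent" state) together with:

* a **specific profile**: a binary vector over the `target_panel`
  (default: 46 epigenetic targets — 8 writers, 37 erasers, 1 reader),
  where 1 means *reported* activity. A 0 means "no report", not
  "inactive" — this asymmetry drives the pseudo-cliff interpretation
  below; for the same reason empty activity cells in an input CSV are
  read as 0 but counted separately in the data-quality summary.
* **general flags**: family-level annotations (e.g. "DNMT family") for
  compounds whose literature reports never resolve the protein. These
  are deliberately excluded from profile similarity and the target
  statistics, and reported as a separate population, because mixing
  family- and protein-resolution bits would make Jaccard similarities
  incomparable across pairs.

A compound with neither specific nor general bits is retained but
flagged `profile_incomplete`.

# Structural similarity

Four fingerprints are computed per compound: MACCS keys (166
substructure keys), extended-connectivity fingerprints of radius 2 and
3, and a path-based topological fingerprint (linear fragments up to 7
bonds). Each fingerprint is used at its backend's native width (166,
4096, 4096 and 1024 bits); at library sizes in the hundreds, hash
collisions are negligible at these widths, and re-hashing to a common
width would only add collisions.

All similarity in the package — structural and activity alike — is the
Jaccard–Tanimoto coefficient

$$T(a, b) = \frac{|a \cap b|}{|a \cup b|},$$

computed by one shared implementation. Two all-zero vectors have no
defined Jaccard value; the package returns 0 with an
`undefined_similarity` flag. Zero is the conservative choice for cliff
detection (an undefined pair can never look "similar in activity"), and
the flag lets every downstream table report such pairs separately.

For $n$ compounds the pair table has exactly $n(n-1)/2$ rows
(self-comparisons carry no information and are excluded; at $n = 187$
that is 17,391 pairs, 17,578 with self-pairs).

# Scaffold diversity

The **Bemis–Murcko scaffold** of a molecule is its ring systems plus
the linkers connecting them, side chains removed. The package extracts
it by graph pruning on the kekulized connection table: terminal atoms
are deleted iteratively until a fixpoint (what survives is exactly the
atoms on cycles or on paths between cycles), then atoms attached to
that framework by double or triple bonds are restored — so a flavone
keeps its exocyclic carbonyl while an acetyl side chain is removed
entirely. Acyclic molecules have an empty scaffold; they are counted,
excluded from `n_unique_scaffolds`, and by default excluded from the
frequency denominator (`ring_bearing_only`), a convention that is
configurable and always recorded in the table.

The **cyclic system recovery (CSR) curve** sorts scaffolds by
descending frequency (ties broken by ascending canonical SMILES, so
curves are deterministic) and plots the cumulative fraction of
compounds recovered against the fraction of scaffolds used. Its
trapezoidal AUC summarizes diversity:

* every compound its own scaffold → the diagonal, AUC $= 0.5$;
* a single dominant scaffold → AUC $\to 1$. The degenerate one-scaffold
  table is *defined* as AUC $= 1.0$ (the limiting vertical-line
  convention), although a literal trapezoid over its two points would
  give 0.5.

Two cautions about common intuitions, both verified in the test suite
against a brute-force integrator: the AUC equals 0.5 exactly whenever
all scaffold counts are *equal* (not only when all are 1), and merging
two scaffolds can *decrease* the AUC because it also rescales the
scaffold axis (counts $\{9,1,1\} \to \{9,2\}$ drops the AUC from 0.742
to 0.659). The monotone statement that does hold, and is tested, is the
fixed-$M$ majorization form: moving one compound from a smaller to a
larger scaffold never decreases the AUC.

# Activity-profile statistics

Target frequencies are column sums of the binary activity matrix
(ties keep panel order); single-target compounds are rows with margin
exactly 1; the multi-target ranking sorts rows by margin with
alphabetical tie-breaks. These conventions make every table
deterministic. The populations partition the library:
single-target + multi-target + zero-profile = $n$.

# SAS maps and pseudo-activity cliffs

Each pair of compounds is a point (structural similarity, activity
similarity). Per fingerprint, the plane is cut at:

* a **structural threshold** = mean + 2 × sample SD (always the $n-1$
  estimator) of that fingerprint's pairwise distribution, computed over
  the without-self pairs (self-pairs are not comparisons and would
  inflate the mean); capped at 1.0 with a warning when the distribution
  is narrow enough to push the cut above the similarity domain; an
  error if the distribution is degenerate (zero variance).
* an **activity threshold** fixed at 0.1.

Boundary handling is strict-greater on structure for regions II and IV,
strict-greater on activity for II, and ≤ on activity for IV. Region II
pairs (similar structure, similar profile) represent smooth
structure–activity relationships; region IV pairs (similar structure,
discordant profile) are **pseudo-activity cliffs** — "pseudo" because a
missing annotation may mean untested rather than inactive, which is why
pairs involving a flagged all-zero profile are classified normally but
carried in a separate annex. Requiring a pair to fall in the same
region under *all four* fingerprints (the consensus rule) filters out
artifacts of any single fingerprint's dictionary or hashing.

Raising the activity threshold can only move pairs II→IV and I→III;
this monotone reclassification, and the fact that the four regions
partition all $n(n-1)/2$ pairs, are tested as properties.

# Chemical-space embedding

Descriptors are the backend's physicochemical panel (MW, logP, MR,
TPSA, H-bond donors/acceptors, fluorine count) extended with
connection-table counts (heavy atoms, bonds, cyclomatic rings,
heteroatoms, halogens, N/O/S counts, aromatic-atom fraction) — 17
numeric descriptors in total, with the panel size always reported in
the run summary. Columns are z-scored before embedding (heterogeneous
units would otherwise dominate the distances), constant columns are
dropped and logged, and failures are median-imputed with a warning so
row alignment is preserved. When a reference collection is overlaid,
standardization is fitted on the union and a set label is carried into
the output.

The 2-D embedding is an exact $O(n^2)$ t-SNE written for this package:
per-point Gaussian bandwidths found by bisection to the target
perplexity (default 30), symmetrized affinities, early exaggeration
(factor 12 for the first quarter of iterations, at most 100), gradient
descent with momentum (0.5 → 0.8 at iteration 250) and adaptive gains,
1,000 iterations and a fixed default seed of 42. At the few-hundred
compound scale of these libraries the exact algorithm runs in seconds,
and avoiding tree approximations removes a whole class of
non-determinism. Because t-SNE coordinates are not identifiable across
implementations, the embedding is validated by its contract —
bit-identical output for identical input and seed, and preservation of
coarse structure (two well-separated synthetic descriptor clusters stay
separated: k-NN label purity > 0.9, centroid gap exceeding intra-cluster
spread) — not by coordinate reproduction.

# The synthetic library generator

The generator builds libraries in which the ground truth of every
downstream statistic is known:

* **Structures.** `n_scaffolds` templates are taken from an internal
  set of 26 ring systems (benzene through flavone), extended with
  linked-ring variants when more are needed. Compounds are built by
  attaching small inert substituents (methyl, hydroxyl, fluoro,
  methoxy) by single bonds at ring carbons with free valence — which
  guarantees every SMILES is valid and that Bemis–Murcko extraction
  provably recovers the template.
* **Scaffold sizes** follow a *deterministic* largest-remainder
  apportionment of Zipf weights $i^{-s}$ ($s = 0$ uniform), with one
  compound guaranteed per scaffold first so that high concentration
  cannot silently empty tail scaffolds. Counts are assigned, never
  sampled, so the generated distribution matches the request exactly.
* **Profiles.** Each scaffold draws a base profile with i.i.d.
  Bernoulli(density) bits; each compound copies its scaffold's base
  profile with independent per-bit flips at rate $\varepsilon$. One
  global seed derives two independent RNG streams (structures,
  profiles). Flips are realized by thresholding one shared uniform draw
  per compound and bit, so fixed-seed libraries at different
  $\varepsilon$ have nested flip sets (common random numbers), making
  noise sweeps directly comparable.

`expected_profile_similarity()` gives the exact expected Jaccard
similarity of two generated profiles, conditional on the pair being
defined (non-empty union): per bit the joint law of the two bits
follows from the shared or independent base bit and the two flips; the
(both-set, exactly-one-set) counts across bits are multinomial and the
expectation of intersection/union is summed over that law exactly. The
test suite checks this closed form against full enumeration at 4
targets and against Monte-Carlo simulation at 46.

**Choice of the default bit density (0.4).** The closed form exposes a
regime boundary worth knowing about: for two unrelated random binary
vectors the expected Jaccard similarity tends to 1/3 as density
approaches 1/2, so for *sparse* base profiles the same-scaffold
similarity is **not** monotone in the noise rate — it dips and then
rises back toward 1/3 as heavy noise reintroduces chance overlap (at
density 0.15 the expectation over $\varepsilon = 0, 0.1, 0.3, 0.5$ is
1, 0.42, 0.26, 0.33). Monotone decay over that whole range — the
behavior that makes $\varepsilon$ interpretable as a pure
coupling-strength dial — requires density ≥ 0.3. The default is 0.4:
inside the monotone regime with margin, while keeping profiles far from
saturation. This is a property of Jaccard similarity, not of the
implementation; users emulating sparse real-world profiles (a curated
database's density is closer to 0.05) should read $\varepsilon$
against the closed form rather than assuming monotonicity.

**What the generator does and does not emulate.** It reproduces the
structural features the pipeline measures (controlled scaffold
frequencies, valid decorated molecules, scaffold-coupled profiles) but
deliberately not drug-likeness, realistic substituent chemistry,
family-structured activity correlations, or the sparsity of real
literature annotation. Green synthetic tests therefore demonstrate
correctness of the *computations* — counts, curves, thresholds, region
logic, recovery of generator parameters — not that any particular real
library will show smooth SAR or cliffs.

# Problem sizes and numerical choices

The test suite and the analysis scripts run the pipeline at sizes where
every stage is exact and fast: libraries of 20–60 compounds (6 scaffolds
in the shared fixture) for unit and property tests, 10,000 simulated
profile pairs for the Monte-Carlo check, 1,000 random bit-vector pairs
against the brute-force Jaccard oracle, and a 187-compound, 90-scaffold
stand-in library for the analysis scripts, mirroring the scale of the
curated database the package is designed around. The acceptance script
uses a 50-compound maximally diverse library. All randomness flows from
explicit seeds; generation restores the caller's RNG state.

Known limitations: no tautomer/charge standardization beyond
canonicalization (two tautomers of one compound count as two
structures); scaffold extraction assumes the backend's aromaticity
perception; the descriptor panel is compact compared to toolkits that
ship hundreds of descriptors (the embedding contract is unaffected, but
absolute map geometry will differ across descriptor panels); and binary
presence-of-report profiles cannot distinguish "inactive" from
"untested" — the pseudo-cliff annex exists precisely because of that.
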