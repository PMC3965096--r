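---
title: "Deriving non-interacting protein and domain pairs from structural complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving non-interacting protein and domain pairs from structural complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Training and benchmarking protein--protein interaction (PPI) predictors
requires negative examples: pairs of proteins for which there is positive
evidence of *non*-interaction. Random pairing is biased, and absence from
interaction databases is not evidence of absence. Two defensible sources of
negatives exist: (i) solved multi-chain structures, where two proteins sit
in the same biological assembly yet make no physical contact, and (ii) the
literature, where authors explicitly report a failure to detect an
interaction. `nipr` implements the structural derivation end to end, the
set algebra that filters and merges such datasets, and a confidence score
for negated-interaction sentences extracted from text as
predicate-argument structures (PAS).

## The contact rule

Each polymer amino-acid residue is reduced to one representative atom: its
C$\beta$, or C$\alpha$ for glycine (which has no side chain). A residue
missing its C$\beta$ (truncated side chain density) falls back to
C$\alpha$, and the substitution is recorded; a residue with neither atom is
skipped and counted. Among alternate locations the highest-occupancy one
wins, ties broken by altloc label --- a deterministic, conventional choice.

For two chains $A$ and $B$ of a biological unit the decision statistic is

$$ d_{\min}(A, B) \;=\; \min_{i \in A,\, j \in B} \lVert x_i - x_j \rVert, $$

the minimum over all cross-chain representative-atom pairs, and the pair is
called **non-interacting** when

$$ d_{\min}(A, B) > \tau, \qquad \tau = 8\ \text{\AA{} (default)}. $$

The inequality is strict: a pair at exactly $\tau$ is treated as
interacting. Whether the boundary case belongs to the negative set is not
decidable from the rule "more than 8 Å apart"; we resolve it conservatively
for a negative reference set, where a false negative label is the expensive
error.

$d_{\min}$ is computed by a compiled uniform-grid (cell list) search:
points of one chain are binned into cells of uniform side $h$, and each
query point expands Chebyshev shells of cells outward, pruning once
$(k-1)h$ exceeds the best distance found. The search is exact --- the same
minimum as an exhaustive $O(n^2)$ scan, which the test suite verifies
bit-for-bit over hundreds of random geometries. The cell side is floored at
1 Å so that degenerate inputs (single-residue chains, collinear points)
index sanely.

## From chains to proteins and domains

Biological units are consumed **pre-expanded** (PDB `.pdb1`-style files or
mmCIF coordinate blocks); the package does not apply crystal-symmetry
operators. For multi-model files only the first model is read (one
deterministic geometry per unit); waters, ligands and nucleic acids are
excluded, and non-standard amino acids carrying a C$\alpha$/C$\beta$ are
admitted. When the same chain identifier restarts its author numbering
within a file, the segments are treated as distinct assembly copies.

Chains map to protein accessions through a SIFTS-style
(structure, chain) → UniProt table. Consolidation applies two rules:

* **Within a unit**, a protein pair is non-interacting only if *every*
  chain-copy pair realizing it is beyond the threshold. A homodimer copy in
  contact falsifies the pair even if another copy is distant.
* **Across units**, a contact observed anywhere suppresses the pair
  globally. The alternative (per-complex listing) is defensible; we chose
  the conservative reading, since one observed contact is positive evidence
  of interaction and a negative set should not contradict it.

Self pairs (the same accession on both sides) are excluded. Isoform
suffixes (`P12345-2`) are kept verbatim by default because splice variants
can genuinely differ in binding; a collapse option truncates them for
analyses at gene-product level.

Protein pairs expand to Pfam domain pairs as the full cross product of the
two proteins' domain lists ($A_1B_1, A_1B_2, A_2B_1, \dots$), canonicalized
and de-duplicated. Domain self-pairs $(D, D)$ are retained so that known
homodomain interactions can subtract them later; proteins without mapped
domains contribute nothing.

## Set algebra and stringent datasets

All dataset rows are canonical unordered pairs: members stored in
byte-wise lexicographic order so equality ignores orientation, and the
ordering does not depend on the session locale. Stringent datasets are
plain set differences: candidates minus every pair reported as interacting
in a PSI-MI TAB (MITAB 2.5) export (columns 1--2, first `uniprotkb:` token
of each interactor; rows without one are skipped and counted in the default
lenient mode, or abort with a line number in strict mode). Domain-pair
subtraction accepts two-column TSV catalogues of domain--domain contacts
and, through the same expansion machinery, domain pairs derived from a
protein-level MITAB file. Merging reports the union together with the
overlap count, and summaries print integer removal percentages, rounded
half away from zero (so $180/2171 = 8.29\% \to 8$), matching how such
tables are conventionally printed.

## The PAS confidence score

Input records are pre-extracted predicate-argument structures: an agent,
a theme, a relation verb, an optional negation token and the sentence.
Semantic role labelling, named-entity recognition and protein/compound
disambiguation are upstream concerns and out of scope here. A record is a
candidate when it carries a negation *and* its verb belongs to an
interaction lexicon (defaults: *bind*, *co-immunoprecipitate*, *interact*,
*associate*, *complex*, *co-localize*, each with a reliability weight).

No published formula exists for ranking such candidates, only the
qualitative behaviours a useful score must have: long arguments hide nested
structure the parser missed, long sentences are misread more often, some
verb classes are interpreted more reliably than others, unusual negation
words are riskier tags, and an agent identical to its theme usually marks a
parsing mistake --- though such sentences are kept, since they may still
contain a real non-interaction. We therefore define

$$ s \;=\; \frac{w_a e^{-(\ell_{\arg}-1)/\tau_a} + w_s e^{-(\ell_{\text{sent}}-1)/\tau_s} + w_r \rho + w_n \nu}{w_a + w_s + w_r + w_n} \cdot \pi_{\text{same}}, $$

with $\ell_{\arg}$ the longer argument length in tokens,
$\ell_{\text{sent}}$ the sentence length, $\rho \in [0,1]$ the verb weight,
$\nu = 1$ for a common negation token and $0.5$ otherwise, and
$\pi_{\text{same}} = 0.5$ when agent and theme coincide (1 otherwise).
Defaults: equal weights, $\tau_a = 10$ tokens, $\tau_s = 30$ tokens ---
chosen so the subscores span their range over the argument/sentence lengths
seen in abstracts, and all configurable (YAML). The score lies in $[0,1]$,
reaches 1 exactly for a best-case record, and every monotonicity claim
above is enforced by property tests over randomized records. Ranking is a
stable descending sort, so equal-score candidates keep corpus order.

## Synthetic data: what it does and does not emulate

The fixture generators make the whole pipeline testable offline:

* **Structures.** Chains are compact random coils (3.8 Å C$\alpha$
  spacing, mild direction persistence, \~3 Å self-clearance) with
  pseudo-C$\beta$ atoms at 1.53 Å along a local frame; about 10% of
  residues are glycine. Chains are rigidly translated --- initial layout by
  classical MDS on approximate centroid separations, then iterative
  closest-point relaxation --- until every *requested* pair gap matches its
  target within 0.1 Å; unrequested pairs only keep a 25 Å clearance
  (pulling them to an exact value as well would over-determine the layout
  for five or more chains). Non-convergence after seeded restarts raises a
  feasibility error. Units are written as both fixed-column PDB and
  single-block mmCIF, with a ground-truth gap table alongside.
* **Known interactions.** MITAB files hitting an exact, requested number of
  a candidate set's pairs, with swapped orientations and non-protein rows
  mixed in to exercise lenient parsing.
* **PAS corpora.** JSON-lines records with controlled lengths and verbs,
  labelled so that exactly the requested fraction passes the candidate
  filter.

These fixtures exercise geometry, bookkeeping and parsing, not biology:
real assemblies have packed interfaces, crystal-contact artifacts, modified
residues, and chains whose SIFTS mapping is ambiguous --- so passing tests
demonstrate the pipeline's correctness on its stated rules, not the
biological quality of any particular negative set. Likewise the gap targets
used in tests (5--25 Å around the 8 Å threshold) probe the decision
boundary, not the distance distribution of real complexes.

All generators run on a private RNG stream: a fixed seed gives
byte-identical files and the caller's RNG state is untouched.

## Numerical and design notes

* Distances are compared in double precision; the grid search and the
  reference scan accumulate squared differences in the same order, so
  equality in tests is exact, not approximate.
* Problem sizes in the shipped tests --- chains of 10--100 residues, up to
  five chains per unit, candidate sets up to 6532 pairs, PAS suites of 1000
  records --- keep the full suite under a minute while covering every rule
  at the sizes the printed dataset arithmetic requires.
* Percentages are reported as integers; `floor(x + 0.5)` implements
  round-half-away-from-zero explicitly because R's `round()` rounds half to
  even.
* Duplicate rows in any input dataset are de-duplicated silently with a
  logged count; conflicting chain-mapping rows are an error, not a warning,
  because a wrong accession silently corrupts every downstream pair.

## Known limitations

* Assemblies are taken as given; no symmetry expansion, no assembly
  selection logic beyond "every coordinate block in the file".
* Contact detection uses representative atoms only --- no all-atom mode,
  no interface area, no residue-level contact maps.
* The PAS score's weights are calibrated to qualitative behaviour, not
  fitted to annotation outcomes; treat the ranking as triage, not
  probability.
* Live retrieval (SIFTS, UniProt, Pfam, interaction databases) is out of
  scope; all mappings and interaction sets arrive as files.
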