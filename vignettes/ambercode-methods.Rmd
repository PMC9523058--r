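---
title: "Detecting and validating amber stop-codon reassignment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and validating amber stop-codon reassignment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambercode)
```

## The biological problem

Some bacteriophages of the human gut — crAss-like phages prominently —
translate the amber codon TAG as glutamine instead of stop. This is NCBI
translation table 15: identical to the standard bacterial table 11 at 63
of 64 codons, differing only at TAG, and admitting only ATG as an
initiation codon. When such a genome is annotated under the standard code,
every in-frame TAG truncates a gene: coding density collapses, genes
fragment, and downstream annotation degrades. Conversely, predicting under
code 15 "restores" the reading frames. `ambercode` operationalises both
the genomic signal (the coding-density contrast between the two codes) and
its proteomic validation (peptides that could only exist if TAG is read
as Q).

## Gene prediction and the coding-density rule

`predict_orfs()` is a deterministic maximal-ORF caller: in each of the six
reading frames, each stop-to-stop interval contributes one ORF, from its
first (most upstream) start codon to the terminating stop; intervals
running off the contig edge are emitted without a stop and flagged. Codons
containing N translate to X and are never starts or stops. Choosing the
most upstream start maximises ORF length and therefore the
fragmentation-versus-restoration contrast between the codes. The caller
deliberately has no coding statistics or ribosome-binding-site model: its
output is exhaustively checkable against an independent enumeration, which
the test suite does on random sequences.

Two consequences of dropping a scored model had to be compensated
explicitly, and both choices are package defaults rather than hard-coded:

* **Overlap resolution.** A six-frame maximal-ORF scan reports overlapping
  calls in every frame; summing their lengths drives the raw coding
  density far above 1 and, worse, erases the dual-code contrast (chance
  ORFs appear under both codes alike, and code 15's ATG-only start set
  actually *penalises* it in non-coding sequence). `select_genes()`
  therefore emulates the one-gene-per-locus behaviour of production gene
  callers with a greedy rule: rank ORFs by decreasing length and keep each
  unless it overlaps an already-kept gene by more than 60 nt (small
  inter-gene overlaps are normal in phage genomes).
* **Length floor.** A scored caller can afford a 30-residue minimum
  because weak short ORFs are rejected by their score. An unscored caller
  cannot; in AT-rich phage sequence (~35 % GC) chance ORFs of 30–50
  residues are common enough to tile most of a genome. The default
  `min_protein_len = 50` keeps the expected density of chance ORFs to a
  few percent while leaving real genes (the planted genes of the
  simulations are 250–450 residues; real crAss structural genes larger
  still) untouched. Both parameters are configurable.

Coding density follows the literal definition: the sum of gene lengths
divided by contig length, overlaps counted with multiplicity; a per-base
union density is available as a diagnostic (`method = "union"`). The
assignment rule (`assign_code()`) uses the gain in *absolute percentage
points* of density: contigs of 5–100 kb are assigned code 15 when the gain
strictly exceeds 10 points, contigs of ≥ 100 kb when it strictly exceeds
5 points, and contigs under 5 kb are reported `indeterminate` rather than
silently defaulting to the standard code. The absolute reading was a
genuinely open choice (the thresholds could also be read as relative
change); we default to absolute because coding density is itself a
percentage and the size-tiered thresholds suggest additive margins, and we
expose `gain_mode = "relative"` as a switch. Gains are rounded at the 9th
decimal before the strict comparison so that floating-point representation
error cannot carry a mathematically-at-threshold value past a strict
inequality.

## GC skew and replichores

`gc_skew()` computes (G − C)/(G + C) in sliding windows (default 1000 nt,
step 10 nt — conventional values; the analysis is insensitive to them over
a wide range) tiled from position 0, with a zero guard for windows without
G or C. The cumulative sum of window skews peaks where the leading strand
switches: under the G-rich-leading-strand convention the global maximum
marks the replication terminus and the global minimum the origin, and the
two arms between them are the replichores. Circular contigs are analysed
linearly; for a genome whose origin sits at the linearisation point, the
minimum may be reported at either edge, so origin distances should be read
circularly.

## The search database

`build_protein_db()` layers, per contig: code-11 gene products, code-15
gene products, upstream-extended code-15 variants, auxiliary proteomes
(e.g. a host reference), contaminants, and reversed decoys of every target
record. Upstream extensions ask whether translation initiates upstream of
the predicted ATG: up to 30 codons upstream of the start are translated —
under code 15, so an upstream TAG reads as Q and does **not** terminate
the walk; only TAA and TGA (or the 30-codon cap, or the contig edge)
bound it. Extended records are separate, suffix-tagged entries rather than
replacements, so any peptide evidence upstream of the annotated start
remains attributable by parent id. Decoys are whole-protein reversals
("reversed-decoy"), preserving length and residue composition exactly.

`digest_protein()` implements trypsin (cleave after K/R, not before P)
with fully tryptic and semi-specific modes (exactly one tryptic terminus)
and a missed-cleavage budget (default 3). The function itself applies no
length bounds — its contract is the cleavage combinatorics, verified
against brute-force substring enumeration — while the callers that emulate
a search engine window apply 6–50 residues. Monoisotopic masses use the
standard residue table with water 18.010565 Da; carbamidomethylation
(+57.021464 Da) is fixed on every cysteine and methionine oxidation
(+15.994915 Da) variable with at most three per peptide, enumerated by
site-count (site permutations are isobaric).

## FDR filtering, mapping, and evidence classes

`fdr_filter()` is the classical target–decoy estimator at peptide level:
best score per modification-stripped sequence, ranked by falling score
(decoys before targets at ties — the conservative choice), FDR at rank k
estimated as decoys/targets at or above k, q-values by running-minimum
monotonisation from the bottom, targets accepted at q ≤ 1 % by default. A
peptide matching only decoy records is a decoy; mixed target/decoy parents
count as target and are flagged. This is deliberately the *classical*
estimator — some search engines use variants such as decoy fusion; with
equal-size target and decoy databases the classical estimate is exact up
to the usual assumption that incorrect matches hit targets and decoys
equally often, and is conservative by the factor (incorrect target
matches)/(decoy matches) otherwise.

`map_peptide()` places each occurrence of an accepted peptide onto the
genome residue by residue: 3-nt spans on the forward axis, strand-aware,
with the upstream-extension offset applied for extended records (residues
upstream of the start map to coordinates outside the gene span). The
literal genomic codon under every residue is re-read from the contig, and
a translation cross-check (code 15, X tolerated at N codons) guards the
arithmetic. Residues sitting on TAG codons define candidate recoding
positions; `recoding_events()` groups them by genome position and
re-asserts — as a hard error, not a filter — that the codon is literally
TAG and the observed residue is Q.

Evidence classes per peptide: *code15-exclusive* if the peptide occurs in
no target record outside the code-15 phage proteome (code-11, auxiliary
and contaminant records are all checked — the operational meaning of
"mapped only to code-15 predictions"); otherwise *shared*;
*stop-readthrough* if a residue sits on a TAG with at least one residue on
each side within the peptide; *start-readthrough* if the peptide's genome
span properly contains the start codon of a same-strand, same-frame
code-11 gene with at least one residue upstream of it. The classes are not
exclusive; a peptide typically carries two.

De novo corroboration (`corroborate_peptide()`): tags must pass ALC > 50,
share ≥ 6 contiguous residues with the peptide (I and L equivalent, since
fragmentation spectra cannot distinguish them; database exclusivity checks
keep I ≠ L because the database is an in-silico translation), and, for a
recoding event, the recoded Q and up to 2 flanking residues on each side
(clipped at tag ends) must each exceed 90 % local confidence. The flank
width quantifies "several flanking residues" — a genuinely open parameter;
±2 makes the corroborated stretch at least 5 residues around the Q while
staying usable near tag ends, and it is configurable. The explicit rule
set replaces the manual validation step of typical proteomics practice;
this is documented behaviour, not an emulation of any particular curator.

## The synthetic-data generator

`simulate_genome()` builds the study conditions end to end: a ~94 kb
contig (the size of a curated crAss-like gut phage genome; a 150 kb
variant exercises the ≥ 100 kb tier) whose first half carries 30
non-overlapping code-15 genes and whose second half 30 code-11 genes, at
35 % GC — crAss-like phages are AT-rich, and that composition is also what
keeps chance ORFs short. Each half carries an opposed G/C strand bias
(expected window skew ±0.2) so the cumulative curve peaks at the region
boundary (the planted terminus) and bottoms at the contig edge (the
origin). Genes are 250–450 residues; code-15 genes carry Poisson(10)
in-frame TAG codons (every gene forced to at least one) — in recoded
crAss-like genomes TAG supplies the majority of glutamine codons and Q is
roughly 4 % of residues, so about ten TAGs per 350-codon gene is the
realistic density, and it is exactly this density that fragments the genes
under code 11. Each gene cassette is preceded, in gene orientation, by an
in-frame TAA guard and a 0–10-codon stop-free start-free spacer: the guard
makes the maximal-ORF caller recover planted genes exactly and gives every
upstream extension a known stop-bounded length; the spacer varies that
length across fixtures. About 30 % of genes are placed on the minus
strand, with the nucleotide bias applied in the forward (replication)
sense, as mutational strand bias acts regardless of coding strand.

`simulate_psms()` samples fully tryptic peptides (7–30 residues, ≤ 1
missed cleavage) of the *expressed* proteome — the planted genes, i.e.
what a mass spectrometer could observe, not the chance ORFs a six-frame
scan also predicts — at a 25 % observation rate, requiring sampled
peptides to be locus-specific within the phage database (mirroring the
phage-specific peptide sets used in metaproteomic validation, and ensuring
a mapped peptide cannot land on a TAG outside its source locus by
coincidence). Scores are abstract Gaussians — only rank order matters to
FDR filtering: correct identifications N(50, 7), incorrect and decoy
identifications N(20, 6). Seventy percent of target identifications are
incorrect (`noise = 0.7`; in a metaproteome search most candidate matches
at the acceptance boundary are wrong), and the number of decoy
identifications equals the number of incorrect target identifications,
which is the classical equal-chance assumption under which the
target–decoy estimate is calibrated. In the fixed 5000-target/5000-decoy
calibration design the decoy pool is intentionally larger than the
incorrect-target pool, so the realized false-discovery proportion at the
1 % threshold is expected around 0.7 %, i.e. the estimator is mildly
conservative — the behaviour the calibration test checks. De novo tags
copy the peptide sequence with per-residue confidences near 96 % (passing
the >90 % rule) for 80 % of recoded-position peptides and near 70 %
(failing it, while still passing the ALC gate) otherwise.

What the generator does **not** emulate: real codon usage and coding
statistics (bodies are nucleotide-i.i.d. within the composition
constraints), spectra and fragment ions (no m/z-level simulation, no
chimeric spectra), retention time, protein abundance structure, suppressor
tRNAs, or origin-spanning genes on circular genomes. Passing tests
therefore demonstrate the correctness of the computational pipeline on
data with the assumed statistical structure, not the sensitivity of the
method on any particular real sample.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally, 1-based inclusive in GFF3.
* Windows without G or C have skew 0; contigs shorter than the window are
  a parameter error, not a silent empty profile.
* Zero decoys in FDR filtering yields all-zero q-values with a warning
  (degenerate but valid); an empty accepted set propagates through
  reporting as header-only tables, never a crash.
* Ties in score ranking put decoys first (conservative FDR).
* Identifications whose sequence occurs nowhere in the database (possible
  for simulated noise) are dropped from mapping and counted in the run
  manifest.
* Gene-cassette placement slack is distributed multinomially, and a
  capacity error is raised when the requested genes cannot fit.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
the 94 kb default genome (30 + 30 genes) and a 150 kb variant; ORF-caller
and digestion oracles on hundreds of random sequences up to 300 nt / 30
residues; FDR calibration on ten seeds of 5000 target + 5000 decoy scores.
These sizes were chosen so that every property that matters — exact
recovery, fragmentation, threshold crossings, calibration — is measured
with comfortable margins while a full run stays in the tens of seconds.

## Known limitations

* Only the TAG→Q (code 15) reassignment is detected; the table registry
  is extensible (e.g. TGA→W codes) but no assignment rule is implemented
  for other recodings, and none is validated.
* Absolute coding densities from the unscored caller are not comparable to
  a scored caller's output; only the dual-code *contrast* on the same
  caller is meaningful, which is what the assignment rule uses.
* Circular genomes are linearised; genes and skew features spanning the
  linearisation point are not modelled.
* The pipeline consumes search-engine output; it does not score spectra,
  and headline counts from any real experiment depend on the instrument
  data and annotation databases, which are outside its scope.
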