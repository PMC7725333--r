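---
title: "Inferring prokaryotic glycan alphabets from pathway homology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring prokaryotic glycan alphabets from pathway homology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoscan)
```

## The problem

Glycans are assembled from monosaccharides that glycosyltransferases consume
as nucleotide-activated sugars (UDP-glucose, GDP-mannose, CMP-Neu5Ac, ...).
Unlike the DNA and protein alphabets, the monosaccharide alphabet is not
universal: different bacteria and archaea biosynthesize different subsets of
the roughly 55 monosaccharides whose pathways have been elucidated. Because
glycan biosynthesis is not template-driven, the practical way to survey an
organism's *glycan alphabet* is indirect: search its proteome for homologues
of every enzyme of every biosynthesis pathway, and call a monosaccharide
present only when a complete pathway is found.

glycoscan implements that inference as a reusable, tested pipeline:

1. a curated **pathway registry** (monosaccharides, nucleotide sugars,
   routes, enzyme families with calibrated thresholds, precursor/product
   relations, genomic-context rules);
2. **hit ingestion** from HMMER3 and BLAST tabular output plus NCBI feature
   tables;
3. **annotation resolution** for proteins passing several profiles and
   context-dependent substrate attribution;
4. **pathway calling** under the completeness rule with closure over
   precursor and product pairs;
5. **prevalence analytics** (common/less-common/rare groups, strain ranges,
   phylum tables, co-occurrence);
6. **threshold calibration** (ROC sweeps, bit-score scatter partitions,
   seed-score thresholds);
7. a **synthetic-universe generator** that emits the same file formats with
   planted ground truth, so the whole chain is verifiable without
   downloads.

## The registry

The registry is a single YAML file (`inst/extdata/registry.yaml`) holding 55
monosaccharides activated as 57 nucleotide sugars. l-Rhamnose and Qui4NAc
occur as both UDP- and TDP-/dTDP-derivatives, which is why there are two
more sugars than monosaccharides; CMP-Leg5Ac7Ac has two routes with distinct
precursors (one from UDP-Glc2NAc, one from Glc2NAc-1-P with its unusual
guanylyltransferase first step), so per-precursor tallies count it twice
while distinct totals count it once. UDP-glucose likewise carries a second
route for its alternative uridylyltransferase family.

```{r}
reg <- load_registry()
reg
registry_summary(reg)
```

Six precursors organize the table: Glc-1-P, Fruf-6-P (which yields GDP-Man
and UDP-Glc2NAc themselves), GDP-Man, UDP-Glc2NAc, Glc2NAc-1-P and Sed-7-P.
Glycolytic precursor formation (Glc-6-P to Glc-1-P and the like) is *not* a
pathway step: those enzymes are ubiquitous and uninformative. The
UDP-Glc2NAc and GDP-Man formation steps are stored once, on their own
sugars, and excluded from the routes of their many derivatives - a genome
can therefore carry, say, l-Qui2NAc enzymes without the UDP-Glc2NAc pathway
(obligate intracellular bacteria show exactly this pattern, sourcing the
precursor from the host). l-Iduronic acid is excluded: it arises by
polymer-level epimerization, not through a nucleotide-sugar pathway.

Detection is per enzyme family. 57 families are profile-HMM based, each with
a bit-score threshold on the *best one domain* score (database-size
independent, unlike E-values). Eleven families with too few experimentally
characterized members for a profile are blastp queries with coverage and
similarity cutoffs (defaults 90 % query coverage, 30 % similarity; the PdeG
retaining-dehydratase query is raised to 70 % similarity because inverting
homologues crowd just below). Step memberships for the well-characterized
cases follow the literature (the RmlA-B-C-D chain for TDP-l-rhamnose, Gmd
for GDP-sugars, PglF/PseB-initiated UDP-Glc2NAc derivatives, blastp-only
heptose pathways); memberships for sparsely characterized pathways are
representative reconstructions, adequate for exercising the inference
machinery but not an exhaustive curation.

Two registered relations drive closure:

* **precursor pairs** (11): the product's pathway runs through the
  precursor, so calling the product implies the precursor (paratose before
  tyvelose, GlcA before GalA, Bac2Ac4Ac before Leg5Ac7Ac, ...);
* **product pairs** (3): rhamnose/6-deoxytalose, cillose/cereose and
  abequose/paratose each share one pathway whose terminal reductases are
  homologous and cannot be separated by sequence, so the members are always
  co-called and have identical prevalence by construction.

## Thresholds

Three calibration procedures are implemented, mirroring how family
thresholds were set:

* `roc_curve()` sweeps every distinct score as an inclusive threshold
  against database annotations (assumed correct) and `choose_threshold()`
  picks the operating point. The published procedure does not state the
  operating-point rule, so the default is the Matthews correlation
  coefficient with ties broken towards the *most stringent* threshold
  (consistent with the stated stringency bias); F1 and Youden's J are
  available by flag, and the choice is recorded in the output metadata.
* `scatter_partition()` handles sibling families whose database annotations
  cannot separate them (C3- vs C4-aminotransferases, hydrolysing vs
  non-hydrolysing 2-epimerases): every sequence is scored against both
  profiles and each axis threshold is placed mid-gap between the
  self-family and cross-family clouds. Overlapping clouds are flagged
  degenerate; the output is always marked curator-reviewable because this
  was a manual practice.
* `seed_threshold()` returns T\_exp (minimum self-score of the
  experimentally characterized seeds) or T\_extend (minimum over the
  extended homologue set); these names are defined here as the minimum seed
  self-score, the natural reading of "score of the weakest trusted member".
  T\_extend \<= T\_exp whenever the extended set contains the seeds. Narrow
  profiles keep their seed threshold rather than a lower ROC threshold
  that would dilute specificity.
* One family (glucose-1-phosphate uridylyltransferase family 2, 303 bits)
  has a discontinuous score distribution - a plateau from about 705 down to
  303 bits, then a detached tail below 57 - that supports neither a ROC nor
  a scatter. `choose_threshold(criterion = "largest_gap")` formalizes the
  manual decision: the threshold is the score at the upper edge of the
  widest gap.

```{r}
db <- generate_score_db(500, 500, pos_mean = 55, neg_mean = 30, sd = 5, seed = 7)
choose_threshold(roc_curve(db), "mcc")$threshold # near the analytic 42.5
```

## Annotation resolution

A protein can pass thresholds for several profiles. Exactly one annotation
is kept, by three ordered rules: (1) a single passing profile wins; (2) a
narrow-specificity profile beats a broad profile generated from a superset
of its seeds (recorded as `superset_of` in the registry) - the broad pass
is explained by the narrow membership; (3) otherwise the profile with the
largest margin above its own threshold wins, ties breaking to the smallest
family id so resolution is deterministic and order-independent. Every
decision is logged to an audit table with the candidate set and the rule
that fired.

One caveat is worth stating: no rule that mixes pairwise dominance with
margins can make the winner fully independent of irrelevant alternatives.
If a narrow profile suppresses its broad sibling but loses on margin to a
third family, removing the narrow profile resurrects the broad one, which
may then win. With the two narrow/broad pairs in the packaged registry this
situation requires a protein passing three specific profiles at once and
has not been observed in synthetic universes; the property tests cover the
cases that matter (removal of dominated broads and of unrelated losers).

### Genomic context for substrate-ambiguous families

The non-hydrolysing UDP-Glc2NAc 2-epimerase sits in the pathways of several
monosaccharides and its substrate cannot be read from sequence. Hits are
treated as Man2NAc-pathway enzymes *unless* another enzyme of the
l-Fuc2NAc, l-Qui2NAc or Man2NAc3NAcA pathway lies within a window of
+/-10 genes on the same replicon (configurable; the window is a
reconstruction, since pathway genes cluster - O-antigen and capsule loci -
but no radius is published). Without a feature table the rule degrades to
whole-genome context and says so in the audit trail.

When an override pathway is found, the attribution extends to pathways that
are sub-routes of it - e.g. l-Rha2NAc, whose pathway is the l-Qui2NAc
pathway minus the last step - provided they share enzymes with the override
beyond the ambiguous family itself. That proviso keeps the bare default
(Man2NAc, whose entire route *is* the ambiguous family) excluded once an
override fires. Without the sub-route extension, a genome carrying exactly
the l-Rha2NAc enzymes could never be called for it.

The UDP-sugar C4-epimerase family is promiscuous across glucose, GlcA,
Glc2NAc, Glc2NAcA and xylose substrates. No context rule restricts it: a
hit counts for every pathway containing the step. The known consequence is
that genomes with the xylose pathway are nearly always also called for
l-arabinose (one extra shared-family step), an over-call that is inherent
to sequence-level evidence and is documented rather than patched.

## Pathway calling and closure

The completeness rule is strict: a step is satisfied if at least one
attributed hit matches any of the step's alternative families (some steps
accept non-orthologous enzymes, e.g. the two phosphomannose isomerase
types); a route is complete only if *every* step is satisfied; a sugar is
made if any of its routes is complete. A single missing enzyme vetoes the
pathway - the veto is what makes the inference conservative. Pathways
missing some but not all steps are reported as partials with their
missing-step counts (useful for spotting pathway decay, as in endosymbionts
that retain fragments of the UDP-Glc2NAc pathway); partials never
contribute to the alphabet.

Detected sugars are then closed: product-pair members are marked present
together, and each product marks its registered precursor present,
iterating to a fixed point (the relation must be acyclic; a cycle is a
configuration error). Monosaccharides added only by closure are tracked as
*implied*, keeping the evidence distinguishable. A protein may support
steps in any number of pathways - shared SDR-superfamily enzymes are the
rule, not the exception - so no exclusivity constraint is imposed.
`alphabet_size()` counts monosaccharides, not nucleotide forms: l-rhamnose
made via both UDP and TDP routes is one letter.

## Prevalence analytics

From the genomes-by-monosaccharides presence matrix:

* `classify_groups()` assigns *common* (fraction \>= 0.50), *rare*
  (\<= 0.10) and *less common* (between), boundaries inclusive towards
  their own group. The denominator is all genomes in the run; a
  species-level denominator is available by aggregating first.
* `species_aggregate()` keeps the best strain per species (the value used
  for species-level plots); `strain_range()` reports per-species min/max
  over strains, restricted to species with more than one sequenced strain
  and at least one monosaccharide in some strain.
* `phylum_prevalence()` computes per-phylum fractions; phyla under five
  sequenced genomes are dropped from the rendered table but kept raw.
* `cooccurrence_pairs()` counts genomes carrying both members of a pair
  (enantiomeric pairs, isomeric N-acetyl derivatives) with a per-phylum
  breakdown; `size_vs_proteome()` gives the Spearman correlation between
  alphabet size and proteome size with a seeded permutation p-value.

## The synthetic universe generator

`generate_universe()` emulates the study inputs end to end: a taxonomy of
phyla/species/strains, per-genome HMMER tblout and BLAST tables, NCBI-style
feature tables, and a ground-truth JSON. Planted pathway genes form
contiguous clusters separated by filler genes wider than the context
window, emulating O-antigen-cluster layouts and making the context rule
testable. Scores are Normal draws truncated at zero sitting at least 5 bits
(the `score_offset`) above threshold so float formatting can never flip a
boundary; decoys sit the same margin below. Dials: `decoy_rate`
(sub-threshold hits), `dropout_rate` (one deleted step per affected
cluster, creating partials), `ambiguity_rate` (planted narrow-profile hits
that also pass their broad sibling - only that direction is injected,
since injecting a narrow pass over a planted broad hit would change the
resolved annotation and make exact recovery undefined), and `strain_jitter`
(per-strain pathway loss, creating strain ranges).

Because enzyme families are shared between pathways, planting one sugar can
legitimately complete another's route (the xylose/l-arabinose situation
above). The ground truth is therefore derived *constructively* from the
emitted gene content by set logic - route coverage, context emulation, and
pair/precursor closure - rather than assumed equal to the planting list.
Alphabet-size targets are met by accepting candidate sugars only while the
closed size stays within target. With a fixed seed the generator is
byte-identical across runs.

What passing closed-loop tests shows: parsing, thresholding, resolution,
context attribution, completeness calling and closure are mutually
consistent and exactly invert the generative model. What it does not show:
performance on real proteomes, where profile scores are not cleanly
separated, annotations are noisy, and pathway gene order is messier than
planted clusters - the stringency/FN trade-off (e.g. divergent archaeal
RmlB homologues scoring just below a 400-bit threshold) cannot be probed
with synthetic scores.

## Numerical and design choices

* Threshold comparisons are inclusive (\>=) everywhere, matching the
  printed blastp cutoffs; boundary behaviour is tested at the exact
  threshold.
* Query coverage is defined on the characterized-enzyme (query) side;
  computed as 100 x alignment length / query length when no coverage
  column is declared, clamped at 100 with a warning.
* Multiple HSPs per protein-query pair keep the single best-scoring HSP;
  duplicate tblout rows keep the maximum best-one-domain score.
* Deduplication of near-identical proteins before scanning is available
  upstream of the pipeline but off by default; hit tables are the input
  boundary.
* Genomes without taxonomy records aggregate under `"unassigned"` rather
  than disappearing; species with all-zero strains are kept by
  `species_aggregate()` (size 0) and excluded by `strain_range()`.
* Test problem sizes: closed-loop validation uses 200 genomes across 5
  phyla with alphabet-size targets sweeping 0-23; the completeness
  criterion enumerates all 60 routes x every step; calibration recovery
  uses 10 000 scores per class. These sizes give exact or
  tightly-converged checks while keeping the default test run fast.

## Limitations

* The registry's route memberships beyond well-characterized pathways are
  representative reconstructions; swapping in a refined registry file is
  the supported upgrade path (the YAML round-trips byte-exactly).
* Absence calls inherit the stringency bias: a pathway whose enzymes score
  marginally below threshold is invisible, and the partial-pathway report
  is the only trace.
* The l-arabinose over-call via the promiscuous C4-epimerase is by design;
  prevalence for xylose and l-arabinose should be read jointly.
* Product-pair members are indistinguishable by construction; their
  prevalence is reported identically rather than split.
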