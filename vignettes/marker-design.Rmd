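---
title: "Developing Y-specific multiplex PCR markers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing Y-specific multiplex PCR markers: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexmarker)
```

# The problem

Dioecious plants with an XY sex-chromosome system — *Cannabis sativa* is
the motivating case — cannot be sexed phenotypically as seedlings, yet
growers usually want females only. A genetic assay solves this by
amplifying a region present only on the Y chromosome. Two things make such
an assay trustworthy across cultivars:

* the target must sit in an **old evolutionary stratum** of the sex
  chromosomes, where X–Y divergence is high and the divergent sites are
  shared by distant populations rather than being private polymorphisms;
* a **multiplex** layout with an autosomal control band separates the
  three outcomes *male* (control + Y band), *female* (control only) and
  *failed reaction* (no control), so a dropped reaction is never scored
  as a female.

`sexmarker` implements the complete development chain: shortlist
sex-linked genes by X–Y synonymous divergence, call fixed X–Y differences,
enumerate allele-specific primer pairs, assemble a gel-resolvable panel,
validate it by in silico PCR on male and female genome templates, and
summarise assay outcomes as confusion statistics.

# Synonymous divergence

`nei_gojobori_ds()` implements Nei–Gojobori (1986) counting. Each codon
contributes synonymous sites equal to the fraction of its nine possible
single-base changes that preserve the amino acid (changes creating a stop
codon count as nonsynonymous), so sites per codon always total 3.
Differences between a codon pair are averaged over all shortest
mutational pathways with equal weight; pathways passing through a stop
codon are excluded (if every pathway does, all are kept with stop steps
counted nonsynonymous — a corner case that cannot arise from the
simulator's stop-free sequences). The Jukes–Cantor correction
$d_S = -\tfrac34 \ln(1 - \tfrac43 p_S)$ maps the proportion of synonymous
differences $p_S$ to a divergence; at $p_S \ge 3/4$ the logarithm is
undefined and the estimate is flagged *saturated* rather than returned as
a number. Saturated genes are ranked above all finite ones during gene
selection, since saturation indicates extreme divergence, not absence of
signal.

Codons containing a gap or `N` in either sequence are excluded pairwise
before counting; a trailing incomplete codon is trimmed and a terminal
stop tolerated, but a premature stop aborts with an error — it almost
always indicates a frame problem upstream, and silently truncating would
bias the site counts.

No maximum-likelihood (codeml-style) estimation is attempted: the
selection step only needs a ranking by divergence, for which NG86 is
fully specifiable, fast, and deterministic.

# Gene selection

`select_candidate_genes()` applies four filters in order: the Y copy must
still be expressed (an input flag — expression analysis is out of scope);
the gene must lie in the oldest stratum present, resolved as the minimum
ordinal stratum label in the metadata (strata are never inferred from
sequence); the gene must rank in the top `top_k = 20` by dS among the
remaining genes (descending, ties broken by gene id); and the intron must
be at least `min_intron_bp = 300` long. The intron filter runs last,
mirroring a workflow in which the divergence ranking is computed on
coding sequence before genomic structure is considered.

# Fixed X–Y differences

`call_fixed_differences()` aligns each X haplotype globally to the Y copy
(`align_global()`, backed by the `Biostrings` alignment engine with
match +2, mismatch −3, gap open −5, gap extend −2 — megablast-like
defaults; any reasonable global scheme works, and the brute-force tests
pin the scoring semantics), projects alignment columns onto Y
coordinates, and reports sites where **all** X haplotypes share one
unambiguous, ungapped base that differs from the Y base. Using three X
haplotypes from distinct cultivar groups is recommended — a warning is
raised below three — because a difference fixed across distant lineages
is far more likely to be universal; with a single haplotype the function
degenerates to listing all ungapped mismatches. All exposed coordinates
in the package are 0-based, half-open, with strand `"+"`/`"-"`.

# Primer design

`enumerate_candidates()` scans every window of the Y coding sequence and
keeps primer pairs satisfying, with the `primer_constraints()` defaults:

| parameter | default | rationale |
|---|---|---|
| length | 18–24 nt | standard allele-specific PCR range |
| Tm | 55–62 °C at 50 mM Na⁺, 0.25 µM | panel must function at a 58 °C annealing step |
| GC | 30–70 % | avoids extreme-composition primers |
| amplicon | 100–600 bp | resolvable on standard agarose |
| 3′ anchor window | 5 nt | a fixed difference near the 3′ end blocks extension on the X allele |
| fixed differences per amplicon | ≥ 2 | redundancy against private X variants |
| dimer limits | run ≥ 8 or 3′ run ≥ 4 rejects | common primer-design heuristics |

Melting temperatures use the unified nearest-neighbor parameter set
(SantaLucia 1998) with the entropic salt correction
$0.368\,(n-1)\ln[\mathrm{Na}^+]$ and a duplex concentration term
$C_T/4$; the implementation is cross-checked in the tests against frozen
values from an independent implementation of the same parameters, within
0.5 °C. The Wallace rule ($2(A{+}T)+4(G{+}C)$) is exposed only as a
secondary cross-check formula.

Two design rules deserve explanation:

* **X-allele rejection.** The 3′-anchor rule alone does not guarantee
  that a primer pair is silent on the X copy: an anchor at offset 3–4
  from the 3′ end, with at most two other footprint mismatches, still
  binds under the in silico PCR model (≤ 2 mismatches, exact 3′-terminal
  3 nt). Each Y-specific pair is therefore additionally required to have
  at least one primer that *fails* to bind its reconstructed X-allele
  counterpart under exactly that binding model. This is the in-package
  equivalent of screening candidate primers against female genomes
  before synthesis, and it makes the design-level specificity property
  (zero female-genome amplicons) hold by construction rather than by
  luck.
* **Dimer screening.** `dimer_score()` slides one primer along the
  reverse complement of the other over all ungapped offsets and reports
  the longest complementary run and the longest run ending at either 3′
  terminus. The reverse primer is screened as its reverse complement —
  the molecule actually synthesised — which matters for the 3′-anchored
  run.

`select_multiplex()` searches all triples of two Y-specific pairs from
distinct genes plus one autosomal control, requiring pairwise product
size gaps of at least `min_size_gap_bp = 60` (separable on agarose) and
cross-pair dimer compatibility, ranked by total fixed differences
covered, then total cross-complementarity, then gene ids. Candidate
lists fed to the search are shortlisted per gene across distinct
product-size bins (`max_candidates_per_gene = 6`), because a panel needs
size diversity more than it needs many same-sized alternatives. The
search is exhaustive on its inputs and raises an explicit infeasibility
error naming the binding constraint when no triple works.

Output ordering is deterministic everywhere (windows by position, panels
by ranking key), so identical inputs give identical panels with no seed.

# In silico PCR

`find_binding_sites()` reports template positions where a primer anneals
with at most `max_mismatch = 2` mismatches and none in its 3′-terminal
`three_prime_exact_nt = 3` bases, on both strands; `N` in the template
counts as a mismatch, and `N` in primers is disallowed. These defaults
mirror common in silico PCR practice and deliberately make X-allele
rejection depend on the 3′ anchor, consistent with the design rule
above. `predict_amplicons()` pairs plus-strand forward sites with
downstream minus-strand reverse sites, rejecting overlapping footprints
and products beyond `amp_max = 3000` bp (large enough for any
intron-containing product the designer emits). `validate_marker()` then
demands exactly one product per male genome and none per female genome
for Y markers, and exactly one product per genome for controls.

`call_sex()` attributes observed band sizes to panel products within
±10 % of the expected size (a gel-resolution proxy); an unattributable
band is flagged but does not change the call, since the control/Y logic
is what carries the decision.

# Assay evaluation

`summarize_assay()` reports, per cultivar and in total: counts of males
called male, females called female, the two error directions, failed
reactions, the true positive success rate
$100\,(MM + FF)/n$ and the specificity $100\,MM/(MM + MF)$ computed
over phenotypic males (undefined when a cultivar has no males). Failed
experiments count in $n$ but never in the numerator — a failed reaction
is not a correct call. Per-cultivar rates are rounded to integers and
the total to one decimal, the conventional reporting precision for
panels of this size. Count-table input is supported through
`counts_to_results()`, which expands per-cultivar counts into an
equivalent sample table (the statistics depend only on the counts;
failed rows are expanded as phenotypic males by documented convention,
since a count table does not record the phenotype of failed samples).

# The simulator

`simulate_cohort()` generates the data regime the pipeline assumes, with
defaults chosen to mirror a realistic marker-development study: 12
sex-linked genes across three strata with target dS 0.25 / 0.10 / 0.03
(usable markers sit near the top of that range, and divergence in the
oldest stratum of such systems reaches ~0.4), three X haplotype
lineages, per-site intra-X diversity 0.002 (X copies must be far closer
to each other than to Y), 300-codon genes with a 400-bp intron at a
random interior codon boundary, two autosomal genes, and a cohort of 12
cultivars × 16 samples = 192 with a 1:1 sex ratio and a phenotyping
error rate of 1/192 (one mislabelled plant per study-sized cohort,
emulating phenotyping mistakes or sex reversion).

The Y copy is produced by `mutate_cds()`: random substitutions, stop
codons never created, nonsynonymous proposals accepted with probability
0.1, stopping when the NG86 estimate against the ancestor first reaches
the target. Because one substitution moves dS by roughly $1/S \approx
0.004$ for a 300-codon gene, the overshoot is small, and estimator
recovery (mean within ±0.02 of targets 0.05–0.40) is verified in the
acceptance tests at 50 replicates per target. A full codon model is
deliberately not used: downstream stages consume only the NG86 value,
so a generator that hits a target NG86 divergence is sufficient.

Genome templates concatenate gene structures with 200–1000 bp random
spacers — long enough that no amplicon spans two genes. Female genomes
carry two copies of their lineage's X chromosome and no Y; male genomes
carry X + Y; both carry an autosome. Samples of a cultivar share the
cultivar lineage's reference genomes, which keeps the 192-sample assay
simulation cheap without changing any count-based statistic. One master
seed drives hierarchical per-gene subseeds, so cohorts are byte-identical
across runs and partially regenerable.

What the simulator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: recombination and
coalescent structure within strata, indel variation between X and Y
(alignments of simulated copies are gapless), repetitive or
low-complexity genomic context (spacers and introns are uniform random
sequence, so off-target binding is rarer than in a real genome),
assembly errors in reference genomes, and PCR chemistry beyond the
binding model (no extension-efficiency or secondary-structure
thermodynamics). A panel designed on real data should still be screened
against real genome assemblies and validated in vitro.

# Numerical and procedural choices

* Problem sizes in the test suite and acceptance script — cohorts of 2–3
  genes of 300 codons, 20 seeds for design-stage properties, 30–50
  replicates per divergence target — were chosen as the smallest sizes at
  which the properties under test are statistically meaningful.
* Candidate enumeration inside the pipeline runs in consecutive
  amplicon-size bands with a per-band cap on accepted pairs
  (position-ordered, hence deterministic): full enumeration is reserved
  for the brute-force equivalence tests, while the pipeline needs only a
  size-diverse shortlist.
* Expected product sizes are genomic: when an amplicon spans the
  exon–intron junction, the intron length is added, and primer
  footprints are never placed across the junction itself.
* Ties anywhere (equal dS, equal ranking keys) break on identifiers,
  never on list order.
* `IUPAC` ambiguity codes other than `N` are rejected at input: the
  fixed-difference caller requires unambiguous bases, and accepting
  ambiguity codes silently would weaken the fixity guarantee.

# Known limitations

* The dS estimator is NG86 with equal pathway weighting; for divergences
  approaching saturation its variance grows quickly, and the saturated
  flag is the only signal provided.
* `predict_amplicons()` pairs forward-plus with reverse-minus sites
  only; a pair binding in the opposite orientation (forward on the minus
  strand) is not reported. For designed panels this orientation is fixed
  by construction.
* Specificity screening is local to the gene's X allele plus whole
  simulated genomes; screening against external genome databases is out
  of scope and should be done with standard tools before synthesis.
* The gel model is a ±10 % size-attribution tolerance; co-migrating
  off-target bands are not simulated.
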