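---
title: "Discriminating multi-copy mitogenome insertions from heteroplasmy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating multi-copy mitogenome insertions from heteroplasmy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meganumt)
```

## The problem

Human mtDNA is inherited strictly maternally, but PCR-based mtDNA typing
of total genomic DNA cannot distinguish genuine mitochondrial templates
from nuclear copies of mitochondrial sequence (NUMTs). Most fixed NUMTs
carry archaic motifs and are easily recognized; a **Mega-NUMT** — a
recent, multi-copy, full-mitogenome insertion — instead mimics a
phylogenetically plausible *mixture* of two modern haplotypes, the exact
signature expected from heteroplasmy or biparental inheritance. This
package implements the evidence chain that separates the two
explanations: deconvolve the mixture, contrast tissues that differ in
nuclear content, check nuclear-style (autosomal dominant) segregation in
the pedigree, and quantify the insert.

## Data model

Haplotypes are **mitotypes**: differences from the rCRS, the 16,569 bp
circular reference, written in forensic nomenclature (`263G`, insertion
`315.1C`, deletion `249DEL`). Mixed Sanger positions carry IUPAC codes
(`73R` = A/G). Coordinates are 1-based inclusive on the circle; the
control region is the wrapping interval 16024–576, and control-region
mitotypes serialize in circular order starting at the 16024 arc
(`16298C 72C ...`), matching forensic reporting practice. Full-genome
mitotypes use plain numeric order.

Because variant semantics are *relative*, almost all operations need no
reference sequence. The two exceptions — computing the IUPAC code when
one haplotype carries no variant at a differing site, and FASTA export —
use `mt_reference()`. The packaged default is a **synthetic stand-in**:
correct length and correct bases at an anchor table of positions used by
the packaged fixtures and motifs (each anchor either standard
nomenclature knowledge or implied by a published mixed-base call
together with its resolution), arbitrary filler elsewhere. Users doing
sequence-level work at other positions should pass a genuine rCRS FASTA.
Insertions present in only one mixture component cannot be IUPAC-encoded
and are carried through unambiguously; a deletion conflicting with a
base is an error. The family data contain neither case.

## Haplogroup plausibility score

A motif table is a rooted fragment of the mtDNA phylogeny; the
cumulative motif $E$ of a haplogroup is the union of defining variants
along the root path, restricted to the haplotype's covered range. With
observed variants $O$ and the hotspot mask removed from both sides, the
score is

$$ s = \frac{|E \cap O|}{|E| + 0.5\,|O \setminus E|}, $$

a match fraction with a half-weight penalty per private variant. It is
monotone: adding a motif variant never lowers a clade's score, adding a
private variant never raises it. Ranking is by score, then clade depth
(deeper wins — a complete HV0 control-region haplotype ranks its nested
clade V first), then name. Two conventions complete the definition:

* An empty in-range motif ($|E| = 0$, e.g. the root) scores 1 for a
  (masked-)empty haplotype and 0 otherwise, so an rCRS-identical
  haplotype ranks the root first while any variant-bearing haplotype
  does not.
* The default hotspot mask is {263, 309, 310, 315}: present in
  virtually every non-rCRS mitotype, hence uninformative. 16519, the
  most common hotspot of all, is *not* masked by default because it is a
  defining variant of the packaged U4c1 motif; the mask is a parameter.

The packaged `family_motif_table()` is deliberately minimal — root, HV0,
V (coding-region 4580A), U4c1 — transcribed from the study family's own
component haplotypes minus universal hotspots. It is a fixture, not a
phylogeny; load a full motif table from TSV for general use.

## Two-source deconvolution

Assuming exactly two contributors (three-or-more-allele IUPAC codes are
rejected), each of the $k$ ambiguous sites assigns one allele to each
component; an allele equal to the reference base yields *no* variant
record — reference alleles are absence of variant, which is why `200R`
resolves to `200G` in one component and nothing in the other. The search
enumerates all $2^{k-1}$ assignments (swap symmetry collapsed by fixing
site 1), scores both components of each candidate against the motif
table, and maximizes the sum of the two top scores; exact ties break to
the lexicographically smaller component-A serialization. The search is
exhaustive, so it provably equals brute-force enumeration; it is
vectorized (per-site, per-allele score increments precomputed per
haplogroup, candidates scored by matrix products) so that $k = 15$
remains subsecond. A configurable cap (default $k \le 20$) bounds the
cost.

**Identifiability limit.** The score penalizes a private variant by
$0.5/|E|$ relative to the motif size, so placing an ambiguous private
variant on the larger-motif component always costs less. A pair whose
smaller-motif component carries private variants at mixed sites is then
not the score optimum, and no count-free method can recover it from the
mixed string alone. The round-trip property is therefore stated — and
tested — conditionally: among mixtures whose true pair attains the
strict score maximum, recovery is essentially perfect. Resolving the
remaining cases needs per-molecule data (clones, single cells), which is
exactly what the study's cloning experiments provide.

Mixture fractions use clone/single-cell counts with exact
Clopper–Pearson 95% intervals (`estimate_fraction()`); 249 negative
clones, for instance, still admit a minor fraction up to 1.5%. The
direct-Sanger detection limit is modelled as a hard threshold (default
20%, applied as ≥) in `sanger_call()`. The threshold is a parameter
because the data themselves strain it: the buccal mixture was visible by
direct sequencing at a ~4% clone fraction. The package records both
observations as transcribed and leaves the tension unresolved.

## Tissue-contrast classification

The discriminating biology: every cell has one nucleus, but mtDNA
copies per cell vary by orders of magnitude across tissues — so a
nuclear-insert minor component shows a tissue-dependent fraction in
nucleated cells, vanishes in anucleate cells (thrombocytes, hair
shafts), and is the *only* signal in mtDNA-depleted (ρ°) cells.
`classify_minor_source()` applies ordered rules: contaminated blanks
suspend interpretation; a nucleated mixture with ≥ `min_anucleate`
(default 10) anucleate observations of which at most
`anucleate_mixed_tolerance` (default 5%) show the minor component — and
any depleted cells showing it exclusively — is `NUCLEAR_NUMT`; minor
signal in anucleate cells above tolerance is `MT_HETEROPLASMY`
(heteroplasmy and paternal leakage are deliberately not distinguished:
without NUMT exclusion they are confounded); anything else is
`INCONCLUSIVE`. The 5% tolerance encodes the empirical reality of hair
shafts: occasional nuclear remnants (1 of 56 shafts in the family data)
should not veto an otherwise unambiguous nuclear verdict.

## Pedigree checks

A nuclear insert segregates as an autosomal dominant marker.
`check_segregation()` reports a conflict for every carrier both of whose
parents are present and typed `non_carrier`; `unknown` is never treated
as negative (degraded aged bone motivates this conservatism). Obligate
carriers are unknown-status individuals on a carrier-to-carrier descent
path. On the packaged family the checker flags exactly one conflict —
the generation-II carrier against both typed-negative founders — which
is the correct output: one founder must have carried the insert (or its
pre-integration mtDNA), and degraded bone DNA plausibly concealed it.
The checker flags, and does not resolve, this conflict.
`check_matriline()` separately verifies that every typed individual's
true mtDNA equals their mother's.

## Quantification

ddPCR: with positive fraction $p$ among $n$ droplets, mean copies per
droplet is $\hat\lambda = -\ln(1-p)$; saturation ($p = 1$) is an error,
and concentration ratios cancel the droplet volume (default 0.85 nL,
configurable, never needed for copy numbers). A heterozygous insert of
$C$ tandem units contributes $C$ mtDNA-like copies per cell against 2
copies of a single-copy autosomal reference, so copies per insert allele
is the mtDNA-like:reference ratio × ploidy (default 2). Replicates are
aggregated as per-replicate copies → mean ± sample SD (n−1) with $n$,
the same reporting shape as the study's 45.00 ± 5.27 (n = 20, ddPCR)
and 56.16 ± 4.35 (n = 76, qPCR). The two published methods disagree;
the package never pools them, reporting a per-method range instead
(insert size 745.6–930.6 kbp at 16,569 bp per unit). Multi-copy
autosomal targets (RNU2, AluYb8) are registry members for relative
quantification only.

The template-topology test formalizes the long-range PCR argument: an
amplicon is supported by a circular template always; by a single
linearized mitogenome run only if it occurs as a contiguous sub-run
(an origin-wrapping amplicon never is, in a 1..16569 unit); by a tandem
repeat of ≥ 2 units always, since every wrap is realized across a unit
junction. Two overlapping long-range products, one wrapping the origin,
therefore exclude a single linear unit. Published amplicon lengths mix
counting conventions; this package uses 1-based inclusive lengths
throughout and does not reproduce the non-inclusive figures.

## The generative model

`simulate_pedigree_dataset()` draws: a pedigree (founder couple,
configurable sibships); Mendelian transmission of the insert allele
(probability 1/2 per allele); strict-matriline mtDNA; per-tissue minor
fractions

$$ f = \frac{A\,C}{A\,C + m_{tissue}}, $$

with $A$ the allele count, $C$ the tandem copy number and $m$ the mtDNA
copies per cell. Defaults are the study regime: $C = 45$,
heterozygous, $m$ = 84 (blood), 1080 (buccal), 5000 (hair roots) —
back-solved from the observed clone fractions (35% blood, 4% buccal),
i.e. configuration, not measured biology. Clone and single-cell calls
are Bernoulli($f$); direct Sanger applies the 20% threshold; hair
shafts are contaminated with nuclear remnants at 1/56 per shaft
(mirroring the one mixed shaft in 56); ρ° cells carry a configurable
residual true-mtDNA fraction (default 0, as achieved in the study).
ddPCR wells draw positives as Binomial($n$, $1-e^{-\lambda}$) with the
high-copy mtDNA-like aliquot pre-diluted by $AC/2$ so both targets sit
in the informative occupancy range (at $C = 45$ an undiluted target
saturates 20,000 droplets — standard practice is to dilute). qPCR noise
is a shared well-loading lognormal factor, which cancels in the
mt:nuclear ratio because the assay is a single-tube multiplex, times a
mean-one lognormal ratio noise (CV 0.15); the stated amplification
efficiency (0.95) cancels between sample and standard curve and is
carried as configuration. The shared-well structure keeps the
mean-of-ratios copy estimator unbiased; independent per-target noise
would bias it by $e^{\sigma^2}$ (+2.3% at CV 0.15). Homozygous carriers
($A = 2$) are supported although the study family is heterozygous
throughout.

In heteroplasmy mode the minor haplotype is placed in the mtDNA pool of
the matriline at a fixed fraction (default 35%) in *every* tissue,
including anucleate cells — the observable that separates the modes.

What the simulator does **not** emulate: germline bottleneck drift of
heteroplasmy fractions across generations and tissues, electropherogram
peak heights, tissue degradation, partial NUMT copies, and read-level
sequencing error. Passing tests therefore validate the inference logic
under the stated generative assumptions, not the wet-lab layer beneath
real data.

## Numerical and testing choices

Determinism: a mandatory seed makes datasets byte-identical;
deconvolution tie-breaks are lexicographic; report JSON is reproducible.
Degenerate inputs error early with the offending token or row named.
Problem sizes in the test suite were chosen to keep the full run in a
few minutes on one core: 1000 random intervals for the circular-length
oracle, 200 trials for the round-trip property, 50 seeds per true copy
number for parameter recovery, 200 seeds per mode for classifier verdict
rates, brute-force cross-checks at $k \in \{2, 5, 10\}$, 2000 draws for
interval coverage.

## Known limitations

* The packaged motif table covers only the clades of the packaged
  family; haplogrouping arbitrary samples requires a user-supplied
  table.
* Deconvolution is strictly two-source and count-free; see the
  identifiability note above.
* The default reference sequence is a synthetic stand-in outside its
  anchor positions.
* The classifier treats observation rows as exchangeable counts; it
  does not model per-individual random effects.
* Insert size assumes complete 16,569 bp units in tandem; partial or
  rearranged units would need sequence-level evidence outside this
  package's scope.
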