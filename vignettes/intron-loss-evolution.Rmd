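---
title: "Reconstructing intron gain and loss histories of gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing intron gain and loss histories of gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronloss)
```

## The problem

Spliceosomal intron positions are usually stable characters: orthologous
genes keep the same introns, at the same codon boundaries, over hundreds of
millions of years. Against that background, a gene family that repeatedly
*loses* introns is informative — both about the mechanism of loss and about
the selective pressure that favours it. The motivating case for this
package is the hatching-enzyme gene family of teleost fishes: an
astacin-family metalloprotease expressed in a short, intense burst by the
hatching gland of the embryo. Basal teleosts (osteoglossomorphs,
elopomorphs) carry a single gene with the ancestral 9-exon/8-intron
structure shared with tetrapod orthologs. In the ancestor of
Clupeocephala the gene duplicated into two lineages (clade I, the HCE
orthologs; clade II, the LCE orthologs), after which clade I shed introns
step by step in otocephalans and wholesale in euteleosts, while clade II
remained close to the ancestral structure — except where it was lost
outright (otophysans) or lost all introns (salmoniforms/esociforms). The
highly expressed clade I genes are precisely the ones that became
intron-poor, which motivates a simple transcription/splicing time-cost
model for why.

`intronloss` turns that style of analysis into a reusable, testable
pipeline. Its inputs are things other tools produce: annotated gene
structures, a protein alignment, and rooted gene and species trees. Its
outputs are homologous intron-site matrices, a duplication–loss
reconciliation, a per-branch event history, and time-cost estimates.

## From gene structures to homologous intron sites

All coordinates are 0-based and half-open on the coding strand;
minus-strand records are normalized at the parser boundary, so a record and
its reverse-complement annotation yield identical intron positions (this
round-trip is tested). An intron's *insertion point* is the CDS offset of
the first base of its downstream exon, and its *phase* is that offset
modulo 3: phase 0 falls between codons, phases 1 and 2 inside one. Introns
outside the CDS are retained structurally but excluded from the character
analysis, which concerns coding-region introns only.

Two introns in different genes are the same evolutionary character exactly
when they project to the same alignment column with the same phase.
Projection assigns an intron to the column of the residue containing its
insertion point (phase 1/2) or of the residue immediately following it
(phase 0); with the codon index counted from the CDS start both rules
reduce to "the residue at `codon_index`", which stays unambiguous under
gaps. Equal columns with different phases are always distinct sites, since
a phase shift means the intron–exon junction moved relative to the reading
frame. Alignment jitter can be absorbed with `column_slop_merge()`
(same-phase sites within a configurable column tolerance are merged to the
leftmost column); the default tolerance is 0 — exact column match — because
homology claims should be strict unless the user opts out, and the toy
alignments of the validation suite are exact.

Sites observed in a designated basal reference set (for the fixture: all
osteoglossomorph and elopomorph genes) are the *ancestral* sites, numbered
1..8 left to right. The character matrix scores each gene as present (`1`),
absent (`0`), or missing (`?`, the site's column lies outside the region
the gene's alignment row covers). Genes with no alignment row are dropped
with a warning rather than scored all-missing, which would only dilute the
reconstruction.

## Reconciliation

The gene tree is mapped onto the species tree by the classical LCA
(last-common-ancestor) mapping: each gene-tree node maps to the LCA of the
species of the genes below it. A node is a duplication when two of its
child lineages descend through a common child branch of the mapped species
node. On binary species trees this is exactly the textbook
"`M(v) == M(child)`" criterion; at polytomies it implements *soft*
semantics — a gene-tree resolution of an unresolved radiation is never, by
itself, evidence of duplication, but two gene lineages descending through
the same polytomy branch still are. Implied losses are counted per
gene-tree edge (one per species-tree node traversed without branching, plus
one at the duplication node itself for a duplicated lineage that leaves
it) and are reported against the child node of the branch on which the
lineage disappeared. Branch addressing is by child-node label throughout,
which remains well defined at polytomies.

The validation suite checks this implementation against exhaustive
enumeration: on 200 random gene trees (≤ 6 leaves) × species trees (≤ 4
leaves, some polytomous), the duplication + loss score equals the minimum
over *all* ancestor-consistent mappings.

## Ancestral intron complements and events

Intron presence is reconstructed per site under Dollo parsimony: a site is
gained exactly once — at the LCA of all genes possessing it — and may be
lost repeatedly below that gain. Missing states are non-informative; they
inherit the parent's state and never generate events. When a
reconciliation is available, reconstruction runs on the *gene tree*, so
paralogous copies keep separate histories, and each event is mapped to a
species-tree branch (the uppermost branch on the path between the mapped
parent and child nodes). A Fitch (unordered, minimum-change)
reconstruction is provided as a sensitivity check; it is implemented as
unit-cost dynamic programming, which stays exact on polytomies, with root
ties resolved toward presence and below-root ties toward the parent state
so that no spurious events appear. Both reconstructions are validated
against exhaustive minima over all state assignments on random ≤ 5-leaf
matrices, and Fitch additionally against phangorn's parsimony scores.

Two conventions extend plain site-minimal Dollo; both are explicit
arguments with documented defaults:

* **Duplication inheritance** (`duplication_inherit = TRUE`). A duplication
  copies the parent gene, introns included, so each daughter locus starts
  from the parent's reconstructed complement and losses are placed within
  each copy's own subsequent history. Strictly site-minimal Dollo will
  instead pool a loss shared by *all* descendants of a duplication onto
  the single post-duplication stem edge. On the packaged fixture the
  difference is concrete: ancestral site 2 is absent from every clade I
  gene, so minimal Dollo deletes it once on the clade I stem, whereas the
  inheritance convention replays it once on the otocephalan stem and once
  inside the euteleost wholesale loss — the biologically coherent reading
  when an intron-less structure arises by a single recombination-style
  event that removes all introns at once. Setting the flag to `FALSE`
  recovers strictly minimal Dollo (and the exhaustive-oracle tests run in
  that regime, where no reconciliation is supplied).
* **Root anchoring** (`root_state`, pipeline option `anchor_root = TRUE`).
  Sites defined as ancestral by the basal reference genes are asserted
  present at the root. When reference sampling is dense this coincides
  with the LCA rule; when it is sparse it prevents the gain from sliding
  down to the LCA of the surviving carriers, which would silently convert
  basal losses into a later origin.

Event summaries follow a branch-episode convention: one "event" is one
branch × gene-lineage combination carrying at least one loss, with
per-site counts reported alongside. On the fixture this yields six
loss-bearing episodes and a maximum cumulative loss count of 8 along the
euteleost clade I path, with the salmoniform/esociform clade I gain at a
site homologous to nothing else (its `ancestral_number` is `NA`).

## The cost model

The expression time-cost of a gene with $n$ introns uses four parameters
(all overridable via `cost_params()`): mean exonic content $E = 1$ kbp,
mean intron length $I = 0.25$ kbp, a transcription rate interval of
$[1, 1.5]$ kbp/min, and a splicing time of 3 min per intron. Gene length
is $L(n) = E + nI$, so $L(8) = 3$ kbp and $L(0) = 1$ kbp; the
transcription-time interval is $[L/1.5,\; L/1]$ minutes. Whether splicing
times add across introns is genuinely open — splicing is largely
co-transcriptional — so both readings are implemented: the default
`serial_minimum` mode charges a single 3-minute bound whenever at least
one intron is present (total lower bound for the 8-intron gene:
$2 + 3 = 5$ min), and `per_intron` charges $3n$ minutes (24 min at
$n = 8$). Lengths are reported in kbp to 3 decimals and times in minutes
to 2 decimals. The model deliberately stops at time bounds: expression
levels themselves (the Northern-blot comparisons that motivate the
hypothesis) are wet-lab measurements outside the package's scope.

## The synthetic fixture and the simulator

The packaged fixture is a fully synthetic reconstruction of the
27-species study dataset: 2 osteoglossomorphs, 4 elopomorphs (one per
order), 8 otocephalans in 6 orders, and 13 euteleosts in 11 orders, with
inter-ordinal relationships following the mitogenomic consensus
(Otocephala = Clupeiformes + Ostariophysi; Otophysi = Cypriniformes +
Characiphysi; Salmoniformes sister to Esociformes) and polytomies wherever
the study constrains nothing. Species the study does not name are explicit
placeholders (`Perciformes_sp` and kin). Every gene shares one
deterministic 120-residue toy protein, so the alignment is the identity;
the 8 ancestral sites sit at every 12th codon boundary (phase 0 — real
intron phases vary, but the study's per-intron phases are figure-only
information, so the fixture deliberately does not invent them), and the
salmoniform/esociform novel site at codon 50. Introns are 60 bp with
canonical GT...AG termini. The six lineage-specific exception genes
(`EHE7`, `PeHE1`, `AcHE2`, `MfHE2`, `AcHE4`, `AcHE5`) appear in the
gene-to-species table flagged `exception = TRUE` and carry no committed
structure, since their exact configurations are not stated in text; the
pipeline excludes them unless asked otherwise.

The simulator (`simulate_family()`) evolves gene content and intron
complements top-down over a species tree: designated duplications and
gene deletions, Bernoulli per-branch/per-site intron losses, per-branch
single-origin gains (each novel site arises exactly once, so simulated
histories satisfy the Dollo constraint by construction), and optional
residue substitutions. It emits leaf gene structures, the identity
alignment, the implied gene tree, and the complete ground-truth event
list; output is byte-identical under a fixed seed. It deliberately does
*not* model indels, codon-level sequence evolution, or expression — it
exists to test *reconstruction*, and its alignments are exact, so passing
recovery tests bound what the method can do under ideal alignment, not
under alignment error.

### What event recovery does and does not show

With per-branch/per-site loss probability 0.1 on the default 10-leaf tree
(a bifurcating ingroup plus a basal reference lineage), the pipeline
recovers about 83% of simulated loss events on their exact branch, with
~96% precision, and the validation suite records this measurement against
a 95% target that it does not reach. The shortfall is informative and
intrinsic rather than a coding artifact: when both daughter branches of a
node independently lose a site, the *minimal* history explains the pattern
with a single loss on their common stem, so no parsimony method can
recover the two true events — supplying even the true root complement
raises recall only to ~90% under these rates. Dollo parsimony
systematically under-counts and slightly mis-places losses when loss
probabilities per branch are of order 0.1; at the desk scale of the real
dataset, where observed structures are strongly clustered, this manifests
as the dependence on the duplication-inheritance convention discussed
above rather than as wrong branch placements.

## Numerical and design choices

* Trees must be explicitly rooted; a basal trichotomy in newick is treated
  as unrooted (ape's convention) and refused rather than silently rooted.
* Terminal-intron prediction (`predict_terminal_intron()`) fires only when
  the annotated CDS does not already end in a stop codon, and then scans a
  10 bp window (configurable) past the last annotated exon for a GT donor.
  The window default is a judgement call — the underlying rule is stated
  without one.
* Site identifiers are `c<column>p<phase>`, deterministic given the
  alignment; matrix rows follow input order, columns column-then-phase
  order, so all outputs are reproducible byte for byte.
* Validation problem sizes: exhaustive reconciliation oracles use gene
  trees to 6 leaves over species trees to 4 leaves (200 cases), state
  oracles 5-leaf matrices (200 cases), and event-recovery runs 200
  simulated replicates on the 10-leaf tree — sizes at which exhaustive
  enumeration is exact and the whole suite runs in well under a minute.

## Limitations

* Parsimony only: no likelihood model of intron gain/loss rates across
  branches, hence no uncertainty quantification on event placements.
* The input gene tree is taken as correct; there is no rearrangement step
  to adjudicate weakly supported gene-tree edges against the duplication
  count.
* Intron-site homology is the column + phase rule; no statistical test of
  projection reliability is attempted.
* The fixture's sequences and within-order topologies are synthetic
  stand-ins constrained only by what the study states; they validate the
  machinery, not the biology of any particular species.
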