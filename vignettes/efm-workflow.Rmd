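---
title: "Selecting, comparing and exporting elementary flux modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting, comparing and exporting elementary flux modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efmtools)
```

## Background and scope

An elementary flux mode (EFM) is a minimal set of reactions that can
operate together at steady state: a full-length flux vector $v$ with
$S v = 0$ over the internal metabolites (with $S$ the stoichiometric
matrix) whose support cannot be reduced without losing feasibility. EFM
enumeration scales badly — even mid-sized bacterial networks admit millions
of modes — so practical analyses start from a pre-computed list of modes
for one exchange reaction of interest and must then *select* the handful
worth inspecting, *compare* them, and *render* them as networks.

`efmtools` implements exactly that downstream leg. It deliberately does
not enumerate EFMs, fit fluxes, or run differential expression: modes,
relative fluxes and gene statistics are inputs, produced upstream by
whichever tools the lab already uses.

## Data model and conventions

A `MetabolicModel` holds ordered reaction and metabolite tables, the
sparse stoichiometric matrix, per-reaction GPR trees and subsystem labels.
Reaction order equals SBML document order and defines the **1-based index
space** that EFM files address; a command-line/`parseEfmFile()` flag
accepts 0-based files and normalizes them on entry. The 1-based default
matches the MATLAB/COBRA heritage of most EFM tool chains.

EFM files are deliberately permissive on the way in: any run of spaces or
tabs delimits, blank lines are skipped, duplicate indices within a row are
collapsed with a warning. Out-of-range indices and non-integer tokens are
hard errors with row/column positions, because silently shifting an index
space corrupts every downstream result. Flux files may be *compact* (one
value per active reaction, same token order) or *full-length* (one value
per model reaction); the row width decides, and a full-length row with
nonzero flux off the active set is rejected rather than truncated.

Boundary species (SBML `boundaryCondition`) are excluded from the
steady-state residual in `validateEfmSteadyState()`: exchange reactions
must be allowed net flux across the system boundary, so only internal
species are required to balance. The default residual tolerance is
$10^{-9}$ in flux units, far below the magnitudes of typical relative
fluxes (order 1–100) and far above double-precision noise for these
problem sizes.

## SBML dialects

Models are read from SBML Level 2 and Level 3. GPRs come from fbc-v2
gene-product associations when present, else from legacy
`GENE_ASSOCIATION:` note strings parsed with the conventional grammar
(`and` binds tighter than `or`, parentheses honored, `&`/`|` spellings
accepted). Subsystems come from the groups package when present, else from
`SUBSYSTEM:` notes; both encodings occur in the wild, so both are accepted
on read. Output is always Level 3 Version 1 with fbc-v2 and groups-v1,
today's de-facto standard for COBRA-style models. Identifiers are written
verbatim (genes additionally get SId-safe alias ids, with the verbatim id
as the fbc label). Flux bounds in written submodels are wide-open
defaults: a submodel is a structural artifact for visualization, not a
calibrated simulation.

## Yield analysis

The yield of a mode is the flux magnitude of a chosen output (release)
reaction divided by that of an input (uptake) reaction. Two choices are
deliberate:

* **Magnitudes, not signed values.** Tools encode exchanges differently —
  some split reversible exchanges into forward/backward pairs with
  opposite sign conventions. Magnitudes make the yield
  convention-independent.
* **Tie handling in extreme selection.** All modes within a relative
  tolerance (`tol = 1e-9`) of the extreme are returned, ordered by
  ascending mode length and then ascending id, so the first element is
  always "the shortest mode at that extreme" — the natural visualization
  candidate. Large mode collections routinely contain dozens of modes
  sharing the minimal yield, so returning a single arbitrary one would
  hide real degeneracy.

Yield is scale-invariant: multiplying a mode's flux vector by any $c > 0$
(EFMs are rays, so the scale is arbitrary) leaves it unchanged; this is a
tested property.

## GPR mapping

Differential-expression results live on genes; mode selection needs them
on reactions. Each reaction's GPR tree is evaluated recursively: `AND`
(complex) nodes adopt the child with the *minimum* ranking value, `OR`
(isozyme) nodes the *maximum*; children whose whole subtree lacks data are
ignored at both node kinds, and a reaction whose tree evaluates empty is
flagged uncovered rather than dropped.

The ranking quantity is a genuine modeling choice: "the gene with minimum
expression" is only well-defined once "expression" is fixed, and
differential-statistics tables do not always carry an expression column.
The package therefore exposes `rankBy = "expression"` (default) with
`"abs_log2_fc"` as an explicit fallback, rather than silently guessing.
Ties are broken by rule order (first child wins); with continuous
expression values ties essentially only arise when the same gene appears
twice in a rule, where the outcome is identical either way.

## Mode enrichment

Each mode is a reaction set; the question is whether it contains more
significantly up- (or down-) regulated reactions than chance would give.
The package uses the one-sided hypergeometric upper tail
$P(X \ge k)$ over **mapped reactions only** — reactions without data are
invisible to the test, appearing in neither $n$ nor $N$ — with
Benjamini–Hochberg adjustment across the tested modes. Conventions at the
edges: a mode with no mapped reactions gets $p = 1$; $k = 0$ gives exactly
$p = 1$ (the tail includes $X \ge 0$); an empty significant background
($K = 0$) warns and returns all-ones.

A self-contained hypergeometric test was chosen over delegating to a
gene-set-analysis package: the statistic is elementary, deterministic, and
verifiable against a combinatorial enumeration oracle, which the test
suite does exhaustively for all $N \le 25$ (agreement within $10^{-12}$)
and literally — every subset enumerated — for small $N$. The background
defaults to *all* mapped reactions in the model, not just those in some
mode, since data are mapped model-wide before enrichment; it is a
parameter.

When no direction is forced, both directions are tested and each mode is
labeled with whichever attains the smaller adjusted p (ties to "up") —
two-direction conflicts have no canonical resolution, so the rule is
simple and documented.

## Submodel extraction

Extracting mode $e$ keeps exactly $e$'s reactions in order, then prunes:
metabolites not touching a retained reaction and genes not appearing in a
retained GPR disappear (the no-orphan rule, tested as an invariant). GPR
trees are never pruned gene-by-gene — a rule is a statement about the
enzyme, and partial rules would misrepresent it.

Ubiquitous (currency) metabolites — ATP, protons, water and kin — connect
so many reactions that their edges obscure pathway structure. The shipped
default list is a plain-text file of base names expanded per compartment
(`atp_c`, `atp_e`, ...), fully overridable; removal deletes the species
and its edges but **never** deletes a reaction, even one left with no
participants, because reaction nodes carry the flux annotations mapped
later. Designated input/output species can be declared protected, making
their removal an error instead of a silent hole in the network. The
extraction records each reaction's original model index on the submodel
(`orig_index`), so index-keyed fluxes remain mappable after extraction.

## Cross-mode comparison

**Subsystem occurrence** is the row-normalized distribution of each mode's
reactions over subsystem labels. Reactions without a label pool under a
reserved `"(unassigned)"` column; a reaction with $m$ labels (possible in
groups-annotated models) counts $1/m$ per label so rows always sum to 1.
Fractions are stored at full precision and formatted (one decimal) only at
export.

**Backbone.** $f_r$ is the fraction of modes containing reaction $r$; the
backbone at cutoff $\tau$ is $\{r : f_r > \tau\}$. The strict inequality
mirrors "present in more than $\tau$" phrasing; an inclusive `>=` mode is
a flag, since both readings occur. Backbone selection is downward-monotone
in $\tau$ — raising the cutoff can only shrink the set — and a reaction in
every mode survives every valid $\tau$; both are tested as theorems over
random collections. The occurrence histogram over right-closed bins sums
to the size of the reaction union.

## Graph export

`buildGraph()` produces the bipartite species–reaction network (plus gene
nodes on request): substrate edges metabolite→reaction, product edges
reaction→metabolite, catalysis edges gene→reaction, with stoichiometric
coefficients on the metabolic edges. Node ids carry `m:`/`r:`/`g:`
prefixes because SBML keeps species, reactions and genes in separate id
spaces while flat graph formats do not. Reversible reactions stay one node
with a `reversible` attribute and edge directions from stoichiometry
signs. A reaction is flagged `is_exchange` when it touches a boundary
species or has at most one participant — the uptake/release points that
styles highlight. Flux mapping puts one constant magnitude on all
metabolic edges of a reaction (one relative flux per reaction, a tested
invariant). Serialization targets GraphML (typed attributes, via igraph),
SIF plus node/edge attribute TSVs (the edge type is the interaction
token), and node-link JSON; layout, styling and interactive exploration
are left to the visualization tool.

## The synthetic bundle

`generateFixture()` builds the study system used throughout the tests: a
two-compartment factory where a boundary substrate is taken up,
transported, converted to a product by one of `nRoutes` parallel ATP-consuming
routes (route $i$ has product stoichiometry $c_i$ on a 0.5–2.0 grid, and
an ATP-regeneration step closes the energy loop), and the product is
exported — plus one futile-cycle mode with no exchanges. Each route is one
planted mode with consistent fluxes, so by construction:

* every mode satisfies $S v = 0$ on internal species exactly;
* route $i$'s yield is exactly $c_i$ (flux scales are powers of two, so
  the ratio recovered from the serialized files is bit-exact);
* backbone fractions are known closed-form counts;
* exactly one route carries significantly upregulated genes
  (others draw $p \in [0.2, 0.9]$ and cannot cross the 0.05 cutoff), making
  its mode the unique most-enriched one, with known contingency counts.

One gene is withheld from the statistics table and one orphan gene is
declared in the model, exercising missing-data paths. The generator is a
deterministic function of its parameters and seed (byte-identical files on
repetition), and defaults to 24 routes — 25 modes — which keeps the full
pipeline in the tests under a second.

What the bundle does **not** emulate: realistic network sizes (thousands
of reactions), long modes with hundreds of reactions, correlated gene
statistics from real RNA-seq, multi-compartment eukaryotic structure, or
reversible-reaction sign gymnastics of real exchange encodings. Passing
tests therefore demonstrate correctness of the algorithms and formats, not
robustness to every quirk of curated reconstructions.

## Problem sizes and numerical choices

The test suite runs the enrichment oracle exhaustively for all
$N \le 25$ (~23,000 cases, formula oracle; literal subset enumeration
spot-checks at $N \le 10$), 1000 random GPR trees of depth ≤ 4 against a
brute-force evaluator, 200 random mode collections for backbone
monotonicity, and 50 submodel SBML round trips — together about twenty
seconds on one core. These sizes were chosen so each property space is
covered densely while the suite stays fast enough to run on every change.

Other numerical decisions collected in one place: yield tie tolerance
$10^{-9}$ (relative); steady-state tolerance $10^{-9}$ (absolute, flux
units); hypergeometric tails via `stats::phyper` (log-space accurate);
BH via `stats::p.adjust`; GPR tie-break = first child in rule order;
occurrence histograms right-closed; all file writes atomic
(temp-file-then-rename) so a crashed run never leaves a truncated
artifact.

## Known limitations

* SBML support targets the COBRA dialect (core + fbc + groups + notes);
  exotic constructs (species types, algebraic rules, comp submodels) are
  ignored.
* Enrichment treats reactions as exchangeable units; no account is taken
  of mode length bias beyond what the hypergeometric conditioning gives.
* The direction label of a mode enriched in both directions is a
  convention, not an inference.
* Submodels are structural: they are not guaranteed flux-consistent or
  simulatable, and written bounds are intentionally uninformative.
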