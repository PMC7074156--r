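# efmtools

Selection, analysis and network export of **elementary flux modes (EFMs)**
computed from genome-scale metabolic models.

EFM enumeration tools (TreeEFM, efmtool, and relatives) emit thousands of
modes as bare lists of reaction indices. The hard part comes afterwards:
deciding *which* modes matter for the biological question and turning them
into something a human can read. `efmtools` covers that downstream leg for
systems-biology researchers working with COBRA-style SBML models:

* **import** EFM files (one mode per line, whitespace-separated reaction
  indices) and their aligned relative-flux files, validated against the
  model's reaction index space;
* **select** modes by reaction presence, by product yield on a substrate,
  or by over-representation of differentially expressed genes mapped
  through gene-protein-reaction (GPR) rules;
* **compare** mode collections via subsystem-occurrence profiles, backbone
  (core-reaction) extraction and pairwise overlap;
* **extract** any single mode as a pruned standalone SBML submodel; and
* **export** annotated bipartite metabolite–reaction(–gene) networks to
  GraphML, SIF or JSON for Cytoscape and friends.

## The statistics at the core

**Yield.** For a mode with relative fluxes $v$, the product yield on a
substrate is

$$Y = \frac{|v_{\text{out}}|}{|v_{\text{in}}|}$$

where $v_{\text{in}}$ and $v_{\text{out}}$ are the fluxes of the chosen
uptake and release reactions. Magnitudes make the result independent of the
sign convention of split forward/backward exchange reactions.

**GPR mapping.** Gene-level statistics (p-value, log2 fold change, an
expression ranking value) are pushed to the reaction level by recursive
evaluation of each reaction's GPR tree: an `AND` node (enzyme complex)
adopts the record of its minimum-expression child — the limiting subunit —
and an `OR` node (isozymes) the maximum-expression child. Genes without
data are ignored at both node kinds.

**Mode enrichment.** Each EFM is treated as a reaction set and tested for
over-representation of significantly regulated reactions with the one-sided
hypergeometric upper tail over the mapped-reaction universe,

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n),$$

with $n$ mapped reactions inside the mode, $k$ of them significant in the
tested direction, and $K$ of $N$ in the background; p-values are
Benjamini–Hochberg adjusted across modes.

**Backbone.** With $f_r$ the fraction of modes containing reaction $r$, the
backbone at cutoff $\tau$ is $\{r : f_r > \tau\}$ — the conserved core of a
mode collection, with occurrence percentages ready to annotate reaction
nodes.

## Worked example

Everything below runs on the package's own synthetic bundle — a
substrate-to-product toy model with six parallel conversion routes of known
stoichiometric yields, one planted significantly upregulated route, and a
futile cycle:

```r
library(efmtools)
bundle <- generateFixture(dir = "demo", nRoutes = 6, seed = 4)
model  <- readModelSBML("demo/model.xml")
model
#> MetabolicModel: toyFactory6
#>   13 reactions, 10 metabolites, 17 genes, 2 compartments
#>   GPR rules on 9 reactions; subsystem labels on 13

efms <- parseFluxFile("demo/fluxes.txt",
                      parseEfmFile("demo/efms.txt", nReactions(model)))
efms
#> EfmSet: 7 EFMs over 13 reactions
#>   EFM length: min 2, median 6, max 6
#>   relative fluxes: present

out_idx <- match("EX_prod", reactionIds(model))
routes  <- filterEfmsByReaction(efms, out_idx)   # drop the futile cycle
y <- computeYields(routes, inputRxn = 1, outputRxn = out_idx)
head(y, 3)
#>   efm_id input_flux output_flux yield
#> 1      1          8         4.0   0.5
#> 2      2          8         6.4   0.8
#> 3      3          8         8.8   1.1
selectExtremeYield(y, "max", routes)
#> [1] 6
```

The yields are the planted route stoichiometries (0.5–2.0); mode 6 is the
highest-yield route. Enrichment recovers the planted upregulated route:

```r
rstats <- mapGeneStatsToReactions(model, bundle$geneStats)
enr <- enrichEfms(efms, rstats, direction = "up")
subset(enr, p_raw < 1)
#>   efm_id direction k n K N     p_raw p_adjusted
#> 2      2        up 1 4 1 9 0.4444444          1
```

Mode 2 is the only mode containing the one significant reaction (k = 1 of
its n = 4 mapped reactions, against K = 1 of N = 9 in the background).
Extract it as a submodel without currency metabolites, and export the
flux-annotated network:

```r
sub <- extractSubmodel(model, efms, 2, ubiquitous = defaultUbiquitousIds(model))
sub
#> MetabolicModel: toyFactory6_EFM2
#>   6 reactions, 6 metabolites, 6 genes, 2 compartments
#>   GPR rules on 4 reactions; subsystem labels on 6
writeSubmodelSBML(sub, "demo/toyFactory6_EFM2.xml")

g <- mapFluxes(buildGraph(sub), efms, id = 2)
g
#> AnnotatedGraph: 18 nodes (6 gene, 6 metabolite, 6 reaction), 16 edges
writeGraph(g, "demo/efm2.graphml", "graphml")

extractBackbone(efms, tau = 0.8)$selected
#> [1]  1  2  9 10 11
```

The backbone above 80% is exactly the five reactions shared by all six
routes (uptake, two transports, ATP regeneration, release), each present in
6 of 7 modes ($f_r \approx 0.857$).

## Command line

A thin wrapper over the same functions mirrors the workflow stages:

```sh
CLI=$(Rscript -e 'cat(system.file("scripts", "efmtools-cli.R", package = "efmtools"))')
Rscript $CLI fixtures --n_routes 6 --seed 4 --out_dir demo
Rscript $CLI yield --model demo/model.xml --efms demo/efms.txt \
    --fluxes demo/fluxes.txt --input_rxn EX_sub --output_rxn EX_prod --out_dir out
Rscript $CLI extract --model demo/model.xml --efms demo/efms.txt \
    --efm_id 2 --use_default_ubiquitous true --out_dir out
```

Subcommands: `import`, `filter`, `yield`, `enrich`, `extract`,
`subsystems`, `backbone`, `export`, `fixtures`. Options may come from a
flat `key = value` file via `--config`; flags override it. Every run writes
a `<subcommand>_log.json` with parameters, package version and counts.

## Graph attribute names

Visualization styles can bind to these exact attributes (GraphML keys, SIF
companion-TSV columns, JSON fields):

| element | attributes |
|---|---|
| node | `type` (metabolite/reaction/gene), `label`, `compartment`, `subsystem`, `index`, `is_exchange`, `reversible`, `occurrence_pct`, `log2_fc`, `p_value`, `no_data` |
| edge | `type` (substrate/product/catalysis), `stoichiometry`, `flux` |

Node ids are namespaced `m:`, `r:`, `g:`; substrate edges run
metabolite→reaction, product edges reaction→metabolite, catalysis edges
gene→reaction.

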