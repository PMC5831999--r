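# lncnets

Weighted co-expression network analysis of long noncoding RNAs (lncRNAs)
for two-colour expression arrays in an age-stratified sepsis design.

## The problem

Sepsis incidence and mortality rise steeply with age, and transcriptome
studies of innate-immunity cells have focused almost entirely on
protein-coding genes. Given neutrophil expression profiles from adult and
elderly subjects, septic and healthy (a 2 × 2 design with six subjects per
cell), the question is which lncRNAs (i) behave as hubs inside
co-expression networks, (ii) change their wiring between the adult and
elderly networks, and (iii) show an inverted sepsis response between age
groups — the candidates most likely to participate in regulatory circuits
behind the poorer outcome of elderly patients.

`lncnets` is for computational biologists who want that workflow as a
tested, scriptable R package: each stage is an exported function, and a
synthetic-data generator with full ground truth makes every stage
verifiable without access to patient data.

## The method

1. **Probe reannotation** — array probes (BED12/PSL alignments, ≤ 2
   mismatches, ≤ 4 genomic loci) are classified against gene catalogs
   (GENCODE > Broad > LNCipedia > NONCODE) by a strict hierarchy on
   same-strand exon overlap: protein-coding ▸ pseudogene ▸ lncRNA ▸
   poorly annotated.
2. **Detection filter** — keep genes flagged well-above-background in ≥ 5
   of 6 subjects in at least one design cell.
3. **Clustering** — UPGMA on 1 − Pearson r over the top-5 %
   highest-CV lncRNAs groups samples by disease status.
4. **Differential expression** — a gene is a DEG at α = 0.01 only if
   *both* a SAM-style statistic *d* = (x̄₁ − x̄₂)/(s + s₀) and a rank
   product (geometric mean of ranks over all sepsis × control pairings)
   are significant, with p-values from the orbit of sepsis/control label
   assignments.
5. **Networks** — per age group, adjacency *a₍ᵢⱼ₎* = |r|^β with β = 13,
   connectivity *k* = Σ a, and the unsigned topological overlap matrix.
6. **Differential connectivity** — per gene the major connectivity
   max(k_adult, k_elderly) and the ratio major/minor; among DEGs, the top
   15 % by major connectivity and the top 20 % by
   mean(k) × ratio are selected.
7. **Pathway similarity** — an lncRNA is tied to a pathway when its mean
   adjacency to the pathway's protein-coding members exceeds the median
   of the members' own mean within-pathway adjacencies; hypergeometric
   enrichment with the detected-gene background (p < 0.05, overlap > 4)
   ranks terms.
8. **Cis analysis** — each DE lncRNA's nearest protein-coding neighbour is
   tested against the empirical |r| distribution of random detected-gene
   pairs, Bonferroni-corrected.

See `vignettes/coexpression-methods.Rmd` for the full model, parameter
defaults and design decisions.

## Worked example

```r
library(lncnets)

gen     <- generate_expression_dataset(sepsis_study_config(seed = 1))
catalog <- generate_gene_catalog(gen$dataset$genes, seed = 2)
cfg <- pipeline_config(dataset  = gen$dataset,
                       pathways = gen$truth$module_pathways,
                       catalog  = catalog,
                       out_dir  = "run1", seed = 1)
res <- run_pipeline(cfg)
```

```
filter: 1839/3000 genes detected
cluster: 20 variable lncRNAs; 2-cut status concordance 1.000
deg: adult=294 elderly=240 union=310
diffconn: DEG mean k=63.2 non-DEG mean k=1.2 p=8.04e-170
pathway: 2 enriched terms; 3 consistent-hub and 3 age-divergent candidate lncRNAs
cis: 47 DE lncRNA-neighbour pairs, 0 significant, 0 proximal (<4 kb)
```

The detection filter keeps 1839 of 3000 genes; clustering the 20 most
variable lncRNAs separates sepsis from control samples perfectly; DEGs are
far more connected than non-DEGs (mean major connectivity 63.2 vs 1.2);
and the two candidate tables recover exactly the planted structures:

```r
res$pathway$candidates$consistent_hubs
#   gene_id k_elderly k_adult   type fc_elderly p_elderly fc_adult p_adult
#    g00001      80.9     122 lncRNA      0.136     0.005    0.105   0.005
#    g00003      82.5     111 lncRNA      0.125     0.005    0.131   0.005
#    g00002      75.7     106 lncRNA      0.123     0.005    0.124   0.005

res$pathway$candidates$age_divergent
#   gene_id k_elderly k_adult   type fc_elderly p_elderly fc_adult p_adult
#    g00053     39.57   117.9 lncRNA      0.456     0.005     8.25   0.005
#    g00051      3.01   117.7 lncRNA      0.461     0.055     7.69   0.005
#    g00052      1.06    97.1 lncRNA      0.745     0.650     7.63   0.005
```

The consistent hubs (g00001–g00003) are the planted lncRNA hubs of the
both-group module: strongly connected in *both* networks and
down-regulated ~8-fold in sepsis in both age groups. The age-divergent
candidates (g00051–g00053) are the planted hubs of the adult-only module:
highly connected in the adult network only, strongly up in adult sepsis
but mildly *down* in elderly sepsis — the inverted pattern. The cis stage
finds no significant lncRNA–neighbour correlations, the expected outcome
when no cis regulation is planted. Every table is also written as TSV
under `out_dir`, with a machine-readable `summary.json` and a `run.log`.

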