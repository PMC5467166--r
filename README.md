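# comod — weighted gene co-expression modules and trait association

`comod` implements the network stage of an islet transcriptomics analysis:
finding groups of co-expressed genes in log2 expression data from human
pancreatic islet donors, summarizing each group by its eigengene, asking
which groups track type 2 diabetes (T2D) and related clinical traits, and
probing candidate regulators of the disease-associated module with gene-set
enrichment, hub-connectivity statistics, cross-dataset signature concordance
and a causal inference test for intervention experiments. Its audience is
anyone analysing a genes × samples expression matrix together with a donor
phenotype table — and anyone who wants a fully synthetic, seeded stand-in
cohort to exercise such a pipeline end to end.

## The model

For genes *i*, *j* with expression vectors *x<sub>i</sub>*, *x<sub>j</sub>*
across samples:

- **Similarity** s<sub>ij</sub> = |cor(x<sub>i</sub>, x<sub>j</sub>)|
  (unsigned Pearson).
- **Adjacency** a<sub>ij</sub> = s<sub>ij</sub><sup>β</sup>, the soft
  threshold. β is the smallest power for which the degree distribution is
  approximately scale-free: bin the connectivities
  k<sub>i</sub> = Σ<sub>j≠i</sub> a<sub>ij</sub>, regress log₁₀ p(k) on
  log₁₀ k, and require R² ≥ 0.8.
- **Topological overlap**
  ω<sub>ij</sub> = (ℓ<sub>ij</sub> + a<sub>ij</sub>) /
  (min(k<sub>i</sub>, k<sub>j</sub>) + 1 − a<sub>ij</sub>) with
  ℓ<sub>ij</sub> = Σ<sub>u≠i,j</sub> a<sub>iu</sub>a<sub>uj</sub>; two genes
  overlap when they share their network neighbourhood. Modules are cut from
  the average-linkage tree of d<sub>ij</sub> = 1 − ω<sub>ij</sub> and then
  refined by eigengene correlation (|kME| ≥ 0.3).
- **Eigengene**: first principal component of a module's standardized
  expression; regressed on traits (logistic for T2D status, linear for
  HbA1c and log-transformed insulin secretion), adjusted for age, sex and
  BMI.
- **Enrichment**: hypergeometric / Fisher tests of gene-set overlap with
  Benjamini–Hochberg correction; hub analyses compare intramodular
  connectivity k<sub>in</sub> between gene sets.
- **Causal inference test**: for a dose L, mediator G and outcome T, four
  component conditions (L–T association, L–G given T, G–T given L, and a
  permutation-based equivalence test of T ⫫ L given G) combine by
  intersection-union into an omnibus p-value for L → G → T; swapping G and
  T gives the reactive omnibus.

## Worked example

```r
library(comod)
syn <- generate_cohort(seed = 3)                 # 64 donors, 5 planted modules
net <- build_network(syn$expression)
net
#> Co-expression network: 300 genes
#>   soft power beta = 9
#>   mean connectivity = 0.06107

part <- refine_modules(syn$expression, detect_modules(net$D))
part
#> Module partition: 5 modules, 48 background genes of 300
#>  1  2  3  4  5
#> 51 51 50 50 50

eig <- module_eigengene(syn$expression, part, 1)
associate_eigengene_trait(eig, syn$phenotype, "hba1c",
                          covariates = c("age", "sex", "bmi"))
#>   predictor_id trait_name  model    beta         se      p_value  n  covariates converged
#> 1          ME1      hba1c linear 0.48347 0.06069807 6.266892e-11 64 age,sex,bmi      TRUE
```

The five planted modules are recovered (the generator planted 50-gene
blocks; 48 pure-noise genes stay unassigned), and module 1's eigengene shows
the planted HbA1c effect (true effect 0.4 per factor SD; estimate 0.48 ±
0.06, covariate-adjusted, n = 64).

A causal triplet — dose 0/0.1/1, mediator driven by dose, outcome driven by
the mediator:

```r
tri <- generate_cit_triplet(300, "causal", seed = 11)
cit_test(tri$L, tri$G, tri$T, n_perm = 500, seed = 11)
#> Causal inference test (n = 300 , 500 permutations)
#>   causal   p1-p4: 4.69e-10 1.15e-29 4.97e-14 0.002 -> omnibus 0.002
#>   reactive p1-p4: 7e-39 0.615 4.97e-14 0.00599 -> omnibus 0.615
#>   verdict: causal
```

`run_pipeline(default_pipeline_config())` chains every stage (simulation or
file input → network → modules → eigengenes → trait association → enrichment
→ hub analyses) and writes all results plus a seeded run log under the
configured output directory.

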