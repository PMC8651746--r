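# discage

Network-based prioritization of significant cancer genes from somatic
mutation data.

## The problem

Tumor cohorts exhibit a "long tail": a few genes are mutated in many
patients, while hundreds of genes are mutated in just a handful of samples
each. Some of those infrequently mutated genes are true drivers, but a
frequency ranking cannot tell them apart from passengers. Driver genes,
however, tend to interact with one another in protein-interaction and
functional networks. `discage` ranks genes by combining a
functional-impact-weighted mutation frequency with the mutation influence a
gene receives from its network neighborhood, so that low-frequency genes
sitting in mutated neighborhoods rise in the ranking.

## The method

Given a MAF file and one or more undirected gene interaction networks:

1. **Preprocessing** — keep eleven whitelisted somatic variant classes;
   remove hypermutated samples whose mutation count exceeds
   `Q3 + 4.5 * IQR`.
2. **Weighted mutation matrix** — `wmm[p, g]` is the mean weight `w(vc)` of
   patient `p`'s mutations in gene `g` (user-definable weights).
3. **Gene score** — weighted frequency `wf(g) = (1/|P|) * sum_p wmm[p, g]`,
   max-normalized to `nwf`.
4. **Consensus network** — the union of the input networks, each edge
   weighted by the fraction of networks containing it.
5. **Spreading strength** — for each consensus edge, in both directions,
   `ss(gi, gj) = (1 + r_i * r_j_out) * p_ij`, where `r_i` is `gi`'s total
   incident weight and `r_j_out` sums `gj`'s edges leading outside `gi`'s
   neighborhood; globally max-normalized to `nss`, yielding a directed gene
   spreading strength network (GSSN).
6. **Neighbor influence and ranking** — each gene accumulates
   `r(g) = sum_k nwf(k) * nss(k -> g)` from its neighbors, normalized to
   `nr`; the final score is `ms(g) = nwf(g) + nr(g)` and genes are ranked
   by decreasing `ms`.

Optionally, each input network is first **enriched** by
overlap-coefficient link prediction (`ssc` on closed neighborhoods) with a
threshold calibrated from known pathways versus random gene sets.
Rankings can be evaluated against driver-gene benchmark lists with
precision and relevance-weighted DCG. A seeded synthetic-cohort generator
with planted driver modules supports end-to-end testing without any
external downloads.

## Worked example

Simulate a toy study (60 patients, 80 genes, 3 planted driver modules of 5
genes each) and run the full pipeline on it:

```r
library(discage)
cfg <- fixture_config(seed = 11)
fx  <- write_fixtures(cfg, "fixtures")
res <- run_discage(fx[["maf"]], list(fx[["network_1"]], fx[["network_2"]]))
#> read 252 mutation records (53 patients, 80 genes)
#> variant-class whitelist kept 208 records
#> hypermutation threshold Q3 + 4.5*IQR = 7.5; removed 3 of 49 samples
#> consensus network: 80 genes, 221 edges
#> max raw spreading strength = 151
print(res$ranking, n = 5)
#> gene_ranking: 80 genes (ties broken lexicographic by gene symbol )
#>   rank gene        nwf        nr       ms
#> 1    1 G048 1.00000000 0.5005986 1.500599
#> 2    2 G003 0.62857143 0.6968178 1.325389
#> 3    3 G012 0.85714286 0.2606142 1.117757
#> 4    4 G049 0.71428571 0.3801331 1.094419
#> 5    5 G005 0.05714286 1.0000000 1.057143
```

The log shows each pipeline stage: 252 simulated mutation records are
filtered to 208 whitelisted ones, 3 hypermutator samples exceed the outlier
threshold of 7.5 mutations and are dropped, and the two noisy replicate
networks merge into an 80-gene consensus. In the ranking, `G048` combines
the cohort's top mutation frequency (`nwf = 1`) with substantial neighbor
influence; `G005` is the long-tail case the method exists for — mutated in
barely any patients (`nwf = 0.057`) but receiving the maximal influence
(`nr = 1`) from its mutated module neighbors, it ranks 5th of 80, far above
its frequency rank.

Evaluating against the planted truth:

```r
truth <- benchmark_bundle(general = list(planted = read_gene_list(fx[["truth"]])))
precision_at(res$ranking, truth, 15)
#> [1] 0.7333333
dcg_at(res$ranking, truth, 15)
#> [1] 4.66348
```

11 of the 15 top-ranked genes are planted drivers.

A thin command-line wrapper with `run`, `enrich-network`, `evaluate` and
`simulate` subcommands is provided at `inst/cli/discage.R`:

```sh
Rscript inst/cli/discage.R simulate --out-dir fixtures --seed 11
Rscript inst/cli/discage.R run --maf fixtures/cohort.maf \
    --networks fixtures/network_1.tsv,fixtures/network_2.tsv --out results
```

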