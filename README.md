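# kelpRefugia

Kelp forests at the warm, equatorward edge of a species' range are both the
most threatened by ocean warming and the most likely to harbour unique
evolutionary diversity left over from glacial refugia. `kelpRefugia`
implements the two analyses used to test that idea for the Laminarian kelp
*Ecklonia radiata* in the south-west Pacific:

1. **COI haplotype diversity and networks.** From an aligned set of
   mitochondrial COI barcodes (~658 bp) and a sample-to-population map, the
   package trims degenerate amplification primers, runs a
   protein-translation quality check, applies a complete-deletion site
   filter, collapses sequences into haplotypes, computes the standard
   diversity panel per population, and builds a statistical-parsimony
   (Templeton–Crandall–Sing style) haplotype network with a 95% connection
   limit and inferred intermediate nodes.
2. **Glacial hindcast of kelp cover.** Mean annual sea-surface temperature
   (SST) is pushed through a unimodal thermal response curve (peak cover at
   ~23 °C, zero at ≥26 °C), masked to the habitable depth band (0–80 m below
   the scenario's sea level, which for the Last Glacial Maximum means shelf
   that is 120–200 m deep today), averaged latitudinally, and compared
   between scenarios as an equatorward range shift in degrees of latitude.

A synthetic-data module generates every input the pipeline needs — a
deterministic 119-sequence, 6-haplotype study fixture and gridded
SST/bathymetry fields — so the whole workflow runs and is tested offline.

## The statistics

For a population of `n` sequences carrying haplotypes at frequencies
`p_i = n_i / n`:

- **Haplotype diversity** (unbiased): `Hd = n (1 − Σ p_i²) / (n − 1)` — the
  probability that two sequences drawn without replacement differ.
- **Mean pairwise differences**: `K = Σ_{i<j} n_i n_j d_ij / C(n, 2)`, with
  `d_ij` the Hamming distance between haplotypes.
- **Nucleotide diversity**: `π = K / L_used`, where `L_used` counts the
  alignment columns kept by complete deletion.
- **Segregating sites** `S`: retained columns showing ≥2 bases.
- **Parsimony probability**: for two sequences of `L` analysed sites
  differing at `j`, the probability that no site was hit more than once,
  under per-site Poisson substitution counts with Jukes–Cantor multiple-hit
  visibility and plug-in divergence `q = j/L`. The network's connection
  limit is the largest `j` keeping this probability ≥ 0.95.

## Worked example

```r
library(kelpRefugia)

run <- runGenetics(list(fixture = TRUE, seed = 1, primers = TRUE,
                        outDir = "genetics_out"))
formatDiversityReport(run$report)
#>     population   N     K S       pi H    Hd L_used
#> 1   SA_Vic_Tas  63 0.502 1 0.000763 2 0.502    658
#> 2          NSW  26 0.077 1 0.000117 2 0.077    658
#> 3          QLD  12 1.152 5 0.001750 4 0.636    658
#> 4 LHI_NI_KI_NZ  18 0.000 0 0.000000 1 0.000    658
#> 5          All 119 0.629 7 0.000956 6 0.528    658
run$limit
#> ParsimonyLimit: 8 steps at 95% confidence (L_used = 658)
run$network
#> HaplotypeNetwork: 6 sampled + 2 inferred nodes, 7 edges, 1 component(s)
```

The report is the classic diversity table: southern Queensland is by far the
most diverse population (4 haplotypes, Hd = 0.636, S = 5 in just 12
sequences) while New South Wales is nearly monomorphic (Hd = 0.077) — the
signature of a low-latitude refugium feeding a young, expanded range. The
network joins all six haplotypes into one component; the rarest Queensland
haplotype sits three substitutions (two inferred intermediates) from the
widespread central haplotype, well inside the 8-step connection limit.

```r
hind <- runHindcast(list(grid = list(noiseSd = 0), outDir = "hindcast_out"))
hind$shift
#> $peak_shift_deg    [1] 5
#> $centroid_shift_deg[1] 4.96
#> $sea_level_offset_m[1] 120
#> $cooling_degC      [1] 4
```

On the synthetic shelf (linear 0.8 °C/° SST gradient), a uniform 4 °C
glacial cooling moves the cover peak 5° of latitude equatorward — the
analytic expectation `ΔT / gradient` — and the glacial depth mask selects
exactly the cells that are 120–200 m deep at present-day sea level.

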