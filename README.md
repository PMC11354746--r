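# crhaplo

Population-level analysis of aligned mitochondrial control-region (CR)
sequences — and of linked coding markers such as COI — for phylogeographic
studies of non-model animals: haplotype collapsing with explicit
IUPAC-ambiguity and NUMT-artefact policies, variability profiling along the
CR, genetic distances with bootstrap errors, nucleotide-diversity
decomposition among populations, strict-clock dating, and from-scratch
median-joining haplotype networks. It is aimed at researchers who have a
multiple-sequence alignment and a sample-to-population table and want the
full descriptive pipeline that papers in this area report (haplotype
counts, segregating sites, distance tables, N_ST matrices, dated splits,
networks) in one reproducible, scriptable place.

## The statistics at its core

* **Tamura 3-parameter distance.** For an aligned pair with transition
  proportion *P*, transversion proportion *Q* and G+C content θ over the
  compared sites (*h* = 2θ(1−θ)):

  d = −h·ln(1 − P/h − Q) − ½(1 − h)·ln(1 − 2Q)

  correcting multiple hits under transition/transversion and G+C-content
  bias; at θ = 0.5 it reduces to the Kimura 2-parameter distance. The
  uncorrected p-distance (P + Q) is also provided. Standard errors come
  from bootstrap resampling of alignment columns (100 replicates by
  default).

* **Nucleotide-diversity decomposition.** With s groups weighted equally
  (w = 1/s), π_i the mean pairwise difference within group i and π_ij the
  mean between groups i and j:

  π_S = (1/s) Σ π_i,  π_T = Σ_i Σ_j w² π_ij,  δ_ST = π_T − π_S,
  N_ST = δ_ST / π_T

  N_ST is the proportion of total diversity attributable to differences
  among populations. π uses **all** samples including identical
  haplotypes; lineage-level distance tables use **unique** haplotypes.

* **Strict molecular clock.** time (ka) = 1000 · d(%) / rate(%/My), with
  linear error propagation; and the rate ratio k between two linked
  markers at the same split, a diagnostic for saturation of the slower
  marker.

* **Median-joining networks.** ε-relaxed minimum spanning networks over
  Hamming distances, augmented with quasi-median (Steiner) vectors
  (majority state per site, branching where a triplet disagrees three
  ways), iterated to a fixed point and pruned to minimal paths; plus the
  minimum substitution count separating two haplogroups.

A seeded sequence simulator (stationary G+C bias, transition/transversion
ratio κ, star or chained genealogies, optional introgression, plantable
conserved blocks and poly-T stretches) generates data with known truth for
every stage.

## Worked example

```r
library(crhaplo)

sim <- simulate_alignment(n_groups = 2, samples_per_group = 8,
                          seq_length = 691, within_div = 0.004,
                          between_div = 0.05, seed = 42)
aln  <- sim$alignment
haps <- collapse_haplotypes(aln)
classify_sites(aln)
#> Sites: 691 bp; S = 50 ; PIS = 28

d <- group_mean_distance(haps, metric = "t3p", scope = "between",
                         groups = c("g1", "g2"), bootstrap = 100, seed = 42)
d
#> T3P between-group distance (g1 / g2): 4.629 ± 0.761 % over 64 pairs
divergence_time(d$mean, d$se, rate = 3.54)
#> Divergence time: 1308 ± 215 ka (distance 4.63 ± 0.76 %, rate 3.54 %/My)

decompose_diversity(aln, bootstrap = 100, seed = 42)
#> Nucleotide diversity decomposition (values x100):
#>   pi(g1) = 0.326 ± 0.1
#>   pi(g2) = 0.543 ± 0.14
#>   pi_S = 0.434 ± 0.084
#>   pi_T = 2.43 ± 0.35
#>   delta_ST = 2 ± 0.35
#>   N_ST (%) = 82.2 ± 4

net <- build_mjn(haps)
group_separation(net, "g1", "g2")
#> [1] 28
```

Reading: the two simulated haplogroups sit 4.6 % apart (T3P), which a
3.54 %/My clock converts to a ~1.3 Ma split; 82 % of the total nucleotide
diversity lies between the groups (N_ST), and their closest haplotypes are
28 substitutions apart in the network. `run_pipeline(pipeline_config(...))`
chains all stages over a FASTA + group-table input and writes TSV/GraphML
outputs with a JSON manifest.

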