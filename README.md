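# sigrefine

Signature-guided refinement of somatic variant calls.

## The problem

Somatic point-mutation calls from tumor sequencing are contaminated by
experimental artifacts — 8-oxoG oxidative damage, FFPE cytosine deamination,
strand-biased read support — that survive caller filters and distort every
downstream analysis. These artifact processes leave recognizable fingerprints
in the SBS96 trinucleotide mutation spectrum, just as biological processes
(tobacco smoke, APOBEC, UV) do. `sigrefine` exploits this: it searches for
per-variant quality cutoffs whose induced split leaves a refined set that
refits to biological mutational signatures and an artifactual set that refits
to sequencing-artifact signatures.

The package is for anyone post-processing somatic VCFs (tumor/normal callers
such as MuTect2, Muse, or Varscan) who has no matched validation data and
wants a principled, automated alternative to hand-tuned hard filters.

## The method

Each configured filter *f<sub>i</sub>* is a per-variant quality metric
(variant allele fraction, base quality, read depth, ...) extracted from the
VCF by a JSON configuration. A cutoff vector *F* = (f₁ … f<sub>k</sub>)
splits the input mutations *M* into *M<sub>h</sub>* (passes the conjunction
of all cutoffs) and *M<sub>l</sub>* = *M* − *M<sub>h</sub>*. Both sides are
refit against a reference signature catalog *R* (96 channels × N signatures,
with a designated artifact subset *A*) by non-negative least squares with
iterative pruning of weights below 0.06. Writing cos θ for the cosine
similarity between a spectrum and its reconstruction and
*w* for the normalized signature weights, the search maximizes

> cos θ<sub>h</sub><sup>R</sup> · (1 − Σ<sub>i∈A</sub> w<sub>h,i</sub>) ·
> cos θ<sub>l</sub><sup>R_A</sup> · Σ<sub>i∈A</sub> w<sub>l,i</sub>

— high exactly when the refined mutations look biological and the artifactual
mutations look like artifacts. The maximization runs a seeded real-coded
genetic algorithm (population 200, ≤ 100 generations; tournament selection,
blend crossover, bounded Gaussian mutation, elitism) over cutoff vectors
bounded by each metric's observed range, seeded with single-filter candidate
solutions found by grid traversal. Inputs with fewer than 50 point mutations,
or whose initial artifact weight sum is already below 0.05, are gated out.
Post-refinement, the package reports per-variant Fisher strand-bias tests
(BH-corrected), per-filter Mann–Whitney comparisons among the original,
refined, and artifactual sets, ±10 bp sequence-context motif profiles, and
clinical rescue of artifact-classified variants from a local annotation
table.

The packaged catalog (`inst/extdata/synthetic_sbs_catalog_v3shape.tsv`) is a
**synthetic** stand-in with the COSMIC v3 shape (96 × 65, artifact subset
SBS27, SBS43, SBS45–SBS60); for real analyses load the genuine COSMIC catalog
with `read_signature_matrix()`.

## Worked example

Everything below is self-contained: the simulator writes a reference FASTA
and a labelled VCF mixing 1000 smoking-signature-like true mutations
(VAF ~ U(0.15, 0.50), base quality ~ N(35, 3)) with 1000
8-oxoG-artifact-like mutations (VAF ~ U(0.01, 0.06), base quality ~ N(22, 3)).

```r
library(sigrefine)

sim <- simulate_dataset(sim_spec(seed = 1), tempfile("demo"))
config <- generic_sim_config()                 # filters: vaf (FORMAT AF), bq (INFO BQ)
mutations <- read_mutations(sim$vcf, sim$fasta, config)

sigs <- fixture_signatures()                   # 4 synthetic signatures
arts <- fixture_artifact_signatures()          # SYN.OXOG, SYN.FFPE, SYN.TG

res <- refine_mutations(mutations, config, sigs, arts, ga = ga_params(seed = 1))
res
#> <refinement> 973 refined / 1027 artifactual; objective = 0.9886
#> cutoffs: vaf = 0.1527, bq = 28.12

glance(res)
#> # A tibble: 1 × 8
#>   n_input n_refined n_artifactual best_objective generations
#>     <int>     <int>         <int>          <dbl>       <int>
#> 1    2000       973          1027          0.989          63
#>   artifact_weight_before artifact_weight_after skipped
#>                    <dbl>                 <dbl> <chr>
#> 1                  0.497                     0 NA
```

The initial fit attributes 49.7% of the unrefined calls to artifact
signatures; after refinement the refined set carries 0% artifact weight.
Against the simulator's truth labels this split recovers 97.3% of the true
mutations and rejects 100% of the artifacts. `tidy(res)` gives the cutoff
table, `autoplot(res)` the objective trace, and
`autoplot(build_spectrum(res$refined))` the 96-channel spectrum. The
one-command wrapper

```r
run_refinement(sim$vcf, sim$fasta, config, signatures = sigs,
               artifacts = arts, out_dir = "demo_out")
```

writes `refined`/`artifactual` VCFs, the per-generation optimization log,
`summary.json`, `manifest.json`, and a self-contained `report.html`. A shell
entry point with the same surface ships at
`system.file("scripts", "sigrefine.R", package = "sigrefine")`.

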