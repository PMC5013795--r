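# viromimic

Predicting host immune proteins from viral mimicry in virome sequence
data.

Some viruses carry degraded copies of their host's immune-protein
domains. `viromimic` exploits this: it searches a host proteome against
a fragmented ("mock") virome with a translated seed-and-extend aligner,
flags proteins with repeated, independent viral matches as immune
candidates, triages them by reference homology and domain content,
tests domain-category enrichment, and predicts membrane topology — all
offline, deterministic, and with a ground-truthed simulator for
end-to-end validation.

## Quick start

```r
library(viromimic)

# Simulate a full study system with known planted mimics
sc <- simulate_scenario(sim_params(seed = 11))

# Run the whole pipeline
res <- run_pipeline(sc$genomes, sc$proteome, sc$reference, sc$models,
                    sc$category_map, pipeline_config(seed = 11),
                    outdir = "run1")

count_categories(res$triage)
#> reference_homolog  domain_annotated        viral_like             novel
#>                29                16                 2                 3

score_recovery(res$summaries$protein_id, sc$immune_ids)
res$enrichment     # PAMP / apoptosis paired t-tests
```

`run_pipeline()` accepts FASTA/FASTQ paths or in-memory sequence sets,
and writes `hits.m6` (BLAST outfmt-6), `protein_summaries.tsv`,
`triage.tsv`, `category_counts.tsv`, `enrichment.tsv`, `tm.tsv`, plus
`config.yaml` and a `manifest.yaml` with the seed and config checksum.
Runs with the same seed are byte-identical.

## Command line

An `Rscript` front end is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("exec", "viromimic", package = "viromimic"))')
Rscript "$CLI" simulate --seed 11 --out simdir
Rscript "$CLI" run-all --virome simdir/virome.fasta \
    --proteome simdir/proteome.fasta --reference simdir/reference.fasta \
    --models simdir/models.txt --out rundir --seed 11
```

Subcommands: `simulate`, `fragment`, `qc`, `search`, `triage`,
`enrich`, `tm`, `run-all` (run any of them without arguments for
usage).

## Modules

| Module | Functions | What it does |
|---|---|---|
| seqio | `read_fasta`, `read_fastq`, `write_fasta`, `parse_hit_table`, `write_hit_table` | FASTA/FASTQ and BLAST tabular (outfmt 6) I/O |
| qc | `qc_filter` | strict read filters: length ≥ 100, mean Q ≥ 25, N fraction ≤ 10% |
| fragmenter | `fragment_set` | 200 nt non-overlapping tiling; trailing piece kept if ≥ 100 nt |
| align_core | `seeded_search`, `smith_waterman_affine`, `compute_ka_params` | tBLASTn/BLASTp-style search, BLOSUM62, affine gaps, Karlin–Altschul E-values, entropy masking |
| triage | `aggregate_hits`, `reference_homology`, `scan_domains`, `triage_classify` | ≥ 5-unique-fragment candidate rule; homology → domain → viral-like → novel cascade; PSSM scan with shuffle null |
| enrichment | `enrichment_test`, `paired_t_test` | paired two-tailed t-test on per-domain presence frequencies (PAMP, apoptosis) |
| tm_predict | `predict_tm_set` | Kyte–Doolittle hydropathy, window 19, threshold 1.6 |
| mimicry_sim | `simulate_scenario`, `sim_params`, `score_recovery` | ground-truthed generator of proteome, mimic-carrying genomes and reference |
| pipeline | `run_pipeline`, `pipeline_config` | end-to-end orchestration with logging and manifest |

## Validation

* `tests/testthat/` — unit tests per module plus
  `test-acceptance.R`, one block per acceptance criterion
  (alignment-oracle agreement, Karlin–Altschul parameter recovery,
  null E-value calibration, planted-mimic recovery with
  sensitivity/precision ≥ 0.9, triage partition, t-test closed form and
  type-I calibration, QC boundaries, fragment-count law, byte-identical
  reruns). Run with `testthat::test_dir("tests/testthat")`.
* `scripts/acceptance.R` — standalone acceptance computations:
  `Rscript scripts/acceptance.R --seed 1 --out acceptance.json`.

See the methods vignette (`vignettes/methods.Rmd`) for the statistical
design, the deliberate approximations in the alignment engine, and the
simulator's construction.
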