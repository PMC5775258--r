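# nociscreen

Cdk5 is a proline-directed Ser/Thr kinase that is active almost exclusively
in neurons and modulates pain signalling. `nociscreen` implements, as a
tested and reusable R pipeline, the computational workflow used to identify
and validate Cdk5 substrates among nociceptor-enriched proteins:

1. **Substrate screen** (`scan_consensus`, `scan_txxh`, `filter_topology`,
   `screen_proteome`): scan protein sequences for the Cdk5 consensus motif
   (S/T)PX(K/H/R) — an S/T phospho-acceptor, the obligate proline at +1 and a
   basic/His residue at +3 — and the overlapping ankyrin-repeat T/SxxH
   tetrapeptide; score sites with a position-specific scoring matrix;
   exclude sites buried in transmembrane or extracellular segments; restrict
   to genes expressed in the nociceptive (TRPV1-lineage) population; and
   extract the 10-residue substrate window (acceptor at position 4, proline
   at 5) used to design peptide kinase-assay substrates.
2. **Single-cell coexpression** (`binarize`, `prevalence`,
   `coexpression_fraction`, `build_network`): binarize FPKM matrices at a
   positivity threshold (5 FPKM, inclusive), compute gene prevalence and
   conditional coexpression fractions, and export a thresholded coexpression
   network (edge list + GraphML).
3. **Calcium imaging** (`compute_ratio`, `normalize_baseline`,
   `amplitude_fold`, `responder_threshold`, `percent_responders`): process
   ratiometric Fura-2 traces (340/380 nm, 2 s sampling) into baseline-
   normalised responses; classify responders with the cutoff defined as
   mean + 3 SD of the non-responder peak distribution (1.15-fold for a
   population with mean 1.00, SD 0.05); flag stimuli compromised by
   incomplete recovery from a preceding dose; and summarise per mouse with
   responder counts normalised to the KCl-responsive population.
4. **Behaviour** (`percent_of_baseline`, `dose_response_table`): lickometer
   aversion expressed as percent of baseline water licking, per animal, over
   an agonist concentration grid.
5. **Synthetic data** (`gen_proteome`, `gen_sc_matrix`, `gen_traces`,
   `gen_lick_sessions`): seeded generators with truth tables, so every stage
   is testable offline.

A command-line wrapper (`exec/nociscreen`, subcommands `screen`, `coexpr`,
`ca`, `behav`, `simulate`) writes a JSON manifest beside every output.

## Worked example

Scan the six decapeptide kinase-assay substrates of mouse TRPA1:

```r
library(nociscreen)
tab <- screen_proteome(trpa1_peptide_records())
tab[, c("protein_id", "acceptor_pos", "acceptor_res", "motif_class", "window")]
#>   protein_id acceptor_pos acceptor_res motif_class window
#> 1    TRPA1_1            4            T        both   TPLH
#> 2    TRPA1_2            4            S        both   SPLH
#> 3    TRPA1_3            4            S        both   SPLH
#> 4    TRPA1_4            4            T        both   TPLH
#> 5    TRPA1_5            4            S        both   SPLH
#> 6    TRPA1_6            4            T        both   TPLH
```

Each peptide carries exactly one consensus site, always with the acceptor at
window position 4; `motif_class = "both"` records that every one of these
consensus sites is simultaneously an ankyrin-repeat-style T/SxxH motif (the
+3 residue is His).

The same screen on a full-length synthetic TRPA1 stand-in (random background
of the real protein's length with the six substrate windows planted at their
known residue positions; see `?synthetic_trpa1_record`) recovers the six
sites at residues 101, 134, 242, 416, 449 and 485, all inside the N-terminal
cytosolic ankyrin-repeat region:

```r
screen_proteome(list(synthetic_trpa1_record()))$acceptor_pos
#> [1] 101 134 242 416 449 485
```

And the responder cutoff rule, applied to a non-responder peak population
with mean 1.00 and SD 0.05:

```r
set.seed(1); x <- rnorm(60)
responder_threshold(1 + 0.05 * (x - mean(x)) / sd(x))
#> [1] 1.15
```

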