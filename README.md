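# segext

Assembly of the sequence content of genomic insertions — unique, copied, or
a mixture of both — from paired-end short reads.

Reference-based pipelines discover *where* a donor genome carries an
insertion, but reconstructing *what* was inserted is harder: reads from
unique inserted sequence do not map at all, while reads from copied inserted
sequence map back to the copy's source locus and vanish from the unmapped
pile. `segext` targets both. It classifies read pairs by their mapping
signature, pools the pairs likely to originate from insertions, and then
grows the reference flank at each insertion breakpoint one consensus column
at a time, using mates anchored behind the frontier to recruit their
partners as voters. It is aimed at people studying structural variation in
resequencing data who need insertion content, not just insertion calls.

## The method in brief

Fragment lengths are modelled Normal(μ, σ), assumed to lie in
[Δ_min, Δ_max] = [μ − 3σ, μ + 3σ]. Pairs are classified as
one-end-anchored (OEA), orphan, concordant, discordant, or concordant with
an **over-coverage** flag — concordant pairs in regions above the mean depth
μ_DOC are admitted to the insertion read set with probability
max(0, 1 − μ_DOC / μ_DOC[r]), capturing reads that actually originate from a
copy of that region inside an insertion. The insertion read set
IRS = {r : OEA ∨ orphan ∨ discordant ∨ over-coverage}.

At frontier position *pos* of a growing segment, reads whose mate lies
wholly in the anchor window [pos − ℓ − Δ_max, pos − Δ_min) are *anchored*;
an anchored pair's partner *extends* if its longest prefix aligning to the
assembled suffix (mismatch fraction ≤ 1 − τ) has length ext with
κ < ext < ℓ, and votes its base at index ext for position *pos*. A base
with support ≥ ε is called; multiple bases above ε_branch trigger a
divergence and the extension branches; hypotheses are ranked by the number
of IRS pairs they account for. Anchored search runs on an FM-index over the
concatenated IRS mates, issuing exactly |window| − ℓ + 1 searches per
column regardless of |IRS|.

The package also ships the simulation framework used to evaluate the
method: planted insertions (unique / copied / mixed) of 2 kb ± 200 bp,
36 bp pairs at 40X with 200 ± 25 bp fragments, and an evaluator that calls
an insertion correct when the assembled contig is within 10 bp edit
distance of the planted sequence.

## A worked example

```r
library(segext)

spec <- simulation_spec(reference_length = 2e5, n_insertions = 5,
                        category = "case2_copied", insert_size_mean = 800,
                        insert_size_sd = 80, seed = 42)
sim <- simulate_dataset(spec)
set.seed(42)
run <- assemble_from_reads(sim$reference, sim$reads, sim$loci)
run$model
#> <insert_size_model> mu = 199.962, sigma = 24.6771, interval [125.931, 273.993]
dplyr::count(run$irs, label)
#> # A tibble: 3 x 2
#>   label             n
#>   <chr>         <int>
#> 1 DISCORDANT      777
#> 2 OEA             339
#> 3 OVER_COVERAGE  6053
asm <- run$assembly
asm$insertion_id <- sim$truth$insertion_id
score_assembly(asm, sim$truth)
#> # A tibble: 5 x 6
#>   insertion_id category     length status distance correct
#>   <chr>        <chr>         <int> <chr>     <int> <lgl>
#> 1 ins0001      case2_copied    797 merged        0 TRUE
#> 2 ins0002      case2_copied    674 merged        0 TRUE
#> 3 ins0003      case2_copied    761 merged        0 TRUE
#> 4 ins0004      case2_copied    837 merged        0 TRUE
#> 5 ins0005      case2_copied    728 merged        0 TRUE
```

Reading the output: the estimated insert model matches the simulated
geometry (μ ≈ 200, σ ≈ 25, slightly shrunk by the ±3σ truncation). Copied
insertions produce no orphans — their reads map back to the copy source,
which is why the insertion read set consists of discordant, OEA and
over-coverage pairs — and all five planted insertions are reconstructed
exactly (edit distance 0, within the 10 bp margin).

For file-based runs there is a thin command-line driver over the same
functions:

```sh
Rscript inst/cli/segext.R all --out out/ --length 200000 --insertions 5 \
    --category case2_copied --seed 42
```

which writes FASTA/FASTQ/BED/TSV artifacts, `report.tsv` and a manifest
into `out/`.

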