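# taxamark

Taxon-specific mutation discovery and target selection for LAMP primer
design, from multi-species, multi-strain nucleotide alignments.

## The problem

Loop-mediated isothermal amplification (LAMP) assays gain specificity when
the 5′- and 3′-ends of their primers sit on nucleotide positions that are
conserved in every strain of the target taxon but absent from all closely
related organisms. Finding such positions by eye in a large multiple
sequence alignment (MSA) is slow and error-prone: a position that differs
between two species may still be useless if it varies *within* the target
species (a strain-specific polymorphism), and the downstream primer-design
software accepts only a single sequence of at most 2,000 bp, with `*` and
`-` symbols marking regions of interest.

`taxamark` automates this screen. Given an MSA in which every record header
encodes a taxon group and a strain
(`>[Taxon ID]—[Target gene ID]—[Strain ID]`, em-dash delimited, gene
optional), it:

1. **classifies every alignment column per group** — *taxon-specific* when
   all members of a group share one unambiguous base (or a conserved
   deletion) that occurs in no other record; *conserved-common* when every
   record shows the same base; strain-polymorphic columns are excluded;
2. **profiles mutation density** — counts taxon-specific columns per 20-nt
   fragment (a primer annealing-site length), giving counts
   `M_f`, and smooths them with a simple moving average over a window of
   `w` fragments (default 15 fragments = 300 bp, an amplicon-scale window):

   ```
   S̄_f = (1/w) Σ_{i=0}^{w-1} M_{f−i}
       = S̄_{f−1} − M_{f−w}/w + M_f/w        (recurrence form)
   ```

   with each value anchored to the *central* fragment of its window (hence
   `w` odd);
3. **selects a target region** — a window of ≤ 2,000 columns centred on the
   density peak, wherever the average mutation index reaches the
   recommended minimum of 2;
4. **exports ready-to-use files** — the processed alignment with per-group
   highlights and per-20-nt counts, per-taxon density plots (eps, pdf, png,
   svg, tiff), per-taxon profile tables, and the masked target: the
   ungapped focal-group consensus with `*` under conserved-common and `-`
   under taxon-specific positions, which pastes straight into a specific
   primer-design run.

A seeded synthetic-alignment generator (`plant_plan()` /
`generate_alignment()`) plants taxon-specific columns, conserved deletions,
strain noise and adversarial near-signatures with exact ground truth, so
the whole pipeline is testable without any downloads.

## Worked example

A small synthetic alignment ships with the package (three groups of two
strains, 600 columns, planted mutations and one conserved deletion):

```r
library(taxamark)

aln <- read_alignment(system.file("extdata", "synthetic_3group_600col.aln",
                                  package = "taxamark"))
aln
#> <grouped_alignment> 6 records, 600 columns, 3 groups
#>   G1: 2 strain(s)
#>   G2: 2 strain(s)
#>   G3: 2 strain(s)

verdicts <- classify_alignment(aln)
dplyr::count(specific_columns(verdicts), taxon_id)
#>   taxon_id     n
#> 1 G1          18      # 8 planted + 8-column conserved deletion + 2 singletons
#> 2 G2           2
#> 3 G3           1

prof <- build_profile(verdicts, "G1")      # 20-nt fragments, 300-bp window
glance(prof)
#>   group n_fragments n_windows total_specific peak_sma peak_fragment
#> 1 G1             30        16             18      1.2            14

select_target_region(prof, threshold = 0.5)
#>   group start   end peak_sma peak_fragment peak_start peak_end
#> 1 G1        1   600      1.2            14        261      280
```

The peak average mutation index of 1.2 sits on fragment 14 (columns
261–280, next to the planted cluster at 121–128 and the deletion at
201–208); because the whole 600-column alignment fits the 2,000-column
limit, the exported region is the full alignment. `autoplot(prof)` draws
the density curve with the threshold line; `make_primerexplorer_input()`
writes the masked target. The same pipeline, end to end and for every
group, is one call:

```r
run_catch(system.file("extdata", "synthetic_3group_600col.aln",
                      package = "taxamark"),
          out_dir = "results", project_id = "demo", threshold = 0.5)
```

or from a shell, via the installed script:

```sh
Rscript "$(Rscript -e 'cat(find.package("taxamark"))')/exec/catch" \
    input.aln --threshold 2 --out results --project-id demo --zip
```

## Scope

`taxamark` selects targets and masks mutations; it does not design
primers (that is the downstream primer-design service's job), run any
aligner, or fetch sequences. Feed it the Clustal or FASTA alignment you
already have — input order is preserved, and strains are grouped strictly
by identical taxon IDs in their headers.
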