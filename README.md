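# addercycle

Quantitative analysis of the *Escherichia coli* cell cycle in steady-state
exponential populations, for microbiologists working with image cytometry of
DAPI-stained cells and with single-cell size-homeostasis models.

The package ties together three classical pieces of bacterial cell-cycle
theory and one measurement pipeline:

1. **Cooper–Helmstetter population relations.** In steady-state growth with
   doubling time *T*<sub>d</sub>, replication period *C* and
   termination-to-division period *D*, the mean DNA content per cell in
   chromosome equivalents is

   *G*<sub>c</sub> = (*T*<sub>d</sub>/(*C* ln 2)) · (2^((C+D)/T_d) − 2^(D/T_d)).

   The package evaluates this closed form, inverts it for *D* given a
   measured *G*<sub>c</sub>, and derives terminal periods from class
   fractions: a class occupying the last *T* minutes of the cycle holds the
   fraction *F* = 2^(T/T_d) − 1 of the population under the steady-state age
   distribution φ(a) = (2 ln 2/*T*<sub>d</sub>) 2^(−a/T_d), so
   *T* = *T*<sub>d</sub> log₂(1 + *F*).

2. **A single-cell multifork replication state machine.** Chromosomes are
   reduced to one normalized origin-to-terminus coordinate; a cell state is
   a backbone count plus nested replication-round progress fractions.
   Genome content is the exact piecewise integral of the local copy number.
   Averaged over the age distribution, the model reproduces the closed form
   above (the two routes cross-check each other in the tests), and it
   simulates rifampicin run-off synthesis: after initiation is blocked, DNA
   per cell rises and plateaus exactly *C* minutes later at one chromosome
   per origin.

3. **Adder sibling lineages.** One asymmetric division produces a large
   (*L*<sub>b</sub> + 1 SD) and a small (*L*<sub>b</sub> − 1 SD) newborn;
   each then grows exponentially and divides after adding a fixed length
   ΔL, with replication initiated a constant *C+D* before each division.
   Birth-size deviations halve every generation, and at fast growth the
   construction predicts a transient DNA excess in the large branch.

4. **A cytometry pipeline** for per-cell measurement tables and 1-D axial
   profiles: modal background subtraction, fluorescence calibration against
   a 1C/2C reference population, constriction classification,
   small-vs-large contrasts with Welch *t* tests, nucleoid counting and
   separation distances, 100-point collective profiles, length-sorted
   profile maps, division-asymmetry (*K(L)*) CVs, and terminal-period
   estimates. A synthetic-population generator with full ground truth makes
   every stage testable without microscope data.

## Worked example

The two growth conditions studied throughout are succinate
(*T*<sub>d</sub> = 122 min, *C* = 70, *D* = 40) and glucose plus amino acids
(*T*<sub>d</sub> = 29 min, *C* = 53, *D* = 25).

```r
library(addercycle)

mean_genome_equivalents(122, 70, 40)
#> [1] 1.541409
mean_genome_equivalents(29, 53, 25)
#> [1] 3.658035
```

1.54 and 3.66 chromosome equivalents per cell: at slow growth cells hold
between one and two chromosomes, at fast growth multifork replication
raises the average well above two. A constricting-cell fraction of 9% at
slow growth converts to the constriction period:

```r
terminal_period_from_fraction(0.09, 122)
#> [1] 15.16803
```

i.e. visible constriction lasts about 15 of the 122 minutes. The fast
condition's newborn already replicates:

```r
fast <- growth_condition(29, 53, 25)
steady_state_cell(fast, 0)
#> <replication_state> 1 chromosome(s), 2 active round(s) at 0.9245, 0.3774; G = 2.6792 eq, 4 origin(s)
```

A newborn carries two nested rounds inherited from its mother and
grandmother (*C+D* = 78 min spans 2.7 generations) and 2.68 genome
equivalents. Following asymmetric siblings through six adder cycles:

```r
pair <- construct_sibling_lineages(2.6, 2.6, fast, asym_sd = 0.15,
                                   n_cycles = 6) |>
  genome_trajectory()
glance(compare_groups_summary(0.62, 0.08, 63, 0.75, 0.12, 56))
#> # A tibble: 1 × 5
#>   percent_difference statistic    df  p_value method
#>                <dbl>     <dbl> <dbl>    <dbl> <chr>
#> 1               21.0      6.86  94.0 7.10e-10 Welch
```

The summary-statistic comparison above is the published fast-growth DNA
contrast between small and large prospective daughter cells: a 21%
difference, *p* < 10⁻⁸.

A fully synthetic analysis run:

```r
cfg <- synth_config_fast(seed = 422)        # Td = 29 min preset
pop <- generate_population(cfg)
ref <- generate_reference_population(1500, 100, peak_cv = 0.1,
                                     fraction_2c = 0.4, seed = 77)
analyze_population(pop$cells, td = 29, reference = ref)
#> <cytometry_report> 2000 cells, Td = 29 min
#>   constricted: 26.6% (deeply: 12.8%)
#>   constriction period: 9.9 min (fraction 0.266)
#>   segregation period: 23.1 min (fraction 0.739)
#>   calibration: 100.8 AU/equivalent; mean DNA 3.642 eq/cell
#>   K(L) CV: 5.26%
#>   DNA, small vs large deeply-constricted:
#>     <group_comparison> small 4.831 +/- 0.288 (n=131) vs large 5.282 +/- 0.317 (n=125)
#>   difference +9.33%, Welch t = 11.9, df = 249, two-tail p = 3.95e-26
```

The pipeline recovers the generator's ground truth: the constriction and
segregation periods (9.7 and 23.2 min configured), the calibration factor
(100 AU/equivalent), the mean DNA content (closed form 3.66), the division
asymmetry CV (4.9% configured) — and the emergent contrast: large
deeply-constricted cells carry significantly more DNA than small ones at
fast growth, while the same analysis on a slow-growth population gives a
much smaller difference.

A thin command-line wrapper is installed as `exec/addercycle`
(subcommands `gc`, `periods`, `runoff`, `lineage`, `simulate`, `analyze`);
`addercycle_cli()` is the same entry point from R.

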