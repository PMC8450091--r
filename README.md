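# g4flank

Flanking nucleotides reshape the folding landscape of intramolecular
G-quadruplexes (G4s): adding even a single thymine next to the G4 core —
especially on the 5′ side — biases the conformational ensemble toward the
parallel topology, while usually costing a little thermal stability. `g4flank`
is an R package for studying this *flanking effect* quantitatively from
circular-dichroism (CD) and UV-melting measurements of loop-permutation
oligonucleotide libraries, aimed at nucleic-acids biophysicists who run
batches of such spectra.

## What it computes

The sequences under study follow the template
5′-GGG T<sub>a</sub> GGG T<sub>b</sub> GGG T<sub>c</sub> GGG-3′, where a, b, c
are the three loop lengths, optionally with flanking nucleotides at either
end; a *group* is the set of sequences obtained by permuting one multiset of
loop lengths (e.g. the **136** group has six members: 136, 163, 316, 361,
613, 631).

The central statistic is the **conformation index**

&nbsp;&nbsp;&nbsp;&nbsp; *r* = CD₂₆₅ / (|CD₂₆₅| + CD₂₉₀)

where CD₂₆₅ and CD₂₉₀ are the ellipticities at 265 and 290 nm. Topologies are
classified with closed thresholds: parallel for *r* ≥ 0.5, hybrid for
0 ≤ *r* < 0.5, antiparallel for *r* < 0. The flanking effect of a
bare/flanked pair is Δ*r* = *r*(flanked) − *r*(bare); within a group the
spread of *r* (or of Tₘ) is the population formula
σ = √(Σ(xᵢ − μ)²/N). Melting temperatures come from first-derivative
analysis of UV-melting curves (the extremum is located on |dA/d(1/T)|, where
a two-state transition is symmetric, and refined off-grid by a parabolic
fit), and batch comparisons use two-sided paired t-tests with the
significance convention \*\*\* p < 0.001, \*\* p < 0.01, ns p > 0.05.

Because measured spectra are rarely redistributable, the package ships a
seeded generator that emulates a full experiment: CD spectra as convex
mixtures of parallel/hybrid/antiparallel Gaussian-band basis spectra plus
noise, two-state van't Hoff melting curves, and a planted flanking-effect
model (5′ shift > 3′ shift, saturating with flank length, modulated by the
position of the shortest loop) whose ground truth every pipeline stage can
be checked against.

## Worked example

Design a library, simulate a 90-pair flanking experiment, and run the
statistics:

```r
library(g4flank)

enumerate_group(c(1, 3, 6), "DT2")
#> # A tibble: 6 × 8
#>   name        a     b     c flank5 flank3 sequence                   category
#> 1 DT2-136     1     3     6 TT     TT     TTGGGTGGGTTTGGGTTTTTTGGGTT 1bc
#> 2 DT2-163     1     6     3 TT     TT     TTGGGTGGGTTTTTTGGGTTTGGGTT 1bc
#> 3 DT2-316     3     1     6 TT     TT     TTGGGTTTGGGTGGGTTTTTTGGGTT a1c
#> 4 DT2-361     3     6     1 TT     TT     TTGGGTTTGGGTTTTTTGGGTGGGTT ab1
#> 5 DT2-613     6     1     3 TT     TT     TTGGGTTTTTTGGGTGGGTTTGGGTT a1c
#> 6 DT2-631     6     3     1 TT     TT     TTGGGTTTTTTGGGTTTGGGTGGGTT ab1

# one synthetic ensemble spectrum: 20% parallel, 50% hybrid, 30% antiparallel
sp <- mix_spectra(c(0.2, 0.5, 0.3), noise_sd = 0.02, seed = 8,
                  sample_id = "163_WO")
conformation_index(sp)
#> # A tibble: 1 × 6
#>   sample_id     r cd265 cd290 label  flags
#> 1 163_WO    0.348 0.275 0.515 hybrid ""

# whole experiment with planted ground truth
des <- sample_design_table(90, seed = 11)
ex  <- synth_experiment(des, flanking_effect_model(), seed = 11)
st  <- run_stats(run_classify(ex$manifest, spectra = ex$spectra))
st$positive
#> # A tibble: 1 × 4
#>   n_positive     n fraction percent
#> 1         90    90        1     100
tidy(paired_t_test(st$pairs$r_flanked, st$pairs$r_bare))
#> # A tibble: 1 × 8
#>   method                  statistic  p_value     n    df mean_difference stars
#> 1 paired two-sided t-test      48.2 1.48e-65    90    89           0.237 ***

# melting temperature of a simulated two-state curve
compute_tm(synth_melting(tm_true = 55, dH = -40, noise_sd = 0.002, seed = 8,
                         sample_id = "163_WO"))
#> <g4_melting_fit> 163_WO
#>   Tm = 54.83 degC (hypochromic)
```

The r of `163_WO` lands in the hybrid class, as its 50% hybrid / 30%
antiparallel mixture should; all 90 planted-positive pairs show Δr > 0 and
the paired test is overwhelmingly significant; the recovered Tₘ sits within
0.2 °C of the generator's 55 °C truth.

A thin command-line front end (`inst/cli/g4flank`) exposes the same steps as
`design`, `classify`, `melt`, `stats` and `simulate` subcommands over a
sample manifest.

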