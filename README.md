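# lineorigin

Hidden-Markov inference of chromosomal line origin for QTL mapping in
crosses between outbred lines.

## The problem

In an F2 intercross between two outbred lines, interval mapping tests for
an association between phenotype and *line origin* — whether a chromosomal
segment descends from a line-1 or a line-2 founder — at regular positions
along the genome, separately for the maternal and the paternal haplotype of
every F2 individual. With outbred lines and generic SNP-chip panels most
markers are only *partially* informative (the same alleles segregate in
both lines), so line origin must be inferred probabilistically from long
stretches of markers at once. The classical approach enumerates every
combination of line origins between fully informative markers and scales
exponentially in the length of partially informative stretches; it breaks
down on dense SNP data. `lineorigin` implements the linear-time
alternative: a four-state hidden Markov model over the line-origin states

&nbsp;&nbsp;&nbsp;&nbsp;(1,1), (1,2), (2,1), (2,2)

(maternal origin, paternal origin), solved exactly by the scaled
forward–backward algorithm.

* **Transitions.** The two meioses are independent, so the 4×4 kernel
  factorizes into two 2×2 kernels with switch probability
  *r* = ½(1 − e^(−2d/100)) for an interval of *d* cM (Haldane's map
  function: no crossover interference, which is what makes line origin a
  Markov process along the chromosome).
* **Emissions.** At each marker, an F2 genotype is compatible with a state
  (i,j) if it can be composed from an allele the dam could transmit on a
  line-i haplotype and one the sire could transmit on a line-j haplotype,
  given the founder genotypes (Mendelian phase resolution). Compatible
  states emit 1, incompatible states emit a small error floor ε (default
  0.01) so genotyping errors cannot zero out the truth.
* **Test positions** are merged into the marker sequence as
  pseudo-observations under which every state is compatible; the posterior
  at any position is α·β normalized over the four states.

The package also ships the study's companion tools: a three-generation
intercross simulator with known truth (gamete dropping: Poisson crossover
counts, uniform positions), a parental phasing procedure, and evaluation
statistics for inferred recombination switches (line-origin error,
imprecision, inaccuracy, detection).

## Worked example

```r
library(lineorigin)

map <- sim_map(length_cM = 100, spacing_cM = 0.5)        # 201 markers
ped <- sim_pedigree(n_sires = 2, n_dams = 8, n_f2 = 120)
sim <- simulate_cross(map, ped, seed = 20)
sim
#> <lo_sim> seed 20: 120 F2 x 201 markers over 100 cM; 208 F2-meiosis crossovers

post <- infer_line_origin(sim$genotypes, sim$pedigree, sim$map)
glance(post)
#> # A tibble: 1 × 5
#>   n_individuals n_positions grid_step_cM error_floor max_sum_deviation
#>           <int>       <int>        <dbl>       <dbl>             <dbl>
#> 1           120         101            1        0.01          2.22e-16

err <- summarize_error(line_origin_error(post, sim$truth))
glance(err)
#> # A tibble: 1 × 5
#>   grand_mean_error mean_sd n_positions worst_position_cM worst_mean_error
#>              <dbl>   <dbl>       <int>             <dbl>            <dbl>
#> 1          0.00652  0.0490         101               100           0.0225

sw <- match_switches(detect_switches(post), sim$truth)
glance(sw)
#> # A tibble: 1 × 6
#>   n_true n_switches n_matched detection_fraction mean_imprecision_cM
#>    <int>      <int>     <int>              <dbl>               <dbl>
#> 1    208        181       181              0.870                2.72
```

Read: with 120 F2 individuals and markers every 0.5 cM, the four
posteriors sum to 1 to machine precision at every grid point; the inferred
line-1 probabilities are on average 0.0065 away from the simulated truth
(0 = perfect, 1 = confidently wrong); 87% of the 208 simulated parental
recombinations are recovered as probability switches, located to within a
mean imprecision of 2.7 cM. `autoplot(post)` draws the per-haplotype
probability curves; `autoplot(err)` the error profile along the
chromosome.

File-based workflows (`read_map()`, `read_pedigree()`, `read_genotypes()`,
`write_posteriors()`, ...) use plain TSV formats, and
`inst/cli/lineorigin.R` exposes `simulate`, `infer`, `evaluate` and
`pipeline` subcommands for shell use:

```sh
Rscript inst/cli/lineorigin.R pipeline --seed 1 --replicates 3 --out runs/
```

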