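# couplonscan

Spatiotemporal analysis of bacterial regulons and **couplons** — the gene
sets under joint control of a nucleoid-associated protein (NAP, e.g. FIS,
H-NS, Lrp, IHF) or a global transcription factor (CRP, Fnr) *and* an RNA
polymerase sigma factor (RpoD or an alternative sigma factor such as RpoS,
RpoN, RpoH, RpoE).

Bacterial transcription is coordinated jointly by the sigma-factor
composition of RNA polymerase and by the abundant NAPs, and both the
chromosomal positions of their target genes and the timing of their
expression over the growth cycle carry signal about that coordination. This
package is for microbial systems biologists who have a transcriptional
regulatory network (TRN), a genome annotation, a growth-phase expression
time-course and/or a genome sequence, and who want to ask, quantitatively:

* How big is each couplon — the intersection of a NAP/global-TF regulon with
  a sigma-factor regulon?
* Is a regulon or couplon spatially clustered on the circular chromosome,
  and does its spatial organisation track the NAP parent or the sigma
  parent?
* Does its growth-phase expression profile track the NAP parent, the sigma
  parent, or the regulator's own gene — and how robust is that profile to
  membership error?
* Do the promoter regions of a gene set sit in more or less GC-rich sequence
  than the genome background?

## Methods at a glance

**Couplons.** For a NAP or global TF with regulon A and a sigma factor with
regulon B, the couplon is A ∩ B on gene identity (activation/repression
signs are kept as metadata but do not affect membership).

**Spatial enrichment.** A gene set of size *n* out of *N* annotated genes is
counted in sliding windows (default 100 kb every 10 kb) around the circular
chromosome, and each window's count is standardised against a resampling
null, Z_w = (O_w − μ_w)/σ_w, where μ_w and σ_w are estimated from 10,000
uniform draws of *n* genes without replacement (or taken from the exact
hypergeometric closed form, μ_w = n k_w/N and
σ²_w = n (k_w/N)(1 − k_w/N)(N − n)/(N − 1), with k_w the number of annotated
genes in window *w*). Windows with Z > 2 are called enriched and Z < −2
depleted. Two spatial distributions are compared by the Pearson correlation
of their Z-profiles.

**Temporal profiles.** Each member gene's expression across the sampled
growth phases (default design: 60, 120, 180, 300, 420 minutes after
inoculation) is min–max normalised to [0, 1]; the normalised patterns are
averaged with equal weights and the averaged curve is rescaled to [0, 1]
(its pre-rescale extremes are reported — they measure how synchronous the
set is). Profile robustness is quantified by a *remapping envelope*: the
per-timepoint SD of the profile when 10% of members are repeatedly swapped
for random non-members.

**Promoter GC.** For every gene the sequence on the coding strand from
−300 to +200 around the TSS is extracted (circularly, reverse-complemented
for minus-strand genes) and the per-position mean G|C fraction across a gene
set is smoothed with a 21 bp moving average.

**Synthetic data.** A generator plants all of the structure the analyses
look for — an OriC→Ter promoter GC gradient, spatially clustered regulons,
configured couplon overlaps, and early/mid/late temporal programs plus
Gaussian noise, including a "fis mutant" switch that removes the planted
stationary-phase repression of the late program — so the whole pipeline is
testable against known ground truth.

## Worked example

Simulate an E. coli-like dataset with planted structure, then run the three
analyses on the FIS/RpoS couplon:

```r
library(couplonscan)

spec <- sim_spec(
  n_genes = 1000, chromosome_length = 1e6,
  regulators = tibble::tibble(
    name  = c("FIS", "RpoD", "RpoS"),
    class = c("NAP", "sigma", "sigma"),
    size  = c(100, 200, 50),
    center = c(1e5, 0, 5e5),
    concentration = c(0.4, 0.1, 0.4),
    program = c("early", "early", "late")
  ),
  overlaps = tibble::tibble(nap = c("FIS", "FIS"),
                            sigma = c("RpoD", "RpoS"),
                            fraction = c(0.25, 0.10))
)
gen <- generate_genome(spec, seed = 1)
rs  <- generate_trn(spec, gen$annotation, seed = 2)
tc  <- generate_timecourse(spec, rs, seed = 3)

couplon_table(rs, naps = "FIS", sigmas = c("RpoD", "RpoS"))
#> # A tibble: 2 × 4
#>   nap_or_tf sigma  size members
#>   <chr>     <chr> <int> <list>
#> 1 FIS       RpoD     25 <chr [25]>
#> 2 FIS       RpoS     10 <chr [10]>
```

The couplon sizes are exactly the configured overlap fractions of the FIS
regulon (0.25 × 100 and 0.10 × 100). Spatial organisation of the FIS
regulon against a 10,000-sample resampling null:

```r
grid   <- make_grid(chromosome_length(gen$annotation))
zp_fis <- z_profile(gen$annotation, regulon_members(rs, "FIS"), grid,
                    n_samples = 10000, seed = 4, set_name = "FIS")
glance(zp_fis)
#>   set_name set_size n_windows n_enriched n_depleted max_z method     n_samples
#> 1 FIS           100       100         18          6  6.16 montecarlo     10000
```

18 of 100 windows are called enriched (Z > 2) — the planted cluster around
position 100 kb. The FIS/RpoS couplon's temporal profile with a 10%
remapping envelope, and its correlation with each parent:

```r
cp   <- build_couplon(rs, "FIS", "RpoS")
prof <- remap_envelope(tc, cp$members, fraction = 0.10, n_reps = 100,
                       seed = 5, set_name = "FIS/RpoS couplon")
prof
#>    time  value envelope_sd
#> 1    60 0.0560      0.0565
#> 2   120 0           0.0160
#> 3   180 0.446       0.0505
#> 4   300 1           0
#> 5   420 0.165       0.0670

p_sig <- set_profile(tc, regulon_members(rs, "RpoS"))
p_nap <- set_profile(tc, regulon_members(rs, "FIS"))
c(vs_sigma = as.numeric(profile_correlation(prof, p_sig)),
  vs_nap   = as.numeric(profile_correlation(prof, p_nap)))
#>  vs_sigma    vs_nap
#> 0.9932475 -0.5708522
```

The couplon rises to its 300-minute peak and declines in stationary phase,
tracking its sigma parent (r = 0.99) and not its NAP parent (r = −0.57) —
the planted sigma-side asymmetry. `autoplot()` methods draw each result
type, and `run_pipeline(config)` executes all stages end-to-end from one
config (see `vignette` source under `vignettes/` and the CLI wrapper in
`inst/cli/couplonscan.R`).

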