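# gutshift

Quantitative gut-content analysis for fish diet studies, built around the
question of **ontogenetic niche shifts**: do juvenile and mature (or small
and large) individuals of one population partition their food resources?
The package grew out of a two-size-class study of the weatherfish
(*Misgurnus fossilis*), a benthic cobitid whose juveniles feed largely from
the water column and vegetation while mature fish turn to benthic prey and
detritus, and it ships that study's published summary tables as reference
fixtures together with a calibrated synthetic cohort generator so the whole
pipeline can be exercised without the original raw data.

It is aimed at trophic ecologists working with per-fish biomass-by-category
diet tables (one row per fish, one biomass column per food category, in mg).

## What it computes

**Diet description.** Frequency of occurrence %FO_i (share of non-empty
guts containing category *i*), percentage biomass %W_i (per-fish mean or
group-pooled), the gut fullness coefficient FC = 100 · gut mass / body
mass, and the Index of Relative Importance in its two-term biomass form

    IRI_i = %FO_i × %W_i,    %IRI_i = 100 · IRI_i / Σ_j IRI_j

plus Welch's unequal-variance *t* (computable directly from printed
mean ± SD summaries).

**Niche breadth and overlap.** Simpson dominance D = Σp², Levins B = 1/D,
Shannon H′ = −Σ p·log p, the evenness forms Ba = (B−1)/(S−1) and
J′ = H′/log S; Schoener's α = 1 − ½Σ|p_ix − p_iy| and Horn's
information-theoretic Ro between two groups. All indices come with
delete-one-fish **jackknife** means and standard errors, and between-group
index differences are tested by a label-permutation test.

**Community comparison.** Bray–Curtis dissimilarities between fish,
Clarke's rank-based **ANOSIM** R with a seeded permutation p-value (exact
enumeration on small problems), and a **SIMPER** decomposition of the
average between-group dissimilarity into per-category contributions.

**Ontogeny classification.** Ward minimum-variance clustering of per-fish
habitat-guild profiles (benthic BE, epiphytic EP, epiphytic/benthic EP_BE,
planktonic PL, detritus DE) with a two-cluster maturity cross-tabulation,
and two-group canonical discriminant analysis on arcsine-transformed guild
percentages: eigenvalue λ₁, Wilks' Λ = 1/(1+λ₁), the exact F on
(p, N−p−1) df, per-variable F-to-remove, structure correlations and a
resubstitution classification table.

## Worked example

```r
library(gutshift)

x <- simulate_cohort(default_cohort_spec(), seed = 1)
x
#> diet_table: 59 fish (3 empty guts), 25 food categories, groups: juvenile, mature

head(diet_summary(x, "mature")[c("category", "pct_w", "cv", "pct_fo", "pct_iri")], 3)
#>                    category pct_w    cv pct_fo pct_iri
#> 1                  Detritus 17.16 117.5    100   21.80
#> 8         Asellus_aquaticus 17.93 128.9     92   20.96
#> 21 Chironomidae_Tanypodinae 16.15 141.5     80   16.42

sub <- subset_fish(x, !is_empty_gut(x))
anosim(bray_curtis(sub), sub$group, n_perm = 9999, seed = 1)
#> ANOSIM: R = 0.2522, p = 0.0001 (sampled, 9999 permutations)

diet_overlap(x, "juvenile", "mature")
#> diet overlap juvenile vs mature (per_fish basis):
#>   Schoener alpha = 0.5393 (jackknife mean 0.5539 +/- 0.0638 se)
#>   Horn Ro = 0.7424 (jackknife mean 0.7866 +/- 0.0508 se)

gp <- guild_profiles(x, weatherfish_guild_map(), transform = "arcsine")
dfa_two_group(gp$profiles, gp$labels)
#> two-group discriminant analysis: eigenvalue = 1.2184, Wilks' lambda = 0.4508
#> F(5, 50) = 12.1842, p = 9.637e-08; resubstitution accuracy = 91.07%
```

Read as: the simulated cohort reproduces the study conditions — a moderate
but highly significant separation of juvenile and mature diets (ANOSIM R
about 0.2), substantial diet overlap (α just above 0.5, Ro about 0.75), a
mature diet led by detritus and *Asellus*, and a single discriminant axis
(Λ ≈ 0.45) separating the maturity classes on their habitat-guild use.

A thin command-line wrapper over the same functions is installed at
`inst/cli/gutshift.R` (`simulate`, `summarize`, `anosim`, `simper`,
`cluster`, `dfa`, `run`, ...). `run_pipeline()` orchestrates every stage
and writes a TSV/JSON report bundle with a reproducibility manifest.

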