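# dusmapr

Mapping dihydrouridine (D) in bacterial tRNAs and attributing each site
to its synthase — the analysis machinery behind knockout-panel
MALDI-TOF fragment mapping, aniline-cleavage sequencing scores, and
flavoenzyme kinetics, with seeded synthetic-data generators replacing
the wet-lab inputs.

## Who this is for

Dihydrouridine is a uridine with a saturated C5=C6 bond (+2.016 Da). In
*Bacillus subtilis*, two FMN-dependent paralogs (DusB1, DusB2) install
it at canonical tRNA positions 16/17/20/20a/20b/47 with overlapping
specificity. Deciding *which enzyme modifies which site* requires
comparing wild type, both single knockouts and the double knockout,
site by site. `dusmapr` is for epitranscriptomics groups running (or
reanalysing) that experiment family: it turns sequences, peak lists and
read-start count tables into per-site enzyme attributions, and turns
rate tables into kinetic parameters.

## What it computes

* **In silico digestion.** RNase T1 (cleaves 3′ of G) and RNase A
  (3′ of C, U and D) fragment an annotated tRNA into 5′-OH /
  3′-phosphate products, with missed-cleavage unions on request.
* **Fragment masses.** Neutral mass = Σ nucleoside-3′-monophosphates −
  (n−1)·H₂O ± terminal adjustments; reported by default as
  monoisotopic [M+H]⁺ at nominal (integer) m/z. A D-for-U substitution
  shifts a fragment by exactly +2 nominal Da — the knockout diagnostic.
* **The attribution grid.** For each site, the smallest unambiguous,
  collision-free digest fragment is monitored across the four strains;
  the modified fraction f = I_mod/(I_mod+I_unmod) is thresholded into
  modified/reduced/unmodified/undetected, and ordered rules return
  `B1_only`, `B2_only`, `redundant` (optionally `_B1_preferred` /
  `_B2_preferred`), `none` or `inconsistent`.
* **Cleavage-sequencing scores.** NormCount (signal over the median
  background of the surrounding 10 nt) and stop ratio
  (read-starts/coverage, a stoichiometry proxy), with the N+1
  attribution offset handled internally; site calling, stoichiometry
  heatmaps, dose–response monotonicity, and WT-normalised panel
  attribution through the same grid.
* **Kinetics.** Michaelis–Menten fits of v = kcat·[E]·[S]/(KM+[S])
  (bounded Levenberg–Marquardt), catalytic-efficiency comparison with a
  1.5-fold indifference band, Hill fits of cooperative tRNA binding,
  and adenosine-normalised relative D content.
* **Synthetic data.** Deterministic, seeded generators for every input
  above with ground truth attached, so the whole pipeline is testable
  offline.

## Worked example

```r
library(dusmapr)

# a toy tRNA with dihydrouridine at position 5, T1-digested
trna <- annotated_trna("phe", "AAGUUGAAA",
  modifications = data.frame(position_label = "5", modification_code = "D"))
sapply(digest(trna, "RNaseT1"), fragment_string)
#> [1] "AAG" "UDG" "AAA"

select_diagnostics(trna, "RNaseT1")
#>   trna_id site fragment start_label end_label mz_modified mz_unmodified
#> 1     phe    5      UDG           4         6    978.1316      976.1159

# four strain spectra: the 978 peak vanishes exactly when B1 is deleted
peaks <- list(
  WT     = data.frame(mz = 978.1, intensity = 95),
  dB1    = data.frame(mz = 976.1, intensity = 90),
  dB2    = data.frame(mz = 978.1, intensity = 97),
  dB1dB2 = data.frame(mz = 976.1, intensity = 93))
attribute_panel(trna, peaks)
#>   trna_id site f_WT f_dB1 f_dB2 f_dB1dB2 attribution
#> 1     phe    5    1     0     1        0     B1_only
```

The diagnostic fragment is the UDG trinucleotide at m/z 978 (976
unmodified). The panel shows the modified fraction collapsing to 0 only
in the strains lacking DusB1, so the grid attributes the site to
`B1_only`.

The same works end to end on simulated studies:

```r
bench <- simulate_knockout_benchmark(n_trnas = 25, seed = 1)
attribution_accuracy(bench)
#> [1] 1
```

A shell entry point (`inst/cli/dusmapr`) wraps the same functions as
verbs (`digest`, `mass`, `diagnose`, `attribute`, `alkascore`,
`kinetics`, `simulate`, `report`); `dus_cli("help")` prints the flags.

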