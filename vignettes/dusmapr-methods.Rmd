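---
title: "Mapping tRNA dihydrouridine and attributing its synthases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping tRNA dihydrouridine and attributing its synthases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dusmapr)
```

## The problem

Dihydrouridine (D) is one of the most abundant tRNA modifications: a
uridine whose C5=C6 double bond has been reduced, adding two hydrogens
(+2.016 Da) and breaking the ring's aromaticity. In bacteria it
clusters in the D-loop (canonical positions 16, 17, 20, 20a, 20b) and,
for some tRNAs, the variable loop (position 47). It is installed by
FMN-dependent flavoenzymes, the dihydrouridine synthases (Dus). In
*Bacillus subtilis* two DusB paralogs (DusB1 and DusB2) divide — and
partly share — this work, a functional redundancy that can only be
untangled by measuring each site in a panel of knockout strains.

`dusmapr` implements the inference machinery for that experiment family
as a reusable, fully testable pipeline:

1. **tRNA model** — modification-annotated sequences with canonical
   position labels (insertion letters like `20a` included).
2. **Digestion** — in silico RNase T1 / RNase A cleavage into
   3'-phosphate fragments.
3. **Mass calculation** — monoisotopic and average masses of modified
   oligonucleotides, and the diagnostic D/U mass pair.
4. **MALDI mapping** — diagnostic-fragment selection, peak matching,
   per-strain state calling and the knockout attribution grid.
5. **Cleavage sequencing** — per-position scoring of aniline-cleavage
   read starts (NormCount, stop ratio), site calling, heatmaps,
   dose–response.
6. **Kinetics** — Michaelis–Menten fits of NAD(P)H oxidase activity,
   Hill fits of cooperative tRNA binding, relative D-content
   bookkeeping.
7. **Synthetic data** — seeded generators for every input above, with
   ground truth attached.

Because real deep-sequencing and mass-spectrometry inputs are bulky and
instrument-specific, the package treats *count tables* and *peak lists*
as its raw data and ships generators that emulate them; everything
downstream of base calling / peak picking is reproduced.

## Digestion model

RNase T1 cleaves 3' of guanosine, RNase A 3' of pyrimidines; both
proceed by transesterification through the ribose 2'-OH and leave a
linear 3'-phosphate upstream and a 5'-OH downstream (a 2',3'-cyclic
intermediate exists but the mature products used for MALDI are linear;
cyclic phosphate remains representable). Three choices deserve
justification:

* **RNase A cleaves after dihydrouridine.** The observed diagnostic
  fragments GGD and GGAD *end* in D, which is only possible if the
  enzyme accepts the saturated ring. D keeps the 2'-OH and the
  pyrimidine ring geometry at the positions RNase A contacts, so this
  is chemically reasonable; it is nonetheless exposed as a configurable
  rule (`cleavage_rule()`), not hard-wired.
* **RNase T1 cleaves after m7G.** The variable-loop diagnostic D47–C–G
  lies immediately 3' of position 46, which is m7G in the relevant
  tRNA; the fragment is observed, so N7-methylation does not block T1.
* **2'-O-methylated residues resist both enzymes** (no 2'-OH, no
  transesterification); any modification flagged `ribose_methyl` in the
  modification table is skipped.

With `missed_cleavages = k`, all unions of up to `k + 1` adjacent
complete-digest fragments are additionally reported — the standard
partial-digest enumeration. The complete digest always partitions the
sequence; the test suite checks this and compares the digestion against
an independent regex-splitting oracle on random sequences.

## Mass model

A fragment's neutral mass is the sum of its residues'
nucleoside-3'-monophosphate masses (plus the modification's mass
delta), minus one water per phosphodiester bond, with terminal
adjustments (3'-OH: −HPO₃; 5'-P: +HPO₃; 2',3'-cyclic: −H₂O). Element
masses are monoisotopic IUPAC/CODATA values to five decimals; average
masses use standard atomic weights. The default reporting convention is
the positive-mode MALDI one: singly protonated, monoisotopic, compared
at nominal (integer) m/z, rounding half away from zero. Under it the
diagnostic trinucleotides compute to

```{r masses}
nominal <- mass_spec(rounding = "nominal")
sapply(c("UDG", "UUG", "GGD", "DAG", "GGAD", "CDAG", "DCG", "UCG"),
       function(s) fragment_mass(fragment_from_string(s), nominal))
```

and the D/U pair is always split by 2 nominal Da — the knockout
diagnostic. `collision_check()` guards against two digest products
falling within instrument tolerance of each other, which would make a
peak unassignable.

## The knockout attribution grid

For each candidate site the smallest digest fragment that contains it —
and no other candidate site, and whose D/U mass pair collides with no
other fragment within tolerance (default 0.5 Da, the linear-mode MALDI
scale for trinucleotides) — is the *diagnostic fragment*. Matching a
strain's peak list against the pair gives intensities (I_mod, I_unmod)
and the modified fraction `f = I_mod / (I_mod + I_unmod)`; intensities
are meaningful only within one spectrum, so nothing else is ever
compared across spectra.

Calls use declared thresholds (the source experiments argue
qualitatively from "absent" and "decreased" peaks; numbers make the
grid testable): `modified` at f ≥ 0.8, `unmodified` at f ≤ 0.1,
`reduced` in between, `undetected` when the pair's summed intensity is
below 5% of the spectrum's median peak. The grid then applies, in
order: wild type unmodified → `none`; double knockout modified →
`inconsistent`; present without B2 but absent without B1 → `B1_only`
(and mirrored); present in both single knockouts and absent in the
double → `redundant`, with a preference suffix when the two
single-knockout fractions differ by ≥ 0.3 (the strain missing the
bigger contributor shows the lower fraction). All thresholds are
function arguments.

## Cleavage-sequencing scores

Alkaline/aniline treatment cleaves the labile D ring (and m7G, m3C,
ho5C), leaving a 5'-phosphate on the *next* residue; a read start at
position i + 1 therefore reports residue i. Scoring undoes this N+1
offset so every output is in residue coordinates.

* **NormCount** — attributed count divided by the median attributed
  count over the surrounding 10 nucleotides. "Surrounding 10" is read
  as 5 flanking residues per side, excluding the scored position, with
  windows truncated at molecule ends; the median is floored at one
  count so empty background cannot divide by zero. The score is
  scale-free (doubling sequencing depth does not change it) and equals
  1 on flat profiles.
* **Stop ratio** — attributed count over traversing coverage: a direct
  stoichiometry proxy in [0, 1]. Zero coverage yields `NA`
  ("undetected"), never a silent 0.

`call_sites()` flags positions with NormCount ≥ 5 (default; the score
has no published cut-off, and 5 balances sensitivity against Poisson
background excursions at the default background of ~5 counts).
Non-uridine positions with high scores — the m7G46 signal being the
canonical example — are emitted in a separate channel rather than
suppressed, because they are real co-detected signal, and because the
D47/m7G46 overlap genuinely cannot be deconvolved by this method.

For knockout panels measured by sequencing, stop ratios are first
normalised to the wild-type column (capped at 1) and then pushed
through the same attribution grid. The normalisation matters: D sites
are sub-stoichiometric even in wild type, so raw ratios would never
reach the 0.8 "modified" threshold that MALDI fractions reach; dividing
by wild type asks the right question — *how much of the wild-type
modification does each knockout retain?*

## Kinetics

NAD(P)H oxidase rates are fitted to `v = kcat·[E]·[S]/(KM + [S])` by
bounded Levenberg–Marquardt least squares (`minpack.lm`), with
deterministic starting values (KM₀ = median [S], Vmax₀ = max v) and no
random restarts. A fit whose concentrations all sit far above the
fitted KM (min [S] > 3·K̂M) is rejected as unidentifiable rather than
reported. Catalytic efficiency kcat/KM carries a first-order
(delta-method) standard error. Substrate preference uses a 1.5-fold
indifference band: efficiency ratios below it are reported as "no
discrimination", encoding the qualitative conclusion appropriate for an
enzyme whose NADH and NADPH parameters are statistically
indistinguishable. Rates may also be derived from A340 slopes with
ε(NAD(P)H, 340 nm) = 6220 M⁻¹cm⁻¹ and a 1 cm path — constants declared
here, not taken from any data source.

Cooperative tRNA binding is fitted with the Hill isotherm
`ΔF = A·[S]ⁿ/(K_halfⁿ + [S]ⁿ)`; fixing n = 1 recovers the rectangular
hyperbola and, on rate data, exactly the Michaelis–Menten shape (a
property the tests exploit as an internal consistency check).

Relative D content is plain normalisation bookkeeping: D ion signal
over adenosine UV signal, expressed as percent of the same ratio in a
reference sample. It is invariant to rescaling all raw signals.

## The synthetic-data generators

Every generator is a pure function of its parameters and a seed.
Defaults: m/z jitter SD 0.05 Da, intensity CV 0.2 (log-normal,
mean 1), Poisson background of 5 read starts per position, coverage
1000. These are declared, field-plausible values — no published noise
model exists for either instrument at this granularity.

Synthetic tRNAs are 76 nt (plus insertions), with D sites embedded in
the sequence contexts that make them monitorable — UDG for 17, DAG for
20, CDAG for 20a, DCG for 47 — and all filler drawn from A/G only.
The purine-only filler is a deliberate trick: purine-only fragments can
never fall within 0.5 Da of the pyrimidine-containing diagnostic pairs,
so designed sites stay monitorable regardless of the random filler.
Sites 20/20a/20b share the D-loop insertion context and therefore
cannot be designed into one molecule (the real experiments likewise
probed them in different tRNAs); each simulated peak list represents
the digest of one purified tRNA species, as on a MALDI target plate.

The per-site enzyme model gives each synthase an efficiency in [0, 1];
a site's stoichiometry under a genotype is `1 − Π(1 − eff)` over the
enzymes that genotype retains. For the end-to-end benchmark, scenario
classes are drawn with efficiencies chosen *a priori* so that the
ground truth is decodable in principle: dedicated or dominant enzymes
install near-stoichiometrically (0.90–0.98 — the MALDI regime, where
the diagnostic peak is present at control-like intensity or absent),
weak partners of a preferred pair at 0.3–0.5. Cleavage-profile
generators default to sub-stoichiometric wild-type levels, which is
what the sequencing assay reports in practice; the WT-normalised
attribution path is designed for exactly that regime.

What the generators do **not** emulate: isotope envelopes, in-source
decay, matrix adducts or mass miscalibration on the MALDI side;
read-level artefacts, ligation bias, alignment error or
position-dependent coverage on the sequencing side; product inhibition
or enzyme inactivation in kinetics. Passing tests therefore demonstrate
correctness of the *inference machinery* under a clean noise model, not
robustness to every instrument pathology.

## Numerical and interface choices

* Residue indices are 1-based throughout, the R convention; canonical
  labels are I/O and display only, so no algorithm does insertion-letter
  arithmetic.
* Nominal rounding rounds half away from zero (peak-label convention),
  not banker's rounding.
* `decide_attribution` treats `undetected` like `unmodified` where the
  grid asks for absence, and any pattern matching no rule falls through
  to `inconsistent` — the grid never guesses.
* Ties in peak matching go to the nearest theoretical mass; a peak
  feeds at most one diagnostic member.
* Generators call `set.seed()` internally, making each one
  reproducible in isolation at the cost of advancing the global RNG
  stream; composite runs derive per-call seeds from the master seed.

Problem sizes used by the test suite — 1000 random digests of ≤ 30 nt,
200 simulated knockout sites, 100 seeded kinetics fits, coverage 1000 —
were chosen to make sampling error comfortably smaller than the margins
being tested while keeping a full run around a minute on one core.

## Known limitations

* No Sprinzl alignment: canonical labels must be supplied (or default
  to 1..n). Automatic canonical numbering of arbitrary tRNAs is a
  different, harder problem.
* Multi-site digest fragments are summarised by a single joint
  stoichiometry when simulating peaks; per-isomer intensity patterns of
  partially modified multi-site fragments are not modelled (such
  fragments are never selected as diagnostics anyway).
* The MALDI attribution grid needs near-stoichiometric modification to
  call `modified`; for chronically sub-stoichiometric sites the
  sequencing route (WT-normalised) is the right tool, which mirrors how
  the two assays divide the work in practice.
* D47 adjacent to m7G46 cannot be resolved by the sequencing score;
  the package reports the m7G signal in its own channel and leaves the
  overlap to the MALDI route.
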