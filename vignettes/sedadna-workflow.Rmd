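---
title: "Authenticating sedimentary ancient DNA: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authenticating sedimentary ancient DNA: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

DNA preserved in deep marine sediment is fragmentary, chemically damaged,
and present in trace amounts, which makes it both a unique archive of
past ecosystems and an easy target for contamination by modern DNA.
Before a down-core taxonomic profile can be interpreted as an ecological
signal, three independent lines of authentication are needed:

1. **Physical contamination control** — a chemical tracer infused into
   the drill fluid during coring; tracer detected at the core periphery
   but not the centre indicates the interior is intact.
2. **Biological contamination control** — extraction blanks, air
   controls and drill-fluid libraries sequenced alongside the samples;
   taxa appearing in controls are subtracted from the samples.
3. **Damage authentication** — genuinely ancient molecules carry excess
   C→T substitutions at fragment 5′ ends (and G→A at 3′ ends in
   double-stranded libraries) from cytosine deamination; reads are
   classified *ancient* or *default* from their terminal mismatches.

`sedapipe` implements this workflow end-to-end — read filtering,
marker-gene alignment with lowest-common-ancestor (LCA) assignment,
control subtraction, damage analysis, tracer QC and the downstream
abundance/correlation statistics — together with a ground-truthed
synthetic sediment-core generator so that every stage is testable
without any external data. The numbered scripts under `analysis/` run
the stages as a narrative workflow writing tables under `results/`.

# The damage model

A fragment of length $L$ from a sample with damage amplitude $d_5$
acquires C→T substitutions at 0-based 5′ position $i$ with probability

$$P(\mathrm{C\to T}\mid i) = d_5\, r^{\,i},$$

and symmetrically G→A at position $j$ counted from the 3′ end with
probability $d_5\, r^{\,j}$ — the double-stranded library signature of
cytosine deamination, which concentrates at single-stranded overhangs
near fragment ends. $r \in (0,1)$ is the geometric decay per position.
Every base additionally flips to a uniformly chosen other base with
background probability $\varepsilon$, standing in for sequencing error
and non-deamination miscoding. A single-stranded-library mode (C→T at
both ends) exists behind the `single_stranded` flag and is off by
default.

The amplitude grows linearly with sample age up to a saturation age:
$d_5(\mathrm{age}) = d_{5,\mathrm{surf}} + (d_{5,\mathrm{deep}} -
d_{5,\mathrm{surf}})\cdot\min(\mathrm{age}, s)/s$. Defaults
($d_{5,\mathrm{surf}} = 0.03$, $d_{5,\mathrm{deep}} = 0.33$,
$s = 400$ ka, $r = 0.5$, $\varepsilon = 0.005$) produce shallow samples
with a few percent of damage-bearing reads and deep samples with
roughly a quarter to a third — the magnitude range reported for
deep-sea sediment records.

Estimation inverts the same model: the positional spectrum
$f_5[i]$ (fraction of aligned columns with reference C at 5′ position
$i$ showing T in the read) is fitted by least squares to
$f[i] = d\,r^i + \varepsilon$ with box constraints
($d \in [0,1]$, $r \in (0,1)$, $\varepsilon \ge 0$; three starting
points, L-BFGS-B). A noiseless spectrum is recovered to $10^{-6}$; a
flat spectrum sits on a ridge ($r \to 1$ trades $d$ against
$\varepsilon$), which is why the tests assert the fitted curve rather
than the split in that case.

Per-read classification is the de-facto rule of the ancient-metagenomics
tool family: a read passing the stringent gate (identity ≥ 0.95, gap
fraction ≤ 0.1 on its best hit) is **ancient** iff it shows ≥1 C→T
within the first `k_terminal = 5` 5′ positions or ≥1 G→A within the last
5 positions, otherwise **default**; failing reads are **rejected** and
excluded from proportion denominators. With $\varepsilon = 0$ the
per-read detection probability has the closed form
$1 - \prod_{\text{terminal C/G pos } p}(1 - d_5 r^p)$, which the test
suite checks empirically to binomial precision. Groups with fewer than
50 retained reads are reported but flagged low-confidence.

# Alignment and assignment

Reads are aligned **semiglobally** (read end-to-end, reference locally)
by dynamic programming with scores +1/−1 and linear gap −2 — degraded
reads must not be clipped, or the terminal damage evidence disappears.
Candidate references are found through an exact 12-mer index of the
forward strand; the query is searched as-is and reverse-complemented and
the better strand kept. A 12-mer seed is guaranteed for reads ≥ 25 bp
with at most one substitution per 13 bp window, which covers the read
lengths and damage rates the generator produces. The DP is restricted to
a window of one read length around the seed matches — shift-invariant
for a reference-local alignment, and verified against an unwindowed
full-matrix oracle in the tests. Mismatches are recorded 0-based from
the read's 5′ end in read orientation; minus-strand hits are complemented
back so that deamination surfaces in the frame the classifier inspects.

Hits are filtered at ≥95% identity (computed over all alignment columns,
gaps included) and within 10% of the read's best score — the score
window is the long-standing default of the naive-LCA family, exposed as
`top_percent`. Assignment then drops hits whose taxon is a strict
ancestor of another hit's taxon and places the read on the LCA of the
rest. Minimum support is off by default (`min_support_percent = 0`);
when positive, under-supported taxa donate their reads to their parent,
deepest first. Rank projection keeps reads assigned above the target
rank in explicit `*_unclassified` buckets so totals are conserved.
Marker-gene profiles are deliberately **not** rarefied — counts are few
and damage analysis needs every read — and relative abundances are used
instead; rarefaction (exact multivariate hypergeometric draws) is
available where a common depth is required, with the depth chosen as the
smallest library that contains the marker of interest.

# Control subtraction

The default mode (`remove_taxon`) zeroes, in every in-scope sample, any
taxon with at least one read in any in-scope control — conservative
whole-taxon removal. A `subtract_counts` mode instead reduces each
sample count by the per-taxon maximum across controls, floored at zero;
both are implemented and reported so the choice is auditable (count
subtraction is by construction not idempotent; whole-taxon removal is,
and the tests pin that). Scope defaults to per-site, matching how
controls are collected; summed-versus-maximum control counts is an open
call and maximum was chosen as the stricter of the two for repeated
controls.

# Tracer QC

Each measurement run carries duplicate-or-more blanks and calibrated
standards. Measurements are blank-corrected by subtracting the mean of
the run's blanks, floored at zero (concentrations are physical); the
detection limit is 3×SD of the blanks, falling back to 3×SD of the
lowest standard's replicates when the blanks have zero spread — the
regime the generator defaults to, with the standard spread set so the
fallback limit lands near a realistic ~0.23 ng/mL. Nominal standard
levels are scaled by the measurable stereoisomer fraction (0.88) before
calibration. The SD convention (sample, n−1) is configurable because the
alternatives differ at these tiny replicate counts. Correct-then-test is
a fixed order and a state flag makes double correction an error.
Verdicts report below-limit values as rejected, flag
periphery-vs-centre detections, and attach a caution note to centre
detections.

# What the generator emulates — and what it does not

The synthetic core reproduces the *structure* of a deep marine sedaDNA
study: a dated sample sheet with mudline and controls; libraries whose
composition steps from a diatom fraction of 0.08 to 0.50 at a 14.5 ka
boundary; lognormal fragment lengths with mode 56 bp (hard minimum 20);
age-graded damage; undamaged fungal contaminants injected into samples
(5%) and making up control libraries entirely; tracer runs with known
injected contamination classes; and geochemical covariates generated by
a Gaussian blend so their correlation with the damage driver hits
configured targets (defaults follow the correlation magnitudes typical
of organic-matter degradation indicators, e.g. 0.56 for ammonium).

It does **not** emulate: platform-specific error profiles or indels;
real marker-gene homology (references are independent random sequences,
so cross-taxon alignment ambiguity is far rarer than against a real
SILVA-style database); community ecology beyond fixed mixing
proportions; or chromatogram-level tracer measurement. Passing tests
therefore demonstrate that the pipeline's inference is correct *under
its stated model*, not that the thresholds would be optimal on real
expedition data.

# Numerical and design notes

* Boundary conventions are frozen in tests: length ≥ 25 retains, score
  ≥ threshold retains, a taxon at exactly 1% mean abundance stays
  separate from the rare group.
* Low-complexity filtering uses the distinct-k-mer fraction (k = 4,
  threshold 0.55); windows containing N are excluded from numerator and
  denominator, and reads too short to assess pass with a warning.
* Deduplication is exact-sequence and per-library; cross-library
  duplicates are retained because they are biologically plausible.
* Tie-breaks are deterministic everywhere: hits sort by score then
  `ref_id`; strand ties resolve to `+`; the DP traceback prefers
  diagonal moves.
* All randomness flows from a single seed per simulation; identical
  configuration and seed give byte-identical outputs.
* Problem sizes used by the tests and the acceptance script were chosen
  to make sampling error negligible relative to the asserted bounds:
  50,000 reads for damage-model recovery (binomial SE ≈ 0.002 at the
  fitted amplitude), 12 × 2,000 reads for the damage–age ranking,
  1,000 instances for each oracle comparison, 5,000 reads per sample for
  the transition study, 1,000 seeds for rarefaction expectations.
* The damage–age monotonicity study spaces its twelve amplitudes evenly
  from 0.03 to 0.33 so adjacent samples differ by more than the binomial
  noise at 2,000 reads per library.

# Known limitations

* The aggregate decay fit over a multi-sample core estimates a
  read-weighted average amplitude, not any single sample's $d_5$;
  per-sample spectra need per-sample read counts large enough for stable
  denominators.
* Identity filtering slightly censors the most heavily damaged reads;
  at the default rates this bias is within the quoted recovery bounds,
  but it would grow with amplitude.
* `remove_taxon` subtraction can delete genuine signal when a real taxon
  also drifts into controls; the report and contaminant list make this
  auditable rather than invisible.
* The LCA implementation walks parent pointers (adequate for
  marker-gene taxonomies of thousands of nodes); it is not engineered
  for full NCBI-scale trees.
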