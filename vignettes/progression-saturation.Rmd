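---
title: "Scoring progression saturation of analog series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring progression saturation of analog series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the method answers

During lead optimization a medicinal-chemistry team keeps making analogs of
a series until, at some point, further synthesis stops paying off. progsat
quantifies how close a series is to that point by comparing the compounds
that *exist* with the candidate analogs that *could still be made*, in a
fixed chemical descriptor space. The intuition: a series is saturating when
(i) its assayed analogs already blanket the space reachable from its core,
and (ii) the neighborhoods of its *active* analogs contain almost no
remaining candidates — the chemistry around what works has been exhausted.

## The procedure

1. **Analog series extraction.** Every compound is fragmented at single
   acyclic bonds matching a retrosynthetic (RECAP-style) rule set. Each cut
   splits the molecule into a core (the larger fragment) and a substituent,
   both carrying one attachment point; compounds sharing a core within the
   same assay form a candidate series. A qualifying series has at least 30
   analogs tested in the same assay and at least 3 actives. The series lead
   is the active analog with the highest ligand efficiency,
   LE = 1.37 · pIC50 / N (kcal/mol per heavy atom, N = non-hydrogen atom
   count).
2. **Virtual candidates.** A substituent fragment library is built by
   applying the same fragmentation to a donor compound set and removing
   every substituent already observed in the analyzed series (candidates
   are novel by construction). Each library fragment is attached to each
   series core; products that fail sanitization, duplicate one another, or
   equal an assayed member are dropped and counted.
3. **Reference space.** Seven descriptors per molecule — molecular weight,
   H-bond donors/acceptors, rotatable bonds, logP, an aqueous-solubility
   estimate (log S), and topological polar surface area — are scaled to
   zero mean and unit variance, and all relationships are Euclidean
   distances in the scaled space.
4. **Dual scores.** With `S` the assayed members, `A ⊆ S` the actives and
   `V` the virtual candidates of a series:
   - the **global score** is |ν_assayed|/|V|, the fraction of candidates
     within radius `r_global` of at least one member, where `r_global` is
     the median of the pooled distances from each candidate to its top-1%
     nearest candidate neighbors;
   - the **local score** is |A|/|ν_active|, the number of actives over the
     number of candidates within radius `r_local` of at least one active,
     where `r_local` is the median pairwise distance between actives.
5. **Normalization and stages.** Global scores are z-scored over the
   ensemble of all scored series; local scores are z-scored after a natural
   log transform. A score is *high* when z ≥ 1. The four combinations map
   to optimization stages: low/high → early, low/low → intermediate,
   high/low → late, high/high → saturated (the "saturation alert").

```{r}
library(progsat)
ex <- worked_example()
res <- score_saturation(ex$compounds, donors = ex$donors,
                        min_members = 6, min_actives = 3)
tidy(res)
autoplot(res)
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_members` | 30 | minimum analogs tested in one assay for a qualifying series |
| `min_actives` | 3 | minimum active analogs |
| `fraction` | 0.01 | nearest-neighbor fraction defining `r_global`; k = max(1, floor(fraction·(\|V\|−1))) |
| `threshold` | 1.0 | z-score at or above which a score counts as high |
| `max_sub_heavy` | 13 | substituent size cap (heavy atoms) for cuts used in series formation |
| `scaler_population` | union | fit the scaler on assayed ∪ virtual compounds (one constant space per run); `"assayed"` restricts the fit |
| `exclusion_scope` | global | fragments observed in *any* analyzed series are excluded from the library; `"series"` excludes per series |

Both scores are ensemble-relative: z-scores computed over two series can
never exceed |z| = 1/√2, so stage categories are only meaningful for
ensembles of, say, ten or more series — or against a stored reference
(`reference =`, persisted in every report) from a prior run.

## Numerical and design choices

- **Neighborhood membership uses closed balls** (distance ≤ radius).
  Distances are accumulated per descriptor dimension so that vectorized
  and naive evaluations agree bit-for-bit at the ball boundary.
- **Top-1% neighbor count** rounds down with a floor of one:
  k = max(1, floor(0.01·(|V|−1))); the pooled distances (not per-compound
  medians) feed one median.
- **Empty active neighborhoods** (ν_active = ∅) leave the local score
  undefined; the implementation substitutes a 0.5 pseudo-count denominator
  so the series ranks as maximally saturated while staying finite, and
  flags the series `saturation_extreme`.
- **Degenerate geometry** (all candidates coincident) yields radius 0 with
  a warning; constant descriptor columns scale to 0 with a warning.
- **Ties in lead selection** break by higher potency, then smaller heavy-atom
  count, then lexicographic id. Ties in core/substituent assignment break
  by canonical SMILES order.
- **The logarithm base** of the local-score transform is immaterial: a base
  change shifts and scales before z-normalization and cancels exactly.
- **Standard deviations** use the sample convention (n − 1) throughout.
- **Descriptors** are open-implementation equivalents (OpenBabel
  Crippen-type logP and Ertl TPSA, Lipinski donor/acceptor counts, a strict
  rotatable-bond definition excluding amides and terminal/triple-bonded
  atoms, and an ESOL-style log S regression on logP, MW, rotatable bonds
  and aromatic proportion). Absolute descriptor values differ between
  toolkits; the method is explicitly representation-agnostic, and every
  score is defined relative to the run's own reference space.
- **RECAP rule set** (11 bond types: amide, ester, amine, urea, ether,
  olefin, quaternary N, aromatic N–aliphatic C, lactam N–aliphatic C,
  aromatic C–aromatic C, sulfonamide) is implemented over the molecular
  graph with OpenBabel's aromaticity/amide perception. Only acyclic bonds
  are cut, so rings survive and every cut reattaches exactly; the olefin
  rule is the one double-bond type and its order is recorded so the
  round trip restores it.
- **A compound may seed several series** (one per distinct core);
  `exclusive = TRUE` assigns each compound to its largest qualifying
  series only. Whether the original corpus restricted membership is not
  determinable, so the permissive behavior is the default.
- **Scaler fit population.** Fitting the constant space on the union of
  assayed and virtual compounds keeps all per-series clouds in one frame;
  the `assayed`-only option exists because either reading of a "constant
  reference space" is defensible.

## The synthetic-data generator

Real corpora of assayed series with candidate clouds cannot be shipped, so
the generator builds them: each series is a set of amide parents
`R–C(=O)–NH–scaffold` over one of 40 distinct aryl-amine scaffolds, with
acyl substituents drawn from a 165-fragment alphabet of graded size and
polarity (alkyl chains, branched and halogenated variants, ethers, amines,
cycloalkyls, substituted aryls and heteroaryls; capped at 11 heavy atoms so
the scaffold is always the larger fragment). Donor compounds carry the
same alphabet on a separate, larger scaffold, so the fragment library and
every virtual cloud emerge from the real extraction and enumeration code
paths rather than being injected.

Two knobs place a series in a regime, both operating in the alphabet's own
scaled descriptor space:

- **coverage** sets the size of the nearest-neighbor ball (around a seeded
  center fragment) from which members are sampled radially — how much of
  the reachable chemistry the series has explored;
- **active_dispersion** places the actives: below 0.5 they sit in a densely
  synthesized contiguous patch (the nearest eligible fragments around a
  seeded sub-center all become members, every s-th one active), above 0.5
  they spread evenly across the member set. This is the latent activity
  rule: actives are exactly the members inside a regime-dependent sphere.

About a quarter of the alphabet (45 fragments selected by content hash,
hence spatially uniform in descriptor space) is reserved for the fragment
library and never used as a member substituent, so candidate clouds interleave the member chemistry at any
ensemble size. Default regime settings are early (coverage 0.25,
dispersion 0.35, 32 members), intermediate (0.50, 0.9, 35), late
(0.75, 0.9, 40) and saturated (0.90, 0.1, 45); actives default to 5.
Member counts grow with progression deliberately: well-covered series are
well covered partly because more analogs have been made, an effect the
dual scoring is designed to contextualize rather than hide. Active
potencies are drawn log-uniformly between 10 µM and 10 nM.

**What passing tests do and do not show.** The generator produces real,
parseable molecules, but its chemistry is a regular amide grammar: one cut
chemistry dominates, substituent effects vary smoothly, and activity is a
clean function of descriptor position. Passing the regime-recovery tests
shows that the scores order coverage and active-neighborhood crowding as
designed; it does not show that real SAR landscapes — activity cliffs,
assay noise, heterogeneous cut chemistries, correlated multi-site
series — are classified correctly.

## Problem sizes

The test-suite and acceptance runs use a 40-series ensemble (10 per
regime, 32–45 members each, ≈ 1 500 compounds, ≈ 200 donors, ≈ 55
candidates per series after exclusion) plus oracle checks on random point
sets of up to 500 compounds; these sizes exercise every code path while
keeping a full run in minutes on one core.

## Known limitations

- Scores are relative to the scored ensemble; absolute values are not
  transferable across runs unless a stored reference is reused.
- Virtual ids are content hashes of canonical structure; different
  OpenBabel versions may canonicalize differently, so ids are stable
  within, not across, toolkit versions.
- Single-cut analog series only; multi-site matched series, scaffold
  hopping, potency-weighted scores and activity-cliff analysis are out of
  scope.
- The solubility descriptor is a regression estimate, not a measurement;
  it exists to span a solubility axis in the reference space, not to
  predict solubility.
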