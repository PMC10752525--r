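---
title: "Designing diverse screening libraries with chemfunnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing diverse screening libraries with chemfunnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Phenotypic and target-based screening against neglected pathogens needs
compound libraries that are (i) novel — not already screened by everyone
else, (ii) diverse — covering as many chemotypes as the budget allows, and
(iii) lead-like — small and polar enough that hits can grow during
optimisation. Make-on-demand virtual catalogs (billions of enumerable
products of two-component reactions over commercial building blocks) are an
attractive source, but selecting tens of thousands of compounds from
billions requires a disciplined, auditable funnel. chemfunnel implements
that funnel as a set of composable R modules: enumeration, structural-alert
filtering, staged physicochemical windows, diversity selection, novelty
filtering, composition-constrained final draws, and scaffold/chemical-space
analytics to profile the result.

Chemistry primitives (SMILES parsing and canonicalization, SMARTS matching,
circular fingerprints, Bemis–Murcko decomposition, 2D descriptors, reaction
application) are computed by RDKit through a bundled Python bridge
(`inst/python/rdkit_bridge.py`); every call is batched so one interpreter
start-up serves a whole compound set. The interpreter is located with
`Sys.which("python")` and can be overridden via
`options(chemfunnel.python = ...)`.

## The model, stage by stage

**Basis sets.** A two-component reaction with block lists $A$ and $B$ has
$|A| \times |B|$ products — too many to review. The basis set represents the
reaction with $|A| + |B| - 1$ products: every $A$-block coupled to the
lowest-molecular-weight $B$-block, plus every remaining $B$-block coupled to
the lowest-MW $A$-block (ties on MW broken lexicographically by canonical
SMILES — the tie rule is a package convention, the formula is normative).
100 amines and 200 acids give exactly 299 basis amides. Triage review files
take the 3 lowest-MW products plus 5 uniformly sampled others per reaction
(`sample_representatives()`); the human accept/reject outcome is represented
as an explicit `include_sublibraries` list in the funnel config —
reproducible and auditable, never simulated.

**Structural alerts.** SMARTS sets (a public PAINS subset, reactive/toxic
functionality such as aromatic nitro groups and acid halides, and a
user-extensible project set with thioethers and sulfoxides) are matched by
presence, once per alert. A malformed SMARTS fails the whole load with line
numbers: alerts must never silently vanish. Institutional sets in the common
`smarts,name` layout load unchanged.

**Property windows.** Three staged windows, all bounds *closed* (a compound
at MWt exactly 320 or 380 passes — the conservative reading of printed
ranges):

| stage  | MWt     | slogP  | HBD | HBA | RotB | SFI |
|--------|---------|--------|-----|-----|------|-----|
| wide   | ≤ 450   | ≤ 5    | ≤ 4 | ≤ 8 | ≤ 8  | —   |
| crude  | 320–420 | 0–4.5  | 0–3 | 0–8 | 1–8  | —   |
| agreed | 320–380 | 1–3    | 0–3 | 0–8 | 1–7  | 2–6 |

SFI (Solubility Forecast Index) is `clogD(pH 7.4) + #aromatic rings`; lower
forecasts better solubility. Because no clogD engine is part of the stack,
clogD is approximated as slogP minus a fixed 1.0 ionization penalty for
compounds classified acid or base (monoprotic ionization at pH 7.4 shifts
logD down roughly one unit) and 0 for neutrals; the function is pluggable
(`compute_properties(clogd_fun = ...)`) so a commercial predictor can be
dropped in. Charge classes are substructure-based, not pKa-based: acids are
carboxylic acids, tetrazoles and acyl sulfonamides; bases are aliphatic
amines, amidines and guanidines, with amides, anilines, sulfonamides and
azoles excluded; acid takes precedence when both match (amino acids are
acids). Rotatable bonds follow the dominant convention (non-ring single
bonds between non-terminal heavy atoms, amide C–N excluded).

**Diversity.** Fingerprints are Morgan/circular, radius 2, 1024 bits —
stereo-insensitive, which is why deduplication and novelty joins also use a
stereochemistry-free canonical key. Pairwise statistics are computed
*exactly* in blocks at any size (no sampling); the reported count is over
ordered pairs, $n(n-1)$, whose mean equals the unordered mean by symmetry.
The histogram defaults to 50 right-closed bins on $[0,1]$. Per-sublibrary
quotas are `pool_size^exponent × (1 − mean_pairwise_similarity)`, normalized
by largest-remainder rounding and clamped to pool sizes with redistribution:
larger and internally less redundant sublibraries contribute more. The
original campaign said only that quotas were "based on an assessment of the
mean pairwise similarity"; this proportional form is an explicit, documented
choice, and the resulting `quota_plan` is inspectable and overridable, so
any hand-tuned allocation can be reproduced. MaxMin selection is greedy on
Tanimoto distance (1 − similarity): the first pick is pseudo-random from the
seed (matching common picker behaviour; an explicit `first` argument
overrides it), each later pick maximizes its minimum distance to the picked
set, and ties within 1e-12 break by canonical SMILES order, so runs are
fully deterministic.

**Novelty.** A compound is removed iff its maximum Tanimoto similarity to
the exclusion set is *strictly* greater than the threshold (default 0.5): a
compound at exactly 0.5 is retained. Removal of commercially available
compounds is a different operation — an exact join on the stereo-free
canonical key (`remove_known()`), not a similarity search.

**Composition.** The final draw is stratified over complexity × charge
class: the simple:complex ratio (default 70:30 — simple means 1–2 step
chemistry with cheap blocks; complex means multistep, expensive blocks or
special purification) is hit exactly (±1 by rounding), and charge targets
(default neutral 60%, base 33%, acid 7%) as closely as each stratum allows,
with largest-remainder rounding and proportional relaxation plus a warning
when a stratum runs short. The reserve (default 15,000 against a 30,000
final library) is drawn from the remainder with the same stratification.
Defaults for `final_size`/`reserve_size` reflect the production-scale
campaign; desk-scale runs set them explicitly.

**Scaffold analytics.** Bemis–Murcko scaffolds keep ring systems and
linkers, dropping side chains but retaining exocyclic double bonds (the
common convention). Generic frameworks abstract every atom to carbon and
every bond to single; because that genericization turns retained exocyclic
substituents into methyl side chains, the framework op strips once more so
frameworks are a true topology-only fixpoint (idempotent). "Unique
fraction" is `100 × distinct / compounds` — the only reading consistent
with the published comparisons across differently sized sets; the
alternative (fraction of scaffolds occurring exactly once) is reported
alongside as `singleton_fraction`. Acyclic molecules have no scaffold and
are excluded from both numerator and denominator by default
(`include_acyclic = TRUE` adds one shared bucket); the choice moves the
fraction by a couple of points, which is why the deposited-data acceptance
checks carry a ±2-point tolerance.

**Chemical space.** 200 two-dimensional descriptors (the first 200 of
RDKit's canonical descriptor list — the published "200" names no list, so a
deterministic, recorded panel is used), standardized to zero mean and unit
variance (otherwise molecular weight dominates), reduced by PCA to 30
components, then embedded by t-SNE (perplexity 50, 15000 iterations —
the stated analysis parameters; tests and examples pass smaller values
explicitly to stay fast, which changes the run, not the defaults). KMeans
cluster composition runs on the PCA space, not the 2-D coordinates, which
distort distances; `k` defaults to 8 and is always recorded. Note sklearn's
t-SNE is not permutation-equivariant: permuting input rows permutes the PCA
scores exactly but can change t-SNE coordinates, so row alignment is
guaranteed structurally (ids), not numerically.

## The synthetic-data generator

`generate_pool()` builds labelled sublibrary pools by fragment-grammar
assembly (head × linker × cores × tail), which guarantees validity by
construction: heads carry the intended charge class, saturated bridged/spiro
cores mark complex chemistry, a thioether tail or nitroaryl ring plants a
structural alert, and per-sublibrary redundancy shrinks the core pool so
mean pairwise similarity rises. Planted label counts are exact
(largest-remainder of the spec fractions) and the generated labels are
*recovered exactly* by the corresponding pipeline stages — that
planted-truth recovery is the module's reason to exist. Molecular weights
span roughly 190–620 with the two-ring median near 350, so the staged
windows have both survivors and casualties. `generate_exclusion()` plants
near-duplicates by single fragment edits, verified > 0.5 Tanimoto to their
parents at generation time (re-edited otherwise), plus unrelated decoys.

What the generator does **not** emulate: the chemistry coverage or scale of
a real make-on-demand catalog, correlated property distributions of real
reaction families, stereochemistry, or realistic clogD. A green test
establishes that the pipeline logic is correct on a world with known truth —
not that the production library would be reproduced bit for bit.

## Numerical choices

- Largest-remainder apportionment everywhere a fraction becomes a count;
  remainder ties break by position (stable and documented).
- Per-stage seeds fan out from the master seed as
  `(master × 10007 + index × 7919) mod (2^31 − 1)`, so any stage can be
  re-run in isolation.
- Tanimoto of two empty fingerprints is defined as 0 (cannot occur for real
  molecules, which always set at least one bit).
- Salt stripping keeps the largest fragment by heavy-atom count, ties by
  molecular weight; unparseable rows are quarantined with reasons, never
  silently dropped and never fatal for bulk tables (curated building-block
  lists, by contrast, fail fast).
- CSV structure columns are auto-detected case-insensitively (any name
  containing "smiles" or "structure") when the default `SMILES` is absent.

## Limitations

- The deposited structure tables of the two published libraries are not
  redistributable inside the package, so the acceptance checks that need
  them fail with an explanatory message until the files are placed under
  `inst/extdata/ghcdl/` (`ghcdl_v1.csv`, `ghcdl_v2.csv`).
- clogD (and hence SFI) uses the fixed-penalty approximation above; absolute
  SFI values can differ by a few tenths from commercial predictors.
- slogP implementations differ by ±0.3 across engines; window checks on
  logP-like quantities should be read with that in mind.
- No multi-step route planning, ≥3-component reactions, pKa prediction, 3D
  descriptors, UMAP, or vendor-API integration.
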