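---
title: "Methods: in-silico design of micro-oxic growth capability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico design of micro-oxic growth capability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anaerodesign)
```

This vignette documents the models, algorithms and design choices behind
the package: what each stage computes, which parameters matter, what the
synthetic generators emulate, and where the numerical edges are.

## The constraint-based model and FBA

A metabolic model is a set of metabolites and stoichiometrically defined
reactions with flux bounds in mmol/(gdw h). Flux Balance Analysis predicts
the specific growth rate as the optimum of the linear program

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0, \; lb \le v \le ub,$$

with $c$ selecting the biomass pseudo-reaction. The assumptions are the
usual ones: steady state (no metabolite accumulation), a fixed biomass
composition, and growth limited only by the declared uptake bounds. Medium
composition enters exclusively through exchange-reaction lower bounds
(uptake is negative flux; secretion bounds are left open), so
`apply_medium()` never touches stoichiometry.

Tunable parameters, with defaults and rationale:

* **Growth threshold** `GROWTH_EPSILON = 1e-6` h^-1. Predictions below it
  count as "no growth". FBA optima are exact LP solutions, so the
  threshold only needs to absorb solver roundoff; 1e-6 is far above the
  kernel's working precision and far below any biologically meaningful
  growth rate.
* **Uptake limits**: glucose at most 6.14 mmol/(gdw h) in the
  minimal-glucose preset (an experimentally measured uptake rate), O2 at
  most 18.5 under the oxic overlay, and 1000 as the "effectively
  unlimited" cap for minerals and for rich-medium compounds. The presets
  resolve compound identity by metabolite name/formula because compound
  ids differ between reconstructions; matches are overridable via
  `extra_limits`.

### The LP kernel and its numerical choices

The package carries its own bounded-variable two-phase primal simplex
(`R/lp.R`). FBA systems are degenerate by construction — conservation
rows (e.g. a phosphate pool) are often linearly dependent and optima sit
on degenerate vertices — so the kernel (i) drops redundant rows by QR
rank reduction, (ii) uses Bland's rule, which provably terminates under
degeneracy, and (iii) recomputes the basic solution from the basis
factorization at every iteration instead of updating it incrementally.
That trades speed for robustness, which is the right trade at desk scale
(tens of reactions; every problem in this package solves in
milliseconds). Pivot tolerance is 1e-9; phase-1 residuals above 1e-7
report infeasibility. Feasible problems are never unbounded here because
all bounds are finite — a non-finite bound is rejected as a
mis-configured medium rather than solved.

Two deliberate contract decisions: only mu is stable across runs and
backends (alternate optima make flux vectors advisory; no secondary
flux-minimization objective is imposed), and an infeasible model — e.g.
a maintenance demand that cannot be met — is reported with
`status = "infeasible"` and `mu = 0` so growth screens treat it as "no
growth" while keeping the flag visible.

## O2 essentiality scan

`o2_essentiality_scan()` finds every reaction whose stoichiometry touches
a molecular-oxygen metabolite and deletes each one alone, recording the
re-optimized mu. Choices worth stating:

* **Deletion = zero bounds**, not structural removal, so reports stay
  aligned with the original reaction index and restoring a reaction is
  exact.
* **O2 exchange and transport reactions are excluded by default**:
  deleting them merely simulates anoxia and would trivially dominate the
  scan, which is after *enzymatic* O2 dependencies. Flags re-include
  them.
* **O2-producing reactions are scanned too** and annotated via
  `o2_role`, letting the user filter; there is no principled reason to
  exempt them a priori.
* The scan refuses a non-growing baseline (the result would be
  vacuous), and O2 detection prefers the elemental formula `"O2"` with a
  fallback to common id patterns, since not every model carries
  formulas.

## Intervention library and design grid

`builtin_designs()` ships nine attributed reaction sets covering
anaerobic ATP generation (acetate kinase; the ethanologenic
PDC/ADH route; lumped nitrate respiration; denitrification steps; a
generic electrode/mediator electron sink) and O2-independent
biosynthesis (class I dihydroorotate dehydrogenase, class III
ribonucleotide reductase with thioredoxin recycling, fumarate-coupled
l-aspartate oxidase, quinone-dependent protoporphyrinogen oxidase).
Published descriptions of such designs name the enzymes but not model
stoichiometries, so the shipped definitions follow the named
biochemistry with standard metabolite formulas; they are balanced for
C, N, O, P and S (protons and charge are host-model-specific and left
unbalanced; thioredoxin uses a small pseudo-formula). Assumptions are
recorded per reaction in its provenance string — e.g. nitrate reduction
translocates 2 H+ per nitrate. The library also exists as plain JSON
(`inst/extdata/design_library.json`), so designs can be added or
overridden without code changes.

`evaluate_designs()` classifies each combo-by-condition cell against the
wild-type oxic reference mu_ref with half-open intervals: `none` below
`GROWTH_EPSILON`, `poor` from the threshold up to (exclusive)
`poor_fraction * mu_ref`, `growth` at or above it. `poor_fraction`
defaults to 0.10 — "poor growth" is not a standardized quantity, and one
tenth of the aerobic wild-type rate is a conservative, configurable cut
that places a percent-scale anaerobic rate in the poor band for a
typical aerobe.

## Comparative core-domainome

Domain presence is genome-level boolean (a domain counts if at least one
gene carries it), and InterPro accessions are the comparison unit —
member-database signature rows without an IPR mapping are dropped and
counted, with no e-value filtering (annotation pipelines have already
applied their own cutoffs). The exclusive core is plain set algebra:

$$X(T, B) \;=\; \bigcap_{g \in T} D_g \;\setminus\; \bigcup_{g \in B} D_g$$

for target panel $T$ and background panel $B$. Two invariants are
asserted on every call: $X \subseteq \bigcap_T D_g$ and $X$ disjoint
from every background set. Categorization assigns each accession exactly
one of `atp_generation`, `unknown_function`, `other`; unmapped
accessions default to `unknown_function` because nothing can be claimed
about them. The shipped map covers only accessions with well-established
roles (acetate kinase IPR000890; ribonucleotide-reductase-associated
IPR012833/IPR012840 as ATP-relevant anaerobic metabolism;
siderophore-transport, pilus-assembly and iron–sulfur-cluster domains as
`other`); a study-specific map should be supplied for full shortlists.

## What the synthetic generators emulate — and what they do not

### Toy metabolic model

`make_toy_model()` reproduces the *logic* of a strict aerobe in ~15
reactions: a redox-neutral glycolytic lump (substrate-level ATP yield
`substrate_level_atp = 1` per glucose), O2-dependent respiration
(`atp_per_o2 = 5`), four O2-dependent biosynthesis steps feeding
biomass, an acetyl-phosphate overflow valve, and a maintenance drain
(`maintenance_atp = 2` mmol/(gdw h), enforced as a lower bound). The
glucose bound defaults to 10 mmol/(gdw h) and the oxic O2 bound to 18.5,
matching the scale of the shipped media presets.

With glucose bound $g$, substrate yield $s$, maintenance $m$ and biomass
ATP demand $b$, the anoxic optimum with the O2-independent alternatives
is ATP-limited at $\mu_{alt} = (sg - m)/b$, and with acetate kinase
$\mu_{ack} = ((s+2)g - m)/(b+4)$. The generator solves

$$b = \frac{8\,(sg - m)}{(2-s)\,g + m}$$

in closed form so that $\mu_{ack} = 2\,\mu_{alt}$ *exactly* — the
doubling is engineered algebraically, not tuned by search, which keeps
the oracle for recovery tests trivial. The generator validates its
regime (maintenance coverable, ATP-limited rather than carbon-limited)
and errors naming the violated budget otherwise. The model is
deterministic: no RNG anywhere, so FBA examples reproduce bit-for-bit.

The pseudo-formula scheme conserves C (carbon units) and P (phosphate);
O is the lumped redox bookkeeping element and is deliberately *not*
conserved (the network has no explicit electron carriers), so balance
checks on the toy run over C and P. What the toy does not emulate:
realistic yields or growth-rate magnitudes, redox-carrier pools,
by-product toxicity, regulation, or the thousands-of-reactions scale of
a genome-scale reconstruction. Passing tests therefore certify the
*algorithms* (scan logic, monotonicity, classification, exact recovery),
not quantitative predictions for a real organism.

### Domain tables

`make_domain_tables()` writes one TSV per genome for a 6-vs-6 panel with
a planted 47-domain exclusive core (defaults mirroring the scale of a
real *Pseudomonas* panel; any sizes work), an 800-domain shared genus
core with 5% per-genome dropout, and 2000 accessory "noise" domains
included per genome with probability 0.3 — numbers in the range of
domain content and core/accessory splits seen in bacterial genus panels.
Two semantics matter:

* Dropout never applies to planted exclusive domains (they define the
  recoverable truth), and planted domains never enter background
  genomes (asserted after writing).
* With thousands of independent noise domains, some will *by chance*
  form a target-exclusive pattern (expected count
  $n_{noise} \, p^{6} (1-p)^{6} \approx 1$ at defaults). The generator
  deterministically breaks every such chance pattern by adding the
  domain to the first background genome. This is part of the generator's
  contract — the planted set is the *exact* exclusive core — and is
  precisely the feature real panels do not have: on real genomes the
  shortlist can contain coincidental absences, and no test here says
  otherwise.

A `planted_truth.json` sidecar accompanies every dataset so downstream
recovery checks read expectations from it rather than hard-coding them.

## Pipeline and reproducibility

`run_pipeline()` is a thin composition of the stage functions — load,
media sweep, scan, design grid, domainome — plus one join: each
essential O2 reaction is paired with the design set that bypasses it
(keyword mapping on reaction identity, with notes where an endogenous
route may suffice, e.g. a HemJ-type protoporphyrinogen oxidase), and
shortlist domains categorized `atp_generation` are cross-referenced with
the ATP-generating design sets. There is no pipeline-only computation
beyond this join, which is what the stage-equivalence tests assert. With
a fixed seed all reports are byte-identical across runs except the
timestamp line of `run.log`; a failing stage aborts with a stage-named
error and leaves completed outputs plus a MANIFEST.

Problem sizes throughout the test suite and acceptance script — toy
networks of 4–15 reactions, 100 random networks for oracle equivalence,
10 seeds of 12-genome panels with ~2800 domains each — were chosen as
the smallest sizes at which every claimed property is exercised
non-trivially; all are desk-scale by design.

## Known limitations

* The simplex kernel is dense and unfactorized; it is not meant for
  genome-scale models (thousands of reactions). The solve contract is
  deliberately small so a faster backend could be swapped in.
* SBML support targets the Level 3 FBC v2 subset the package writes
  (species, compartments, shared flux-bound parameters, one maximization
  objective); gene-product associations and annotations are not
  round-tripped through SBML (they are in the JSON dialect, stored but
  never evaluated).
* Medium presets match compounds by name/formula heuristics; for models
  with unusual nomenclature the limits must be supplied explicitly.
* The domainome arm consumes pre-computed annotation tables; it does not
  run gene prediction or InterProScan, and category assignments beyond
  the shipped accessions require a user-supplied map.
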