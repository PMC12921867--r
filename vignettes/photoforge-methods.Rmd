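---
title: "Methods: desk-scale inverse design of EnT photocatalysts"
author: "photoforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale inverse design of EnT photocatalysts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoforge)
```

# The problem

Organic energy-transfer (EnT) photocatalysts must combine several
photophysical properties at once: an adiabatic triplet energy
$\Delta E_T$ above the substrate's triplet energy, useful absorption
($\lambda_{max}$), an efficient intersystem crossing (ISC) to populate the
triplet state, and a rigid scaffold that keeps the triplet alive. No single
property identifies a good sensitizer; the design problem is inherently
multi-objective, and the chemical space of candidate chromophores is far
too large to screen exhaustively.

`photoforge` implements the full desk-scale workflow for this problem:

1. a **multi-objective reward** that maps predicted properties onto
   $[0,1]$ and aggregates them multiplicatively, with hard structural
   vetoes;
2. a **$\pi$-electronic engine** (Hückel theory) supplying cheap proxies
   for the quantities that govern ISC;
3. a **seedable generative optimizer** (a genetic algorithm over molecular
   graphs) with a scaffold-diversity filter;
4. a **triage funnel**: threshold filtering, fingerprint clustering for
   diverse candidate selection, and combinatorial enumeration of a local
   quinoxaline library with lead screening.

# The reward model

Each property $x_i$ is transformed to a component score
$s_i \in [0,1]$ by a rising or falling sigmoid
$\sigma(x) = 1/(1+e^{-k(x-c)})$, a band-pass *double sigmoid* (the product
of a rising sigmoid at the lower band edge and a falling one at the upper
edge), or a strict step indicator. The total score of a molecule is the
weight-normalized geometric mean

$$S \;=\; \prod_i s_i^{\,w_i/\sum_j w_j},$$

which is bounded by the smallest and largest component score, equals $c$
whenever all components equal $c$, and is comparable across reward
specifications with different numbers of components. A raw-product mode
(`normalizeWeights = FALSE`) is available. "Weighted multiplication" admits
both readings; the normalized form was chosen because it makes scores
scale-free in the number of objectives. Any matched structural alert
short-circuits the whole computation to $S = 0$ — vetoes dominate every
property.

**Default steepness.** Published campaigns state thresholds but not sigmoid
steepnesses. The package default makes a sigmoid rise from 0.1 to 0.9 over
10 % of its center value ($k = 2\ln 9 / (0.1\,|c|)$), sharp enough to act
as a soft threshold and smooth enough to give the optimizer a gradient.
All steepnesses are configurable per component.

**Presets.** Four named reward presets carry the published threshold sets:
*rediscovery* ($\Delta E_T > 58$ kcal/mol, $\lambda_{max} > 365$ nm,
$\theta_{conj} > 0.5$; no vetoes), *exploration* ($>55$, $>330$, $>0.5$,
plus an $O_{FMO}$ component and the full alert catalog), *global-triage*
($>60$, $>350$, $\lambda_{max\text{-}sTDA} > 325$) and *local-lead*
($>57$, $>290$). The $O_{FMO}$ component rewards **low** overlap (a
falling sigmoid at 0.5): a small frontier-orbital overlap means a small
exchange interaction, hence a small $\Delta E_{S_1\!-\!T_1}$ and a
suppressed radiative channel — both favor ISC. Component weights default
to 1; the published weights are not stated, so the presets document these
as package choices.

## Structural alerts

The default catalog vetoes the five motifs excluded from exploration-style
campaigns: carbonyls (HAT-prone aryl ketones among them), single/double
bonds between two of {N, O, S, P}, aliphatic amines, alcohols, and
non-aromatic olefins. Decisions worth noting:

* *Olefins in rings count.* Photodecomposition of olefins is not specific
  to acyclic C=C, so any non-aromatic C=C matches.
* *Aromatic heteroatom–heteroatom bonds count* (pyridazine-type N–N): they
  are formally single/double bonds between heteroatoms.
* *Aliphatic amine* means an sp³ nitrogen with no aromatic neighbor;
  anilines pass. Amide nitrogens match this definition — a deliberate
  simplification, acceptable because amides are rare in the targeted
  chromophore space.
* Alerts are evaluated as graph predicates on the package's own molecular
  graph; user-supplied SMARTS patterns are matched through the OpenBabel
  command-line tool and can replace or extend the catalog via YAML.

# Molecules and descriptors

Every molecule is canonicalized through OpenBabel
(`ChemmineOB::convertFormat`), and the canonical SMILES is parsed into an
explicit heavy-atom graph (element, aromaticity, formal charge, hydrogen
count per atom; order and aromaticity per bond). Canonicalization is the
single identity relation in the package; unparsable SMILES raise a typed
error that scoring loops convert into score 0 rather than a crash.
Stereochemistry is accepted on input and ignored throughout (a declared
non-goal), as are tautomer normalization and 3D geometry.

**Conjugated fraction.** $\theta_{conj}$ is the number of conjugated
heavy-atom bonds divided by all heavy-atom bonds. A bond is conjugated if
it is aromatic, has order $\ge 2$, or is a single bond whose two ends are
both $\pi$ atoms (aromatic or multiply bonded) or a $\pi$ atom and a
lone-pair donor heteroatom. Hydrogens are excluded from numerator and
denominator; counting them would make the descriptor depend on
implicit-hydrogen conventions rather than on the molecule. Single-atom
molecules define $\theta = 0$ (logged as degenerate).

**Scaffolds.** Bemis–Murcko frameworks are computed by iteratively
deleting terminal atoms connected by a plain single bond; terminal atoms
held by a double bond (exocyclic carbonyls such as the thioxanthone
ketone) remain part of the framework. Acyclic molecules map to an explicit
empty-scaffold sentinel, and only the largest fragment of a multi-fragment
input is considered, so exactly one scaffold is assigned per molecule.
Three generalization modes are provided because "generalized scaffold"
admits several conventions: `murcko` keeps atom identities and bond orders,
`generic_bonds` equalizes all bonds, `fully_generic` additionally maps all
atoms to carbon. The default is the atom-typed `murcko` mode: a fully
generic key cannot distinguish a thioxanthone-like framework from a plain
carbocycle when the difference is heteroatoms only, and that distinction
matters for scaffold-occurrence analytics. The modes are strictly nested:
equal `murcko` keys imply equal `fully_generic` keys.

**Fingerprints.** A deterministic circular (Morgan-style) fingerprint is
computed on the package graph: iterative neighbor-invariant hashing for
`radius` rounds (default 2), folded into `nbits` bits (default 2048). The
hash is plain 31-bit modular arithmetic, so vectors are identical across
platforms and sessions. No installed R package provides a circular
fingerprint with this (radius, nbits) contract, which is why it is
implemented here.

# The Hückel engine and the ISC proxies

Computing ISC efficiency rigorously needs spin–orbit couplings and
excited-state calculations far beyond a desk-scale package. The package
instead follows the golden-rule structure of the rate,

$$k_{ISC} \propto \frac{\langle S_1|H_{SO}|T_1\rangle^2}{(\Delta E_{S_1-T_1})^2},$$

and supplies the pieces from the cheapest defensible electronic model:

* **Hückel theory** on the conjugated subgraph. The largest connected
  component of the conjugated-bond graph becomes the $\pi$ system; the
  Hückel matrix carries Coulomb shifts $h_X$ on the diagonal and bond
  scalings $k_{XY}$ on $\pi$ bonds, in units of $|\beta|$. The parameter
  table ships standard Streitwieser/Van Catledge-type values (e.g.
  pyridine-type N 0.51/1.02, pyrrole-type N 1.37/0.89, carbonyl O
  0.97/1.06); heteroatom–heteroatom scalings use the product rule
  $k_{XY} = k_{CX} k_{CY}$. Electron counting is the textbook rule: one
  electron per atom in a localized multiple bond or aromatic CH, two for
  lone-pair donors (pyrrole N, furan O, aniline N), with charges
  subtracted. Odd electron counts raise an explicit open-shell error.
* **Energy scale.** $E = -x\,|\beta|$ with $\alpha = 0$ and
  $|\beta| = 2.4$ eV by default. The value is an order-of-magnitude
  convention (it puts the benzene gap $2|\beta| = 4.8$ eV, i.e. 258 nm, in
  a plausible place); it is a config knob, not a fit.
* **$O_{FMO}$** is the atom-condensed density overlap
  $\sum_a \sqrt{\rho_H(a)\rho_L(a)}$ with $\rho$ the squared orbital
  coefficient per atom — bounded in $[0,1]$ by Cauchy–Schwarz, 1 when the
  frontier densities coincide (ethylene), 0 for disjoint donor/acceptor
  supports. The published work does not write its overlap formula; the
  density overlap is one defensible reading and is documented as the
  package's choice. Degenerate frontier orbitals (benzene) are handled by
  averaging over all HOMO/LUMO pairs within a $10^{-6}$ eV window, which
  removes the arbitrariness of eigenvectors inside a degenerate block.
* **$\Delta E_{ST}$ proxy**: a linear map
  `intercept + slope * o_fmo`, floored at 0, with `slope >= 0` enforced —
  the exchange interaction grows with spatial overlap, and a negative
  slope would invert that physics. The calibration against a reference
  method is *not* shipped; slope and intercept are configuration.
* **$k_{ISC}$ proxy**: `soc^2 / delta_e_st^2` with unit proportionality
  constant. SOC is never computed from structure (that cost is the very
  thing the proxy avoids); it enters as an explicit input or a configured
  constant. `delta_e_st = 0` is a hard error (resonance case outside the
  model).
* **CT/LE classification**: overlap below a threshold (default 0.5,
  documented as uncalibrated) is charge-transfer, at or above it locally
  excited.
* **$\lambda_{max}$ estimate**: the photon conversion
  $1239.84/\mathrm{gap_{eV}}$ nm applied to the frontier gap — a stand-in
  for learned or semiempirical absorption predictors, adequate for
  ranking, not for spectroscopy.

The solver itself is validated against closed forms: chain spectra
$2\cos(k\pi/(n+1))$, ring spectra $2\cos(2\pi k/n)$ ($n \le 12$, tolerance
$10^{-10}$) and the pairing theorem for alternant hydrocarbons.

**Known limitation.** Hückel theory is planar-topological: the
twist-induced donor–acceptor decoupling that minimizes $O_{FMO}$ in real
biaryl chromophores is only partially visible to it (through connectivity,
not through dihedral angles). The proxies rank candidates; they do not
replace excited-state calculations, which remain an external adapter.

# Predictors

The reward engine is predictor-agnostic. A `Predictor` is a named,
deterministic map from a molecule to one property value; backends are
lookup tables keyed by canonical SMILES (the stand-in for external ML
models, and the test oracle), the Hückel proxies, constants, or
user-registered adapters. Missing predictions are explicit `NA`s, never
silent zeros; the *generation* policy maps them to score 0 (throughput
matters), the *triage* policy raises an error naming molecule and property
(correctness matters). `batchPredict` is guaranteed to equal elementwise
prediction — there is no batching side channel.

# The generative optimizer

The published workflow couples the reward to a recurrent SMILES generator
trained by reinforcement learning. The package's contribution-relevant
surface is the reward/filter contract, and any maximizer honoring it
exercises that contract; a **genetic algorithm** was chosen because it is
seedable, dependency-free and desk-scale. The RNN coupling remains an
external mode. Operators:

* *Mutations* (one per offspring, rejection-sampled): aromatic C→N and
  N→C swaps, append/remove small substituents (methyl, fluoro, cyano,
  phenyl), benzo-ring fusion onto an aromatic CH–CH edge, and acyclic C–C
  bond-order toggling. The menu is deliberately biased toward
  aromatic/heteroaromatic edits because the target space is
  aryl-substituted fused heterocycles. Every proposal is rewritten to
  SMILES and re-perceived by OpenBabel, which acts as the valence and
  aromaticity validity check; after 8 failed proposals the parent is
  returned, making the operator total.
* *Crossover*: cut each parent at a random acyclic non-aromatic single
  bond and join one fragment of each. Identical parents cut the same bond,
  so self-crossover is the identity; parents without a cuttable bond fall
  back to the higher-scoring parent.
* *Selection*: tournament (size 3) on the **diversity-adjusted** score;
  elitism (2) ranks by **raw** score, which is what makes the best-so-far
  raw score non-decreasing even when the diversity filter later zeroes a
  saturated scaffold.
* *Diversity filter*: each scaffold key owns a bucket; once `limit`
  molecules with raw score > 0 carry that scaffold, further ones score 0
  for selection purposes. The hard zero (rather than a decay) is the
  simplest reading of a scaffold-similarity filter; the default limit is
  25. Zero-score molecules never consume bucket capacity. Acyclic
  molecules share a sentinel bucket.

All randomness flows from the mandatory config seed through a private RNG
stream (the global RNG state is saved and restored), and every ordering
that breaks ties does so by canonical SMILES under locale-independent
radix ordering — two runs with the same config are bit-identical on any
machine. The trajectory records every evaluated molecule, supporting the
top-k score series and cumulative scaffold-occurrence analytics.

# The triage funnel

* `filterByCriteria` applies published thresholds with **strict**
  comparators — every printed criterion uses ">", so a candidate exactly
  at a threshold fails. Missing properties are hard errors.
* `rateRatio` computes $\log_{10}k_{ISC}/\log_{10}k_f$, defined only when
  both rates exceed 1 s⁻¹ (both logs positive); anything else is flagged
  undefined and fails every criterion on it. Criteria presets:
  global-triage (60/350/325), refined (55/250/0.75), local-lead
  (57/290/0.65).
* `clusterSelect` implements the diverse-candidate selection as Butina
  leader clustering on Tanimoto distance over Morgan fingerprints (radius
  2, 2048 bits, distance cutoff 0.35 ≡ similarity 0.65 — conventional
  values, documented as package choices), one representative per cluster
  (the objective maximizer, ties by canonical SMILES), clusters ranked by
  representative objective and truncated to `n_max`. Leader ordering uses
  static neighbor counts, the classic Butina formulation.
* `enumerateCondensation` applies the quinoxaline-forming template —
  aromatic ortho-diamine + 1,2-diketone → fused pyrazine + 2 H₂O — as
  direct graph surgery followed by canonicalization. Both orientations are
  generated for unsymmetric partners and deduplicated by canonical SMILES,
  so regiochemistry is decided by structure identity, not bookkeeping;
  fully symmetric reagent sets give exactly one product per pair. Reagents
  failing their motif (primary amines on adjacent aromatic carbons;
  adjacent non-aromatic carbonyl carbons) error at construction. When a
  reagent contains several motif sites, the first site in atom order is
  used.

# Fixtures and what passing tests show

The fixture module ships six named reference structures (thioxanthone,
benzophenone, quinoxaline, 2,3-diphenylquinoxaline, phenyl maleimide,
trans-methyl cinnamate), six symmetric aromatic ortho-diamines and three
symmetric 1,2-diketones (whose condensation affords exactly 18 unique
bicyclic pyrazines), and a **synthetic** lookup property table. The
computable descriptors in that table ($\theta_{conj}$, $O_{FMO}$) are
produced by the package's own predictors; the external-model quantities
($\Delta E_T$, $\lambda_{max}$, $\lambda_{max\text{-}sTDA}$, $k_{ISC}$,
$k_f$) are hand-set plausible values. By construction benzophenone clears
the rediscovery objectives, and exactly four library members clear the
local-lead criteria — a deliberate qualitative echo of a four-lead
outcome, not a prediction.

Passing tests therefore demonstrate that the *machinery* is correct — the
algebra, the filters, the enumeration, the optimizer contract — under
controlled property oracles. They do not validate property predictions on
real chromophores: the lookup values are not measurements, the Hückel
proxies are rankings, and no ML model is trained or shipped.

# Numerical choices and problem sizes

* Hückel eigensolve: base `eigen(symmetric = TRUE)`; orthonormality
  asserted to $10^{-8}$, closed forms to $10^{-10}$.
* Degeneracy window $10^{-6}$ eV for frontier averaging.
* Transform fuzzing: 1000 random cases; aggregation bounds: 200 random
  score vectors.
* GA study sizes: population 50 × 10 generations for the determinism and
  elitism checks; the diversity-filter contrast runs population 30 × 8
  generations on five seeds against the same seeds unfiltered — sizes at
  which the selection pressure has visibly converged while the whole
  suite stays interactive on a single CPU.
* Cluster-oracle fixtures: 30 molecules, cutoffs 0.4/0.6.
* Canonicalization idempotence: a 60-molecule GA-mutated pool plus the
  50-molecule diverse fixture.

# Limitations

* No stereochemistry, tautomers, charges beyond formal bookkeeping, or 3D.
* Hückel proxies are topological; twisted geometries, solvent effects and
  vibronic structure are invisible.
* SOC never computed; $k_{ISC}$ proxy is relative, not absolute.
* The GA explores a neighborhood of its seed population; it is a contract
  oracle and a desk-scale explorer, not a trained generative model.
* External adapters (semiempirical or TD-DFT backends, learned property
  models) are interface-only and excluded from the test suite.
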