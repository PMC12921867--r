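# photoforge

Inverse design of organic energy-transfer (EnT) photocatalysts at desk
scale, in R.

Triplet sensitizers for EnT catalysis need several properties at once: an
adiabatic triplet energy ΔE_T above the substrate's, useful absorption
(λmax), efficient intersystem crossing (ISC) into the triplet state, and a
rigid, conjugated scaffold that keeps the triplet alive. `photoforge`
implements the complete in-silico funnel for this multi-objective problem,
for computational and medicinal-photochemistry practitioners who want a
reproducible, dependency-light workflow:

- **Multi-objective reward.** Properties are transformed to [0, 1] by
  sigmoid/step/double-sigmoid functions and aggregated as a
  weight-normalized geometric mean, S = Π sᵢ^(wᵢ/Σw). Structural alerts
  (carbonyls, heteroatom–heteroatom bonds, aliphatic amines, alcohols,
  olefins) are hard vetoes: one match forces S = 0. Named presets carry the
  campaign thresholds (rediscovery: ΔE_T > 58 kcal/mol, λmax > 365 nm,
  θ_conj > 0.5; exploration: 55/330/0.5 plus an O_FMO objective and the
  full alert catalog; global-triage: 60/350/325; local-lead: 57/290).
- **Hückel π-electronic engine.** Conjugated subgraph extraction with
  heteroatom parameters, eigensolution, and the ISC proxies built on it:
  the frontier-orbital overlap O_FMO = Σₐ √(ρ_H(a)·ρ_L(a)), a linear
  singlet–triplet-gap proxy, the golden-rule rate k_ISC ∝ SOC²/ΔE_ST², a
  CT/LE classifier, and λmax = 1239.84/gap_eV nm.
- **Seedable generative optimizer.** A genetic algorithm over molecular
  graphs (aromatic C↔N swaps, substituent edits, benzo fusion, crossover
  at acyclic bonds) honoring the same reward contract, with a
  Bemis–Murcko scaffold-bucket diversity filter and full trajectory
  analytics (top-k score series, cumulative scaffold occurrence).
  Identical config + seed ⇒ bit-identical trajectories.
- **Triage funnel.** Strict-threshold criteria filtering, the refinement
  statistic log₁₀(k_ISC)/log₁₀(k_f), Butina clustering on Morgan
  fingerprints for diverse candidate selection, and combinatorial
  enumeration of the local quinoxaline space (aromatic ortho-diamine +
  1,2-diketone → fused pyrazine) with lead screening.

Molecule identity runs through OpenBabel canonical SMILES (via
`ChemmineOB`); everything else — the graph model, descriptors, scaffolds,
fingerprints, Hückel solver, GA and funnel — is implemented in the
package. See the methods vignette (`vignettes/photoforge-methods.Rmd`) for
the model assumptions, parameter defaults and design decisions.

## Worked example

```r
library(photoforge)

mol <- parseSmiles("O=C(c1ccccc1)c1ccccc1", name = "benzophenone")
mol
#> Molecule O=C(c1ccccc1)c1ccccc1 (benzophenone) | 14 atoms, 15 bonds

orb <- solveHuckel(buildPiSystem(mol))
orb
#> OrbitalSet: 14 orbitals | HOMO 7 (-2.373 eV), LUMO 8 (0.782 eV), gap 3.155 eV
fmoOverlap(orb)
#> [1] 0.767
```

The Hückel frontier gap (3.155 eV at |β| = 2.4 eV) and the large
frontier-orbital overlap (0.767: HOMO and LUMO live on the same atoms, a
locally excited picture) are the package's cheap electronic descriptors.
Scoring the same molecule under two campaign presets shows the funnel
logic:

```r
res <- scoreMolecule(mol, rewardPreset("rediscovery"), fixturePredictors())
res$componentScores
#>         delta_e_t        lambda_max theta_conjugation
#>             1.000             0.646             1.000
res$score
#> [1] 0.864

scoreMolecule(mol, rewardPreset("exploration"), fixturePredictors())$score
#> [1] 0   # veto: "carbonyl"
```

Under *rediscovery* benzophenone scores 0.864 — its fixture triplet energy
(69 kcal/mol) saturates the ΔE_T sigmoid, its absorption sits on the rising
flank of the λmax sigmoid, and it is fully conjugated. Under *exploration*
the carbonyl veto sends the score to exactly 0: aryl ketones are excluded
there to push the generator into new chemistry.

The local combinatorial space and its lead screen:

```r
lib <- enumerateCondensation(fixtureReagents())
nrow(lib)
#> [1] 18   # 6 symmetric diamines x 3 symmetric diketones
leads <- screenLocal(lib, fixturePredictors())$leads
nrow(leads)
#> [1] 4    # survivors of delta_e_t > 57, lambda_max > 290, ratio > 0.65
```

A generative run, seeded and fully reproducible:

```r
traj <- runGA(gaConfig(populationSize = 50, generations = 10, seed = 1),
              deskGenerationSpec(), livePredictors(),
              c("c1ccccc1", "c1ccncc1", "c1ccsc1", "Cc1ccccc1"))
topKScores(traj, 3)          # Fig-style top-k score series
scaffoldOccurrence(traj)     # cumulative scaffold counts per generation
```

A thin command-line dispatcher over the same functions is installed at
`inst/exec/photoforge` (`score`, `generate`, `triage`, `local`,
`fixtures`).

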