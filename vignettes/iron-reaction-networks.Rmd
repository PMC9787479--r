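---
title: "Modeling iron's effect on abiotic reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling iron's effect on abiotic reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feronet)
```

## The model

`feronet` models diversity-generating abiotic chemistry as a *combinatorial
reaction network*: a growing set of molecular species connected by reaction
events, produced by exhaustively applying a library of mechanism rules to a
seed set, generation by generation. The question it is built to answer is
structural, not kinetic: when aqueous Fe^2+^/Fe^3+^ chemistry is added to a
prebiotic reaction system — the formose reaction, pyruvic acid degradation,
glucose degradation, or the glucose–glycine Maillard reaction — how does the
reachable product space change? Which compounds become reachable in fewer
steps, which mechanisms fire more often, and how does product diversity grow
per generation?

Three modeling commitments follow from that question:

* **Molecules are labeled graphs.** Atoms (C, H, N, O, Fe) are vertices with
  formal charges; bonds are integer-order edges. Hydrogens are implicit
  per-atom counts. Two products are "the same compound" exactly when their
  graphs are isomorphic, so every product is *canonicalized*: a canonical
  vertex order is computed with BLISS canonical labeling (bond orders are
  encoded as colored subdivision vertices, since the labeling colors only
  vertices), and a deterministic SMILES writer over that order yields the
  species' `canonical_id`. Canonicalization is idempotent and
  representation-independent; tests cross-check the induced equivalence
  classes against OpenBabel's independent canonicalizer.

* **Mechanisms are graph-transformation rules.** A rule is one or two
  molecular subgraph templates (pattern atoms may be wildcards, may require a
  minimum free-hydrogen count) plus an edit set: bond-order changes,
  implicit-hydrogen deltas, charge deltas, and fixed multisets of ubiquitous
  co-agents (H~2~O, H^+^, OH^−^, Fe^2+^, Fe^3+^) consumed, produced, or
  carried catalytically on both sides. This is the L/K/R decomposition of
  graph rewriting: the template is L, the edits are L∖K and R∖K, everything
  else is context. The loader enforces internal consistency (deleted bonds
  exist in L, created bonds do not) and full element/charge balance of every
  rule against its co-agents, so *every* event in every network conserves
  atoms and charge by construction — and an independent audit
  (`check_conservation()`) re-verifies it from the event multisets.

* **Expansion is purely combinatorial.** Generation 0 is the seed set. At
  generation *g* every rule is applied to every reactant tuple whose newest
  member first appeared at *g*−1; an event is therefore discovered at
  max(reactant first generation) + 1, independent of enumeration order, and
  each tuple is processed exactly once. There are no concentrations, rates,
  or yields anywhere — the network is a map of what is mechanistically
  reachable, which is also why no random seed exists: the expansion is
  deterministic and two runs of the same configuration are identical.

### The mass cap

Unbounded rule application diverges (condensations compose indefinitely), so
products are capped at a nominal mass, 200 AMU by default — integer
most-abundant-isotope masses (H=1, C=12, N=14, O=16, Fe=56), chosen over
average molecular weight so the cap is an exact integer comparison. An event
with *any* over-cap product is discarded whole: a reaction that needs a
too-heavy intermediate cannot contribute its light fragments either. Under a
cap the reachable space is finite, so every network eventually *saturates*:
a generation arrives at which no new species and no new events appear, after
which the pool is a fixed point. `saturation_generation()` reports it, and
`analysis/04_saturation.R` demonstrates the full trajectory (rise, peak,
collapse to zero novelty) on the formose network at an 80 AMU cap.

## The rule libraries

The shipped libraries are *reconstructions from mechanism names*: the named
aldol, retro-aldol, Knoevenagel (H and C variants with inverses),
Cannizzaro (including both crossed formaldehyde variants), benzilic acid
rearrangement, keto–enol migration, hemiacetal formation/opening and O,O
ring closures at ring sizes 5/6/7, eliminations, hydrations and four
decarboxylation variants, each encoded as its textbook bond reorganization
on a minimal template. The iron library holds the seven iron-induced rules:
two-electron organic oxidations paired with 2 Fe^3+^ → 2 Fe^2+^ (aldehyde →
acid; α-hydroxy → α-keto), their reductive inverses consuming 2 Fe^2+^ + 2
H^+^, a four-iron deoxygenation pair, and an iron-mediated sugar
β-elimination-plus-oxidation. Protons balance every electron transfer, so
iron events conserve charge exactly.

Two encoding choices deserve explanation:

* **Cannizzaro uses water, not hydroxide.** The iron-free seed sets contain
  no OH^−^, yet iron-free networks must show Cannizzaro events (methanol and
  formic acid are prominent iron-free products). Encoding the
  disproportionation as 2 RCHO + H~2~O → alcohol + acid keeps it available
  in both variants and keeps the event charge-balanced; hydroxide mediation
  is treated as implicit, consistent with a bookkeeping-free view of the
  medium.

* **The formose network needs a C–C bootstrap.** Formaldehyde has no
  α-carbon, so the classical aldol cannot produce the first C–C bond from
  HCHO + H~2~O alone. The formose library therefore carries a 32nd rule,
  *Formose C–C Coupling*: umpolung addition of an aldehyde C–H across a
  carbonyl (2 HCHO → glycolaldehyde). Once glycolaldehyde exists, the
  ordinary aldol/Knoevenagel machinery takes over and the network grows
  roughly exponentially.

The Maillard library adds a nitrogen layer — four substituent variants of
Strecker degradation of an α-amino acid by a 1,2-dicarbonyl, and amide
formation/hydrolysis — and is explicitly labeled a reconstruction: it covers
the mechanisms named in the published frequency tables, not an exhaustive
Maillard chemistry.

Per-rule *frequencies* are therefore reconstruction-specific and absolute
network magnitudes are not comparable to the original study's (whose exact
machine-readable rule encodings are not published); the quantities this
package reproduces exactly are the *derived statistics* computable from the
published tables, and the qualitative structure (supersets, catalysis,
growth direction) at reduced scale.

## Iron-free versus iron-containing pairs

An iron-containing variant differs from its iron-free twin only by added
ionic seeds (Fe^2+^, Fe^3+^, H^+^, OH^−^) and added iron-dependent rules —
asserted structurally at load (`check_preset_containment()`). Because
patterns never test for the *absence* of anything, additions can only grow
the network: every iron-free species appears in the iron network at the same
or an earlier generation. That monotonicity is the backbone of the catalysis
definition: a compound is **catalyzed** when its first generation is
*strictly* earlier with iron, i.e. it needs fewer reaction steps. Percent
catalysis divides the catalyzed count by the iron-free compound total
(ubiquitous ions excluded from both sides, and from all diversity counts —
they are background medium, not products; they do participate in degree
metrics, where Fe^2+^/Fe^3+^ and water rank among the most connected nodes
exactly because so many events touch them).

The percent-change convention for rule frequencies is
100·(f~iron~ − f~free~)/f~free~, rounded to the nearest integer — the
convention every published row follows (12 → 54 is printed as 350%), even
though the original table caption states a ratio formula that would give
450%; iron-only rules (f~free~ = 0) print the sentinel "–". Catalysis
percentages are printed at one decimal below 2% and as integers otherwise;
the published values mix the two conventions (8.4% alongside 7% and 3%), so
raw percentages are reported everywhere and the formatter is a separate,
documented step.

Growth curves are fit as least-squares lines on log~10~(cumulative product
count) versus generation — the simplest family consistent with roughly
exponential growth — and projections are back-transformed fitted values.
They are extrapolations: once the mass cap begins to bite they
systematically overestimate (the saturation script shows a projected 1368
species versus 58 actual at the formose cap-80 fixed point), which is the
right mental model for any capped-network extrapolation.

## The toy systems and the oracle

Because the engine's correctness claims are structural, they are tested
against closed forms and an independent re-implementation:

* `chain_growth`: formaldehyde inserts into an aldose terminus
  (R–CHO + HCHO → R–CH(OH)–CHO), so the reachable species are exactly the
  linear aldoses of mass 30·n ≤ cap — ⌊cap/30⌋ species, one new species and
  one event per generation, saturation at generation ⌊cap/30⌋. The monomer
  is fixed at formaldehyde because its insertion uniquely regenerates the
  reactive aldehyde terminus, keeping one isomer per mass and the count in
  closed form; the cap is the free parameter.
* `reversible_pair`: acetaldehyde ⇌ vinyl alcohol through explicit
  enolization/ketonization rules — two species, two events, saturation at 3.
* `iron_shortcut`: glyceraldehyde reaches lactic acid in three iron-free
  steps (dehydration to pyruvaldehyde, aldehyde hydration, intramolecular
  hydride shift) or in one step with catalytic Fe^3+^ — the classic
  iron(III)-mediated glyceraldehyde → lactic acid conversion — so lactic
  acid is catalyzed with generations (3, 1) and percent catalysis 20%.

`brute_force_expand()` re-derives the expansion semantics with none of the
engine's machinery: matching enumerates all injective maps and filters at
the end, rewriting edits a dense adjacency matrix, and every generation
re-enumerates every tuple of the whole cumulative pool. Engine and oracle
must agree field-for-field (species, first generations, event multisets with
generation labels) on every toy, in both variants.

What the toys do *not* emulate: competing channels at realistic densities,
nitrogen tautomerism, ring strain, or any kinetic weighting. Passing them
shows the rewriting semantics are exact, not that the preset libraries are
chemically complete.

## Numerical and design choices

* **Determinism.** Rules are applied in library order, species in insertion
  order, embeddings in a canonical backtracking order; events are
  deduplicated by (rule, reactant multiset, product multiset). Runs are
  bit-reproducible and seed-order invariant.
* **Embedding symmetry.** Template self-symmetries that preserve the edit
  set are quotiented out, so a symmetric rule applied to a symmetric
  reactant pair yields one embedding, while asymmetric edits (such as
  Cannizzaro's oxidized/reduced roles) keep both assignments.
* **Valence guard.** Post-edit atoms must satisfy C ≤ 4, N ≤ 3, O ≤ 2
  bonds-plus-hydrogens; violating applications are silently skipped, as are
  hydrogen underflows and bond creation onto already-bonded atoms (which
  blocks degenerate "ring closures" of adjacent atoms).
* **Mass pruning.** Bimolecular condensations annotate how much lighter
  than the combined reactant mass their largest product can be
  (`combine_slack`), letting the engine skip over-cap tuples before
  matching. The annotation is conservative; correctness never depends on it.
* **Tautomers are distinct species** connected by explicit migration rules;
  stereochemistry is ignored (no shipped rule is stereospecific).
* **Problem sizes.** The tests and the analysis scripts run formose and
  pyruvic at a 100 AMU cap for four generations and the glucose-seeded
  networks at 200 AMU for two generations — glucose itself is 180 AMU, so a
  100 AMU cap would reject a seed, which the configuration validator treats
  as an error. These scales preserve every structural contrast (supersets,
  catalysis, growth direction, the pyruvic network's outsized iron
  sensitivity) at desk-scale cost.
* **Memory guard.** A configurable species limit (default 10^6^) aborts
  cleanly with a diagnostic, since network size grows roughly exponentially
  with generation.

## Known limitations

* Absolute species/event counts depend on the rule encodings and are not
  comparable to the original study's absolute magnitudes; only derived
  statistics and qualitative structure are.
* One consequence worth knowing: at generation 1 of the formose pair the
  species counts tie (the only iron rule applicable to formaldehyde produces
  formic acid, which the iron-free Cannizzaro also produces); event counts
  already differ, and species counts diverge strictly from generation 2.
* The Maillard nitrogen library is a deliberately partial reconstruction.
* Fenton/radical chemistry, iron–sulfur clusters, pH/temperature effects,
  kinetics and yields are out of scope by design; the networks are maps of
  mechanistic reachability.

## A worked example

```{r example}
toy <- make_toy_system("iron_shortcut")
free <- expand(toy$config)
iron <- expand(toy$config_iron)
compare_networks(free, iron)
catalyzed_species(free, iron)
```

Lactic acid appears at generation 3 without iron and generation 1 with
catalytic Fe^3+^: the one compound of five that iron "catalyzes", hence 20%.
The same functions drive the four preset networks in
`analysis/01_expand_networks.R` through `analysis/04_saturation.R`.
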