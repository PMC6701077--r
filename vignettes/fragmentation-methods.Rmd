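---
title: "Automatic fragmentation of molecules into UNIFAC groups: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic fragmentation of molecules into UNIFAC groups: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupfrag)
```

## The problem

Group-contribution models predict thermophysical properties (activity
coefficients, boiling points, partition coefficients, ...) as sums of
contributions of a molecule's functional groups. Applying such a model to a
large structure database requires mapping every molecule onto a
*fragmentation*: a partition of its heavy atoms into non-overlapping
functional-group matches that covers every atom exactly once. Done by hand,
this mapping is the bottleneck of group-contribution development.

groupfrag automates the mapping. A *fragmentation scheme* is a flat CSV of
groups, each a UNIFAC-style group id, a name, and one or more SMARTS
patterns; the packaged default (`default_scheme()`) is the full published
UNIFAC scheme of 111 groups (ids 1–109, 118, 119). Two difficulties make
the mapping non-trivial:

* **Non-unique assignment.** Several partitions can be valid. Phenol's
  C–OH site is one ACOH group or an AC plus an OH; which one the model
  expects is a matter of convention (UNIFAC expects ACOH).
* **Incomplete assignment.** A greedy search can strand atoms: if the four
  aromatic CH of 2-chlorophenol are taken first as ACH and the substituted
  carbons as AC, the chlorine can no longer be assigned to anything.

## The two fragmenters

### Simple (heuristic) fragmentation

`fragment_simple()` searches for one solution. Three devices steer it to
the conventional assignment:

1. **Descriptor priority sort.** Every pattern gets an 8-component
   descriptor vector (next section); groups are searched in descending
   lexicographic order, so large, specific, heteroatom-rich groups go
   first.
2. **Parent–child prioritization.** The scheme is analysed once for
   pattern containment: CH2 is contained in the amide pattern CONHCH2, so
   before the CH2 group consumes an atom, the fragmenter checks whether
   that atom lies inside an intact match of a containing ("parent")
   pattern and, if so, leaves it for the parent's group.
3. **Adjacency-constrained retries.** If the sequential pass strands
   atoms, the neighbourhood of the stranded atoms is cleared of placed
   groups (radius = retry number, growing each iteration up to the graph
   diameter) and the search repeats, now requiring every new match to be
   bonded to the groups already placed, which pulls the assignment back
   toward the stuck region.

```{r}
res <- fragment_simple("c1c(Cl)c([OH])ccc1")
group_counts_by_name(res)
```

### Complete (exhaustive) fragmentation

`fragment_complete()` enumerates *every* partition by a recursive
exact-cover search: each node branches over the candidates that cover the
lowest-index unassigned atom, so each partition is generated exactly once.
Residual atom sets proven uncoverable are memoized and pruned on
re-encounter (whether a residual can be covered depends only on the
residual). Solutions are ranked by ascending number of placed groups —
fewer pieces means larger groups — then by number of distinct group ids,
then by scheme precedence of the groups used; the first solution is the
answer, the full ranked list is retained.

```{r}
res <- fragment_complete("Cc1ccccc1")  # toluene
length(res$solutions)                  # ACCH3+5ACH beats CH3+AC+5ACH
group_counts_by_name(res)
```

The search is exponential in molecule size; `max_heavy_atoms` (default 20)
rejects larger inputs with a typed error. `fragment(..., algorithm =
"combined")` runs the simple fragmenter first and falls back to the
complete search for unfragmented structures under the cap.

## The 8 descriptors

For a pattern, in sort order: (1) whether it has zero free bonds, (2)
whether it is "simple" (a lone valence-one atom, or one carbon with
valence-one atoms bonded to it, with a free bond left), (3) the number of
defining atoms, including atoms of positive recursive environments, (4)
whether exactly one free bond is available, (5) the number of atoms that
are neither hydrogen nor carbon, (6) whether it includes ring atoms
(aromatic or ring-constrained), (7) triple bonds, (8) double bonds.
Booleans sort as 1/0, the comparison is lexicographic and descending, ties
keep scheme-file order (the published table does not define a tie-break;
stable order makes runs reproducible).

The accounting that reproduces the published descriptor table exactly, for
all 111 rows, is:

* **Free bonds** are counted per atom as the element's standard valence
  minus declared hydrogens minus the bond orders written in the pattern
  (aromatic bonds count 1.5), clamped at zero per atom. A lowercase
  aromatic atom written without its ring keeps its unconsumed ring valence
  as free bonds.
* **Recursive environments**: atoms of positive environments count toward
  descriptor 3 (they define the group's vicinity); atoms of negated
  environments do not; bonds inside any environment never count toward
  descriptors 7/8.
* A group's descriptor vector is that of its **first pattern** — the
  published table prints one vector per group, and alternative patterns of
  a group can genuinely differ (the second pattern of group 7 is aromatic,
  the row is not flagged as ring). `validate_scheme()` reports such
  disagreements informationally.

## Pattern containment

`pattern_contains(parent, child)` decides whether the child pattern is
structurally inside the parent with compatible constraints, by graph
embedding plus atom-wise constraint comparison. The published rule for
hydrogen counts is followed: declared explicit-H counts are compared, an
undeclared atom counting as zero. This corrects the toolkit-style false
positive ([CH3][OH] is *not* in [CH3][O;H0]) and deliberately lets `[c]`
stand for a substituted aromatic carbon, so the bare AC group defers to
ACCH3/ACOH/ACCl sites — which the search needs — at the price of not being
literally sound for every molecule site. Ring constraints, connectivity
constraints (satisfied when declared identically, or when the parent atom
has at most one valence unit left open) and recursive environments must be
guaranteed by explicit parent declarations. These guards keep the relation
acyclic, which the parent-first suppression requires to terminate. The map
is computed once per scheme at load time (`load_scheme()`), an O(P²) cost
of about two seconds for the packaged scheme.

## Structure handling

Input SMILES are normalized before fragmentation: deuterium/tritium become
ordinary hydrogens, explicit hydrogens fold into per-atom counts, isotope
labels are stripped. Dot-disconnected inputs (salts, mixtures) and
radical-bearing structures (an uncharged bracket atom below its minimum
valence) are *excluded* — reported distinctly from failure to fragment.
Heavy atoms are indexed 1-based in SMILES order; hydrogens are never
assigned to groups (every group in the scheme is heavy-atom-defined).

Aromaticity is perceived with a deliberately small Hückel-style model:
5- and 6-membered rings of C/N/O/S with six π electrons contributed by
ring-internal double bonds or heteroatom lone pairs become aromatic; rings
with triple bonds or exocyclic double bonds do not. Lowercase aromatic
SMILES input is honoured directly. This covers benzenoids, pyridines,
furan/thiophene/pyrrole and their fused relatives, i.e. everything the
scheme's aromatic groups address, but it is not a full aromaticity model:
charged rings, azulene-type systems and tautomer-dependent cases will be
perceived as aliphatic and typically fail to fragment. Aromaticity
perception is a known source of disagreement between toolkits and between
this package and any externally produced reference fragmentation.

## Fixtures and the oracle

Because real reference databases cannot ship with the package, tests build
their own ground truth two ways:

* `generate_series()` emits homologous series with closed-form expected
  counts: n-alkanes \{CH3:2, CH2:n−2\}, 1-alkanols \{CH3:1, CH2:n−1,
  OH:1\}, terminal chloroalkanes \{CH3:1, CH2:n−2, CH2Cl:1\} and
  n-alkylbenzenes \{ACH:5, ACCH3:1\} / \{ACH:5, ACCH2:1, CH3:1,
  CH2:n−2\}. The generators are deterministic; nothing is stored on disk.
* `oracle_enumerate_covers()` enumerates all exact covers by naive
  include/exclude recursion over the raw candidate list — no memoization,
  no cover-directed branching, no ordering heuristics — sharing no logic
  with either fragmenter. On every fixture molecule of at most 8 heavy
  atoms the complete fragmenter's solution set is checked to equal the
  oracle's, and every simple-fragmenter solution to be a member.

These fixtures exercise chain/ring chemistry, heteroatoms, halogens and
protected sites, but not the conformational and tautomeric diversity of a
real database; passing them shows algorithmic correctness against the
scheme, not coverage of all chemistry the scheme was designed for.

## Numerical and design choices

* **Tie-breaks**: stable sorts everywhere; candidate order is (pattern
  index, lexicographically smallest atom tuple); within one group's pass
  candidates are placed greedily in that order.
* **Retry cap**: the molecule's graph diameter — by then clearing has
  emptied the state and the search has had one unconstrained restart, so
  termination is guaranteed.
* **Parent suppression**: a child candidate is withheld when its atom set
  is a (non-strict) subset of a live parent-pattern match; non-strict so
  that e.g. the open-chain ether pattern defers to the ring-constrained
  THF pattern on the same two atoms.
* **Ranking ambiguity**: "number of different patterns" is read primarily
  as the total number of placed groups (this is what makes larger groups
  win), with distinct-group count as tie-break; both are computed.
* **Unsorted mode** (`sorted = FALSE`) searches in scheme-file order — the
  natural reading for the published unsorted baseline — and is expected to
  fragment less reliably; the solution *set* of the complete search is
  proven independent of the flag.
* **Problem sizes in tests**: oracle cross-checks run on molecules of ≤ 8
  heavy atoms, series properties on chain lengths 2–12, the complete
  fragmenter's default cap is 20 heavy atoms — the sizes at which the
  exhaustive reference computations are exact and fast.

## Known limitations

* The simplified aromaticity model above.
* No stereochemistry (no pattern in the scheme is stereo-specific).
* The simple fragmenter guarantees a *valid* partition, not the
  conventionally "correct" one among alternatives; conventions are encoded
  only through the descriptor sort and parent–child priorities.
* Ranking of complete-search solutions by descriptor-based scoring (rather
  than group counts) is out of scope.
* The full published reference-database evaluation (tens of thousands of
  structures) requires that external database; the package ships the
  comparison pipeline (`run_reference_comparison()`) and validates it on
  generated fixtures.
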