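# groupfrag

Automatic fragmentation of molecules into functional groups for
group-contribution modelling.

Group-contribution methods (UNIFAC and relatives) predict thermophysical
properties from the counts of a molecule's functional groups. Applying them
to large structure databases requires mapping every SMILES onto a
*fragmentation* — a partition of the heavy atoms into non-overlapping
SMARTS-defined group matches covering every atom exactly once. groupfrag
performs that mapping automatically, shipping the full published UNIFAC
fragmentation scheme (111 groups) as its default, and is aimed at people
developing or applying group-contribution models who need thousands of
molecules fragmented reproducibly.

Two algorithms are provided:

* **Simple (heuristic)** — `fragment_simple()`: the scheme is sorted by
  descending lexicographic order of 8 automatically computed pattern
  descriptors d = (zero free bonds, simple pattern, #atoms, one free bond,
  #heteroatoms, ring, #triple bonds, #double bonds); groups are searched
  sequentially with parent–child pattern prioritization (a CH2 inside an
  intact CONHCH2 site is left for the amide group), and stranded atoms
  trigger retries that clear a growing neighbourhood and require new
  matches adjacent to those already placed.
* **Complete (exhaustive)** — `fragment_complete()`: a recursive
  exact-cover tree search enumerating *every* valid partition, with
  memoized pruning of uncoverable residuals; solutions ranked by ascending
  group count (larger groups first), then distinct groups, then scheme
  precedence. `fragment(..., algorithm = "combined")` runs simple first
  with complete as fallback.

The matching engine (SMILES/SMARTS parsing, substructure search with
recursive environments, pattern-on-pattern containment with the explicit
hydrogen-count correction) is implemented in the package.

## Worked example

```r
library(groupfrag)

res <- fragment_simple("c1c(Cl)c([OH])ccc1")   # 2-chlorophenol
res
#> <fragmentation_result> c1c(Cl)c([OH])ccc1 [simple]: success
#>   groups: ACH 9:4, ACOH 17:1, ACCl 53:1

group_counts_by_name(res)
#>  ACH ACOH ACCl
#>    4    1    1
```

Four aromatic CH (ACH, group 9), one aromatic C–OH (ACOH, 17) and one
aromatic C–Cl (ACCl, 53): the descriptor sort places the substituted
aromatic groups before bare ACH/AC, so the chlorine is not stranded, and
the hydroxyl is kept with its ring carbon as the UNIFAC convention expects.
The exhaustive search agrees and shows the one alternative partition:

```r
res <- fragment_complete("Cc1ccccc1")          # toluene
length(res$solutions)
#> [1] 2
group_counts_by_name(res)                      # ranked first: 6 groups
#> ACH ACCH3
#>   5     1
```

A molecule whose ring no group can cover is reported honestly:

```r
fragment_simple("C1=CN=CC#C1")$status
#> [1] "no_solution"
```

Reference comparison and fixtures:

```r
ref <- generate_fixture_reference(2:8)          # series with known counts
summary <- run_reference_comparison(ref, algorithm = "simple")
summary
#> <run_summary> 28 structures: 28 fragmented (100.0%), 28 like reference (100.0%), 0 excluded
```

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/fragment.R fragment --input mols.csv --output out.csv \
    --algorithm combined --max-heavy-atoms 20
Rscript inst/cli/fragment.R scheme-sort --output sorted_scheme.csv
Rscript inst/cli/fragment.R compare --reference ref.csv --summary out.json
Rscript inst/cli/fragment.R make-fixtures --output fixtures.csv
```

Output CSV columns: `smiles,status,group_counts,iterations_used`, group
counts as `id:count` pairs joined by `;`.

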