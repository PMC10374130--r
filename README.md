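# crossmapr

Tools for building, auditing, and publishing typed concept mappings between
two health-classification hierarchies — modelled on the harmonization of the
ICF Body Structures with the ICD-11 Anatomic Detail extension codes, and
usable for any pair of classifications in the same shape.

The WHO-FIC classifications (ICD-11, ICF, ICHI) share a common Foundation,
but shared concept sets such as human anatomy are modelled separately, at
different granularity. Reconciling them needs a crosswalk in which each
source entity *s* is related to one or more target entities *t* by a typed
relation:

- `identical_to` / `synonym_of` — equivalences (collapsed to
  `equivalent_to` for analysis),
- `broader_than` / `narrower_than` — **source-relative** directional
  relations covering both taxonomic and partonomic views.

`crossmapr` provides the computational pipeline around the human raters:

1. **classification IO** — read ClaML XML (`parse_claml()`) and offline
   ICD-11-Foundation-style JSON snapshots (`parse_foundation_snapshot()`)
   into a common tibble-based polyhierarchy with ancestor/descendant
   queries (`hierarchy_query()`); flag residual "other specified" /
   "unspecified" categories (`flag_residuals()`), which are never mapped;
2. **lexical matching** — `auto_match()` asserts `identical_to` on
   normalized-title identity, `synonym_of` via the "Structure of X" → "X"
   rule and an explicit synonym table; `search_candidates()` gives ranked
   candidates for manual mapping;
3. **multi-rater analysis** — `collapse_equivalents()`,
   `tally_by_rater()`, pair-level strict inter-observer `agreement()`, and
   hierarchy-aware redundancy detection (`find_redundant()`: `narrower_than
   Brain` is redundant once `narrower_than` a region of the brain is
   asserted);
4. **consolidation** — `consolidate()` applies a support threshold (auto
   equivalences exempt), removes redundant maps, and selects per source by
   the priority *equivalent_to ≻ narrower_than ≻ broader_than*, routing
   everything it drops to a review report;
5. **SSSOM export** — `write_sssom()` / `read_sssom()` serialize the result
   as a Simple Standard for Sharing Ontological Mappings TSV with the
   object-relative SKOS predicates (`narrower_than` → `skos:broadMatch`);
6. **fixtures** — `generate_pair()` / `simulate_raters()` build synthetic
   classification pairs with planted ground truth and an
   independent-confusion rater model, so everything above is testable
   offline.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on results, `autoplot()` for the agreement report and the
consolidation.

## Worked example

The paper-shaped synthetic preset: 321 source entities, 103 residuals, 113
planted exact-title matches.

```r
library(crossmapr)

fx <- fixture_paper(seed = 1)
fx$source
#> <classification> icf : 321 entities, 1 roots, 103 residual

auto <- auto_match(fx$source, fx$target, fx$synonyms)
auto
#> <mapset> icf -> icd11: 113 assertions, 1 raters
```

All 218 non-residual sources are considered; the 113 whose titles occur
verbatim in the target are auto-matched, the other 105 land in
`unmatched_report(auto)`. Add three simulated raters, collapse, and measure
agreement:

```r
sim <- simulate_raters(fx$truth, seed = 1)
m <- collapse_equivalents(mapset(dplyr::bind_rows(
  tibble::as_tibble(auto), tibble::as_tibble(sim)
)))
agreement(m)
#> <agreement_report> 105 pairs compared, 3 discordant, agreement 97.1%

consolidate(m, fx$target)
#> <consolidation> 113 maps (113 equivalent_to, 0 broader_than, 0 narrower_than), 3 under review
```

105 (source, target) pairs were asserted by at least two raters; on 3 of
them the raters chose different relations, so those go to review and the
agreed 113 equivalences survive consolidation.

The bundled mini fixture encodes three classic review situations on a
brain / skin-gland / heart toy hierarchy:

```r
fx <- fixture_mini()
m <- collapse_equivalents(fx$assertions)
find_redundant(m, fx$target)
#> # A tibble: 1 × 4
#>   source_code relation      target_code witness_code
#> 1 s110        narrower_than BR          SUP

consolidate(m, fx$target)$maps
#> # A tibble: 3 × 6
#>   source_code relation      target_code raters    support auto
#> 1 s110        narrower_than SUP         <chr [2]>       2 FALSE
#> 2 s4100       equivalent_to ATR         <chr [2]>       2 FALSE
#> 3 s820        narrower_than SKN         <chr [2]>       2 FALSE
```

The diencephalon's `narrower_than Brain` is redundant (witness: the
supratentorial region); the skin-gland structure keeps `narrower_than Skin`
over three broader-than maps; the atria keep their agreed equivalence.

## Command line

A thin CLI over the same functions lives at `exec/fic-harmonizer`:

```sh
fic-harmonizer automatch --claml icf.xml --snapshot icd11.json --out maps.tsv
fic-harmonizer agree --maps maps.tsv
fic-harmonizer consolidate --maps maps.tsv --snapshot icd11.json --out consolidated.tsv
fic-harmonizer export --maps maps.tsv --claml icf.xml --snapshot icd11.json --out maps.sssom.tsv
fic-harmonizer run --preset paper --seed 1 --out run/
```

## Acceptance script

`scripts/acceptance.R` runs the installed package's full pipeline end to end
on the paper-shaped preset — load, residual flagging, auto-matching,
simulated raters, collapse, agreement, consolidation, SSSOM export — and
writes its results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/crossmapr-methods.Rmd`) describes the data
model, the matching and consolidation rules, the agreement definition, the
synthetic world and its limits, and every numerical/degenerate-input choice.
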