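---
title: "Methods: cross-classification mapping, agreement, and consolidation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-classification mapping, agreement, and consolidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmapr)
library(dplyr)
```

## The problem

The WHO Family of International Classifications (ICD-11, ICF, ICHI) shares a
common Foundation, but overlapping concept sets — most visibly human anatomy —
are modelled separately in each classification, at different granularity and
sometimes under different anatomical models. Harmonizing them requires typed
crosswalks: for each entity of a source classification (e.g. the 321 ICF Body
Structures), one or more entities of a target (e.g. the ICD-11 Anatomic
Detail extension codes) with a relation stating whether the pair is
equivalent, or whether the source is broader or narrower than the target.
`crossmapr` implements the computational side of such an exercise: lexical
auto-matching, multi-rater assertion management, agreement and redundancy
analysis, priority consolidation, and SSSOM export — plus a synthetic fixture
generator so the whole pipeline is testable without any downloads.

## Data model

A **classification** is a tibble of entities (`code`, `title`, `synonyms`,
`parents`, `residual`) with the name and version in attributes. Both
hierarchies are treated as rooted acyclic polyhierarchies: an entity may have
several parents, mixing taxonomic (is-a) and partonomic (part-of) links, as
both WHO-FIC hierarchies do. Codes are opaque and case-sensitive; all title
comparison happens on a normal form (lower case, punctuation to spaces,
collapsed whitespace). Ancestor/descendant queries are transitive closures
over the parent links (igraph underneath).

**Residual categories** ("other specified", "unspecified", "not otherwise
specified") are semantically equivalent to their parent and are never mapped.
The source document does not fix a detection rule, and ICF residuals could
equally be recognized by their code suffixes (8/9); we flag by
case-insensitive title substring against a configurable pattern list, because
it works for both classifications and for synthetic fixtures. The default
patterns are the three phrases above.

A **mapset** is a tibble of assertions — one row per (source, target,
relation, rater). Raw assertions distinguish `identical_to` (same title and
concept) from `synonym_of` (different title, same concept); both are
equivalences, and every analysis first rewrites them to a single
`equivalent_to` (`collapse_equivalents()`). The directional relations are
source-relative: `broader_than` means the *source* is the broader concept.

## Auto-matching

`auto_match()` reproduces the software stage of the exercise. For each
non-residual source entity, in order:

1. **identity** — if exactly one target entity has a title *or synonym*
   normalizing equal to the source title, assert `identical_to`;
2. **structure-of** — else, if the source title has the form
   "Structure(s) of X" and exactly one target *title* matches X, assert
   `synonym_of` ("Structure of brain" → "Brain"). Strictly, "structure of X"
   is not a synonym of "X", but because both hierarchies mix taxonomic and
   partonomic links this identification yields the most economical map set.
   The rule consults titles only — a deliberately narrower net than the
   identity rule, since it already involves a lexical transformation;
3. **synonym table** — else, if an explicit, versioned synonym table links
   the source title to exactly one target title, assert `synonym_of`.

Identity beats structure-of; ambiguous candidates (duplicated target titles)
produce *no* assertion, since silence is safer than guessing; every source
with zero or ambiguous candidates lands in the unmatched report. Residual
sources are never matched, and at most one auto assertion is emitted per
source.

`search_candidates()` is the interactive-search stand-in: score
`0.75 · J + 0.25 · C` with `J` the token-set Jaccard overlap and `C` a
whole-phrase containment indicator, ties broken by code. The constants are
arbitrary but fixed; search supports manual mapping and is not part of the
consolidated output. Because token-set Jaccard is 1 for reordered tokens, a
non-exact score is capped at `1 - 1e-6` so that a score of exactly 1 occurs
iff the normalized strings are equal.

## Agreement

The published figure for this kind of exercise is a plain percent agreement;
numerator and denominator are rarely stated. Our reconstruction, documented
as this package's definition rather than anyone else's: after collapse,
every (source, target) pair asserted by ≥ 2 raters is *compared*, and it is
*concordant* iff all its raters asserted the same collapsed relation. The
agreement fraction is `1 − discordant/compared`. Pairs asserted by a single
rater are excluded — raters may legitimately map a source onto different
targets, and such pairs are neither agreements nor disagreements. Software
("auto") assertions are excluded by default: they are not an observer. No
chance correction is attempted (the relation margin is so skewed that a
kappa would mostly measure the margin).

## Redundancy

With multiple directional maps per source, hierarchy-implied maps add no
information: `narrower_than Brain` is redundant once
`narrower_than Supratentorial region of brain` is asserted.
`find_redundant()` flags `narrower_than(s, T)` iff another
`narrower_than(s, T′)` exists with `T` a strict ancestor of `T′`, and
symmetrically `broader_than(s, T)` iff a `broader_than(s, T′)` exists with
`T′` a strict ancestor of `T`. Equivalences are never flagged; equal targets
are duplicates, handled by mapset deduplication, not redundancy. Each flag
names a witness (the lexicographically smallest when several exist), so the
output is independent of assertion order. Both directions are treated
symmetrically — the narrower case is the one usually cited, but the same
logic applies to broader maps.

## Consolidation

`consolidate()` mechanizes the experts' review into four deterministic
steps:

1. **support** — a distinct (source, relation, target) triple survives iff
   asserted by ≥ `min_support` distinct raters (default 2 — a majority of
   three raters), *except* auto equivalences, which always qualify: lexical
   identity needs no vote. Everything dropped goes to a review report, never
   silently deleted — the mechanical analogue of "discrepancies were
   examined by the experts".
2. **redundancy** — surviving triples flagged by `find_redundant()` are
   moved to review with their witness.
3. **priority** — per source: an agreed equivalence is the selected relation
   even if directional maps are available; otherwise `narrower_than`;
   otherwise `broader_than`. With `exclusive = TRUE` (default) losing
   relations go to review; with `FALSE` they are kept as a secondary table.
   The source document's wording suggests exclusive selection but its counts
   cannot confirm it, hence the flag.
4. All targets within the winning relation class are retained — one source
   may legitimately map to several targets (an aggregate source entity can
   be broader than many specific target entities).

One subtlety worth stating: the *final* output is **not** monotone in
`min_support`. Dropping an under-supported equivalence promotes that
source's well-supported directional maps into the output, and dropping a
witness can un-flag a previously redundant map. What is monotone — and what
the property tests assert — is the set of triples surviving step 1.

## SSSOM export

The consolidated set serializes to SSSOM TSV: a commented YAML-style header
(curie map first, then metadata keys sorted; `mapping_set_id` and `license`
required) and a tab-separated body sorted by subject then object id, so
output is byte-stable. The predicate convention is the classic crosswalk
trap: SKOS match predicates are *object*-relative while our relations are
*source*-relative, so source-`narrower_than`-target becomes
`skos:broadMatch` (the object is the broader concept), source-`broader_than`
becomes `skos:narrowMatch`, and equivalences become `skos:exactMatch`.
Auto-supported rows carry `semapv:LexicalMatching`, the rest
`semapv:ManualMappingCuration`. The reader accepts exactly this dialect and
rejects any other predicate with the offending row number.

## The synthetic world

`generate_pair()` emulates the count structure of the modelled exercise, not
its anatomical content. Defaults are the exercise's stated shape: 321 source
entities, 103 of them residual (leaving 218 mappable), and 113 of the
mappable sources planted with titles found verbatim in the target — so the
auto matcher recovers exactly 113 maps. The breakdown of the 113 between
identical titles and obvious synonyms is not published, so the default
plants them all as identical titles; structure-of and synonym-table
plantings are available through their own fractions. The target defaults to
450 entities — between the 297 distinct targets actually used and the larger
branch searched. Titles come from pseudo-anatomical token pools, and the
pools for target titles and non-planted source titles are disjoint, so a
fixture with no planted match can produce no accidental collision
(matcher precision 1 by construction). Hierarchies are random DAGs of
depth ≤ 4 with occasional second parents (the target is explicitly
polyhierarchical). Residual sources take "⟨parent title⟩, other specified"
titles.

`simulate_raters()` is an independent-error model: each rater re-asserts
each true map, omitting it with probability `omission` and, when asserting,
replacing the collapsed relation by one of the two others uniformly with
probability `relation_confusion`. Defaults: confusion 0.022, chosen once so
that three fully-asserting raters have expected pair concordance
`(1−c)³ + 2(c/2)³ ≈ 0.935`, the agreement level reported for careful human
raters on this task; omission 0.2, matching raters who each mapped most but
not all of 218 sources (~210 maps each). `expected_discordance()` gives the
closed-form expectation including the omission-conditioned binomial
weighting; Monte-Carlo runs at fixed seed are tested against it at 3
standard errors.

What a green test on this world does establish: the pipeline's arithmetic,
filters, priority rules, and serialization behave exactly as specified, and
agree with brute-force oracles. What it does not: anything about real ICF or
ICD-11 content — real anatomical titles are not random token pairs, real
rater errors are not independent relation flips, and the published
consolidated counts (164/230/40) depend on the experts' raw assertions,
which are not reproducible from printed numbers.

## Numerical and degenerate-input choices

- Empty hierarchies, empty mapsets and header-only SSSOM documents are legal
  everywhere and produce empty (not missing) outputs.
- Agreement with < 2 raters, or with no doubly-rated pair, is reported as
  1.0 (with a warning in the first case) rather than NaN.
- Duplicate parent links are de-duplicated silently; duplicate entity codes
  are errors; duplicate titles are legal (they trigger the matcher's
  ambiguity policy).
- Tie-breaks are lexicographic on codes throughout (search ranking,
  redundancy witnesses, SSSOM row order), which is what makes every output
  deterministic and byte-stable.
- All randomness (fixtures, simulated raters) flows through explicit integer
  seeds; the pipeline manifest records them.

## Worked example

```{r mini}
fx <- fixture_mini()
m <- collapse_equivalents(fx$assertions)
find_redundant(m, fx$target)
consolidate(m, fx$target)$maps
```

The three bundled cases behave as a reviewer would expect: the
diencephalon's `narrower_than Brain` is flagged redundant (witness: the
supratentorial region), the skin-gland structure keeps its `narrower_than
Skin` over three broader-than maps onto sibling glands, and the atria keep
their agreed equivalence onto the cardiac atrium with the broader map onto
the right atrium superseded.
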