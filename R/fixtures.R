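# Pseudo-anatomical vocabulary used by the generator. Targets and
# non-planted sources draw from disjoint pools so that a fixture with no
# planted match never produces an accidental lexical collision.
target_nouns <- c(
  "cortex", "gland", "lobe", "membrane", "nucleus", "plexus", "tract",
  "valve", "vesicle", "canal", "fossa", "ganglion", "septum", "sinus",
  "tubercle", "fissure", "capsule", "duct", "follicle", "ligament"
)
target_adjs <- c(
  "anterior", "posterior", "medial", "lateral", "superior", "inferior",
  "dorsal", "ventral", "proximal", "distal", "cranial", "caudal",
  "thoracic", "lumbar", "cervical", "pelvic", "orbital", "palmar",
  "plantar", "axillary", "inguinal", "occipital", "parietal", "temporal"
)
source_nouns <- c(
  "region", "zone", "segment", "compartment", "field", "district",
  "territory", "band", "belt", "stratum", "layer", "sheath", "cord",
  "bundle", "web", "arch", "ridge", "groove", "notch", "recess"
)
source_adjs <- c(
  "upper", "lower", "inner", "outer", "central", "peripheral", "deep",
  "superficial", "primary", "secondary", "accessory", "marginal",
  "terminal", "basal", "apical", "oblique", "transverse", "circular",
  "radial", "spiral", "major", "minor", "first", "second"
)

unique_titles <- function(n, adjs, nouns) {
  grid <- expand.grid(a = adjs, b = nouns, stringsAsFactors = FALSE)
  grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
  if (n > nrow(grid)) {
    grid2 <- expand.grid(a = adjs, b = nouns, c = nouns, stringsAsFactors = FALSE)
    extra <- paste(grid2$a, grid2$b, "of the", grid2$c)
    pool <- unique(c(paste(grid$a, grid$b), extra))
    if (n > length(pool)) abort("Vocabulary too small for requested entity count.")
    return(stringr::str_to_sentence(pool[seq_len(n)]))
  }
  stringr::str_to_sentence(paste(grid$a, grid$b)[seq_len(n)])
}

# Random rooted DAG over n entities: each non-root picks 1 parent (plus a
# second with prob p2) among earlier nodes, keeping depth <= max_depth.
random_hierarchy <- function(n, codes, titles, name, max_depth = 4, p2 = 0.15) {
  depth <- integer(n)
  parents <- vector("list", n)
  parents[[1]] <- character()
  depth[1] <- 1L
  for (i in seq_len(n)[-1]) {
    elig <- which(depth[seq_len(i - 1)] < max_depth)
    if (length(elig) == 0) elig <- 1L
    p <- elig[sample.int(length(elig), 1)]
    parents[[i]] <- codes[p]
    depth[i] <- depth[p] + 1L
    if (length(elig) > 1 && runif(1) < p2) {
      q <- elig[sample.int(length(elig), 1)]
      if (q != p && depth[q] < depth[i]) parents[[i]] <- c(codes[p], codes[q])
    }
  }
  classification(
    tibble(code = codes, title = titles, parents = parents),
    name = name
  )
}

#' Parameters for the synthetic classification-pair generator
#'
#' Defaults reproduce the shape of the mapping exercise this package models:
#' a 321-entity source classification of which 103 are residual categories
#' (leaving 218 mappable) and 113 of the mappable entities carry titles
#' found verbatim in the target, so the auto matcher recovers exactly 113
#' maps. The target defaults to 450 entities, in between the 297 distinct
#' targets the raters used and the larger branch they searched.
#'
#' @param n_source,n_target Entity counts (>= 1).
#' @param residual_fraction Proportion of source entities given
#'   residual-pattern titles.
#' @param exact_title_fraction,structure_of_fraction,synonym_fraction
#'   Proportions of *non-residual* sources planted as exact-title matches,
#'   "Structure of X" matches, and synonym-table matches; their sum must be
#'   <= 1.
#' @param max_depth Maximum hierarchy depth.
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @return A list of class `fixture_params`.
#' @export
fixture_params <- function(n_source = 321, n_target = 450,
                           residual_fraction = 103 / 321,
                           exact_title_fraction = 113 / 218,
                           structure_of_fraction = 0,
                           synonym_fraction = 0,
                           max_depth = 4, seed = 1L) {
  fr <- c(exact_title_fraction, structure_of_fraction, synonym_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1 ||
    residual_fraction < 0 || residual_fraction >= 1) {
    abort("Fractions must lie in [0, 1] and planted fractions sum to <= 1.")
  }
  if (n_source < 1 || n_target < 1) abort("Entity counts must be >= 1.")
  structure(
    list(
      n_source = n_source, n_target = n_target,
      residual_fraction = residual_fraction,
      exact_title_fraction = exact_title_fraction,
      structure_of_fraction = structure_of_fraction,
      synonym_fraction = synonym_fraction,
      max_depth = max_depth, seed = as.integer(seed)
    ),
    class = "fixture_params"
  )
}

#' Generate a synthetic classification pair with planted ground truth
#'
#' Builds a source and a target hierarchy plus the ground-truth mapset of
#' planted lexical correspondences, deterministically for a given seed.
#' Planted matches copy target titles into the source (exact), prefix them
#' with "Structure of" (structure-of rule), or register a synonym-table pair;
#' every other source title is drawn from a vocabulary disjoint from the
#' target's, so un-planted sources can never match. Residual sources get
#' "<parent title>, other specified" titles and are never part of the truth.
#'
#' @param p A [fixture_params()].
#' @return List with `source`, `target` ([classification()]s, residuals
#'   already flagged), `truth` (a [mapset()] with rater `"truth"`), and
#'   `synonyms` (a [synonym_table()]).
#' @export
generate_pair <- function(p = fixture_params()) {
  stopifnot(inherits(p, "fixture_params"))
  withr::with_seed(p$seed, {
    n_res <- round(p$residual_fraction * p$n_source)
    n_map <- p$n_source - n_res
    n_exact <- round(p$exact_title_fraction * n_map)
    n_structof <- round(p$structure_of_fraction * n_map)
    n_syn <- round(p$synonym_fraction * n_map)
    n_plant <- n_exact + n_structof + n_syn
    if (n_plant > n_map) abort("Planted matches exceed mappable sources.")
    if (n_plant > p$n_target) abort("Planted matches exceed target entities.")

    t_codes <- sprintf("T%03d", seq_len(p$n_target))
    t_titles <- unique_titles(p$n_target, target_adjs, target_nouns)
    target <- random_hierarchy(p$n_target, t_codes, t_titles, "icd11", p$max_depth)

    s_codes <- sprintf("s%03d", seq_len(p$n_source))
    s_titles <- unique_titles(p$n_source, source_adjs, source_nouns)
    source <- random_hierarchy(p$n_source, s_codes, s_titles, "icf", p$max_depth)

    # residuals: non-root source entities relabelled after their parent
    non_root <- which(lengths(source$parents) > 0)
    if (n_res > length(non_root)) abort("Not enough non-root sources for residuals.")
    res_idx <- sort(sample(non_root, n_res))
    parent_title <- stats::setNames(source$title, source$code)
    source$title[res_idx] <- paste0(
      parent_title[vapply(source$parents[res_idx], `[`, character(1), 1)],
      ", other specified"
    )

    # plant matches on mappable sources, each onto a distinct target
    map_idx <- setdiff(seq_len(p$n_source), res_idx)
    plant_idx <- sample(map_idx, n_plant)
    plant_t <- sample.int(p$n_target, n_plant)
    kinds <- rep(c("exact", "structof", "synonym"), c(n_exact, n_structof, n_syn))
    syn_pairs <- list()
    truth_rows <- vector("list", n_plant)
    for (j in seq_along(plant_idx)) {
      i <- plant_idx[j]
      tc <- t_codes[plant_t[j]]
      tt <- target$title[plant_t[j]]
      rel <- switch(kinds[j],
        exact = {
          source$title[i] <- tt
          "identical_to"
        },
        structof = {
          source$title[i] <- paste("Structure of", stringr::str_to_lower(tt))
          "synonym_of"
        },
        synonym = {
          syn_pairs[[length(syn_pairs) + 1]] <-
            tibble(title_a = source$title[i], title_b = tt)
          "synonym_of"
        }
      )
      truth_rows[[j]] <- tibble(
        source_code = s_codes[i], source_label = source$title[i],
        relation = rel, target_code = tc, target_label = tt,
        rater = "truth", provenance = "manual", note = kinds[j]
      )
    }
    source <- flag_residuals(source)
    truth <- mapset(bind_rows(truth_rows), source_ref = "icf", target_ref = "icd11")
    list(
      source = source, target = target, truth = truth,
      synonyms = synonym_table(bind_rows(syn_pairs))
    )
  })
}

#' Simulate independent raters over a ground-truth mapset
#'
#' Each rater re-asserts each truth map independently: the map is omitted
#' with probability `omission`; when asserted, its collapsed relation is
#' replaced by one of the two other collapsed relations (uniformly) with
#' probability `relation_confusion`. The default confusion of 0.022 makes
#' three fully-asserting raters agree on about 93.5% of shared pairs — the
#' level reported for careful human raters on this kind of task — and the
#' default omission of 0.2 reflects raters who each map most but not all
#' sources. See [expected_discordance()] for the closed form.
#'
#' @param truth A [mapset()] of true relations (any rater id).
#' @param n_raters Number of simulated raters (>= 1).
#' @param relation_confusion,omission Error probabilities in `[0, 1)`.
#' @param seed Integer seed.
#' @return A [mapset()] with raters `"rater_1"`, ..., provenance
#'   `"manual"`.
#' @export
simulate_raters <- function(truth, n_raters = 3, relation_confusion = 0.022,
                            omission = 0.2, seed = 1L) {
  if (n_raters < 1) abort("`n_raters` must be >= 1.")
  stopifnot(
    relation_confusion >= 0, relation_confusion < 1,
    omission >= 0, omission < 1
  )
  tr <- as_tibble(collapse_equivalents(truth))
  withr::with_seed(seed, {
    out <- vector("list", n_raters)
    for (r in seq_len(n_raters)) {
      keep <- runif(nrow(tr)) >= omission
      a <- tr[keep, , drop = FALSE]
      if (nrow(a) > 0) {
        confuse <- runif(nrow(a)) < relation_confusion
        a$relation[confuse] <- vapply(
          a$relation[confuse],
          function(rel) sample(setdiff(collapsed_relations(), rel), 1),
          character(1)
        )
      }
      a$rater <- sprintf("rater_%d", r)
      a$provenance <- "manual"
      a$note <- NA_character_
      out[[r]] <- a
    }
    ms <- distinct(
      bind_rows(out),
      .data$source_code, .data$target_code, .data$relation, .data$rater,
      .keep_all = TRUE
    )
    as_mapset_like(ms, truth)
  })
}

#' Paper-shaped and worked-example fixtures
#'
#' `fixture_paper()` is [generate_pair()] at the default
#' [fixture_params()] — 321 sources, 103 residuals, 113 planted exact
#' titles. `fixture_mini()` is a small static fixture encoding three classic
#' consolidation situations on a brain / skin-gland / heart toy hierarchy:
#' a redundant `narrower_than` onto Brain (implied by `narrower_than` onto
#' the Supratentorial region), a source broader than three sibling glands
#' yet narrower than Skin (nothing redundant), and a source with an agreed
#' equivalence that supersedes its `broader_than`.
#'
#' @param seed Integer seed (paper fixture only).
#' @return Like [generate_pair()]: list with `source`, `target`, and for
#'   `fixture_mini()` an `assertions` [mapset()] from two simulated raters.
#' @export
fixture_paper <- function(seed = 1L) {
  generate_pair(fixture_params(seed = seed))
}

#' @rdname fixture_paper
#' @export
fixture_mini <- function() {
  target <- classification(
    tibble(
      code = c("BR", "SUP", "DIE", "THA", "SKN", "SEB", "APO", "ECC", "ATR", "RAT"),
      title = c(
        "Brain", "Supratentorial region of brain", "Diencephalon", "Thalamus",
        "Skin", "Sebaceous gland", "Apocrine sweat gland", "Eccrine gland",
        "Cardiac atrium", "Right atrium"
      ),
      parents = list(
        character(), "BR", "SUP", "DIE",
        character(), "SKN", "SKN", "SKN", character(), "ATR"
      )
    ),
    name = "icd11", version = "mini"
  )
  source <- classification(
    tibble(
      code = c("s110", "s820", "s4100"),
      title = c("Structure of diencephalon", "Structure of skin glands", "Atria"),
      parents = list(character(), character(), character())
    ),
    name = "icf", version = "mini"
  )
  rows <- function(rater) {
    tibble(
      source_code = c("s110", "s110", "s110", "s820", "s820", "s820", "s820", "s4100", "s4100"),
      relation = c(
        "narrower_than", "narrower_than", "broader_than",
        "broader_than", "broader_than", "broader_than", "narrower_than",
        "equivalent_to", "broader_than"
      ),
      target_code = c("SUP", "BR", "THA", "SEB", "APO", "ECC", "SKN", "ATR", "RAT"),
      rater = rater
    )
  }
  assertions <- mapset(
    bind_rows(rows("rater_1"), rows("rater_2")),
    source_ref = "icf", target_ref = "icd11"
  )
  list(source = source, target = target, assertions = assertions)
}

#' Per-rater tally counts of the modelled mapping exercise
#'
#' Reads the static transcription shipped in `inst/extdata/rater_tallies.tsv`
#' — the per-rater equivalent_to / broader_than / narrower_than counts of a
#' three-expert ICF-to-ICD-11 anatomy mapping (totals 141 / 416 / 74, grand
#' total 631). Used for tally arithmetic only; it contains counts, not
#' assertions.
#'
#' @return A tibble `rater`, `equivalent_to`, `broader_than`,
#'   `narrower_than`.
#' @export
rater_tallies <- function() {
  path <- system.file("extdata", "rater_tallies.tsv", package = "crossmapr")
  readr::read_tsv(path, col_types = readr::cols(
    rater = readr::col_character(), .default = readr::col_integer()
  ))
}

#' Expand a tally table into a placeholder mapset
#'
#' Builds a mapset with synthetic codes whose per-rater tallies reproduce a
#' given count table exactly — useful for testing tally arithmetic against
#' published totals without inventing anatomical content.
#'
#' @param tallies A tibble like [rater_tallies()].
#' @return A collapsed [mapset()] with `tally_by_rater()` equal to
#'   `tallies` (plus totals).
#' @export
mapset_from_tallies <- function(tallies) {
  rows <- list()
  for (i in seq_len(nrow(tallies))) {
    for (rel in collapsed_relations()) {
      k <- tallies[[rel]][i]
      if (k > 0) {
        rows[[length(rows) + 1]] <- tibble(
          source_code = sprintf("s_%s_%s_%03d", tallies$rater[i], rel, seq_len(k)),
          relation = rel,
          target_code = sprintf("t_%s_%s_%03d", tallies$rater[i], rel, seq_len(k)),
          rater = tallies$rater[i]
        )
      }
    }
  }
  mapset(bind_rows(rows), source_ref = "tally", target_ref = "tally")
}
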