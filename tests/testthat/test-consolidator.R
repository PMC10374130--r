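two_raters <- function(...) {
  rows <- dplyr::bind_rows(lapply(list(...), function(r) {
    tibble::tibble(source_code = r[[1]], relation = r[[2]], target_code = r[[3]])
  }))
  mapset(dplyr::bind_rows(
    dplyr::mutate(rows, rater = "rater_1"),
    dplyr::mutate(rows, rater = "rater_2")
  ))
}

flat_target <- function(codes) {
  classification(tibble::tibble(code = codes, title = codes))
}

test_that("an agreed equivalence supersedes directional relations", {
  target <- flat_target(c("t1", "t2"))
  m <- two_raters(
    list("s1", "equivalent_to", "t1"),
    list("s1", "broader_than", "t2")
  )
  cons <- consolidate(m, target)
  expect_equal(cons$maps$relation, "equivalent_to")
  expect_equal(cons$maps$target_code, "t1")
  expect_true("superseded_by_equivalent_to" %in% cons$review$reason)
})

test_that("narrower_than beats broader_than without an equivalence", {
  target <- flat_target(c("t1", "t2"))
  m <- two_raters(
    list("s1", "narrower_than", "t1"),
    list("s1", "broader_than", "t2")
  )
  cons <- consolidate(m, target, exclusive = TRUE)
  expect_equal(cons$maps$relation, "narrower_than")
  expect_true("superseded_by_narrower_than" %in% cons$review$reason)

  # with exclusive = FALSE the broader map survives as secondary
  cons2 <- consolidate(m, target, exclusive = FALSE)
  expect_equal(cons2$secondary$relation, "broader_than")
  expect_equal(sum(cons2$counts$n), 2)
})

test_that("support filtering routes weak assertions to review, auto equivalences exempt", {
  target <- flat_target(c("t1", "t2", "t3"))
  m <- mapset(tibble::tibble(
    source_code = c("s1", "s1", "s2", "s3"),
    relation = c("equivalent_to", "equivalent_to", "equivalent_to", "narrower_than"),
    target_code = c("t1", "t1", "t2", "t3"),
    rater = c("rater_1", "rater_2", "auto", "rater_1")
  ))
  cons <- consolidate(m, target, min_support = 2)
  expect_setequal(cons$maps$source_code, c("s1", "s2")) # auto equivalence kept
  expect_equal(
    cons$review$reason[cons$review$source_code == "s3"],
    "below_min_support"
  )
  expect_error(consolidate(m, target, min_support = 0), "min_support")
})

test_that("empty input consolidates to empty output with zero counts", {
  cons <- consolidate(mapset(), flat_target("t1"))
  expect_equal(nrow(cons$maps), 0)
  expect_equal(cons$counts$n, c(0L, 0L, 0L))
  expect_equal(nrow(cons$review), 0)
})

test_that("redundant directional maps are removed with their witness recorded", {
  target <- chain_clf(c(SUP = "BR", DIE = "SUP"))
  m <- two_raters(
    list("s1", "narrower_than", "SUP"),
    list("s1", "narrower_than", "BR")
  )
  cons <- consolidate(m, target)
  expect_equal(cons$maps$target_code, "SUP")
  red <- cons$review[cons$review$reason == "redundant", ]
  expect_equal(red$target_code, "BR")
  expect_equal(red$witness_code, "SUP")
})

test_that("consolidation matches the independent rule-by-rule oracle", {
  for (seed in 1:6) {
    h <- random_dag(30, seed + 40)
    fxm <- random_mapset(h, 60, seed + 50, n_sources = 8)
    # add an auto layer on a few pairs
    a <- tibble::as_tibble(fxm)
    auto_rows <- dplyr::mutate(
      dplyr::distinct(utils::head(a[a$relation == "equivalent_to", ], 3),
        source_code, target_code,
        .keep_all = TRUE
      ),
      rater = "auto", provenance = "auto"
    )
    m <- mapset(dplyr::bind_rows(a, dplyr::anti_join(auto_rows, a,
      by = c("source_code", "target_code", "relation", "rater")
    )))
    for (ms in c(1, 2)) {
      for (excl in c(TRUE, FALSE)) {
        cons <- consolidate(m, h, min_support = ms, exclusive = excl)
        got <- dplyr::arrange(
          dplyr::bind_rows(cons$maps, cons$secondary)[
            , c("source_code", "relation", "target_code")
          ],
          source_code, relation, target_code
        )
        want <- oracle_consolidate(m, h, min_support = ms, exclusive = excl)
        expect_equal(as.data.frame(got), as.data.frame(want))
        # per-relation counts sum to retained pairs
        expect_equal(sum(cons$counts$n), nrow(got))
      }
    }
  }
})

test_that("raising min_support only shrinks the support-qualified set", {
  # Note: the *final* output is deliberately not monotone in min_support —
  # dropping an equivalence can promote a well-supported directional map
  # (priority rules), and dropping a witness can un-flag a redundant one.
  # What is monotone is the set of triples that survive the support filter.
  h <- random_dag(20, 77)
  m <- random_mapset(h, 50, 78, n_sources = 6)
  qualified <- lapply(1:3, function(ms) {
    cons <- consolidate(m, h, min_support = ms)
    dropped <- cons$review[cons$review$reason == "below_min_support", ]
    setdiff(
      paste(m$source_code, m$relation, m$target_code),
      paste(dropped$source_code, dropped$relation, dropped$target_code)
    )
  })
  expect_true(all(qualified[[2]] %in% qualified[[1]]))
  expect_true(all(qualified[[3]] %in% qualified[[2]]))
  # and no triple ever enters the output without qualifying
  for (ms in 1:3) {
    cons <- consolidate(m, h, min_support = ms)
    expect_true(all(
      paste(cons$maps$source_code, cons$maps$relation, cons$maps$target_code) %in%
        qualified[[ms]]
    ))
  }
})

test_that("no source with an equivalence carries directional maps in exclusive output", {
  h <- random_dag(25, 91)
  m <- random_mapset(h, 70, 92, n_sources = 10)
  cons <- consolidate(m, h, min_support = 1, exclusive = TRUE)
  by_src <- split(cons$maps$relation, cons$maps$source_code)
  for (rels in by_src) {
    expect_equal(length(unique(rels)), 1)
  }
  # and nothing retained is redundant
  expect_equal(nrow(find_redundant(
    mapset(tibble::tibble(
      source_code = cons$maps$source_code, relation = cons$maps$relation,
      target_code = cons$maps$target_code, rater = "x"
    )), h
  )), 0)
})

test_that("the worked mini-fixture consolidates as reviewed by the experts", {
  fx <- fixture_mini()
  m <- collapse_equivalents(fx$assertions)

  red <- find_redundant(m, fx$target)
  expect_equal(nrow(red), 1) # exactly one redundant map in the three cases
  expect_equal(red$source_code, "s110")
  expect_equal(red$target_code, "BR")
  expect_equal(red$witness_code, "SUP")

  cons <- consolidate(m, fx$target, min_support = 2)
  maps <- cons$maps
  # diencephalon: narrower_than the supratentorial region only
  expect_equal(maps$target_code[maps$source_code == "s110"], "SUP")
  expect_equal(maps$relation[maps$source_code == "s110"], "narrower_than")
  # skin glands: the narrower_than Skin wins over three broader_than glands
  expect_equal(maps$target_code[maps$source_code == "s820"], "SKN")
  # atria: agreed equivalence wins
  expect_equal(maps$relation[maps$source_code == "s4100"], "equivalent_to")
  expect_equal(maps$target_code[maps$source_code == "s4100"], "ATR")
})
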