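mini_assertions <- function(...) {
  rows <- list(...)
  mapset(dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      source_code = r[[1]], relation = r[[2]], target_code = r[[3]],
      rater = if (length(r) > 3) r[[4]] else "rater_1"
    )
  })))
}

test_that("mapsets enforce relation types and tuple uniqueness", {
  expect_error(
    mapset(tibble::tibble(
      source_code = "s", relation = "related_to", target_code = "t", rater = "a"
    )),
    "Unknown relation"
  )
  expect_error(
    mapset(tibble::tibble(
      source_code = c("s", "s"), relation = "equivalent_to",
      target_code = c("t", "t"), rater = "a"
    )),
    "Duplicate"
  )
  # same pair from two raters is fine
  m <- mapset(tibble::tibble(
    source_code = "s", relation = "equivalent_to", target_code = "t",
    rater = c("a", "b")
  ))
  expect_equal(nrow(m), 2)
  expect_equal(m$provenance, c("manual", "manual"))
})

test_that("collapse_equivalents rewrites both equivalence flavours and nothing else", {
  m <- mini_assertions(
    list("s1", "identical_to", "t1", "A"),
    list("s1", "synonym_of", "t1", "B"),
    list("s2", "synonym_of", "t2", "A"),
    list("s3", "broader_than", "t3", "A")
  )
  cm <- collapse_equivalents(m)
  expect_setequal(unique(cm$relation), c("equivalent_to", "broader_than"))
  expect_equal(sum(cm$relation == "equivalent_to"), 3)
  # idempotent, and the (source, target, rater) multiset is preserved
  expect_identical(
    tibble::as_tibble(collapse_equivalents(cm)),
    tibble::as_tibble(cm)
  )
  expect_setequal(
    paste(cm$source_code, cm$target_code, cm$rater),
    paste(m$source_code, m$target_code, m$rater)
  )
  # a rater asserting both flavours on one pair collapses to one row
  m2 <- mini_assertions(
    list("s1", "identical_to", "t1", "A"),
    list("s1", "synonym_of", "t1", "A")
  )
  expect_equal(nrow(collapse_equivalents(m2)), 1)
})

test_that("tally_by_rater conserves counts and handles the empty set", {
  t0 <- tally_by_rater(mapset())
  expect_equal(t0$total, 0)
  expect_equal(t0$rater, "Total")

  m <- collapse_equivalents(simulate_raters(
    fixture_paper(seed = 3)$truth,
    n_raters = 3, relation_confusion = 0.1, omission = 0.3, seed = 4
  ))
  tal <- tally_by_rater(m)
  expect_equal(tal$total[tal$rater == "Total"], nrow(m))
  body <- tal[tal$rater != "Total", ]
  expect_equal(sum(body$total), tal$total[tal$rater == "Total"])
  expect_equal(
    body$equivalent_to + body$broader_than + body$narrower_than,
    body$total
  )
})

test_that("agreement scores strict pair-level concordance", {
  # all raters identical on every shared pair -> 1.0
  m <- mini_assertions(
    list("s1", "equivalent_to", "t1", "A"), list("s1", "equivalent_to", "t1", "B"),
    list("s2", "narrower_than", "t2", "A"), list("s2", "narrower_than", "t2", "B")
  )
  expect_equal(agreement(m)$agreement_fraction, 1.0)

  # the classic discrepancy: equivalent_to vs broader_than on one pair
  m <- mini_assertions(
    list("bronchial_tree", "equivalent_to", "bronchus", "A"),
    list("bronchial_tree", "broader_than", "bronchus", "B"),
    list("s2", "equivalent_to", "t2", "A"), list("s2", "equivalent_to", "t2", "B")
  )
  rep <- agreement(m)
  expect_equal(rep$pairs_compared, 2L)
  expect_equal(rep$pairs_discordant, 1L)
  expect_equal(rep$agreement_fraction, 0.5)
  expect_equal(tidy(rep)$source_code, rep("bronchial_tree", 2))

  # singly-rated pairs do not enter the denominator
  m <- mini_assertions(
    list("s1", "equivalent_to", "t1", "A"),
    list("s1", "broader_than", "t9", "B")
  )
  expect_warning(r1 <- agreement(mini_assertions(list("s1", "equivalent_to", "t1", "A"))), "Fewer")
  expect_equal(r1$agreement_fraction, 1)
  expect_equal(agreement(m)$pairs_compared, 0L)
})

test_that("agreement is invariant to rater relabeling and row order", {
  fx <- fixture_paper(seed = 6)
  m <- collapse_equivalents(simulate_raters(fx$truth,
    relation_confusion = 0.2, omission = 0.2, seed = 7
  ))
  base <- agreement(m)
  a <- tibble::as_tibble(m)
  relabeled <- mapset(dplyr::mutate(a, rater = paste0("x_", rater)))
  shuffled <- mapset(a[withr::with_seed(1, sample(nrow(a))), ])
  expect_equal(agreement(relabeled)$agreement_fraction, base$agreement_fraction)
  expect_equal(agreement(shuffled)$agreement_fraction, base$agreement_fraction)
  expect_equal(agreement(shuffled)$pairs_compared, base$pairs_compared)
})

test_that("auto assertions are excluded from agreement by default", {
  m <- mini_assertions(
    list("s1", "equivalent_to", "t1", "auto"),
    list("s1", "broader_than", "t1", "A"),
    list("s1", "broader_than", "t1", "B")
  )
  expect_equal(agreement(m)$pairs_discordant, 0L)
  expect_equal(agreement(m, exclude_auto = FALSE)$pairs_discordant, 1L)
})

test_that("find_redundant flags implied directional maps with witnesses", {
  target <- chain_clf(c(SUP = "BR", DIE = "SUP", THA = "DIE"))
  m <- mini_assertions(
    list("s1", "narrower_than", "SUP"),
    list("s1", "narrower_than", "BR")
  )
  red <- find_redundant(m, target)
  expect_equal(red$target_code, "BR")
  expect_equal(red$witness_code, "SUP")

  # single assertions and equivalences are never flagged
  expect_equal(nrow(find_redundant(
    mini_assertions(list("s1", "narrower_than", "BR")), target
  )), 0)
  expect_equal(nrow(find_redundant(
    mini_assertions(
      list("s1", "equivalent_to", "BR"),
      list("s1", "equivalent_to", "SUP")
    ), target
  )), 0)

  # broader_than flags the more specific target
  m <- mini_assertions(
    list("s1", "broader_than", "SUP"),
    list("s1", "broader_than", "THA")
  )
  red <- find_redundant(m, target)
  expect_equal(red$target_code, "THA")
  expect_equal(red$witness_code, "SUP")

  expect_error(
    find_redundant(mini_assertions(
      list("s1", "broader_than", "ghost"),
      list("s1", "broader_than", "SUP")
    ), target),
    "ghost"
  )
})

test_that("find_redundant equals the brute-force oracle and is order-stable", {
  sizes <- c(10, 18, 25, 32, 40, 15, 22, 38)
  for (seed in 1:8) {
    h <- random_dag(sizes[seed], seed)
    m <- random_mapset(h, 40, seed + 100)
    got <- find_redundant(m, h)
    expect_equal(got, oracle_redundant(m, h))
    shuffled <- mapset(tibble::as_tibble(m)[withr::with_seed(seed, sample(nrow(m))), ])
    expect_equal(find_redundant(shuffled, h), got)
  }
})

test_that("removing a flagged assertion never creates a new flag", {
  for (seed in 21:24) {
    h <- random_dag(25, seed)
    m <- random_mapset(h, 35, seed + 200)
    red <- find_redundant(m, h)
    if (nrow(red) == 0) next
    a <- tibble::as_tibble(m)
    drop_key <- paste(red$source_code[1], red$relation[1], red$target_code[1])
    kept <- a[paste(a$source_code, a$relation, a$target_code) != drop_key, ]
    red2 <- find_redundant(mapset(kept), h)
    old_keys <- paste(red$source_code, red$relation, red$target_code)
    new_keys <- paste(red2$source_code, red2$relation, red2$target_code)
    expect_true(all(new_keys %in% old_keys))
  }
})

test_that("assertion TSVs round-trip through read and write", {
  fx <- fixture_mini()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_mapset(fx$assertions, tf)
  back <- read_mapset(tf, source_ref = "icf", target_ref = "icd11")
  expect_equal(
    tibble::as_tibble(back)[c("source_code", "relation", "target_code", "rater")],
    tibble::as_tibble(fx$assertions)[c("source_code", "relation", "target_code", "rater")]
  )
})
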