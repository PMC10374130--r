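# Independent brute-force oracles and tiny builders. Everything here avoids
# the package's graph machinery on purpose: reachability is recursive path
# following over the raw parent lists, consolidation is a literal rule-by-rule
# transcription applied triple by triple.

# Quick classification from a named parent list: chain_clf(c(B = "A", C = "B"))
# gives entities A, B, C with those parents; titles default to the codes.
chain_clf <- function(parent_map, titles = NULL, name = "test") {
  codes <- unique(c(names(parent_map), unlist(parent_map)))
  parents <- lapply(codes, function(cd) {
    p <- parent_map[names(parent_map) == cd]
    as.character(unlist(p))
  })
  if (is.null(titles)) titles <- codes
  classification(
    tibble::tibble(code = codes, title = titles, parents = parents),
    name = name
  )
}

# All codes reachable from `code` by repeatedly following parent links.
oracle_ancestors <- function(h, code) {
  parents <- stats::setNames(h$parents, h$code)
  seen <- character()
  frontier <- parents[[code]]
  while (length(frontier) > 0) {
    nxt <- setdiff(frontier, seen)
    seen <- union(seen, nxt)
    frontier <- unique(unlist(parents[nxt]))
  }
  sort(setdiff(seen, code))
}

oracle_descendants <- function(h, code) {
  sort(h$code[vapply(h$code, function(cd) code %in% oracle_ancestors(h, cd), logical(1))])
}

# Random DAG: node i may take 1-2 parents among nodes 1..(i-1).
random_dag <- function(n, seed, p_second = 0.3) {
  withr::with_seed(seed, {
    codes <- sprintf("N%02d", seq_len(n))
    parents <- vector("list", n)
    parents[[1]] <- character()
    for (i in seq_len(n)[-1]) {
      k <- 1 + (stats::runif(1) < p_second && i > 2)
      parents[[i]] <- codes[sample.int(i - 1, min(k, i - 1))]
    }
    classification(tibble::tibble(code = codes, title = codes, parents = parents))
  })
}

# Random collapsed mapset over a target hierarchy.
random_mapset <- function(target, n_assert, seed, n_sources = 5) {
  withr::with_seed(seed, {
    a <- tibble::tibble(
      source_code = sample(sprintf("s%d", seq_len(n_sources)), n_assert, replace = TRUE),
      relation = sample(collapsed_relations(), n_assert, replace = TRUE),
      target_code = sample(target$code, n_assert, replace = TRUE),
      rater = sample(c("rater_1", "rater_2", "rater_3"), n_assert, replace = TRUE)
    )
    a <- dplyr::distinct(a, source_code, target_code, relation, rater, .keep_all = TRUE)
    mapset(a, target_ref = clf_name(target))
  })
}

# Brute-force redundancy: test every pair of distinct (source, relation,
# target) triples against full reachability.
oracle_redundant <- function(m, target) {
  a <- dplyr::distinct(tibble::as_tibble(m), source_code, relation, target_code)
  flags <- list()
  for (i in seq_len(nrow(a))) {
    if (!a$relation[i] %in% c("narrower_than", "broader_than")) next
    wits <- character()
    for (j in seq_len(nrow(a))) {
      if (i == j) next
      if (a$source_code[j] != a$source_code[i] || a$relation[j] != a$relation[i]) next
      ti <- a$target_code[i]
      tj <- a$target_code[j]
      implied <- if (a$relation[i] == "narrower_than") {
        ti %in% oracle_ancestors(target, tj)
      } else {
        ti %in% oracle_descendants(target, tj)
      }
      if (implied) wits <- c(wits, tj)
    }
    if (length(wits) > 0) {
      flags[[length(flags) + 1]] <- tibble::tibble(
        source_code = a$source_code[i], relation = a$relation[i],
        target_code = a$target_code[i], witness_code = min(wits)
      )
    }
  }
  if (length(flags) == 0) {
    return(tibble::tibble(
      source_code = character(), relation = character(),
      target_code = character(), witness_code = character()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(flags), source_code, relation, target_code)
}

# Literal transcription of the consolidation rules, applied independently:
# support filter (auto equivalences exempt), redundancy via the brute-force
# oracle, then per-source priority equivalent > narrower > broader.
oracle_consolidate <- function(m, target, min_support = 2, exclusive = TRUE) {
  a <- tibble::as_tibble(m)
  key <- paste(a$source_code, a$relation, a$target_code, sep = "|")
  triples <- unique(tibble::tibble(
    source_code = a$source_code, relation = a$relation,
    target_code = a$target_code
  ))
  tkey <- paste(triples$source_code, triples$relation, triples$target_code, sep = "|")
  support <- vapply(tkey, function(k) length(unique(a$rater[key == k])), integer(1))
  has_auto <- vapply(tkey, function(k) "auto" %in% a$rater[key == k], logical(1))
  ok <- support >= min_support | (has_auto & triples$relation == "equivalent_to")
  triples <- triples[ok, , drop = FALSE]

  red <- oracle_redundant(mapset(cbind(triples, rater = "x")), target)
  if (nrow(red) > 0) {
    rk <- paste(red$source_code, red$relation, red$target_code, sep = "|")
    triples <- triples[!paste(triples$source_code, triples$relation,
      triples$target_code,
      sep = "|"
    ) %in% rk, , drop = FALSE]
  }

  keep <- logical(nrow(triples))
  for (s in unique(triples$source_code)) {
    rel <- triples$relation[triples$source_code == s]
    win <- if ("equivalent_to" %in% rel) {
      "equivalent_to"
    } else if ("narrower_than" %in% rel) {
      "narrower_than"
    } else {
      "broader_than"
    }
    keep[triples$source_code == s & triples$relation == win] <- TRUE
    if (!exclusive) keep[triples$source_code == s] <- TRUE
  }
  dplyr::arrange(
    triples[keep, , drop = FALSE],
    source_code, relation, target_code
  )
}

# Brute-force ranked search: score every entity with an independently
# written copy of the formula, sort by score then code.
oracle_search <- function(query, target, k) {
  norm <- function(s) {
    s <- tolower(s)
    s <- gsub("[[:punct:]]+", " ", s)
    trimws(gsub("\\s+", " ", s))
  }
  q <- norm(query)
  score1 <- function(l) {
    if (q == l) {
      return(1)
    }
    qt <- unique(strsplit(q, " ")[[1]])
    lt <- unique(strsplit(l, " ")[[1]])
    j <- length(intersect(qt, lt)) / length(union(qt, lt))
    cont <- grepl(q, l, fixed = TRUE) || grepl(l, q, fixed = TRUE)
    min(0.75 * j + 0.25 * cont, 1 - 1e-6)
  }
  sc <- vapply(seq_len(nrow(target)), function(i) {
    max(vapply(
      unique(norm(c(target$title[i], target$synonyms[[i]]))),
      score1, numeric(1)
    ))
  }, numeric(1))
  out <- tibble::tibble(code = target$code, score = sc)
  out <- out[out$score > 0, ]
  head(out[order(-out$score, out$code, method = "radix"), ], k)
}

# Merge an auto mapset and a manual mapset into one collapsed mapset.
merge_collapse <- function(auto, manual) {
  collapse_equivalents(mapset(
    dplyr::bind_rows(tibble::as_tibble(auto), tibble::as_tibble(manual)),
    source_ref = attr(auto, "source_ref"), target_ref = attr(auto, "target_ref")
  ))
}
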