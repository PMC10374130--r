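#' Run the full harmonization pipeline
#'
#' Wires the stages end to end: load (or generate) the two classifications,
#' flag residuals, auto-match, merge manual rater assertions, collapse
#' equivalences, compute agreement, consolidate, and export SSSOM — writing
#' every artifact plus a JSON run manifest (package version, seed,
#' parameters, per-stage counts) into `out_dir`. Identical config and seed
#' give byte-identical outputs.
#'
#' @param config A named list:
#'   * `preset` — `"paper"` or `"mini"` to run on generated fixtures, or
#'     omit and give `claml` / `snapshot` / `raters` file paths instead
#'     (`raters` is an assertion TSV readable by [read_mapset()]);
#'   * `synonyms` — optional synonym-table TSV path;
#'   * `seed` (default 1), `min_support` (default 2), `exclusive`
#'     (default `TRUE`), `exclude_auto` (default `TRUE`);
#'   * `n_raters`, `relation_confusion`, `omission` — simulated-rater
#'     parameters, used with `preset = "paper"`.
#' @param out_dir Output directory (created if needed). On any stage error,
#'   partial outputs are removed and the error is re-thrown with the stage
#'   name.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = list(preset = "paper"), out_dir = tempfile("run")) {
  cfg <- utils::modifyList(
    list(
      preset = NULL, claml = NULL, snapshot = NULL, raters = NULL,
      synonyms = NULL, seed = 1L, min_support = 2L, exclusive = TRUE,
      exclude_auto = TRUE, n_raters = 3L, relation_confusion = 0.022,
      omission = 0.2
    ),
    config
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  out <- function(f) {
    p <- file.path(out_dir, f)
    written <<- c(written, p)
    p
  }
  stage <- "configure"
  res <- tryCatch(
    {
      syn <- if (!is.null(cfg$synonyms)) read_synonym_table(cfg$synonyms) else synonym_table()
      manual <- NULL
      stage <- "load"
      if (!is.null(cfg$preset)) {
        if (cfg$preset == "mini") {
          fx <- fixture_mini()
          source_h <- fx$source
          target_h <- fx$target
          manual <- fx$assertions
        } else if (cfg$preset == "paper") {
          fx <- generate_pair(fixture_params(seed = cfg$seed))
          source_h <- fx$source
          target_h <- fx$target
          syn <- fx$synonyms
        } else {
          abort(sprintf("Unknown preset '%s'.", cfg$preset))
        }
      } else {
        if (is.null(cfg$claml) || is.null(cfg$snapshot)) {
          abort("Config needs either `preset` or both `claml` and `snapshot`.")
        }
        source_h <- flag_residuals(parse_claml(cfg$claml, quiet = TRUE))
        target_h <- parse_foundation_snapshot(cfg$snapshot, name = "icd11")
        if (!is.null(cfg$raters)) {
          manual <- read_mapset(cfg$raters,
            source_ref = clf_name(source_h), target_ref = clf_name(target_h)
          )
        }
      }

      stage <- "automatch"
      auto <- auto_match(source_h, target_h, syn)
      write_mapset(auto, out("auto_maps.tsv"))

      stage <- "simulate_raters"
      if (is.null(manual) && identical(cfg$preset, "paper")) {
        manual <- simulate_raters(
          fx$truth,
          n_raters = cfg$n_raters,
          relation_confusion = cfg$relation_confusion,
          omission = cfg$omission, seed = cfg$seed
        )
      }
      if (is.null(manual) || nrow(manual) == 0) {
        warn("No manual assertions; consolidating auto matches only.")
        manual <- mapset(
          source_ref = clf_name(source_h), target_ref = clf_name(target_h)
        )
      }

      stage <- "collapse"
      merged <- as_mapset_like(
        bind_rows(as_tibble(auto), as_tibble(manual)), auto
      )
      collapsed <- collapse_equivalents(merged)
      write_mapset(collapsed, out("all_maps.tsv"))

      stage <- "agree"
      agr <- withCallingHandlers(
        agreement(collapsed, exclude_auto = cfg$exclude_auto),
        warning = function(w) invokeRestart("muffleWarning")
      )
      readr::write_tsv(glance(agr), out("agreement.tsv"))

      stage <- "consolidate"
      cons <- consolidate(collapsed, target_h,
        min_support = cfg$min_support, exclusive = cfg$exclusive
      )
      flat <- function(t) {
        t$raters <- purrr::map_chr(t$raters, paste, collapse = "|")
        t
      }
      readr::write_tsv(flat(tidy(cons)), out("consolidated.tsv"))
      readr::write_tsv(flat(cons$review), out("review.tsv"))

      stage <- "export"
      write_sssom(
        cons, source_h, target_h,
        metadata = list(
          mapping_set_id = "https://example.org/mappings/run",
          license = "https://creativecommons.org/licenses/by/4.0/"
        ),
        path = out("maps.sssom.tsv")
      )

      stage <- "manifest"
      n_loaded <- nrow(source_h)
      n_res <- sum(source_h$residual)
      manifest <- list(
        package = "crossmapr",
        version = as.character(utils::packageVersion("crossmapr")),
        seed = cfg$seed,
        params = cfg[c(
          "preset", "min_support", "exclusive", "exclude_auto",
          "n_raters", "relation_confusion", "omission"
        )],
        counts = list(
          loaded = n_loaded,
          residual = n_res,
          mappable = n_loaded - n_res,
          auto = nrow(auto),
          manual = nrow(manual),
          assertions = nrow(collapsed),
          pairs_compared = agr$pairs_compared,
          pairs_discordant = agr$pairs_discordant,
          agreement_fraction = agr$agreement_fraction,
          consolidated = stats::setNames(
            as.list(cons$counts$n), cons$counts$relation
          ),
          consolidated_total = sum(cons$counts$n),
          under_review = nrow(cons$review)
        )
      )
      jsonlite::write_json(manifest, out("manifest.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA
      )
      manifest
    },
    error = function(e) {
      unlink(written)
      abort(sprintf("Pipeline failed at stage '%s': %s", stage, conditionMessage(e)))
    }
  )
  invisible(res)
}
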