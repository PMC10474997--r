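#' Study-level detection summary
#'
#' Computes the Results-style summary of a survey: the fraction of field
#' samples (site-month biological replicates) with at least one positive
#' replicate call of any target species, and the site-level fractions of
#' ponds holding any target species, prey (amphibians), prey only, fish,
#' fish only, and a predator-prey co-occurrence — months pooled per site,
#' so a prey detection in May and a fish detection in July at the same pond
#' count as co-occurrence.
#'
#' @param x A [detection_matrix()].
#' @param wells Optional wells `data.frame`; when supplied together with
#'   `curves`, sample-level positivity is computed (otherwise `NA`).
#' @param curves Standard curve(s) with LODs, as in [call_detections()].
#' @param roles Species roles; defaults to those attached to `x`.
#' @return An object of class `site_summary` with fields `n_sites`,
#'   `n_samples`, `n_samples_positive`, `fraction_samples_positive`,
#'   `fraction_sites_any_target`, `fraction_prey_any`, `fraction_prey_only`,
#'   `fraction_fish_any`, `fraction_fish_only`, `fraction_cooccur`.
#' @export
summarize_study <- function(x, wells = NULL, curves = NULL, roles = NULL) {
  sites <- summarize_sites(x, roles = roles)
  n_sites <- nrow(sites)
  n_samples <- n_samples_positive <- NA_integer_
  if (!is.null(wells) && !is.null(curves)) {
    sp <- sort(unique(wells$species_id))
    cl <- .curve_list(curves, sp)
    q <- rep(NA_real_, nrow(wells))
    for (s in sp) {
      i <- wells$species_id == s
      q[i] <- quantify_cq(cl[[s]], wells$cq[i])
    }
    lods <- vapply(cl, function(cv) cv$lod, numeric(1))
    pos <- !is.na(q) & q > lods[wells$species_id]
    samp <- interaction(wells$site_id, wells$month, wells$bio_rep, drop = TRUE)
    n_samples <- nlevels(samp)
    n_samples_positive <- sum(tapply(pos, samp, any))
  }
  out <- list(n_sites = n_sites, n_samples = n_samples,
              n_samples_positive = n_samples_positive,
              fraction_samples_positive =
                if (is.na(n_samples)) NA_real_ else n_samples_positive / n_samples,
              fraction_sites_any_target = mean(sites$any_target),
              fraction_prey_any = mean(sites$prey_any),
              fraction_prey_only = mean(sites$prey_only),
              fraction_fish_any = mean(sites$fish_any),
              fraction_fish_only = mean(sites$fish_only),
              fraction_cooccur = mean(sites$cooccur),
              sites = sites)
  class(out) <- "site_summary"
  out
}

#' @export
print.site_summary <- function(x, ...) {
  pct <- function(f) if (is.na(f)) "NA" else sprintf("%d%% (%.4f)", round(100 * f), f)
  cat("Study summary\n")
  if (!is.na(x$n_samples)) {
    cat(sprintf("  samples positive for >= 1 target: %d of %d, %s\n",
                x$n_samples_positive, x$n_samples, pct(x$fraction_samples_positive)))
  }
  cat(sprintf("  sites surveyed: %d\n", x$n_sites))
  cat(sprintf("  any target species: %s\n", pct(x$fraction_sites_any_target)))
  cat(sprintf("  prey (amphibians):  %s  [prey only: %s]\n",
              pct(x$fraction_prey_any), pct(x$fraction_prey_only)))
  cat(sprintf("  predatory fish:     %s  [fish only: %s]\n",
              pct(x$fraction_fish_any), pct(x$fraction_fish_only)))
  cat(sprintf("  predator-prey co-occurrence (months pooled): %s\n",
              pct(x$fraction_cooccur)))
  invisible(x)
}

#' Assemble and validate a pipeline configuration
#'
#' @param wells Wells CSV path or `data.frame`.
#' @param dilution_series Named list (by species id) of dilution-series CSV
#'   paths or data frames, or pre-fitted [standard_curve()]s (one shared
#'   curve is also accepted).
#' @param species A [species_roster()]; defaults to the A1/A2/F1/F2 roster.
#' @param months Ordered month labels (default May, June, July).
#' @param n_perm,alpha,seed Monte-Carlo test settings.
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(wells, dilution_series, species = species_roster(),
                            months = .default_month_labels,
                            n_perm = 10000, alpha = 0.05, seed = 1L,
                            out_dir = "ednadyn-out", quiet = FALSE) {
  structure(list(wells = wells, dilution_series = dilution_series,
                 species = species, months = months,
                 mc = list(n_perm = .check_count(n_perm, "n_perm"),
                           alpha = alpha, seed = as.integer(seed)),
                 out_dir = out_dir, quiet = isTRUE(quiet)),
            class = "pipeline_config")
}

#' Run the full inference pipeline
#'
#' Chains every stage: read the replicate wells, fit (or accept) a standard
#' curve per species, score site-month detections, encode transitions for
#' every consecutive month pair, run the Monte-Carlo permutation test per
#' pair, and write all artifacts (detections, detection matrix, transitions,
#' per-pair test TSVs, study summary) into `out_dir`. Every artifact carries
#' a provenance header with the config hash, seed and package version; a
#' rerun with the same config reproduces the outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted `curves`, `calls`, `matrix`,
#'   `transitions`, `tests`, `summary` and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!config$quiet) message(sprintf(...))
  wells <- if (is.character(config$wells)) read_wells(config$wells) else config$wells
  if (!nrow(wells)) stop("wells table is empty", call. = FALSE)
  roster <- config$species
  extra <- setdiff(unique(wells$species_id), roster$species_id)
  if (length(extra)) {
    stop(sprintf("species in wells but not in roster: %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }

  ds <- config$dilution_series
  curves <- if (inherits(ds, "standard_curve")) {
    ds
  } else {
    lapply(ds, function(d) {
      if (inherits(d, "standard_curve")) d
      else if (is.character(d)) fit_standard_curve(read_dilution_series(d))
      else fit_standard_curve(d)
    })
  }
  say("fitted %d standard curve(s)",
      if (inherits(curves, "standard_curve")) 1L else length(curves))

  months <- sort(unique(wells$month))
  roles <- stats::setNames(roster$role, roster$species_id)
  det <- call_detections(wells, curves, roles = roles, months = months)
  say("scored %d site-month-species detection calls", nrow(det$calls))

  prov <- c(config_hash = .config_hash(config), seed = config$mc$seed,
            package_version = as.character(utils::packageVersion("ednadyn")))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(detections = file.path(config$out_dir, "detections.csv"),
                matrix = file.path(config$out_dir, "detection_matrix.csv"),
                transitions = file.path(config$out_dir, "transitions.csv"),
                summary = file.path(config$out_dir, "summary.json"),
                config = file.path(config$out_dir, "config.json"))
  write_detections(det$calls, paths$detections, provenance = prov)
  write_detection_matrix(det$matrix, paths$matrix, provenance = prov)

  tabs <- list()
  tests <- list()
  for (t in months[-length(months)]) {
    if (!((t + 1L) %in% months)) next
    tt <- encode_transitions(det$matrix, c(t, t + 1L))
    lab <- attr(tt, "label")
    tabs[[lab]] <- tt
    # distinct sub-seed per month pair, one config seed
    tests[[lab]] <- cooc_test(tt, n_perm = config$mc$n_perm,
                              alpha = config$mc$alpha,
                              seed = config$mc$seed + match(t, months) - 1L)
    write_cooc_results(tests[[lab]],
                       file.path(config$out_dir, sprintf("mc_%s.tsv", gsub("[^A-Za-z0-9-]", "_", lab))),
                       provenance = prov)
    say("month pair %s: %d cells flagged", lab, sum(tests[[lab]]$direction != "none"))
  }
  write_transitions(tabs, paths$transitions, provenance = prov)

  summ <- summarize_study(det$matrix, wells = wells, curves = curves)
  sj <- summ[setdiff(names(summ), "sites")]
  sj$provenance <- as.list(prov)
  jsonlite::write_json(sj, paths$summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  .write_config_json(config, paths$config)

  invisible(list(curves = curves, calls = det$calls, matrix = det$matrix,
                 transitions = tabs, tests = tests, summary = summ,
                 paths = paths))
}

# Canonical JSON serialization of a config (paths kept, data frames hashed
# by content) and its md5 hash.
.config_json <- function(config) {
  # out_dir is deliberately excluded: the hash identifies the analysis
  # inputs and settings, not where artifacts land
  canon <- list(species = config$species, months = config$months, mc = config$mc,
                wells = if (is.character(config$wells)) config$wells else "<inline>")
  jsonlite::toJSON(canon, auto_unbox = TRUE, digits = NA)
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(.config_json(config)), tf)
  unname(tools::md5sum(tf))
}

.write_config_json <- function(config, path) {
  writeLines(as.character(jsonlite::prettify(.config_json(config))), path)
  invisible(path)
}
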