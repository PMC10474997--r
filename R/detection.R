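#' Score site-month detections from replicate qPCR wells
#'
#' Applies the replicate positivity rule: a replicate reaction counts as
#' positive when its back-calculated DNA quantity exceeds the assay's limit
#' of detection, and a site-month-species is scored detected when at least
#' `min_positive` (default 2) replicates are positive — two technical
#' replicates of one water sample or two different water samples both
#' qualify. The default `"pooled"` mode counts positives across all
#' replicates of the site-month; `"strict"` mode requires explicitly either
#' >= 2 positive technical replicates within one biological sample or >= 2
#' distinct biological samples with a positive (for the default threshold of
#' 2 the two modes coincide). Site-months with no wells at all are marked
#' missing (`NA`) in the returned matrix.
#'
#' @param wells A wells `data.frame` (see [read_wells()]).
#' @param curves A [standard_curve()] shared by all species, or a named list
#'   keyed by species id. Every curve must carry a finite LOD.
#' @param roles Optional species roles attached to the returned matrix.
#' @param sites,months Optional full site and month sets; site-months in
#'   the grid but absent from `wells` become `NA`. Defaults to the sites and
#'   months observed in `wells`.
#' @param rule `"pooled"` (default) or `"strict"`; see Details.
#' @param min_positive Minimum number of positive replicates (default 2).
#' @return A list with elements `calls` (a `data.frame` with columns
#'   `site_id, month, species_id, detected, n_positive_replicates, basis`)
#'   and `matrix` (a [detection_matrix()]).
#' @examples
#' curve <- standard_curve(-1.526, 41.232, lod = 0.01)
#' wells <- data.frame(site_id = "P01", month = 1, species_id = "A1",
#'                     bio_rep = 1, tech_rep = 1:3,
#'                     cq = c(35, 35.2, NA))
#' call_detections(wells, curve)$calls
#' @export
call_detections <- function(wells, curves, roles = NULL, sites = NULL,
                            months = NULL, rule = c("pooled", "strict"),
                            min_positive = 2L) {
  rule <- match.arg(rule)
  min_positive <- .check_count(min_positive, "min_positive")
  need <- c("site_id", "month", "species_id", "bio_rep", "tech_rep", "cq")
  stopifnot(all(need %in% names(wells)))
  sp <- sort(unique(wells$species_id))
  curves <- .curve_list(curves, sp)
  lods <- vapply(curves, function(cv) cv$lod, numeric(1))
  if (anyNA(lods) || any(!is.finite(lods))) {
    stop(sprintf("curve(s) without a defined LOD for species: %s",
                 paste(sp[!is.finite(lods)], collapse = ", ")), call. = FALSE)
  }

  q <- rep(NA_real_, nrow(wells))
  for (s in sp) {
    i <- wells$species_id == s
    q[i] <- quantify_cq(curves[[s]], wells$cq[i])
  }
  positive <- !is.na(q) & q > lods[wells$species_id]

  key <- interaction(wells$site_id, wells$month, wells$species_id, drop = TRUE)
  first <- !duplicated(key)
  n_pos <- as.integer(tapply(positive, key, sum)[as.character(key[first])])
  # per biological sample: number of positive techs
  bio_key <- interaction(key, wells$bio_rep, drop = TRUE)
  pos_by_bio <- tapply(positive, bio_key, sum)
  parent <- tapply(as.character(key), bio_key, `[`, 1L)
  tech_ok <- tapply(pos_by_bio >= min_positive, parent, any)[as.character(key[first])]
  n_bio_pos <- tapply(pos_by_bio >= 1L, parent, sum)[as.character(key[first])]
  bio_ok <- n_bio_pos >= min_positive

  detected <- if (rule == "pooled") n_pos >= min_positive else (tech_ok | bio_ok)
  basis <- ifelse(tech_ok & bio_ok, "both",
                  ifelse(tech_ok, "technical",
                         ifelse(bio_ok, "biological", "none")))

  calls <- data.frame(site_id = wells$site_id[first],
                      month = as.integer(wells$month[first]),
                      species_id = wells$species_id[first],
                      detected = as.logical(detected),
                      n_positive_replicates = n_pos,
                      basis = as.character(basis), stringsAsFactors = FALSE)
  calls <- calls[order(calls$site_id, calls$month, calls$species_id), , drop = FALSE]
  rownames(calls) <- NULL

  sites <- sites %||% sort(unique(calls$site_id))
  months <- sort(unique(as.integer(months %||% calls$month)))
  arr <- array(NA_integer_, dim = c(length(sp), length(sites), length(months)),
               dimnames = list(sp, sites, as.character(months)))
  arr[cbind(match(calls$species_id, sp), match(calls$site_id, sites),
            match(calls$month, months))] <- as.integer(calls$detected)
  list(calls = calls, matrix = detection_matrix(arr, roles = roles))
}
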