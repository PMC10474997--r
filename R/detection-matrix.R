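#' Species x site x month detection matrix
#'
#' The central container of the pipeline: a 3-d array of presence/absence
#' states (`1` = detected/present, `0` = not, `NA` = site-month not sampled)
#' indexed by species, site and month ordinal, with the species roles
#' attached. Missingness is per site-month: if a pond was not sampled in a
#' month, all species carry `NA` there.
#'
#' @param states A 3-d array `[species, site, month]` of 0/1/NA, with
#'   dimnames giving species ids, site ids and month ordinals.
#' @param roles Named character vector mapping `species_id` to
#'   `"prey"`/`"predator"`, or a [species_roster()] data frame. Optional.
#' @return An object of class `detection_matrix`.
#' @export
detection_matrix <- function(states, roles = NULL) {
  if (!is.array(states) || length(dim(states)) != 3L) {
    stop("`states` must be a 3-d array [species, site, month]", call. = FALSE)
  }
  if (is.null(dimnames(states)) || any(vapply(dimnames(states), is.null, logical(1)))) {
    stop("`states` must carry dimnames: species ids, site ids, months", call. = FALSE)
  }
  vals <- states[!is.na(states)]
  if (length(vals) && !all(vals %in% c(0, 1))) {
    stop("states must be 0, 1 or NA", call. = FALSE)
  }
  storage.mode(states) <- "integer"
  if (is.data.frame(roles)) roles <- stats::setNames(roles$role, roles$species_id)
  if (!is.null(roles)) {
    miss <- setdiff(dimnames(states)[[1L]], names(roles))
    if (length(miss)) {
      stop(sprintf("roles missing for species: %s", paste(miss, collapse = ", ")),
           call. = FALSE)
    }
    roles <- roles[dimnames(states)[[1L]]]
  }
  structure(states, roles = roles, class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("detection_matrix: %d species x %d sites x %d months\n",
              d[1L], d[2L], d[3L]))
  occ <- apply(x, c(1L, 3L), function(v) mean(v, na.rm = TRUE))
  cat("occupancy by month (fraction of sampled sites):\n")
  print(round(occ, 3))
  n_missing <- sum(apply(is.na(unclass(x)), c(2L, 3L), all))
  cat(sprintf("unsampled site-months: %d\n", n_missing))
  invisible(x)
}

#' @export
as.data.frame.detection_matrix <- function(x, ...) {
  dn <- dimnames(x)
  out <- expand.grid(species_id = dn[[1L]], site_id = dn[[2L]],
                     month = dn[[3L]], KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$month <- as.integer(out$month)
  out$state <- as.integer(unclass(x))
  out[order(out$species_id, out$site_id, out$month), , drop = FALSE]
}

# Build a detection_matrix from a long data.frame (species_id, site_id,
# month, state), erroring on duplicates.
.dm_from_long <- function(df, roles = NULL, path = "<data>") {
  key <- paste(df$species_id, df$site_id, df$month, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    .parse_error(path, i + 1L,
                 sprintf("duplicate (species, site, month) key: %s/%s/%s",
                         df$species_id[i], df$site_id[i], df$month[i]))
  }
  sp <- unique(df$species_id)
  sites <- unique(df$site_id)
  months <- sort(unique(as.integer(df$month)))
  arr <- array(NA_integer_, dim = c(length(sp), length(sites), length(months)),
               dimnames = list(sp, sites, as.character(months)))
  idx <- cbind(match(df$species_id, sp), match(df$site_id, sites),
               match(as.integer(df$month), months))
  arr[idx] <- as.integer(df$state)
  detection_matrix(arr, roles = roles)
}

#' Read / write a detection matrix CSV
#'
#' The schema is long-format CSV with header
#' `species_id,site_id,month,state`, `state` in `{0, 1, NA}` (`NA` marks an
#' unsampled site-month and is never coerced to 0). Duplicate
#' (species, site, month) keys and unknown state tokens are parse errors
#' naming the offending line. Lines starting with `#` (provenance headers)
#' are ignored on read. The writer and reader round-trip exactly.
#'
#' @param path File path.
#' @param roles Optional roles (see [detection_matrix()]).
#' @return `read_detection_matrix()` returns a `detection_matrix`;
#'   `write_detection_matrix()` returns `path` invisibly.
#' @export
read_detection_matrix <- function(path, roles = NULL) {
  df <- .read_table_checked(path, sep = ",",
                            cols = c("species_id", "site_id", "month", "state"))
  bad <- !(df$state %in% c("0", "1", "NA", NA))
  if (any(bad)) {
    .parse_error(path, which(bad)[1L] + 1L,
                 sprintf("unknown state token '%s' (expected 0, 1 or NA)",
                         df$state[which(bad)[1L]]))
  }
  df$state <- suppressWarnings(as.integer(df$state))
  df$month <- month_ordinal(df$month)
  .dm_from_long(df, roles = roles, path = path)
}

#' @param x A `detection_matrix`.
#' @param provenance Optional named character vector written as `# key=value`
#'   header lines.
#' @rdname read_detection_matrix
#' @export
write_detection_matrix <- function(x, path, provenance = NULL) {
  stopifnot(inherits(x, "detection_matrix"))
  df <- as.data.frame(x)
  df$state <- ifelse(is.na(df$state), "NA", as.character(df$state))
  .write_table_headed(df, path, sep = ",", provenance = provenance)
}
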