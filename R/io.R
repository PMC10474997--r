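# Readers and writers for the tabular schemas. All writers can prepend
# provenance comment lines ("# key=value"); all readers skip them.

.write_table_headed <- function(df, path, sep = ",", provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(provenance)) {
    writeLines(sprintf("# %s=%s", names(provenance), as.character(provenance)), con)
  }
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# read.csv wrapper that checks the header and reports located errors.
.read_table_checked <- function(path, sep = ",", cols) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                      colClasses = "character", stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) .parse_error(path, 1L, conditionMessage(e)))
  if (nrow(df) == 0L) .parse_error(path, 1L, "file contains no data rows")
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    .parse_error(path, 1L, sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  df[cols]
}

.as_int_col <- function(df, col, path, min = NULL) {
  v <- suppressWarnings(as.integer(df[[col]]))
  bad <- is.na(v) & !(is.na(df[[col]]) | df[[col]] == "")
  if (!is.null(min)) bad <- bad | (!is.na(v) & v < min)
  if (any(bad)) {
    .parse_error(path, which(bad)[1L] + 1L,
                 sprintf("invalid value '%s' in column '%s'", df[[col]][which(bad)[1L]], col))
  }
  v
}

#' Read / write a replicate-level qPCR wells table
#'
#' Schema: CSV with header `site_id,month,species_id,bio_rep,tech_rep,cq`.
#' An empty `cq` field means no amplification (stored as `NA`); a present Cq
#' must lie in `(0, 50]`, matching a 50-cycle protocol. Month tokens may be
#' ordinals or month names.
#'
#' @param path File path.
#' @return `read_wells()` returns a `data.frame` with typed columns;
#'   `write_wells()` returns `path` invisibly.
#' @export
read_wells <- function(path) {
  cols <- c("site_id", "month", "species_id", "bio_rep", "tech_rep", "cq")
  df <- .read_table_checked(path, sep = ",", cols = cols)
  out <- data.frame(site_id = df$site_id,
                    month = month_ordinal(df$month),
                    species_id = df$species_id,
                    bio_rep = .as_int_col(df, "bio_rep", path, min = 1L),
                    tech_rep = .as_int_col(df, "tech_rep", path, min = 1L),
                    cq = NA_real_, stringsAsFactors = FALSE)
  has_cq <- !(is.na(df$cq) | df$cq == "")
  cq <- suppressWarnings(as.numeric(df$cq[has_cq]))
  bad <- is.na(cq) | cq <= 0 | cq > 50
  if (any(bad)) {
    .parse_error(path, which(has_cq)[which(bad)[1L]] + 1L,
                 sprintf("invalid Cq '%s' (must be in (0, 50] or empty)",
                         df$cq[has_cq][which(bad)[1L]]))
  }
  out$cq[has_cq] <- cq
  out
}

#' @param wells A wells `data.frame`.
#' @param provenance Optional named vector of `# key=value` header lines.
#' @rdname read_wells
#' @export
write_wells <- function(wells, path, provenance = NULL) {
  cols <- c("site_id", "month", "species_id", "bio_rep", "tech_rep", "cq")
  stopifnot(all(cols %in% names(wells)))
  .write_table_headed(wells[cols], path, sep = ",", provenance = provenance)
}

#' Read / write a dilution-series table
#'
#' Schema: CSV with header `concentration,rep,cq`; empty `cq` = no
#' amplification.
#'
#' @param path File path.
#' @return `read_dilution_series()` returns a [dilution_series()].
#' @export
read_dilution_series <- function(path) {
  df <- .read_table_checked(path, sep = ",", cols = c("concentration", "rep", "cq"))
  conc <- suppressWarnings(as.numeric(df$concentration))
  if (anyNA(conc)) {
    .parse_error(path, which(is.na(conc))[1L] + 1L, "invalid concentration")
  }
  cq <- suppressWarnings(as.numeric(ifelse(df$cq == "", NA, df$cq)))
  dilution_series(data.frame(concentration = conc,
                             rep = .as_int_col(df, "rep", path, min = 1L),
                             cq = cq, stringsAsFactors = FALSE))
}

#' @param series A dilution-series `data.frame`.
#' @rdname read_dilution_series
#' @export
write_dilution_series <- function(series, path, provenance = NULL) {
  .write_table_headed(series[c("concentration", "rep", "cq")], path, sep = ",",
                      provenance = provenance)
}

#' Write site-month detection calls
#'
#' Schema: CSV `site_id,month,species_id,detected,n_positive_replicates`
#' (plus the `basis` column recording whether the positives came from
#' biological replicates, technical replicates, or both).
#'
#' @param calls The calls `data.frame` from [call_detections()].
#' @param path File path.
#' @param provenance Optional named vector of header lines.
#' @export
write_detections <- function(calls, path, provenance = NULL) {
  cols <- c("site_id", "month", "species_id", "detected",
            "n_positive_replicates", "basis")
  .write_table_headed(calls[cols], path, sep = ",", provenance = provenance)
}

#' Read / write transition tables
#'
#' Schema: CSV `month_pair,site_id,species_id,state` with state one of
#' `--`, `++`, `-+`, `+-`. A file may hold several month pairs; the reader
#' returns a named list of [transition_table()] objects.
#'
#' @param path File path.
#' @return `read_transitions()` returns a named list of `transition_table`s.
#' @export
read_transitions <- function(path) {
  df <- .read_table_checked(path, sep = ",",
                            cols = c("month_pair", "site_id", "species_id", "state"))
  bad <- !(df$state %in% TRANSITION_CODES)
  if (any(bad)) {
    .parse_error(path, which(bad)[1L] + 1L,
                 sprintf("unknown transition state '%s'", df$state[which(bad)[1L]]))
  }
  out <- lapply(split(df, df$month_pair), function(d) {
    sites <- unique(d$site_id); sp <- unique(d$species_id)
    m <- matrix(NA_character_, length(sites), length(sp),
                dimnames = list(sites, sp))
    m[cbind(match(d$site_id, sites), match(d$species_id, sp))] <- d$state
    if (anyNA(m)) {
      .parse_error(path, 1L, sprintf(
        "month pair %s: missing state for some (site, species) combinations",
        d$month_pair[1L]))
    }
    pair <- suppressWarnings(as.integer(strsplit(d$month_pair[1L], "-", fixed = TRUE)[[1L]]))
    transition_table(m, month_pair = if (anyNA(pair)) c(NA_integer_, NA_integer_) else pair,
                     label = d$month_pair[1L])
  })
  out[order(names(out))]
}

#' @param tables A `transition_table` or list of them.
#' @rdname read_transitions
#' @export
write_transitions <- function(tables, path, provenance = NULL) {
  if (inherits(tables, "transition_table")) tables <- list(tables)
  rows <- lapply(tables, function(tt) {
    data.frame(month_pair = attr(tt, "label"),
               site_id = rep(rownames(tt), times = ncol(tt)),
               species_id = rep(colnames(tt), each = nrow(tt)),
               state = as.vector(tt), stringsAsFactors = FALSE)
  })
  .write_table_headed(do.call(rbind, rows), path, sep = ",", provenance = provenance)
}
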