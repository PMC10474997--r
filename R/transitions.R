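#' Construct a transition table
#'
#' A transition table records, for one pair of consecutive months, each
#' species' transition state at each site: `--` (stay zero), `++` (persist),
#' `-+` (enter), `+-` (disappear). Usually built from a detection matrix via
#' [encode_transitions()]; this constructor validates a site x species
#' character matrix built directly (e.g. for worked examples).
#'
#' @param states A character matrix, sites in rows, species in columns,
#'   entries drawn from `--`, `++`, `-+`, `+-`.
#' @param month_pair Integer vector `c(t, t + 1)` labelling the pair.
#' @param label Optional display label (default `"t-(t+1)"`).
#' @return An object of class `transition_table`.
#' @examples
#' m <- cbind(A = c("++", "++", "--"), B = c("+-", "--", "-+"))
#' rownames(m) <- paste0("P", 1:3)
#' transition_table(m, month_pair = c(1, 2))
#' @export
transition_table <- function(states, month_pair = c(1L, 2L), label = NULL) {
  if (!is.matrix(states) || !is.character(states)) {
    stop("`states` must be a character matrix (sites x species)", call. = FALSE)
  }
  bad <- setdiff(unique(as.vector(states)), TRANSITION_CODES)
  if (length(bad)) {
    stop(sprintf("unknown transition state(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(colnames(states))) stop("`states` needs species column names", call. = FALSE)
  if (is.null(rownames(states))) rownames(states) <- sprintf("S%03d", seq_len(nrow(states)))
  structure(states, month_pair = as.integer(month_pair),
            label = label %||% paste(month_pair, collapse = "-"),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("transition_table (months %s): %d sites x %d species\n",
              attr(x, "label"), nrow(x), ncol(x)))
  tab <- apply(unclass(x), 2L, function(v) table(factor(v, TRANSITION_CODES)))
  print(t(tab))
  invisible(x)
}

#' Encode month-to-month transitions from a detection matrix
#'
#' For a pair of consecutive months, maps each species' states at each site
#' to one of the four transition codes: (0,0) stay zero `--`, (1,1) persist
#' `++`, (0,1) enter `-+`, (1,0) disappear `+-`. Sites with a missing state
#' in either month of the pair are dropped for all species (complete-pair
#' analysis), keeping every species on a common site set.
#'
#' @param x A [detection_matrix()].
#' @param month_pair The first month `t` of the pair, or `c(t, t + 1)`;
#'   month names are accepted (May = 1, June = 2, July = 3). Only
#'   consecutive pairs are legal.
#' @return A [transition_table()].
#' @examples
#' ds <- make_scenario("null_model", seed = 1)
#' encode_transitions(ds$truth, c(1, 2))
#' @export
encode_transitions <- function(x, month_pair) {
  stopifnot(inherits(x, "detection_matrix"))
  mp <- month_ordinal(month_pair)
  if (length(mp) == 1L) mp <- c(mp, mp + 1L)
  if (length(mp) != 2L || mp[2L] != mp[1L] + 1L) {
    stop("`month_pair` must name two consecutive months", call. = FALSE)
  }
  months <- dimnames(x)[[3L]]
  if (!all(as.character(mp) %in% months)) {
    stop(sprintf("months %s not both present in the matrix",
                 paste(mp, collapse = "-")), call. = FALSE)
  }
  m1 <- t(x[, , as.character(mp[1L]), drop = TRUE])
  m2 <- t(x[, , as.character(mp[2L]), drop = TRUE])
  if (dim(x)[1L] == 1L) {  # single species: drop = TRUE collapsed a dimension
    m1 <- matrix(x[, , as.character(mp[1L])], ncol = 1L,
                 dimnames = list(dimnames(x)[[2L]], dimnames(x)[[1L]]))
    m2 <- matrix(x[, , as.character(mp[2L])], ncol = 1L,
                 dimnames = list(dimnames(x)[[2L]], dimnames(x)[[1L]]))
  }
  keep <- !apply(is.na(m1) | is.na(m2), 1L, any)
  m1 <- m1[keep, , drop = FALSE]; m2 <- m2[keep, , drop = FALSE]
  codes <- matrix(.transition_lookup[2L * m1 + m2 + 1L], nrow(m1),
                  dimnames = dimnames(m1))
  lab <- paste(month_label(mp), collapse = "-")
  transition_table(codes, month_pair = mp, label = lab)
}

# Event keys for a table: every species crossed with the four codes,
# labelled "SPECIES:STATE".
.event_keys <- function(species) {
  data.frame(species_id = rep(species, each = length(TRANSITION_CODES)),
             state = rep(TRANSITION_CODES, length(species)),
             label = paste(rep(species, each = length(TRANSITION_CODES)),
                           rep(TRANSITION_CODES, length(species)), sep = ":"),
             stringsAsFactors = FALSE)
}

# Sites x events indicator matrix for a transition table.
.event_indicator <- function(table) {
  species <- colnames(table)
  ev <- .event_keys(species)
  E <- matrix(0L, nrow(table), nrow(ev), dimnames = list(rownames(table), ev$label))
  for (k in seq_len(nrow(ev))) {
    E[, k] <- (table[, ev$species_id[k]] == ev$state[k]) * 1L
  }
  E
}

#' Row-conditional co-occurrence matrix of transition events
#'
#' For every ordered pair of events (a species with one of the four
#' transition states), counts the sites at which the row event was
#' accompanied by the column event in the same month pair, and divides by
#' the number of sites showing the row event. The matrix is row-conditional
#' and therefore not symmetric; rows whose event never occurred are
#' undefined (`NA`), never 0. Same-species diagonal cells equal 1 whenever
#' their row event occurred.
#'
#' @param table A [transition_table()].
#' @return An object of class `cooc_matrix`: list with `proportions`
#'   (events x events, `NA` rows where the row event is absent),
#'   `joint_counts`, `row_counts`, `events` and the month-pair label.
#' @examples
#' m <- cbind(A = rep("++", 4), B = c("+-", "+-", "--", "--"))
#' rownames(m) <- paste0("P", 1:4)
#' cm <- cooccurrence_matrix(transition_table(m))
#' cm$proportions["A:++", "B:+-"]  # 0.5
#' @export
cooccurrence_matrix <- function(table) {
  stopifnot(inherits(table, "transition_table"))
  if (nrow(table) == 0L) stop("transition table is empty", call. = FALSE)
  E <- .event_indicator(table)
  joint <- crossprod(E)
  storage.mode(joint) <- "integer"
  row_counts <- diag(joint)
  prop <- sweep(joint, 1L, row_counts, `/`)
  prop[row_counts == 0L, ] <- NA_real_
  structure(list(proportions = prop, joint_counts = joint,
                 row_counts = row_counts, events = .event_keys(colnames(table)),
                 month_pair = attr(table, "month_pair"),
                 label = attr(table, "label")),
            class = "cooc_matrix")
}

#' @export
print.cooc_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("cooc_matrix (months %s): %d events, row-conditional proportions\n",
              x$label, nrow(x$proportions)))
  print(round(x$proportions, digits))
  invisible(x)
}

#' Site-level detection summary by trophic guild
#'
#' Pools months per site (a species detected in any sampled month counts as
#' present) and summarizes which sites held any target species, prey only,
#' fish only, or a predator-prey co-occurrence.
#'
#' @param x A [detection_matrix()].
#' @param roles Named character vector of species roles; defaults to the
#'   roles attached to `x`.
#' @return A `data.frame` with one row per site and logical columns
#'   `any_target`, `prey_any`, `prey_only`, `fish_any`, `fish_only`,
#'   `cooccur`.
#' @seealso [summarize_study()] for the study-level fractions.
#' @export
summarize_sites <- function(x, roles = NULL) {
  stopifnot(inherits(x, "detection_matrix"))
  roles <- roles %||% attr(x, "roles")
  if (is.null(roles)) stop("species roles are required", call. = FALSE)
  sp <- dimnames(x)[[1L]]
  miss <- setdiff(sp, names(roles))
  if (length(miss)) {
    stop(sprintf("roles missing for species: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  pooled <- apply(unclass(x), c(1L, 2L), function(v) {
    if (all(is.na(v))) NA_integer_ else as.integer(any(v == 1L, na.rm = TRUE))
  })
  prey <- roles[sp] == "prey"
  prey_any <- apply(pooled[prey, , drop = FALSE], 2L, function(v) any(v == 1L, na.rm = TRUE))
  fish_any <- apply(pooled[!prey, , drop = FALSE], 2L, function(v) any(v == 1L, na.rm = TRUE))
  data.frame(site_id = dimnames(x)[[2L]],
             any_target = prey_any | fish_any,
             prey_any = prey_any, prey_only = prey_any & !fish_any,
             fish_any = fish_any, fish_only = fish_any & !prey_any,
             cooccur = prey_any & fish_any,
             row.names = NULL, stringsAsFactors = FALSE)
}
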