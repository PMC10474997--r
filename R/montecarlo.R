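#' Permute a transition table across sites, per species
#'
#' Draws one permutation-null realisation: for each species independently,
#' the multiset of transition states is kept but its assignment to sites is
#' uniformly shuffled, breaking cross-species association while preserving
#' each species' transition frequencies. Uses the current RNG stream.
#'
#' @param table A [transition_table()].
#' @return A `transition_table` with the same attributes and per-species
#'   state frequencies.
#' @export
permute_transitions <- function(table) {
  stopifnot(inherits(table, "transition_table"))
  n <- nrow(table)
  out <- table
  for (j in seq_len(ncol(table))) {
    out[, j] <- table[sample.int(n), j]
  }
  out
}

#' Monte-Carlo permutation test of transition co-occurrence
#'
#' Tests whether transition events of different species co-occur across
#' sites more or less often than expected by chance. The empirical
#' row-conditional co-occurrence matrix (see [cooccurrence_matrix()]) is
#' contrasted with a null distribution obtained by repeatedly permuting each
#' species' transitions across sites ([permute_transitions()]) and
#' recomputing the matrix. The null preserves each species' transition-type
#' frequencies (and hence the temporal autocorrelation summarized by them)
#' while breaking cross-species association.
#'
#' P-values use the add-one convention, `p = (1 + #extreme) / (1 + B)`, with
#' ties counted as extreme, so they are never zero; the two-sided p doubles
#' the smaller tail (capped at 1). A cell is directional at level `alpha`:
#' `"more_than_expected"` when the empirical proportion sits in the upper
#' tail, `"less_than_expected"` in the lower. By default only cross-species
#' cells are tested; same-species cells (whose null is degenerate given the
#' per-species frequencies) are reported descriptively with `NA` p-values.
#' Cells whose row event never occurs empirically carry no summary.
#'
#' @param table A [transition_table()] with >= 2 species and >= 2 sites.
#' @param n_perm Number of permutations (default 10000).
#' @param alpha Significance level for the direction call (default 0.05).
#' @param scope `"cross_species_only"` (default) or `"all_cells"`.
#' @param tail Which p-value drives the direction call: `"two_sided"`
#'   (default), `"one_sided_upper"` or `"one_sided_lower"`. All three
#'   p-values are always reported.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return An object of class `cooc_test`: list with the empirical
#'   `cooc_matrix`, event-by-event matrices `null_mean`, `null_sd`,
#'   `p_upper`, `p_lower`, `p_two_sided`, the `direction` character matrix
#'   (`more_than_expected` / `less_than_expected` / `none`), the logical
#'   `tested` matrix, and the `config` snapshot.
#' @examples
#' ds <- make_scenario("strong_avoidance", seed = 1)
#' tt <- encode_transitions(ds$truth, c(1, 2))
#' res <- cooc_test(tt, n_perm = 500, seed = 1)
#' res
#' @export
cooc_test <- function(table, n_perm = 10000, alpha = 0.05,
                      scope = c("cross_species_only", "all_cells"),
                      tail = c("two_sided", "one_sided_upper", "one_sided_lower"),
                      seed = NULL) {
  stopifnot(inherits(table, "transition_table"))
  scope <- match.arg(scope)
  tail <- match.arg(tail)
  n_perm <- .check_count(n_perm, "n_perm")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (ncol(table) < 2L) stop("need >= 2 species to test co-occurrence", call. = FALSE)
  if (nrow(table) < 2L) stop("need >= 2 sites to permute", call. = FALSE)

  emp <- cooccurrence_matrix(table)
  ev <- emp$events
  K <- nrow(ev)
  row_counts <- emp$row_counts
  defined <- row_counts > 0L
  if (any(!defined)) {
    message(sprintf("cooc_test: %d event row(s) absent empirically, skipped: %s",
                    sum(!defined), paste(ev$label[!defined], collapse = ", ")))
  }

  E0 <- .event_indicator(table)
  n <- nrow(E0)
  S <- ncol(table)
  blocks <- lapply(seq_len(S), function(s) ((s - 1L) * 4L + 1L):(s * 4L))
  emp_p <- emp$proportions

  cnt_ge <- cnt_le <- acc <- acc2 <- matrix(0, K, K)
  with_seed(seed, {
    E <- E0
    for (b in seq_len(n_perm)) {
      for (s in seq_len(S)) {
        E[, blocks[[s]]] <- E0[sample.int(n), blocks[[s]]]
      }
      prop <- sweep(crossprod(E), 1L, row_counts, `/`)
      prop[!defined, ] <- 0  # excluded below; keep arithmetic NA-free
      cnt_ge <- cnt_ge + (prop >= emp_p & !is.na(emp_p))
      cnt_le <- cnt_le + (prop <= emp_p & !is.na(emp_p))
      acc <- acc + prop
      acc2 <- acc2 + prop^2
    }
  })

  p_upper <- (1 + cnt_ge) / (1 + n_perm)
  p_lower <- (1 + cnt_le) / (1 + n_perm)
  null_mean <- acc / n_perm
  null_sd <- sqrt(pmax((acc2 - n_perm * null_mean^2) / max(1, n_perm - 1), 0))
  p_two <- pmin(2 * pmin(p_upper, p_lower), 1)  # matrix first so dims survive pmin

  same_species <- outer(ev$species_id, ev$species_id, `==`)
  tested <- !is.na(emp_p)
  if (scope == "cross_species_only") tested <- tested & !same_species
  for (m in c("p_upper", "p_lower", "p_two", "null_mean", "null_sd")) {
    v <- get(m); v[!defined, ] <- NA_real_; assign(m, v)
  }
  p_upper[!tested] <- NA_real_; p_lower[!tested] <- NA_real_; p_two[!tested] <- NA_real_

  direction <- matrix("none", K, K, dimnames = dimnames(emp_p))
  p_sig <- switch(tail, two_sided = p_two, one_sided_upper = p_upper,
                  one_sided_lower = p_lower)
  sig <- tested & !is.na(p_sig) & p_sig <= alpha
  if (tail == "two_sided") {
    direction[sig & p_upper < p_lower] <- "more_than_expected"
    direction[sig & p_lower < p_upper] <- "less_than_expected"
  } else if (tail == "one_sided_upper") {
    direction[sig] <- "more_than_expected"
  } else {
    direction[sig] <- "less_than_expected"
  }
  dimnames(null_mean) <- dimnames(null_sd) <- dimnames(p_upper) <-
    dimnames(p_lower) <- dimnames(p_two) <- dimnames(tested) <- dimnames(emp_p)

  structure(list(empirical = emp, null_mean = null_mean, null_sd = null_sd,
                 p_upper = p_upper, p_lower = p_lower, p_two_sided = p_two,
                 direction = direction, tested = tested,
                 month_pair = emp$month_pair, label = emp$label,
                 config = list(n_perm = n_perm, alpha = alpha, scope = scope,
                               tail = tail, seed = seed)),
            class = "cooc_test")
}

#' @export
print.cooc_test <- function(x, ...) {
  n_more <- sum(x$direction == "more_than_expected")
  n_less <- sum(x$direction == "less_than_expected")
  cat(sprintf("Monte-Carlo co-occurrence test (months %s)\n", x$label))
  cat(sprintf("  %d permutations, alpha = %g, scope = %s\n",
              x$config$n_perm, x$config$alpha, x$config$scope))
  cat(sprintf("  %d cell(s) more than expected, %d less than expected\n",
              n_more, n_less))
  sig <- which(x$direction != "none", arr.ind = TRUE)
  if (nrow(sig)) {
    lab <- rownames(x$direction)
    for (i in seq_len(nrow(sig))) {
      r <- sig[i, 1L]; c <- sig[i, 2L]
      cat(sprintf("    [%s | %s] empirical %.3f vs null %.3f (p = %.4f, %s)\n",
                  lab[c], lab[r], x$empirical$proportions[r, c],
                  x$null_mean[r, c], x$p_two_sided[r, c], x$direction[r, c]))
    }
  }
  invisible(x)
}

#' Tabulate a Monte-Carlo co-occurrence test
#'
#' Flattens a [cooc_test()] into one row per (row event, column event) cell
#' with the empirical proportion, null mean/sd, p-values and direction —
#' the layout written by [write_cooc_results()].
#'
#' @param x A `cooc_test`.
#' @param ... Unused.
#' @return A `data.frame` with columns `month_pair, row_species, row_state,
#'   col_species, col_state, empirical, null_mean, null_sd, p_upper,
#'   p_lower, p_two_sided, direction`.
#' @export
as.data.frame.cooc_test <- function(x, ...) {
  ev <- x$empirical$events
  K <- nrow(ev)
  ri <- rep(seq_len(K), times = K)
  ci <- rep(seq_len(K), each = K)
  out <- data.frame(month_pair = x$label,
                    row_species = ev$species_id[ri], row_state = ev$state[ri],
                    col_species = ev$species_id[ci], col_state = ev$state[ci],
                    empirical = x$empirical$proportions[cbind(ri, ci)],
                    null_mean = x$null_mean[cbind(ri, ci)],
                    null_sd = x$null_sd[cbind(ri, ci)],
                    p_upper = x$p_upper[cbind(ri, ci)],
                    p_lower = x$p_lower[cbind(ri, ci)],
                    p_two_sided = x$p_two_sided[cbind(ri, ci)],
                    direction = x$direction[cbind(ri, ci)],
                    stringsAsFactors = FALSE)
  out[order(out$row_species, out$row_state, out$col_species, out$col_state), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' @export
summary.cooc_test <- function(object, ...) {
  df <- as.data.frame(object)
  df[!is.na(df$empirical), , drop = FALSE]
}

#' @param path Output TSV path.
#' @param provenance Optional named vector of `# key=value` header lines.
#' @rdname as.data.frame.cooc_test
#' @export
write_cooc_results <- function(x, path, provenance = NULL) {
  .write_table_headed(as.data.frame(x), path, sep = "\t", provenance = provenance)
}

#' Dot-matrix plot of a co-occurrence test
#'
#' Draws the event-by-event matrix as a dot grid: dot area scales with the
#' empirical row-conditional proportion; blue marks cells where the event
#' pair co-occurred more often than expected by chance, red less often,
#' grey no evidence either way.
#'
#' @param x A [cooc_test()].
#' @param cex_max Radius scale of a proportion-1 dot.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cooc_test <- function(x, cex_max = 3, ...) {
  p <- x$empirical$proportions
  K <- nrow(p)
  lab <- rownames(p)
  cols <- c(more_than_expected = "#2166ac", less_than_expected = "#b2182b",
            none = "grey60")
  op <- graphics::par(mar = c(1, 6, 6, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(0.5, K + 0.5), ylim = c(K + 0.5, 0.5),
                 axes = FALSE, xlab = "", ylab = "", asp = 1,
                 main = sprintf("Transition co-occurrence, months %s", x$label), ...)
  graphics::axis(3, at = seq_len(K), labels = lab, las = 2, cex.axis = 0.7, tick = FALSE)
  graphics::axis(2, at = seq_len(K), labels = lab, las = 2, cex.axis = 0.7, tick = FALSE)
  for (r in seq_len(K)) for (c in seq_len(K)) {
    if (is.na(p[r, c])) next
    graphics::points(c, r, pch = 16, cex = cex_max * sqrt(p[r, c]),
                     col = cols[[x$direction[r, c]]])
  }
  invisible(x)
}
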