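# Independent oracles and fixture builders used across the suite.

# All permutations of 1..n as an (n! x n) matrix, by recursive insertion.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], n, after = pos - 1L)
    }
  }
  out
}

# Brute-force row-conditional co-occurrence proportions by exhaustive
# site-by-site tabulation (independent of the crossprod implementation).
brute_cooc <- function(states) {
  codes <- c("--", "++", "-+", "+-")
  sp <- colnames(states)
  ev <- expand.grid(state = codes, species = sp, stringsAsFactors = FALSE)[, 2:1]
  lab <- paste(ev$species, ev$state, sep = ":")
  K <- nrow(ev)
  joint <- matrix(0L, K, K, dimnames = list(lab, lab))
  for (r in seq_len(K)) for (c in seq_len(K)) {
    for (site in seq_len(nrow(states))) {
      joint[r, c] <- joint[r, c] +
        (states[site, ev$species[r]] == ev$state[r] &&
         states[site, ev$species[c]] == ev$state[c])
    }
  }
  rc <- diag(joint)
  prop <- matrix(NA_real_, K, K, dimnames = list(lab, lab))
  for (r in seq_len(K)) if (rc[r] > 0) prop[r, ] <- joint[r, ] / rc[r]
  list(proportions = prop, joint_counts = joint, row_counts = rc)
}

# Exact permutation null for a two-species transition table: enumerate all
# joint site-assignments (n! x n!) and return, per cell, tie-inclusive
# exact tail probabilities and the null mean of the proportion.
exact_two_species_null <- function(states) {
  stopifnot(ncol(states) == 2L)
  n <- nrow(states)
  perms <- all_perms(n)
  emp <- brute_cooc(states)$proportions
  K <- nrow(emp)
  p_up <- p_lo <- nmean <- matrix(0, K, K, dimnames = dimnames(emp))
  total <- 0L
  st <- states
  for (i in seq_len(nrow(perms))) {
    st[, 1L] <- states[perms[i, ], 1L]
    for (j in seq_len(nrow(perms))) {
      st[, 2L] <- states[perms[j, ], 2L]
      pr <- brute_cooc(st)$proportions
      total <- total + 1L
      ge <- pr >= emp; le <- pr <= emp
      ge[is.na(ge)] <- FALSE; le[is.na(le)] <- FALSE
      p_up <- p_up + ge
      p_lo <- p_lo + le
      pr[is.na(pr)] <- 0
      nmean <- nmean + pr
    }
  }
  list(p_upper = p_up / total, p_lower = p_lo / total,
       null_mean = nmean / total, empirical = emp, n_assignments = total)
}

# Dilution series generated exactly on the assay line Cq = a*ln(x) + b,
# optionally with per-level replicate detection counts.
exact_series <- function(slope = -1.526, intercept = 41.232,
                         conc = 50 / 3^(0:7), n_rep = 20, detected = NULL) {
  rows <- do.call(rbind, lapply(seq_along(conc), function(i) {
    n_det <- if (is.null(detected)) n_rep else detected[i]
    cq <- rep(NA_real_, n_rep)
    if (n_det > 0) cq[seq_len(n_det)] <- slope * log(conc[i]) + intercept
    data.frame(concentration = conc[i], rep = seq_len(n_rep), cq = cq)
  }))
  dilution_series(rows)
}

# Small detection matrix from per-species site x month state matrices.
dm_build <- function(..., roles = NULL) {
  mats <- list(...)
  sp <- names(mats)
  arr <- array(NA_integer_, dim = c(length(sp), nrow(mats[[1]]), ncol(mats[[1]])),
               dimnames = list(sp, rownames(mats[[1]]),
                               colnames(mats[[1]]) %||% as.character(seq_len(ncol(mats[[1]])))))
  for (s in seq_along(sp)) arr[s, , ] <- as.matrix(mats[[s]])
  detection_matrix(arr, roles = roles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
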