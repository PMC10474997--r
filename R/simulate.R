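#' Simulate latent pond-occupancy dynamics
#'
#' Generates a multi-month occupancy time series for a community of prey and
#' predator species across independent sites (ponds). Month 1 states are
#' Bernoulli(`psi0`); for each later month an occupied site stays occupied
#' with probability `1 - epsilon'` and an empty site is colonized with
#' probability `gamma'`, where the primed rates carry the predator-prey
#' interaction multipliers of [occupancy_params()], keyed on the partner
#' guild's presence in the preceding month (or, if
#' `interaction_lag = "same_month"`, on the predators' current-month states,
#' with predators updated first). No missingness is applied here; see
#' [apply_missingness()].
#'
#' @param species A [species_roster()] data frame.
#' @param params An [occupancy_params()] object.
#' @param n_sites Number of sites (>= 1).
#' @param n_months Number of months (>= 2).
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return A [detection_matrix()] of latent truth (no `NA`s), with attribute
#'   `n_capped` counting interaction-multiplied probabilities clipped to
#'   `[0, 1]`.
#' @examples
#' truth <- simulate_occupancy(species_roster(), occupancy_params(),
#'                             n_sites = 10, n_months = 3, seed = 1)
#' @export
simulate_occupancy <- function(species, params, n_sites, n_months, seed = NULL) {
  stopifnot(is.data.frame(species), inherits(params, "occupancy_params"))
  n_sites <- .check_count(n_sites, "n_sites")
  n_months <- .check_count(n_months, "n_months", min = 2L)
  sp <- species$species_id
  role <- species$role
  psi0 <- .per_species(params$psi0, sp, "psi0")
  gamma <- .per_species(params$gamma, sp, "gamma")
  epsilon <- .per_species(params$epsilon, sp, "epsilon")
  is_pred <- role == "predator"
  is_prey <- role == "prey"

  with_seed(seed, {
    S <- length(sp)
    arr <- array(NA_integer_, dim = c(S, n_sites, n_months),
                 dimnames = list(sp, sprintf("P%02d", seq_len(n_sites)),
                                 as.character(seq_len(n_months))))
    # occ: sites x species matrix for the current month
    occ <- matrix(stats::runif(n_sites * S) < rep(psi0, each = n_sites),
                  n_sites, S) * 1L
    arr[, , 1L] <- t(occ)
    n_capped <- 0L

    step_guild <- function(occ_prev, partner_present, cols, g_mult, e_mult) {
      # advance the species in `cols` one month, multipliers applied where
      # the partner guild is present
      out <- matrix(0L, nrow(occ_prev), length(cols))
      u <- matrix(stats::runif(nrow(occ_prev) * length(cols)), nrow(occ_prev))
      for (j in seq_along(cols)) {
        s <- cols[j]
        g <- ifelse(partner_present, gamma[s] * g_mult, gamma[s])
        e <- ifelse(partner_present, epsilon[s] * e_mult, epsilon[s])
        n_capped <<- n_capped + sum(g > 1) + sum(e > 1)
        g <- pmin(g, 1); e <- pmin(e, 1)
        prev <- occ_prev[, s]
        out[, j] <- ifelse(prev == 1L, u[, j] >= e, u[, j] < g) * 1L
      }
      out
    }

    for (t in 2:n_months) {
      pred_prev <- rowSums(occ[, is_pred, drop = FALSE]) > 0
      prey_prev <- rowSums(occ[, is_prey, drop = FALSE]) > 0
      new <- occ
      new[, is_pred] <- step_guild(occ, prey_prev, which(is_pred),
                                   params$phi_pred, 1)
      pred_ref <- if (params$interaction_lag == "same_month") {
        rowSums(new[, is_pred, drop = FALSE]) > 0
      } else {
        pred_prev
      }
      new[, is_prey] <- step_guild(occ, pred_ref, which(is_prey),
                                   params$theta_col, params$theta_ext)
      occ <- new
      arr[, , t] <- t(occ)
    }
    out <- detection_matrix(arr, roles = stats::setNames(role, sp))
    attr(out, "n_capped") <- n_capped
    out
  })
}

#' Mark unsampled site-months in a truth matrix
#'
#' Applies missing-completely-at-random site-month dropout: every site-month
#' from month 2 onward is independently unsampled with probability
#' `missing_rate` (month 1 is never missing), setting all species to `NA`
#' there. This emulates field campaigns where some ponds could not be
#' revisited (drying, disturbance) without modelling the cause.
#'
#' @param truth A [detection_matrix()].
#' @param missing_rate Per site-month dropout probability.
#' @param seed Optional integer seed.
#' @return The matrix with `NA`-masked site-months.
#' @export
apply_missingness <- function(truth, missing_rate, seed = NULL) {
  stopifnot(inherits(truth, "detection_matrix"))
  .check_prob(missing_rate, "missing_rate", allow_vector = FALSE)
  if (missing_rate == 0) return(truth)
  d <- dim(truth)
  with_seed(seed, {
    for (t in seq_len(d[3L])[-1L]) {
      drop <- stats::runif(d[2L]) < missing_rate
      if (any(drop)) truth[, drop, t] <- NA_integer_
    }
    truth
  })
}

#' Simulate replicate-level qPCR wells from latent occupancy
#'
#' Lays the qPCR observation layer of [observation_params()] over a latent
#' truth matrix. For every sampled site-month-species, each of the
#' `n_bio * n_tech` replicate reactions amplifies with probability `p_rep`
#' when the species is present (drawing its relative DNA amount from a
#' log-normal and its Cq from the standard curve plus Gaussian noise), and
#' with probability `p_fp` when absent (at a concentration of `lod / 2`).
#' Non-amplifying replicates carry `NA` Cq, as do replicates whose noisy Cq
#' would fall beyond the 50-cycle protocol (the instrument never observes
#' them). No rows are emitted for unsampled (`NA`) site-months.
#'
#' @param truth A [detection_matrix()] (possibly with `NA`-masked
#'   site-months).
#' @param obs An [observation_params()] object.
#' @param curve A single [standard_curve()] shared by all species, or a
#'   named list of curves keyed by species id. If `p_fp > 0` the curve(s)
#'   must carry a finite LOD.
#' @param seed Optional integer seed.
#' @return A wells `data.frame` with columns
#'   `site_id, month, species_id, bio_rep, tech_rep, cq`.
#' @export
simulate_wells <- function(truth, obs, curve, seed = NULL) {
  stopifnot(inherits(truth, "detection_matrix"), inherits(obs, "observation_params"))
  sp <- dimnames(truth)[[1L]]
  curves <- .curve_list(curve, sp)
  for (s in sp) {
    cv <- curves[[s]]
    if (!is.finite(cv$slope_ln) || !is.finite(cv$intercept)) {
      stop("standard curve must have finite slope and intercept", call. = FALSE)
    }
    if (obs$p_fp > 0 && !is.finite(cv$lod)) {
      stop(sprintf("curve for species %s needs a finite LOD when p_fp > 0", s),
           call. = FALSE)
    }
  }
  long <- as.data.frame(truth)
  long <- long[!is.na(long$state), , drop = FALSE]
  if (nrow(long) == 0L) stop("truth matrix has no sampled site-months", call. = FALSE)

  n_rep <- obs$n_bio * obs$n_tech
  wells <- long[rep(seq_len(nrow(long)), each = n_rep), , drop = FALSE]
  wells$bio_rep <- rep(rep(seq_len(obs$n_bio), each = obs$n_tech), nrow(long))
  wells$tech_rep <- rep(seq_len(obs$n_tech), obs$n_bio * nrow(long))
  rownames(wells) <- NULL

  with_seed(seed, {
    p_amp <- ifelse(wells$state == 1L, obs$p_rep, obs$p_fp)
    amp <- stats::runif(nrow(wells)) < p_amp
    conc <- rep(NA_real_, nrow(wells))
    pres_amp <- amp & wells$state == 1L
    conc[pres_amp] <- stats::rlnorm(sum(pres_amp), obs$conc_mu, obs$conc_sigma)
    abs_amp <- amp & wells$state == 0L
    if (any(abs_amp)) {
      lods <- vapply(curves, function(cv) cv$lod, numeric(1))
      conc[abs_amp] <- lods[wells$species_id[abs_amp]] / 2
    }
    cq <- rep(NA_real_, nrow(wells))
    if (any(amp)) {
      slopes <- vapply(curves, function(cv) cv$slope_ln, numeric(1))
      inters <- vapply(curves, function(cv) cv$intercept, numeric(1))
      cq[amp] <- slopes[wells$species_id[amp]] * log(conc[amp]) +
        inters[wells$species_id[amp]] +
        stats::rnorm(sum(amp), 0, obs$cq_sd)
      # a reaction that would only cross threshold beyond the 50-cycle
      # protocol is never observed: record it as non-amplifying
      cq[!is.na(cq) & cq > 50] <- NA_real_
    }
    out <- data.frame(site_id = wells$site_id, month = wells$month,
                      species_id = wells$species_id, bio_rep = wells$bio_rep,
                      tech_rep = wells$tech_rep, cq = cq,
                      stringsAsFactors = FALSE)
    out[order(out$site_id, out$month, out$species_id, out$bio_rep, out$tech_rep), ,
        drop = FALSE] -> out
    rownames(out) <- NULL
    out
  })
}

.curve_list <- function(curve, species_id) {
  if (inherits(curve, "standard_curve")) {
    return(stats::setNames(rep(list(curve), length(species_id)), species_id))
  }
  if (is.list(curve)) {
    miss <- setdiff(species_id, names(curve))
    if (length(miss)) {
      stop(sprintf("no standard curve supplied for species: %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    return(curve[species_id])
  }
  stop("`curve` must be a standard_curve or a named list of them", call. = FALSE)
}

#' Generate a complete synthetic study under a named preset
#'
#' Bundles the occupancy simulator, the site-month missingness mask and the
#' qPCR observation layer into one reproducible dataset. Three presets are
#' provided:
#'
#' * `"null_model"`: the pond-survey design (31 sites, 3 months, 2 prey +
#'   2 predators, 15% of later site-months unsampled) with all interaction
#'   multipliers at 1, so species evolve independently — the calibration
#'   scenario for the permutation test.
#' * `"strong_avoidance"`: 60 sites with a strong negative interaction
#'   (`theta_col = 0.1`, `theta_ext = 5`, `phi_pred = 2`): predators
#'   suppress prey colonization, amplify prey extinction, and are drawn to
#'   ponds holding prey.
#' * `"paper_like"`: the 31-pond, 3-month design with the same interaction
#'   multipliers as `strong_avoidance` and ~15% missing site-months.
#'
#' All presets share the same base rates (prey: psi0 0.25, gamma 0.6,
#' epsilon 0.15; predators: psi0 0.5, gamma 0.05, epsilon 0.05 — a mobile
#' breeding-season prey guild over resident fish), the default observation
#' layer (3 water samples x qPCR triplicates, `p_rep` 0.8, `p_fp` 0.005) and
#' a shared assay curve (slope -1.526, intercept 41.232, LOD 0.01 relative
#' units).
#'
#' @param name Preset id: `"null_model"`, `"strong_avoidance"` or
#'   `"paper_like"`.
#' @param seed Integer seed; the whole dataset is generated from one RNG
#'   stream, so identical (preset, seed) calls are bit-identical.
#' @param n_sites Optional override of the preset's site count.
#' @param n_months Optional override of the preset's month count.
#' @return An object of class `synthetic_dataset`: a list with elements
#'   `truth` (masked [detection_matrix()]), `wells`, `curve`, `species`,
#'   `params` (occupancy + observation), `preset`, `seed`.
#' @examples
#' ds <- make_scenario("paper_like", seed = 1)
#' dim(ds$truth)
#' @export
make_scenario <- function(name, seed, n_sites = NULL, n_months = NULL) {
  presets <- list(
    null_model = list(n_sites = 31L, n_months = 3L, missing_rate = 0.15,
                      theta_col = 1, theta_ext = 1, phi_pred = 1),
    strong_avoidance = list(n_sites = 60L, n_months = 3L, missing_rate = 0,
                            theta_col = 0.1, theta_ext = 5, phi_pred = 2),
    paper_like = list(n_sites = 31L, n_months = 3L, missing_rate = 0.15,
                      theta_col = 0.1, theta_ext = 5, phi_pred = 2))
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets)) {
    stop(sprintf("unknown preset '%s' (expected one of: %s)",
                 as.character(name)[1L], paste(names(presets), collapse = ", ")),
         call. = FALSE)
  }
  p <- presets[[name]]
  n_sites <- n_sites %||% p$n_sites
  n_months <- n_months %||% p$n_months
  species <- species_roster()
  occ_p <- occupancy_params(
    psi0 = c(A1 = 0.25, A2 = 0.25, F1 = 0.5, F2 = 0.5),
    gamma = c(A1 = 0.6, A2 = 0.6, F1 = 0.05, F2 = 0.05),
    epsilon = c(A1 = 0.15, A2 = 0.15, F1 = 0.05, F2 = 0.05),
    theta_col = p$theta_col, theta_ext = p$theta_ext, phi_pred = p$phi_pred)
  obs_p <- observation_params(missing_rate = p$missing_rate)
  curve <- suppressWarnings(standard_curve(-1.526, 41.232, r_squared = 1,
                                           lod = 0.01, loq = 0.05))
  with_seed(seed, {
    truth <- simulate_occupancy(species, occ_p, n_sites, n_months, seed = NULL)
    truth <- apply_missingness(truth, obs_p$missing_rate, seed = NULL)
    wells <- simulate_wells(truth, obs_p, curve, seed = NULL)
    structure(list(truth = truth, wells = wells, curve = curve,
                   species = species,
                   params = list(occupancy = occ_p, observation = obs_p),
                   preset = name, seed = seed),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  d <- dim(x$truth)
  cat(sprintf("synthetic_dataset (preset '%s', seed %d): %d species x %d sites x %d months, %d wells\n",
              x$preset, x$seed, d[1L], d[2L], d[3L], nrow(x$wells)))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Writes `wells.csv`, `truth.csv` and a `params.json` sidecar recording the
#' preset, seed and all parameters, so a dataset can be regenerated or
#' re-analysed exactly.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_scenario <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(preset = dataset$preset, seed = dataset$seed,
            package_version = as.character(utils::packageVersion("ednadyn")))
  write_wells(dataset$wells, file.path(dir, "wells.csv"), provenance = prov)
  write_detection_matrix(dataset$truth, file.path(dir, "truth.csv"), provenance = prov)
  pj <- list(preset = dataset$preset, seed = dataset$seed,
             species = dataset$species,
             occupancy = unclass(dataset$params$occupancy),
             observation = unclass(dataset$params$observation),
             curve = unclass(dataset$curve))
  jsonlite::write_json(pj, file.path(dir, "params.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
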