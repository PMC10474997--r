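#' Define the species roster for a survey or simulation
#'
#' A roster lists the target species with their trophic role. The default
#' mirrors a two-predator / two-prey pond community: two amphibian prey
#' species (`A1`, `A2`) and two predatory fish (`F1`, `F2`).
#'
#' @param species_id Character vector of unique short labels.
#' @param role Character vector, one of `"prey"` or `"predator"` per species.
#' @param display_name Optional free-text names (defaults to `species_id`).
#'
#' @return A `data.frame` with columns `species_id`, `role`, `display_name`.
#' @examples
#' species_roster()
#' species_roster(c("newt", "pike"), c("prey", "predator"))
#' @export
species_roster <- function(species_id = c("A1", "A2", "F1", "F2"),
                           role = c("prey", "prey", "predator", "predator"),
                           display_name = species_id) {
  species_id <- as.character(species_id)
  role <- as.character(role)
  if (length(species_id) < 1L) stop("at least one species is required", call. = FALSE)
  if (anyDuplicated(species_id)) stop("`species_id` must be unique", call. = FALSE)
  if (length(role) != length(species_id)) {
    stop("`role` must have one entry per species", call. = FALSE)
  }
  bad <- setdiff(unique(role), c("prey", "predator"))
  if (length(bad)) {
    stop(sprintf("unknown role(s): %s (must be 'prey' or 'predator')",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  data.frame(species_id = species_id, role = role,
             display_name = as.character(display_name),
             stringsAsFactors = FALSE)
}

#' Occupancy dynamics parameters
#'
#' Parameters of the per-site, per-month occupancy process. Each species
#' starts occupied with probability `psi0`; between consecutive months an
#' empty site is colonized with probability `gamma` and an occupied site
#' goes extinct with probability `epsilon`. The predator-prey interaction
#' enters through three multipliers keyed on presence in the *preceding*
#' month: when at least one predator was present at a site, the prey
#' colonization probability is multiplied by `theta_col` and the prey
#' extinction probability by `theta_ext`; when at least one prey was
#' present, the predator colonization probability is multiplied by
#' `phi_pred`. Multiplied probabilities are capped to `[0, 1]` (the number
#' of caps applied is recorded on the simulated object). Setting all three
#' multipliers to 1 makes every species evolve independently.
#'
#' `psi0`, `gamma` and `epsilon` may be scalars (shared by all species) or
#' named vectors keyed by `species_id`.
#'
#' @param psi0 Initial occupancy probability.
#' @param gamma Monthly colonization probability.
#' @param epsilon Monthly extinction probability.
#' @param theta_col Multiplier on prey `gamma` under predator presence (>= 0).
#' @param theta_ext Multiplier on prey `epsilon` under predator presence (>= 0).
#' @param phi_pred Multiplier on predator `gamma` under prey presence (>= 0).
#' @param interaction_lag `"preceding_month"` (default) conditions month-`t`
#'   decisions on partner states at `t - 1`; `"same_month"` updates predators
#'   first and conditions prey on the predators' month-`t` states.
#'
#' @return An object of class `occupancy_params`.
#' @examples
#' occupancy_params(psi0 = 0.4, gamma = 0.3, epsilon = 0.1, theta_col = 0.2)
#' @export
occupancy_params <- function(psi0 = 0.4, gamma = 0.2, epsilon = 0.1,
                             theta_col = 1, theta_ext = 1, phi_pred = 1,
                             interaction_lag = c("preceding_month", "same_month")) {
  .check_prob(psi0, "psi0"); .check_prob(gamma, "gamma"); .check_prob(epsilon, "epsilon")
  for (nm in c("theta_col", "theta_ext", "phi_pred")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop(sprintf("`%s` must be a single non-negative number", nm), call. = FALSE)
    }
  }
  structure(list(psi0 = psi0, gamma = gamma, epsilon = epsilon,
                 theta_col = theta_col, theta_ext = theta_ext,
                 phi_pred = phi_pred,
                 interaction_lag = match.arg(interaction_lag)),
            class = "occupancy_params")
}

#' qPCR observation-layer parameters
#'
#' Parameters of the replicate-level observation process laid over the
#' latent occupancy states. Each sampled site-month yields `n_bio` water
#' samples, each run in `n_tech` qPCR replicates. Where the species is truly
#' present each replicate amplifies independently with probability `p_rep`,
#' drawing a relative DNA amount from a log-normal with log-scale location
#' `conc_mu` and scale `conc_sigma`; where it is absent a replicate
#' false-amplifies with probability `p_fp` at a concentration of half the
#' assay's limit of detection. Observed Cq values are the standard-curve
#' prediction plus Gaussian noise with sd `cq_sd`. Site-months in months
#' 2 onwards are independently unsampled with probability `missing_rate`
#' (month 1 is never missing).
#'
#' @param n_bio Biological replicates (water samples) per site-month.
#' @param n_tech Technical qPCR replicates per biological sample.
#' @param p_rep Per-replicate amplification probability given presence.
#' @param p_fp Per-replicate false-amplification probability given absence.
#' @param conc_mu,conc_sigma Log-scale location and scale of the relative
#'   DNA amount for a replicate of a truly present species.
#' @param cq_sd Gaussian Cq noise (cycles) around the curve prediction.
#' @param missing_rate Probability a site-month after the first is unsampled.
#'
#' @return An object of class `observation_params`.
#' @export
observation_params <- function(n_bio = 3, n_tech = 3, p_rep = 0.8, p_fp = 0.005,
                               conc_mu = log(0.1), conc_sigma = 1,
                               cq_sd = 0.35, missing_rate = 0) {
  n_bio <- .check_count(n_bio, "n_bio"); n_tech <- .check_count(n_tech, "n_tech")
  .check_prob(p_rep, "p_rep", allow_vector = FALSE)
  .check_prob(p_fp, "p_fp", allow_vector = FALSE)
  .check_prob(missing_rate, "missing_rate", allow_vector = FALSE)
  if (!is.numeric(conc_sigma) || conc_sigma < 0) stop("`conc_sigma` must be >= 0", call. = FALSE)
  if (!is.numeric(cq_sd) || cq_sd < 0) stop("`cq_sd` must be >= 0", call. = FALSE)
  structure(list(n_bio = n_bio, n_tech = n_tech, p_rep = p_rep, p_fp = p_fp,
                 conc_mu = conc_mu, conc_sigma = conc_sigma,
                 cq_sd = cq_sd, missing_rate = missing_rate),
            class = "observation_params")
}

# Expand a scalar or named per-species parameter to the roster order.
.per_species <- function(x, species_id, name) {
  if (length(x) == 1L && is.null(names(x))) return(rep(unname(x), length(species_id)))
  if (!is.null(names(x))) {
    miss <- setdiff(species_id, names(x))
    if (length(miss)) {
      stop(sprintf("`%s` missing values for species: %s", name,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    return(unname(x[species_id]))
  }
  if (length(x) == length(species_id)) return(unname(x))
  stop(sprintf("`%s` must be a scalar, a named vector, or one value per species", name),
       call. = FALSE)
}
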