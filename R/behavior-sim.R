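#' Default behavioral ground-truth parameters
#'
#' Parameters of the generative link between lesion topography and the
#' reaching deficit, and of the recovery trajectory. Units and rationale:
#' * `weights`: named non-negative weights over informative region ids;
#'   the damage score is `sum(w_r * pct_r / 100)`.
#' * `link_mid`, `link_slope`: midpoint and slope of the logistic mapping
#'   from damage score to acute deficit. The logistic is shifted and
#'   rescaled so zero damage maps to zero deficit.
#' * `acute_noise_sd`: SD of Gaussian noise on the logit scale (biological
#'   variability of the acute deficit at a given lesion topography).
#' * `recovery_rate`: per-day exponential relaxation rate of the deficit.
#' * `recovery_floor`, `recovery_ceiling`, `recovery_shape`: residual
#'   deficit = `d * (floor + (ceiling - floor) * d^shape)` for acute
#'   deficit `d`; mildly affected animals recover almost fully while
#'   severely affected animals retain most of their deficit
#'   (recoverees vs non-recoverees).
#' * `residual_noise_sd`: scale of the Gaussian noise added to the
#'   residual deficit (deficit fraction scale); the effective SD is
#'   `residual_noise_sd * (0.3 + 2.5 * acute_deficit^2)`, encoding that
#'   severe acute deficits have the most heterogeneous long-term outcomes
#'   (recoverees vs non-recoverees).
#' * `nonparetic_factor`, `nonparetic_rate`: size and relaxation rate of
#'   the smaller transient dip of the non-paretic paw.
#' * `n_pellets`: pellets presented per side per day (sets binomial noise
#'   granularity only).
#' * `plateau_mean`, `plateau_sd`: per-animal trained baseline retrieval
#'   probability.
#'
#' @param weights Named numeric vector of deficit weights (names = region
#'   ids).
#' @param ... Overrides of the defaults listed above.
#' @return Named list of parameters.
#' @export
ground_truth_params <- function(weights = NULL, ...) {
  p <- list(
    weights = weights,
    link_mid = 4.5,
    link_slope = 0.8,
    acute_noise_sd = 0.5,
    recovery_rate = 0.15,
    recovery_floor = 0.3,
    recovery_ceiling = 0.7,
    recovery_shape = 1,
    residual_noise_sd = 0.08,
    nonparetic_factor = 0.5,
    nonparetic_rate = 0.5,
    n_pellets = 20L,
    plateau_mean = 0.75,
    plateau_sd = 0.06
  )
  dots <- list(...)
  p[names(dots)] <- dots
  stopifnot(p$recovery_rate > 0, p$residual_noise_sd >= 0,
            p$acute_noise_sd >= 0)
  p
}

# Shifted-rescaled logistic link: damage 0 -> deficit 0, saturates at 1.
deficit_link <- function(damage, mid, slope, noise = 0) {
  p0 <- stats::plogis(-slope * mid)
  raw <- stats::plogis(slope * (damage - mid) + noise)
  clamp((raw - p0) / (1 - p0), 0, 1)
}

# Deterministic residual deficit as a function of acute deficit: mild
# animals recover towards recovery_floor * d, severe ones towards
# recovery_ceiling * d.
residual_from_acute <- function(d, params) {
  d * (params$recovery_floor +
         (params$recovery_ceiling - params$recovery_floor) *
         d^params$recovery_shape)
}

#' Simulate one animal's staircase reaching record
#'
#' Generates per-day, per-side pellet retrieval counts for the training
#' period (days -21..-1, exponential ramp to a per-animal plateau) and the
#' post-stroke period (days 2..21). On the paretic side the retrieval
#' probability is `plateau * (1 - deficit(t))`, where the deficit relaxes
#' exponentially from the acute level (a noisy logistic function of the
#' weighted damage over informative regions) to the residual level (a
#' deterministic recovery curve of the acute deficit plus noise). The
#' non-paretic side gets a smaller, faster-resolving dip. Sham animals get
#' noise-only trajectories around their plateau.
#'
#' @param region_profile A `region_lesion_profile` (or a bare named pct
#'   vector) giving percent lesion per region.
#' @param params List from [ground_truth_params()]; `params$weights` must
#'   be a named vector over informative region ids.
#' @param is_sham Logical; sham animals carry no deficit.
#' @param paretic_side `"left"` or `"right"`.
#' @param seed Integer seed.
#' @param animal_id Identifier used in the output rows.
#' @return A long-format `data.frame` (`animal_id`, `day`, `side`,
#'   `pellets_retrieved`, `pellets_presented`) with attribute `"truth"`:
#'   list with `acute_deficit`, `residual_deficit`,
#'   `true_subacute_deficit`, `true_residual_deficit` (deterministic phase
#'   means of the deficit trajectory over days 2-6 and 12-21), `damage`
#'   and the per-side plateaus.
#' @export
simulate_behavior <- function(region_profile, params, is_sham = FALSE,
                              paretic_side = "right", seed = 1L,
                              animal_id = "animal") {
  pct <- if (inherits(region_profile, "region_lesion_profile")) {
    region_profile$pct
  } else {
    region_profile
  }
  stopifnot(all(pct >= 0 & pct <= 100))
  w <- params$weights
  if (is.null(w)) stop("params$weights must be set", call. = FALSE)
  common <- intersect(names(w), names(pct))
  damage <- sum(w[common] * pct[common] / 100)

  days_pre <- -21:-1
  days_post <- 2:21
  with_seed(seed, {
    plateau <- clamp(stats::rnorm(2, params$plateau_mean, params$plateau_sd),
                     0.35, 0.95)
    names(plateau) <- c("paretic", "nonparetic")

    if (is_sham) {
      d_acute <- 0
      d_res <- 0
    } else {
      d_acute <- deficit_link(damage, params$link_mid, params$link_slope,
                              noise = stats::rnorm(1, 0, params$acute_noise_sd))
      # recovery heterogeneity scales with the acute deficit: mildly
      # affected animals converge to near-complete recovery, severely
      # affected ones split into recoverees and non-recoverees
      res_sd <- params$residual_noise_sd * (0.3 + 2.5 * d_acute^2)
      d_res <- clamp(residual_from_acute(d_acute, params) +
                       stats::rnorm(1, 0, res_sd), 0, 1)
    }
    deficit_t <- d_res + (d_acute - d_res) *
      exp(-params$recovery_rate * days_post)
    deficit_np <- params$nonparetic_factor * d_acute *
      exp(-params$nonparetic_rate * days_post)

    ramp <- 1 - exp(-(days_pre + 22) / 5)
    n_pel <- params$n_pellets
    draw <- function(p) stats::rbinom(length(p), n_pel, clamp(p, 0, 1))

    sides <- c(paretic_side, setdiff(c("left", "right"), paretic_side))
    rec <- rbind(
      data.frame(day = days_pre, side = sides[1],
                 pellets_retrieved = draw(plateau["paretic"] * ramp)),
      data.frame(day = days_pre, side = sides[2],
                 pellets_retrieved = draw(plateau["nonparetic"] * ramp)),
      data.frame(day = days_post, side = sides[1],
                 pellets_retrieved = draw(plateau["paretic"] *
                                            (1 - deficit_t))),
      data.frame(day = days_post, side = sides[2],
                 pellets_retrieved = draw(plateau["nonparetic"] *
                                            (1 - deficit_np))))
    rec$pellets_presented <- n_pel
    rec <- data.frame(animal_id = animal_id, rec)
    rec <- rec[order(rec$day, rec$side), ]
    rownames(rec) <- NULL
    attr(rec, "truth") <- list(
      damage = damage,
      acute_deficit = d_acute,
      residual_deficit = d_res,
      true_subacute_deficit = mean(d_res + (d_acute - d_res) *
                                     exp(-params$recovery_rate * (2:6))),
      true_residual_deficit = mean(d_res + (d_acute - d_res) *
                                     exp(-params$recovery_rate * (12:21))),
      plateau = plateau
    )
    rec
  })
}
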