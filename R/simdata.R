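#' Configuration for a simulated study group
#'
#' Bundles every parameter of the mechanistic simulator: group composition,
#' dyadic affinity structure, spatial spread, flight-threshold distribution,
#' observer-distance distribution, and the focal sampling plan. Defaults
#' emulate a habituated group of 65 non-infant individuals sampled over two
#' study years (28 and 25 retained focals per individual), with repeatable
#' log-normal flight thresholds (repeatability 0.6) and observer end
#' distances with median 4.5 m.
#'
#' @param n_individuals Number of (non-infant) individuals in the group.
#' @param n_subgroups Number of affinity subgroups; individuals in the same
#'   subgroup get an affinity bonus and therefore sit closer together.
#' @param affinity_base Baseline dyadic affinity (dimensionless, > 0).
#' @param affinity_bonus Added affinity for same-subgroup dyads.
#' @param spatial_rate Baseline exponential rate (1/m) for the focal-to-
#'   neighbour radial distance; the rate for dyad (i, j) is
#'   `spatial_rate * affinity[i, j]`, so higher affinity means closer.
#' @param max_radius Truncation radius (m) for neighbour placement.
#' @param touch_radius Radius (m) below which a neighbour counts as touching.
#' @param buffers Strictly decreasing metric proximity buffers (m); the touch
#'   buffer is handled separately via `touch_radius`.
#' @param sd_greg Log-scale SD of individual gregariousness: each animal
#'   carries a multiplier `g_i = exp(N(0, sd_greg))` on its dyadic
#'   affinities, so some individuals sit systematically closer to everyone.
#'   Without it every individual would have the same expected neighbour
#'   rate and network positions would be pure noise.
#' @param mu_logfid Population mean log flight-initiation distance
#'   (log-metres).
#' @param sd_id Between-individual SD of log FID (log scale).
#' @param sd_res Within-individual (residual) SD of log FID.
#' @param obs_dist_median Median observer end distance (m).
#' @param obs_dist_sigma Log-scale SD of the observer end distance.
#' @param displacement_enabled If `TRUE`, neighbours closer to the observer
#'   than their realized flight threshold relocate away from the observer.
#' @param focal_conditioning If `TRUE`, the observer end distance is drawn
#'   conditional on not triggering the focal animal's own realized flight
#'   threshold (focals can only be completed at tolerated distances).
#' @param overshoot Extra distance (m) a displaced animal moves beyond the
#'   minimum needed to satisfy its threshold.
#' @param year_plan Named integer vector: retained focals per individual per
#'   year after down-sampling.
#' @param extra_focals_max Maximum number of extra raw focals (0 to this
#'   value, uniform) an individual receives beyond the year plan, emulating
#'   uneven raw sampling before down-sampling.
#' @param n_approaches Approach trials per individual for the flight-
#'   initiation-distance assay.
#' @param seed Integer seed; all stochastic draws flow from this one stream.
#'
#' @return An object of class `group_config` (a validated list).
#' @export
#' @examples
#' cfg <- group_config(n_individuals = 10, seed = 1)
#' cfg$buffers
group_config <- function(n_individuals = 65,
                         n_subgroups = 5,
                         affinity_base = 1,
                         affinity_bonus = 1,
                         spatial_rate = 0.0055,
                         max_radius = 550,
                         touch_radius = 0.1,
                         buffers = c(5, 2.5, 1),
                         sd_greg = 0.4,
                         mu_logfid = log(2),
                         sd_id = sqrt(0.6),
                         sd_res = sqrt(0.4),
                         obs_dist_median = 4.5,
                         obs_dist_sigma = 0.6,
                         displacement_enabled = TRUE,
                         focal_conditioning = TRUE,
                         overshoot = 0,
                         year_plan = c("2018" = 28L, "2019" = 25L),
                         extra_focals_max = 2L,
                         n_approaches = 24L,
                         seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals), n_subgroups = as.integer(n_subgroups),
    affinity_base = affinity_base, affinity_bonus = affinity_bonus,
    spatial_rate = spatial_rate, max_radius = max_radius,
    touch_radius = touch_radius, buffers = sort(buffers, decreasing = TRUE),
    sd_greg = sd_greg, mu_logfid = mu_logfid, sd_id = sd_id, sd_res = sd_res,
    obs_dist_median = obs_dist_median, obs_dist_sigma = obs_dist_sigma,
    displacement_enabled = isTRUE(displacement_enabled),
    focal_conditioning = isTRUE(focal_conditioning),
    overshoot = overshoot,
    year_plan = year_plan, extra_focals_max = as.integer(extra_focals_max),
    n_approaches = as.integer(n_approaches), seed = as.integer(seed)
  )
  if (cfg$n_individuals < 2) stop("need at least 2 individuals")
  if (any(diff(cfg$buffers) >= 0)) stop("buffers must be strictly decreasing")
  if (cfg$touch_radius >= min(cfg$buffers)) {
    stop("touch_radius must be smaller than the smallest metric buffer")
  }
  if (cfg$sd_id < 0 || cfg$sd_res < 0) stop("SDs must be nonnegative")
  if (cfg$displacement_enabled && cfg$sd_res <= 0 && cfg$sd_id <= 0) {
    stop("displacement requires a positive flight-threshold scale (sd_id or sd_res)")
  }
  if (cfg$spatial_rate <= 0 || cfg$obs_dist_sigma <= 0) {
    stop("spatial_rate and obs_dist_sigma must be positive")
  }
  if (is.null(names(cfg$year_plan)) || any(!nzchar(names(cfg$year_plan)))) {
    stop("year_plan must be a named vector (names are year labels)")
  }
  class(cfg) <- "group_config"
  cfg
}

#' Intraclass correlation implied by a group configuration
#'
#' @param config A [group_config()].
#' @return sd_id^2 / (sd_id^2 + sd_res^2).
#' @export
config_icc <- function(config) {
  config$sd_id^2 / (config$sd_id^2 + config$sd_res^2)
}

#' Simulate latent group structure (ground truth)
#'
#' Draws per-individual tolerance deviations on the log-FID scale and builds
#' the symmetric dyadic affinity matrix from round-robin subgroup labels.
#'
#' @param config A [group_config()].
#' @return A list of class `latent_truth` with elements `ids` (character),
#'   `logfid_dev` (named numeric: individual deviation of log flight
#'   distance from the population mean; this enters every realized flight
#'   threshold), `tolerance_true` (= `-logfid_dev`: ground truth on the
#'   tolerance axis, high values = short flight distances = highly tolerant
#'   of observers — the axis the downstream tolerance estimates use),
#'   `gregariousness` (named positive multiplier on dyadic affinity),
#'   `subgroup` (named integer) and `affinity` (symmetric matrix, zero
#'   diagonal).
#' @export
#' @examples
#' truth <- simulate_group(group_config(n_individuals = 6, seed = 1))
#' truth$affinity
simulate_group <- function(config) {
  stopifnot(inherits(config, "group_config"))
  n <- config$n_individuals
  ids <- sprintf("ID%02d", seq_len(n))
  u <- stats::rnorm(n, 0, config$sd_id)
  names(u) <- ids
  g <- exp(stats::rnorm(n, 0, config$sd_greg))
  names(g) <- ids
  sub <- ((seq_len(n) - 1L) %% config$n_subgroups) + 1L
  names(sub) <- ids
  aff <- (config$affinity_base +
            config$affinity_bonus * outer(sub, sub, "==")) * outer(g, g)
  diag(aff) <- 0
  dimnames(aff) <- list(ids, ids)
  structure(list(ids = ids, logfid_dev = u, tolerance_true = -u,
                 gregariousness = g, subgroup = sub, affinity = aff),
            class = "latent_truth")
}

# squared-triangle distance between observer at (D, 0) and a neighbour at
# polar position (r, theta) relative to the focal at the origin
observer_neighbour_distance <- function(D, r, theta) {
  sqrt(D^2 + r^2 - 2 * D * r * cos(theta))
}

# draw from LogNormal(meanlog, sdlog) truncated below at `lower`
rlnorm_trunc <- function(n, meanlog, sdlog, lower) {
  p_lo <- stats::plnorm(lower, meanlog, sdlog)
  u <- stats::runif(n)
  stats::qlnorm(p_lo + u * (1 - p_lo), meanlog, sdlog)
}

# truncated exponential on (0, upper]
rexp_trunc <- function(n, rate, upper) {
  u <- stats::runif(n)
  -log(1 - u * (1 - exp(-rate * upper))) / rate
}

# Vectorised core: simulates all neighbour placements + displacement for a
# block of focals of the same focal individual. Returns a list of per-buffer
# neighbour id strings (semicolon separated) plus the observer distances.
simulate_focal_block <- function(config, truth, focal_id, n_focals) {
  ids <- truth$ids
  others <- setdiff(ids, focal_id)
  m <- length(others)
  mu <- config$mu_logfid

  # observer end distance, optionally conditioned on the focal tolerating it
  f_thresh <- exp(mu + truth$logfid_dev[[focal_id]] +
                    stats::rnorm(n_focals, 0, config$sd_res))
  meanlog_d <- log(config$obs_dist_median)
  if (config$focal_conditioning) {
    D <- rlnorm_trunc(n_focals, meanlog_d, config$obs_dist_sigma, f_thresh)
  } else {
    D <- stats::rlnorm(n_focals, meanlog_d, config$obs_dist_sigma)
  }

  rate <- config$spatial_rate * truth$affinity[focal_id, others]
  r <- matrix(rexp_trunc(n_focals * m, rep(rate, each = n_focals),
                         config$max_radius), n_focals, m)
  theta <- matrix(stats::runif(n_focals * m, 0, 2 * pi), n_focals, m)
  x <- r * cos(theta)
  y <- r * sin(theta)
  d_obs <- sqrt((x - D)^2 + y^2)

  final_dist <- r
  if (config$displacement_enabled) {
    f_j <- exp(mu + rep(truth$logfid_dev[others], each = n_focals) +
                 stats::rnorm(n_focals * m, 0, config$sd_res))
    dim(f_j) <- c(n_focals, m)
    disp <- d_obs < f_j
    if (any(disp)) {
      d0 <- d_obs[disp]
      d0[d0 == 0] <- 1e-9        # degenerate overlap: push along +x
      scale <- (f_j[disp] + config$overshoot) / d0
      nx <- D[row(disp)[disp]] + (x[disp] - D[row(disp)[disp]]) * scale
      ny <- y[disp] * scale
      final_dist[disp] <- sqrt(nx^2 + ny^2)
    }
  }

  join <- function(member) {
    apply(member, 1L, function(z) paste(others[z], collapse = ";"))
  }
  out <- list(end_observer_distance_m = D)
  for (b in config$buffers) {
    out[[buffer_column(b)]] <- join(final_dist <= b)
  }
  out[["touch"]] <- join(final_dist <= config$touch_radius)
  out
}

# canonical column name for a metric buffer, e.g. 5 -> "n5", 2.5 -> "n2_5"
buffer_column <- function(buffer) {
  paste0("n", gsub("\\.", "_", format(buffer, trim = TRUE)))
}

#' Buffer labels used across the package
#'
#' @param config A [group_config()] (only its `buffers` are used).
#' @return Character vector of buffer column labels, widest first, ending in
#'   `"touch"` (e.g. `c("n5", "n2_5", "n1", "touch")`).
#' @export
buffer_labels <- function(config = group_config()) {
  c(vapply(config$buffers, buffer_column, character(1)), "touch")
}

#' Simulate one 30-s focal sample
#'
#' Places the focal at the origin and the observer at its end distance on
#' the positive x-axis, scatters the other group members around the focal at
#' affinity-dependent radial distances, and (if enabled) relocates any
#' neighbour that finds itself closer to the observer than its realized
#' flight threshold: it moves radially away from the observer, along the
#' observer-to-neighbour direction, until its observer distance equals the
#' threshold. Per-buffer neighbour sets are read off the final focal
#' distances; buffers are nested.
#'
#' @param config A [group_config()].
#' @param truth A `latent_truth` from [simulate_group()].
#' @param focal_id Identifier of the focal individual.
#' @param year Year label for the record.
#' @param time_period Time period 1-4.
#' @return One-row data frame in focal-record form (see [simulate_study()]).
#' @export
simulate_focal <- function(config, truth, focal_id, year,
                           time_period = 1L) {
  if (!focal_id %in% truth$ids) stop("unknown focal_id: ", focal_id)
  blk <- simulate_focal_block(config, truth, focal_id, 1L)
  data.frame(focal_id = focal_id, year = as.character(year),
             time_period = as.integer(time_period),
             as.data.frame(blk, stringsAsFactors = FALSE),
             stringsAsFactors = FALSE)
}

#' Simulate a full study: approach assay plus focal sampling
#'
#' Generates (a) the flight-initiation-distance approach table — each
#' individual approached `n_approaches` times, FID = exp(mu + u_i + eps) —
#' and (b) the focal-record table for every year in the sampling plan, with
#' individuals visited in randomized order and 0 to `extra_focals_max` extra
#' raw focals per individual (down-sampling to the plan is a separate,
#' later, pipeline stage).
#'
#' @param config A [group_config()].
#' @return List with `approaches` (data frame: individual_id, approach_num,
#'   fid_m), `focals` (data frame: focal_id, year, time_period,
#'   end_observer_distance_m, one semicolon-separated id-list column per
#'   buffer), and `truth` (the `latent_truth`). The config seed is attached
#'   as attribute `seed` on both tables.
#' @export
#' @examples
#' study <- simulate_study(group_config(n_individuals = 8, seed = 42,
#'                                      year_plan = c("2018" = 4L),
#'                                      n_approaches = 6L))
#' nrow(study$approaches)  # 8 * 6
simulate_study <- function(config) {
  stopifnot(inherits(config, "group_config"))
  set.seed(config$seed)
  truth <- simulate_group(config)
  n <- config$n_individuals

  appr <- data.frame(
    individual_id = rep(truth$ids, each = config$n_approaches),
    approach_num = rep(seq_len(config$n_approaches), n),
    stringsAsFactors = FALSE
  )
  appr$fid_m <- exp(config$mu_logfid +
                      truth$logfid_dev[appr$individual_id] +
                      stats::rnorm(nrow(appr), 0, config$sd_res))
  rownames(appr) <- NULL

  focal_rows <- vector("list", length(config$year_plan) * n)
  k <- 0L
  for (yr in names(config$year_plan)) {
    n_base <- config$year_plan[[yr]]
    order_ids <- sample(truth$ids)
    for (id in order_ids) {
      n_foc <- n_base + sample.int(config$extra_focals_max + 1L, 1L) - 1L
      blk <- simulate_focal_block(config, truth, id, n_foc)
      k <- k + 1L
      focal_rows[[k]] <- data.frame(
        focal_id = id, year = yr,
        time_period = sample(1:4, n_foc, replace = TRUE),
        as.data.frame(blk, stringsAsFactors = FALSE),
        stringsAsFactors = FALSE
      )
    }
  }
  focals <- do.call(rbind, focal_rows)
  rownames(focals) <- NULL
  attr(appr, "seed") <- config$seed
  attr(focals, "seed") <- config$seed
  list(approaches = appr, focals = focals, truth = truth)
}

#' Write / read the simulator's ground truth
#'
#' Tolerances go to a plain CSV (`individual_id, tolerance_true, subgroup`);
#' the affinity matrix to a square CSV with id header row and column.
#'
#' @param truth A `latent_truth`.
#' @param tol_path,aff_path Output CSV paths.
#' @return Invisibly, the paths written.
#' @export
write_truth_csv <- function(truth, tol_path, aff_path) {
  utils::write.csv(
    data.frame(individual_id = truth$ids,
               tolerance_true = unname(truth$tolerance_true),
               subgroup = unname(truth$subgroup)),
    tol_path, row.names = FALSE)
  utils::write.csv(as.data.frame(truth$affinity), aff_path,
                   row.names = TRUE)
  invisible(c(tol_path, aff_path))
}
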