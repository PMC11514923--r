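#' Cohort specification
#'
#' Defines a synthetic cohort with the covariate structure of a presurgical
#' epilepsy study group: temporal (TLE) and extratemporal (ETLE) lobe
#' epilepsy subgroups, duration of epilepsy spanning 2-44 years, memory
#' scores standardized to a normative mean of 100 and SD of 10, and
#' injection-to-scan latencies with a median around 34-35 minutes over an
#' 18-266 minute range, for both the interictal and the postictal injection.
#'
#' Subtraction-map biomarker values are generated at the summary level (one
#' per-subject mean per region and map kind) as: baseline + group/region
#' effect + duration slope x duration + subject random intercept + residual,
#' all on the SSS-normalized scale.
#'
#' @param n_tle,n_etle subgroup sizes (defaults 14 and 23).
#' @param duration_shape,duration_scale gamma parameters of the duration of
#'   epilepsy (years); draws are clamped to `duration_range`.
#' @param duration_range allowed duration range in years, default `c(2, 44)`.
#' @param memory_mean,memory_sd normative memory-score distribution.
#' @param latency_meanlog,latency_sdlog log-normal injection-to-scan latency
#'   (minutes); clamped to `latency_range`.
#' @param latency_range allowed latency range, default `c(18, 266)`.
#' @param p_side_known probability that the seizure-onset side is known
#'   (default 28/37); known sides split evenly left/right.
#' @param baseline_ni,baseline_ip baseline normalized biomarker level.
#' @param duration_slope_ni,duration_slope_ip change in normalized biomarker
#'   per year of epilepsy duration.
#' @param effects_ni,effects_ip named list per group (`TLE`, `ETLE`) of named
#'   numeric vectors over region families (`cortex`, `hippocampus`,
#'   `amygdala`, `piriform`): additive biomarker effects (applied to both
#'   hemispheres).
#' @param sd_subject between-subject random intercept SD.
#' @param sd_resid residual SD per region measurement.
#' @param seed integer seed; fixed seed gives identical cohorts.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_tle = 14, n_etle = 23,
                        duration_shape = 2.2, duration_scale = 8,
                        duration_range = c(2, 44),
                        memory_mean = 100, memory_sd = 10,
                        latency_meanlog = log(34.6), latency_sdlog = 0.6,
                        latency_range = c(18, 266),
                        p_side_known = 28 / 37,
                        baseline_ni = 0.02, baseline_ip = 0,
                        duration_slope_ni = 0.001, duration_slope_ip = 0,
                        effects_ni = list(), effects_ip = list(),
                        sd_subject = 0.01, sd_resid = 0.02,
                        seed = 1L) {
  if (n_tle < 1 || n_etle < 1) stop("each group needs at least one subject")
  if (any(duration_range < 0)) stop("durations must be >= 0")
  structure(list(n_tle = as.integer(n_tle), n_etle = as.integer(n_etle),
                 duration_shape = duration_shape, duration_scale = duration_scale,
                 duration_range = duration_range,
                 memory_mean = memory_mean, memory_sd = memory_sd,
                 latency_meanlog = latency_meanlog, latency_sdlog = latency_sdlog,
                 latency_range = latency_range, p_side_known = p_side_known,
                 baseline_ni = baseline_ni, baseline_ip = baseline_ip,
                 duration_slope_ni = duration_slope_ni,
                 duration_slope_ip = duration_slope_ip,
                 effects_ni = effects_ni, effects_ip = effects_ip,
                 sd_subject = sd_subject, sd_resid = sd_resid,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

cohort_roi_set <- function() c("cortex", parenchymal_rois())

roi_family <- function(roi) sub("_(l|r)$", "", roi)

effect_of <- function(effects, group, family) {
  v <- effects[[group]]
  if (is.null(v)) return(0)
  x <- unname(v[family])
  if (length(x) == 0 || is.na(x)) 0 else x
}

clamp <- function(x, rng) pmin(pmax(x, rng[1]), rng[2])

#' Simulate a synthetic cohort
#'
#' Draws per-subject clinical covariates and summary-level biomarker values
#' from a [cohort_spec()]. Returns the subject table, the long measurement
#' table (one row per subject x region x map kind) and their join, which is
#' the input format of [run_group_analyses()].
#'
#' @param cs a [cohort_spec()].
#' @return list with `subjects`, `measurements` and `table` data.frames.
#' @export
simulate_cohort <- function(cs = cohort_spec()) {
  stopifnot(inherits(cs, "cohort_spec"))
  set.seed(cs$seed)
  n <- cs$n_tle + cs$n_etle
  group <- c(rep("TLE", cs$n_tle), rep("ETLE", cs$n_etle))
  id <- sprintf("sub-%03d", seq_len(n))
  duration <- clamp(stats::rgamma(n, shape = cs$duration_shape,
                                  scale = cs$duration_scale), cs$duration_range)
  verbal <- stats::rnorm(n, cs$memory_mean, cs$memory_sd)
  figural <- stats::rnorm(n, cs$memory_mean, cs$memory_sd)
  lat_ii <- clamp(stats::rlnorm(n, cs$latency_meanlog, cs$latency_sdlog),
                  cs$latency_range)
  lat_pi <- clamp(stats::rlnorm(n, cs$latency_meanlog, cs$latency_sdlog),
                  cs$latency_range)
  known <- stats::runif(n) < cs$p_side_known
  side <- ifelse(known, ifelse(stats::runif(n) < 0.5, "left", "right"),
                 "unknown")
  subjects <- data.frame(id = id, group = group, side = side,
                         duration = duration,
                         latency_ii = lat_ii, latency_pi = lat_pi,
                         verbal_memory = verbal, figural_memory = figural,
                         stringsAsFactors = FALSE)

  rois <- cohort_roi_set()
  fam <- roi_family(rois)
  hemi <- ifelse(endsWith(rois, "_l"), "left",
                 ifelse(endsWith(rois, "_r"), "right", "both"))
  intercept <- stats::rnorm(n, 0, cs$sd_subject)
  k <- length(rois)
  eff_mat <- function(effects) {
    vapply(unique(group), function(g)
      vapply(fam, function(f) effect_of(effects, g, f), numeric(1)),
      numeric(k))
  }
  mk <- function(kind, baseline, slope, effects) {
    em <- eff_mat(effects)                   # roi x group
    data.frame(id = rep(id, each = k), roi = rep(rois, n),
               hemisphere = rep(hemi, n), kind = kind,
               value = baseline + slope * rep(duration, each = k) +
                 as.vector(em[, match(group, colnames(em))]) +
                 rep(intercept, each = k) +
                 stats::rnorm(n * k, 0, cs$sd_resid),
               stringsAsFactors = FALSE)
  }
  measurements <- rbind(mk("ni", cs$baseline_ni, cs$duration_slope_ni,
                           cs$effects_ni),
                        mk("ip", cs$baseline_ip, cs$duration_slope_ip,
                           cs$effects_ip))
  rownames(measurements) <- NULL
  list(subjects = subjects, measurements = measurements,
       table = merge(measurements, subjects, by = "id", sort = TRUE))
}
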