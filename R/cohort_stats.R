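#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference distribution
#' (k - 1 degrees of freedom), delegating to [stats::kruskal.test()]. The
#' degenerate case in which every observation is identical is defined as
#' H = 0, p = 1 (no evidence of any difference).
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return list with `H`, `p`, `df` and `n`.
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1, df = length(groups) - 1L, n = length(x)))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), n = length(x))
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("at least two groups are required")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("every group must be non-empty")
  if (sum(sizes) < 3L) stop("at least three observations are required")
  x <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(x))) stop("group values must be finite")
  invisible(sizes)
}

#' Dunn post hoc test
#'
#' All pairwise z statistics on the pooled mid-ranks with tie correction,
#' \deqn{z_{ij} = (\bar r_i - \bar r_j) /
#'   \sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum (t^3 - t)}{12(N-1)}\right)
#'         \left(\frac{1}{n_i} + \frac{1}{n_j}\right)},}
#' two-sided p-values from the standard normal, adjusted for the number of
#' pairwise comparisons. Bonferroni (capped at 1) is the default; Holm and
#' no adjustment are offered.
#'
#' @param groups list of two or more non-empty numeric vectors (optionally
#'   named; names label the matrix).
#' @param adjustment `"bonferroni"` (default), `"holm"` or `"none"`.
#' @return list with symmetric matrices `z` (zero diagonal), `p_adjusted`
#'   (unit diagonal, values in [0, 1]) and `p_raw`.
#' @export
dunn_posthoc <- function(groups, adjustment = c("bonferroni", "holm", "none")) {
  adjustment <- match.arg(adjustment)
  sizes <- check_groups(groups)
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)                                   # mid-ranks for ties
  gidx <- rep(seq_len(k), sizes)
  rbar <- tapply(r, gidx, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))

  z <- matrix(0, k, k, dimnames = list(nm, nm))
  p_raw <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  pairs <- utils::combn(k, 2)
  for (c_ in seq_len(ncol(pairs))) {
    i <- pairs[1, c_]; j <- pairs[2, c_]
    se <- sqrt(sigma2 * (1 / sizes[i] + 1 / sizes[j]))
    zij <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    z[i, j] <- zij; z[j, i] <- -zij
    p_raw[i, j] <- p_raw[j, i] <- 2 * stats::pnorm(-abs(zij))
  }
  pv <- p_raw[upper.tri(p_raw)]
  adj_method <- switch(adjustment, bonferroni = "bonferroni", holm = "holm",
                       none = "none")
  pa <- stats::p.adjust(pv, method = adj_method)
  p_adj <- matrix(1, k, k, dimnames = list(nm, nm))
  p_adj[upper.tri(p_adj)] <- pa
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  diag(p_raw) <- 1
  list(z = z, p_adjusted = p_adj, p_raw = p_raw)
}

#' Glass' delta effect size
#'
#' Standardized mean difference using the reference group's sample standard
#' deviation as denominator:
#' \eqn{\Delta = (\bar x_{roi} - \bar x_{ref}) / s_{ref}}. In the regional
#' analyses the whole cortex is the reference group; an effect is regarded
#' as large when \eqn{|\Delta| > 0.8}.
#'
#' @param roi_values numeric vector of the focal sample.
#' @param cortex_values numeric vector of the reference sample (n >= 2, SD
#'   strictly positive).
#' @return numeric `Delta` with attribute `large` (logical).
#' @export
glass_delta <- function(roi_values, cortex_values) {
  if (length(cortex_values) < 2L) stop("reference group needs n >= 2")
  s <- stats::sd(cortex_values)
  if (!is.finite(s) || s == 0) stop("reference group SD must be positive")
  d <- (mean(roi_values) - mean(cortex_values)) / s
  structure(d, large = abs(d) > 0.8)
}

#' Linear model over a biomarker table
#'
#' Ordinary least squares with treatment coding; the region factor is
#' releveled so the whole cortex is the reference, making region coefficients
#' (and, with `interactions = TRUE`, duration x region coefficients) read
#' directly as offsets and slope differences from cortex.
#'
#' @param table data.frame with the response column plus any of `duration`,
#'   `latency`, `roi`, `group`, `memory_status`.
#' @param response name of the response column.
#' @param terms character vector of predictor names (subset of the above).
#' @param interactions if `TRUE`, `duration` (when present) interacts with
#'   `roi`.
#' @return list of class `qt1_lm` with `coefficients` (data.frame: term,
#'   estimate, se, p), `formula`, `n` and the underlying `fit`.
#' @export
fit_linear_model <- function(table, response,
                             terms = c("duration", "roi"),
                             interactions = FALSE) {
  stopifnot(response %in% names(table))
  known <- c("duration", "latency", "roi", "group", "memory_status")
  bad <- setdiff(terms, known)
  if (length(bad)) stop("unknown terms: ", paste(bad, collapse = ", "))
  if (!all(terms %in% names(table)))
    stop("table lacks columns: ",
         paste(setdiff(terms, names(table)), collapse = ", "))
  tab <- table
  if ("roi" %in% terms) {
    fam <- roi_family(as.character(tab$roi))
    tab$roi <- stats::relevel(factor(fam), ref = "cortex")
  }
  rhs <- terms
  if (interactions && all(c("duration", "roi") %in% terms)) {
    rhs <- setdiff(rhs, c("duration", "roi"))
    rhs <- c("duration * roi", rhs)
  }
  fml <- stats::reformulate(rhs, response = response)
  fit <- stats::lm(fml, data = tab)
  cf <- stats::coef(fit)
  if (any(is.na(cf)))
    stop("design matrix is rank deficient; aliased terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)$coefficients
  list(coefficients = data.frame(term = rownames(sm),
                                 estimate = sm[, 1], se = sm[, 2],
                                 p = sm[, 4], row.names = NULL,
                                 stringsAsFactors = FALSE),
       formula = deparse(fml), n = stats::nobs(fit), fit = fit) |>
    structure(class = "qt1_lm")
}

#' @export
print.qt1_lm <- function(x, ...) {
  cat("<qt1_lm>", x$formula, sprintf(" (n = %d)\n", x$n))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Memory-impairment classification
#'
#' Scores are standardized to a normative sample with mean 100 and SD 10;
#' impairment is assumed for scores strictly below 90, i.e. more than one SD
#' below the normative mean. A score of exactly 90 is unimpaired. Missing
#' scores give a missing status, which excludes the subject from
#' memory-stratified analyses.
#'
#' @param score numeric standardized memory score(s).
#' @param domain `"verbal"` or `"figural"` (recorded, same rule for both).
#' @return character vector: `"impaired"`, `"unimpaired"` or `NA`.
#' @export
classify_memory <- function(score, domain = c("verbal", "figural")) {
  domain <- match.arg(domain)
  ifelse(is.na(score), NA_character_,
         ifelse(score < 90, "impaired", "unimpaired"))
}

bilateral_average <- function(table) {
  tab <- table
  tab$family <- roi_family(as.character(tab$roi))
  agg <- stats::aggregate(value ~ id + family + kind, data = tab, FUN = mean)
  agg
}

dunn_vs_cortex <- function(values_by_family, adjustment = "bonferroni") {
  dn <- dunn_posthoc(values_by_family, adjustment = adjustment)
  fams <- setdiff(names(values_by_family), "cortex")
  stats_rows <- lapply(fams, function(f) {
    gd <- glass_delta(values_by_family[[f]], values_by_family$cortex)
    data.frame(roi = f, dunn_p_vs_cortex = dn$p_adjusted["cortex", f],
               glass_delta = as.numeric(gd), large_effect = attr(gd, "large"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, stats_rows)
}

#' Cohort-level analysis battery
#'
#' Runs the study's analysis matrix on a tidy cohort table (the `table`
#' element of [simulate_cohort()] or the output of [run_cohort()]):
#'
#' * `roi_comparison` — per subgroup (TLE, ETLE) and map kind, Kruskal-Wallis
#'   across the bilateral-averaged regions (cortex, hippocampus, amygdala,
#'   piriform), Dunn post hoc p-values versus cortex and Glass' delta with
#'   cortex as reference. Regions measured in the same subjects are compared
#'   with unpaired rank tests, replicating the published analysis; see the
#'   package vignette for the paired alternative.
#' * `duration_regression` — OLS of the biomarker on duration of epilepsy and
#'   region (plus the matching injection-to-scan latency), with and without
#'   duration x region interaction, across all subjects.
#' * `ipsilateral` — subjects with known seizure-onset side only: regional
#'   values from the ipsilateral hemisphere, regression on latency x region,
#'   plus the regional comparison battery.
#' * `memory` — subjects with impaired verbal (left hemisphere) or figural
#'   (right hemisphere) memory: regional comparison battery on the
#'   material-specific hemisphere.
#'
#' Scenarios whose prerequisites are unmet (e.g. no subject with known side)
#' are skipped with a logged reason rather than failing the run.
#'
#' @param table long tidy data.frame with columns `id`, `group`, `side`,
#'   `duration`, `latency_ii`, `latency_pi`, `verbal_memory`,
#'   `figural_memory`, `roi`, `hemisphere`, `kind`, `value`.
#' @param scenarios subset of
#'   `c("roi_comparison", "duration_regression", "ipsilateral", "memory")`.
#' @param adjustment Dunn adjustment method, see [dunn_posthoc()].
#' @return list of result data.frames per scenario plus `skipped` (named
#'   character vector of reasons).
#' @export
run_group_analyses <- function(table,
                               scenarios = c("roi_comparison",
                                             "duration_regression",
                                             "ipsilateral", "memory"),
                               adjustment = "bonferroni") {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  need <- c("id", "group", "duration", "roi", "kind", "value")
  if (!all(need %in% names(table)))
    stop("cohort table lacks columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  table <- table[order(table$id, table$kind, table$roi), ]  # row-order invariance
  out <- list(skipped = character(0))

  if ("roi_comparison" %in% scenarios) {
    avg <- bilateral_average(table)
    covar <- unique(table[, c("id", "group")])
    avg <- merge(avg, covar, by = "id")
    rows <- list()
    for (g in unique(avg$group)) for (kd in unique(avg$kind)) {
      sub <- avg[avg$group == g & avg$kind == kd, ]
      fams <- split(sub$value, sub$family)
      fams <- fams[c("cortex", setdiff(names(fams), "cortex"))]
      kw <- kruskal_wallis(fams)
      vs <- dunn_vs_cortex(fams, adjustment)
      rows[[paste(g, kd)]] <- cbind(data.frame(group = g, kind = kd,
                                               n = length(fams$cortex),
                                               kw_H = kw$H, kw_p = kw$p), vs)
    }
    out$roi_comparison <- do.call(rbind, c(rows, make.row.names = FALSE))
  }

  if ("duration_regression" %in% scenarios) {
    rows <- list()
    for (kd in c("ni", "ip")) {
      sub <- table[table$kind == kd, ]
      if (!nrow(sub)) next
      sub$latency <- if (kd == "ni") sub$latency_ii else sub$latency_pi
      for (inter in c(FALSE, TRUE)) {
        fit <- fit_linear_model(sub, "value",
                                terms = c("duration", "latency", "roi"),
                                interactions = inter)
        cf <- fit$coefficients
        cf$kind <- kd
        cf$model <- if (inter) "duration * roi" else "duration + roi"
        rows[[paste(kd, inter)]] <- cf
      }
    }
    out$duration_regression <- do.call(rbind, c(rows, make.row.names = FALSE))
  }

  if ("ipsilateral" %in% scenarios) {
    known <- table[table$side %in% c("left", "right"), ]
    if (!nrow(known)) {
      out$skipped <- c(out$skipped,
                       ipsilateral = "no subject with known seizure-onset side")
    } else {
      ipsi <- known[known$hemisphere == "both" |
                      known$hemisphere == known$side, ]
      rows <- list()
      for (kd in unique(ipsi$kind)) {
        sub <- ipsi[ipsi$kind == kd, ]
        sub$latency <- if (kd == "ni") sub$latency_ii else sub$latency_pi
        fit <- fit_linear_model(sub, "value", terms = c("latency", "roi"),
                                interactions = FALSE)
        # latency x roi interaction model as published
        sub$roi_fam <- stats::relevel(factor(roi_family(as.character(sub$roi))),
                                      ref = "cortex")
        fit2 <- stats::lm(value ~ latency * roi_fam, data = sub)
        sm <- summary(fit2)$coefficients
        cf <- data.frame(term = rownames(sm), estimate = sm[, 1],
                         se = sm[, 2], p = sm[, 4], kind = kd,
                         model = "latency * roi", row.names = NULL,
                         stringsAsFactors = FALSE)
        fams <- split(sub$value, roi_family(as.character(sub$roi)))
        fams <- fams[c("cortex", setdiff(names(fams), "cortex"))]
        vs <- dunn_vs_cortex(fams, adjustment)
        vs$kind <- kd
        vs$n <- length(unique(sub$id))
        rows[[kd]] <- list(regression = cf, comparison = vs)
      }
      out$ipsilateral <- list(
        regression = do.call(rbind, c(lapply(rows, `[[`, "regression"),
                                      make.row.names = FALSE)),
        comparison = do.call(rbind, c(lapply(rows, `[[`, "comparison"),
                                      make.row.names = FALSE)))
    }
  }

  if ("memory" %in% scenarios) {
    specs <- list(verbal = list(col = "verbal_memory", hemi = "left"),
                  figural = list(col = "figural_memory", hemi = "right"))
    rows <- list()
    for (dom in names(specs)) {
      sp <- specs[[dom]]
      if (!sp$col %in% names(table)) {
        out$skipped <- c(out$skipped,
                         stats::setNames(paste("missing", sp$col), paste0("memory_", dom)))
        next
      }
      status <- classify_memory(table[[sp$col]], dom)
      imp <- table[!is.na(status) & status == "impaired" & table$kind == "ni" &
                     (table$hemisphere %in% c("both", sp$hemi)), ]
      if (length(unique(imp$id)) < 3) {
        out$skipped <- c(out$skipped,
                         stats::setNames("fewer than 3 impaired subjects", paste0("memory_", dom)))
        next
      }
      fams <- split(imp$value, roi_family(as.character(imp$roi)))
      fams <- fams[c("cortex", setdiff(names(fams), "cortex"))]
      vs <- dunn_vs_cortex(fams, adjustment)
      vs$domain <- dom
      vs$hemisphere <- sp$hemi
      vs$n <- length(unique(imp$id))
      rows[[dom]] <- vs
    }
    if (length(rows))
      out$memory <- do.call(rbind, c(rows, make.row.names = FALSE))
  }

  out
}
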