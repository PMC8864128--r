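.T1_SCALES <- c("attitude", "subjective_norm", "perceived_behavioral_control",
                "baseline_intention", "past_behavior", "prevention_focus",
                "promotion_focus", "perceived_susceptibility",
                "perceived_severity", "food_involvement", "perceived_risk",
                "perceived_benefit", "hedonism", "diffused_responsibility",
                "desensitization", "denial_negative_consequences")
.T2_SCALES <- c("systematic_processing", "message_involvement",
                "message_distress", "future_intention")

#' Default scale calibration (entire-sample means and SDs)
#'
#' One row per psychosocial scale: the calibration targets of the synthetic
#' cohort generator. All scales live on a 1-7 Likert range except past
#' behavior, measured in servings per week (lower bound 0).
#'
#' Note: the printed entire-sample SD for baseline intention (3.10) exceeds
#' the largest SD attainable on a bounded 1-7 scale at its mean; the
#' generator matches the mean exactly and gets as close to the SD as the
#' bounds allow (see the methods vignette).
#'
#' @return Data frame with columns `scale`, `mean`, `sd`, `lower`, `upper`.
#' @export
scale_defaults <- function() {
  d <- data.frame(
    scale = c(.T1_SCALES, .T2_SCALES),
    mean = c(4.61, 3.55, 4.23, 4.16, 6.99, 4.64, 5.02, 4.02, 4.16, 5.27,
             3.67, 4.08, 4.75, 3.68, 3.66, 4.30,
             4.38, 4.10, 1.64, 4.38),
    sd = c(1.34, 1.40, 1.19, 3.10, 3.52, 0.97, 0.97, 1.05, 0.63, 1.14,
           1.19, 1.27, 1.40, 1.20, 0.58, 1.19,
           1.25, 1.47, 0.68, 0.90),
    lower = 1, upper = 7,
    stringsAsFactors = FALSE)
  d$lower[d$scale == "past_behavior"] <- 0
  d$upper[d$scale == "past_behavior"] <- Inf
  d
}

#' Default ground-truth structural coefficients for the likert generator
#'
#' Framing main effects on intention change, framing-by-moderator
#' interactions (baseline intention, prevention focus, perceived severity,
#' diffused responsibility), mediated coefficients through systematic
#' processing (promotion focus, food involvement, perceived behavioral
#' control, desensitization), and the baseline-to-future intention
#' carryover. Moderators enter standardized (centered by the configured
#' mean, scaled by the configured SD); effects are in Likert points.
#'
#' @return Named list of coefficient blocks.
#' @export
effect_defaults <- function() {
  inter <- rbind(gain    = c(-0.15, -0.15,  0.15, -0.05),
                 nonloss = c(-0.15,  0.15, -0.15, -0.05),
                 nongain = c( 0.15, -0.15, -0.15, -0.05),
                 loss    = c( 0.15,  0.15,  0.15, -0.05))
  colnames(inter) <- c("baseline_intention", "prevention_focus",
                       "perceived_severity", "diffused_responsibility")
  list(main = c(gain = 0.15, nonloss = 0.05, nongain = -0.05, loss = -0.15),
       interactions = inter,
       mediation_in = c(promotion_focus = 0.25, food_involvement = 0.25,
                        perceived_behavioral_control = 0.20,
                        desensitization = -0.20),
       sp_framing = c(gain = 0.2, nonloss = 0.1, nongain = -0.1, loss = -0.2),
       mediation_out = 0.30,
       carryover = 0.60)
}

#' Configure the synthetic cohort generator
#'
#' Defaults reproduce the study conditions: 834 initial respondents,
#' four-arm randomization proportional to 134/134/136/141, entire-sample
#' scale calibration, and the study's exclusion burden (124 special-diet
#' respondents of 834; low-meat eaters arise from the past-behavior
#' distribution itself; 70 incomplete responders of the remainder).
#'
#' @param n Initial cohort size (positive integer).
#' @param seed Integer seed (mandatory; generation is bit-reproducible).
#' @param arms Named positive weights over the four framings; condition is
#'   assigned independently of all Time-1 variables with probabilities
#'   proportional to the weights.
#' @param scales Calibration table as in [scale_defaults()].
#' @param effects Structural coefficients as in [effect_defaults()].
#' @param noise_sd SD of the residual noise on intention change (Likert
#'   points).
#' @param special_diet_rate Probability of the special-diet flag.
#' @param incomplete_rate Probability that a respondent fails to complete
#'   both questionnaires.
#' @param low_meat_threshold Weekly servings below which a respondent is
#'   excluded (default 3).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n = 834L, seed,
                          arms = c(gain = 134, nonloss = 134,
                                   nongain = 136, loss = 141),
                          scales = scale_defaults(),
                          effects = effect_defaults(),
                          noise_sd = 0.8,
                          special_diet_rate = 124 / 834,
                          incomplete_rate = 70 / 614,
                          low_meat_threshold = 3) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("n must be a positive count", call. = FALSE)
  stopifnot(is.data.frame(scales),
            all(c("scale", "mean", "sd", "lower", "upper") %in% names(scales)))
  unknown <- setdiff(scales$scale, c(.T1_SCALES, .T2_SCALES))
  if (length(unknown))
    stop("unknown scale name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (any(scales$sd <= 0)) stop("scale sds must be > 0", call. = FALSE)
  if (!setequal(names(arms), .FRAMINGS) || any(arms <= 0))
    stop("arms must be positive weights named ",
         paste(.FRAMINGS, collapse = ", "), call. = FALSE)
  eff_vars <- c(colnames(effects$interactions), names(effects$mediation_in))
  bad <- setdiff(eff_vars, scales$scale)
  if (length(bad))
    stop("effect coefficients reference absent variable(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- list(n = as.integer(n), seed = as.integer(seed),
              arms = arms[.FRAMINGS] / sum(arms),
              scales = scales, effects = effects, noise_sd = noise_sd,
              special_diet_rate = special_diet_rate,
              incomplete_rate = incomplete_rate,
              low_meat_threshold = low_meat_threshold)
  class(out) <- "cohort_config"
  out
}

## Latent clipped-normal parameters matched to target moments (cached).
.latent_cache <- new.env(parent = emptyenv())

.clip_moments <- function(mu, sigma, L, U) {
  a <- if (is.finite(L)) (L - mu) / sigma else -Inf
  b <- if (is.finite(U)) (U - mu) / sigma else Inf
  Fa <- stats::pnorm(a); Fb <- stats::pnorm(b)
  fa <- stats::dnorm(a); fb <- stats::dnorm(b)
  termL <- if (is.finite(L)) L * Fa else 0
  termU <- if (is.finite(U)) U * (1 - Fb) else 0
  m1 <- termL + termU + mu * (Fb - Fa) + sigma * (fa - fb)
  afa <- if (is.finite(a)) a * fa else 0
  bfb <- if (is.finite(b)) b * fb else 0
  m2 <- (if (is.finite(L)) L^2 * Fa else 0) +
    (if (is.finite(U)) U^2 * (1 - Fb) else 0) +
    mu^2 * (Fb - Fa) + 2 * mu * sigma * (fa - fb) +
    sigma^2 * ((Fb - Fa) + afa - bfb)
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

.latent_params <- function(mean, sd, lower, upper) {
  key <- sprintf("%.10g|%.10g|%g|%g", mean, sd, lower, upper)
  hit <- .latent_cache[[key]]
  if (!is.null(hit)) return(hit)
  obj <- function(p) {
    mm <- .clip_moments(p[1L], exp(p[2L]), lower, upper)
    100 * (mm[["mean"]] - mean)^2 + (mm[["sd"]] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj,
                      control = list(maxit = 2000, reltol = 1e-12))
  out <- c(mu = fit$par[1L], sigma = exp(fit$par[2L]))
  .latent_cache[[key]] <- out
  out
}

.draw_scale <- function(n, mean, sd, lower, upper) {
  p <- .latent_params(mean, sd, lower, upper)
  pmin(upper, pmax(lower, stats::rnorm(n, p[["mu"]], p[["sigma"]])))
}

#' Generate a synthetic two-wave cohort
#'
#' In `likert` mode, Time-1 scores are clipped-Gaussian draws whose latent
#' parameters are moment-matched so the clipped scores reproduce the
#' configured means and SDs; condition is randomized independently of all
#' Time-1 variables; Time-2 scores add the configured structural terms
#' (framing main effects, framing-by-moderator interactions, mediation
#' through systematic processing, baseline carryover) on top of calibrated
#' draws; `delta_intention = future_intention - baseline_intention`.
#' In `categorical` mode, records are ancestrally sampled from a supplied
#' ground-truth network. Identical seeds give bit-identical tables.
#'
#' @param config A [cohort_config()].
#' @param mode `"likert"` (continuous scores) or `"categorical"`
#'   (sampling from a ground-truth discrete network).
#' @param network For categorical mode: `list(structure =, cpts =)`.
#' @return Data frame with one row per initial respondent: `id`, the
#'   Time-1 scales, eligibility flags (`special_diet`, `complete`),
#'   `condition`, the Time-2 scales, and `delta_intention` (likert mode).
#' @export
simulate_cohort <- function(config, mode = c("likert", "categorical"),
                            network = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  mode <- match.arg(mode)
  set.seed(config$seed)
  n <- config$n
  if (mode == "categorical") {
    if (is.null(network) || is.null(network$structure) ||
        is.null(network$cpts))
      stop("categorical mode needs network = list(structure =, cpts =)",
           call. = FALSE)
    df <- sample_network(network$structure, network$cpts, n)
    return(cbind(id = sprintf("p%05d", seq_len(n)), df,
                 stringsAsFactors = FALSE))
  }

  sc <- config$scales
  row_of <- function(v) sc[match(v, sc$scale), ]
  draw <- function(v) {
    r <- row_of(v)
    .draw_scale(n, r$mean, r$sd, r$lower, r$upper)
  }
  zscore <- function(x, v) {
    r <- row_of(v)
    (x - r$mean) / r$sd
  }
  t1 <- setNames(lapply(.T1_SCALES, draw), .T1_SCALES)

  condition <- factor(sample(.FRAMINGS, n, replace = TRUE,
                             prob = config$arms),
                      levels = .FRAMINGS)
  special_diet <- stats::runif(n) < config$special_diet_rate
  complete <- stats::runif(n) >= config$incomplete_rate

  eff <- config$effects
  lp_sp <- unname(eff$sp_framing[as.character(condition)])
  for (v in names(eff$mediation_in))
    lp_sp <- lp_sp + eff$mediation_in[[v]] * zscore(t1[[v]], v)
  sp <- pmin(7, pmax(1, draw("systematic_processing") + lp_sp))

  message_involvement <- draw("message_involvement")
  message_distress <- draw("message_distress")

  lp <- unname(eff$main[as.character(condition)]) +
    eff$mediation_out * zscore(sp, "systematic_processing") +
    stats::rnorm(n, 0, config$noise_sd)
  for (v in colnames(eff$interactions))
    lp <- lp + eff$interactions[as.character(condition), v] *
      zscore(t1[[v]], v)
  rf <- row_of("future_intention"); rb <- row_of("baseline_intention")
  future <- pmin(7, pmax(1, rf$mean +
                           eff$carryover * (t1$baseline_intention - rb$mean) +
                           lp))

  out <- data.frame(id = sprintf("p%05d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (v in .T1_SCALES) out[[v]] <- t1[[v]]
  out$special_diet <- special_diet
  out$complete <- complete
  out$condition <- condition
  out$systematic_processing <- sp
  out$message_involvement <- message_involvement
  out$message_distress <- message_distress
  out$future_intention <- future
  out$delta_intention <- delta_intention(out$baseline_intention, future)
  out
}

#' Intention change between the two waves
#'
#' `future - baseline`, both on the 1-7 intention scale, giving a value in
#' `[-6, 6]`.
#'
#' @param baseline,future Numeric vectors in `[1, 7]`.
#' @return Numeric vector of intention changes.
#' @export
delta_intention <- function(baseline, future) {
  if (any(baseline < 1 | baseline > 7, na.rm = TRUE) ||
      any(future < 1 | future > 7, na.rm = TRUE))
    stop("intention scores must lie in [1, 7]", call. = FALSE)
  future - baseline
}

#' Apply the study's eligibility filter
#'
#' Removes, in order: respondents on a special diet, respondents eating
#' fewer weekly servings of red/processed meat than the threshold, and
#' respondents who did not complete both questionnaires. A record
#' triggering several rules is counted only under the first rule applied.
#'
#' @param cohort Data frame with columns `special_diet` (logical),
#'   `past_behavior` (servings/week) and `complete` (logical).
#' @param low_meat_threshold Weekly servings cutoff (default 3).
#' @return List with `cohort` (survivors) and `counts` (named removals per
#'   rule); survivors + removals equal the input count.
#' @export
apply_exclusions <- function(cohort, low_meat_threshold = 3) {
  need <- c("special_diet", "past_behavior", "complete")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  r1 <- cohort$special_diet
  r2 <- !r1 & cohort$past_behavior < low_meat_threshold
  r3 <- !r1 & !r2 & !cohort$complete
  keep <- !(r1 | r2 | r3)
  list(cohort = cohort[keep, , drop = FALSE],
       counts = c(special_diet = sum(r1), low_meat = sum(r2),
                  incomplete = sum(r3)))
}

#' Read/write a cohort table as CSV
#'
#' Fixed dialect: comma separator, `.` decimal, UTF-8, header row with the
#' canonical scale names; condition values are exactly
#' `gain|nonloss|nongain|loss`.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the
#'   data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if ("condition" %in% names(df))
    df$condition <- factor(df$condition, levels = .FRAMINGS)
  df
}

#' Read/write a generator configuration (JSON)
#'
#' @param config A [cohort_config()].
#' @param path File path.
#' @return `write_cohort_config` returns `path` invisibly;
#'   `read_cohort_config` the restored config.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  ser <- unclass(config)
  ser$arms <- as.list(config$arms)           # keep names through JSON
  ser$effects$main <- as.list(config$effects$main)
  ser$effects$mediation_in <- as.list(config$effects$mediation_in)
  ser$effects$sp_framing <- as.list(config$effects$sp_framing)
  ser$effects$interactions <-
    list(rows = rownames(config$effects$interactions),
         cols = colnames(config$effects$interactions),
         values = unname(apply(config$effects$interactions, 1L, c,
                               simplify = FALSE)))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- raw$effects$interactions$values
  inter <- if (is.matrix(vals)) vals else do.call(rbind, vals)
  dimnames(inter) <- list(raw$effects$interactions$rows,
                          raw$effects$interactions$cols)
  eff <- list(main = unlist(raw$effects$main),
              interactions = inter,
              mediation_in = unlist(raw$effects$mediation_in),
              sp_framing = unlist(raw$effects$sp_framing),
              mediation_out = raw$effects$mediation_out,
              carryover = raw$effects$carryover)
  cohort_config(n = raw$n, seed = raw$seed, arms = unlist(raw$arms),
                scales = as.data.frame(raw$scales), effects = eff,
                noise_sd = raw$noise_sd,
                special_diet_rate = raw$special_diet_rate,
                incomplete_rate = raw$incomplete_rate,
                low_meat_threshold = raw$low_meat_threshold)
}
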