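.FRAMINGS <- c("gain", "nonloss", "nongain", "loss")

.RPMC_T1_DIRECT <- c("baseline_intention", "prevention_focus",
                     "perceived_severity", "diffused_responsibility")
.RPMC_T1_MEDIATED <- c("promotion_focus", "food_involvement",
                       "perceived_behavioral_control", "desensitization")

#' Reference message-framing network for the red/processed-meat study
#'
#' The three-slice structure over the study's retained dimensions: eight
#' ternary Time-1 antecedents, the four-framing message node, the ternary
#' systematic-processing mediator, and the five-category intention-change
#' outcome. Message framing acts on the outcome both directly and through
#' systematic processing; baseline intention, prevention focus, perceived
#' severity and diffused responsibility act directly on intention change,
#' while promotion focus, food involvement, perceived behavioral control
#' and desensitization act through the mediator.
#'
#' @return A [bn_structure()] with 11 nodes and 11 arcs.
#' @export
rpmc_network <- function() {
  t1 <- c(.RPMC_T1_DIRECT, .RPMC_T1_MEDIATED)
  vars <- c(
    lapply(t1, bn_variable, slice = "T1", categories = .TERNARY_LABELS),
    list(bn_variable("condition", "MESSAGE", .FRAMINGS),
         bn_variable("systematic_processing", "T2", .TERNARY_LABELS),
         bn_variable("delta_intention", "OUTCOME", .OUTCOME_LABELS)))
  arcs <- c(
    list(c("condition", "delta_intention"),
         c("condition", "systematic_processing"),
         c("systematic_processing", "delta_intention")),
    lapply(.RPMC_T1_DIRECT, function(v) c(v, "delta_intention")),
    lapply(.RPMC_T1_MEDIATED, function(v) c(v, "systematic_processing")))
  bn_structure(vars, arcs)
}

#' Ground-truth CPTs from a latent ordinal response model
#'
#' Builds conditional probability tables for a network of the reference
#' graph class from an interpretable latent score: for each parent
#' configuration, a score `eta` accumulates a framing shift, weighted
#' centered parent levels, and framing-by-moderator interaction terms; the
#' node's category probabilities follow a proximity kernel
#' `p(k) propto exp(-beta (a_k - eta_scale * eta)^2)` over centered
#' category scores `a_k`. Larger `beta` gives sharper (more nearly
#' deterministic) rows; root nodes are uniform. Defaults give the strong
#' contrasts used by the recovery simulations.
#'
#' @param structure A [bn_structure()] (default [rpmc_network()]); every
#'   non-root node's parents must be the message node and/or categorical
#'   nodes.
#' @param beta Sharpness of the CPT rows (default 3).
#' @param eta_scale Compression of the latent score onto the category-score
#'   axis (default 0.5), keeping typical scores inside the category range.
#' @param outcome_shift Named framing shifts for the outcome's latent score.
#' @param outcome_weights Named weights of the outcome's categorical
#'   parents (centered levels; unlisted parents get weight 0).
#' @param interactions Framing x moderator matrix (rows named by framing,
#'   columns by moderator) added to the outcome's latent score.
#' @param mediator_shift,mediator_weights Same, for Time-2 nodes.
#' @return A `bn_cpts` (counts set to the probabilities; usable for
#'   sampling and inference).
#' @export
rpmc_cpts <- function(structure = rpmc_network(), beta = 3, eta_scale = 0.5,
                      outcome_shift = c(gain = 0.9, nonloss = 0.3,
                                        nongain = -0.3, loss = -0.9),
                      outcome_weights = c(baseline_intention = 1,
                                          prevention_focus = 1,
                                          perceived_severity = -1,
                                          diffused_responsibility = -1,
                                          systematic_processing = 1),
                      interactions = .default_interactions(),
                      mediator_shift = c(gain = 0.5, nonloss = 0.2,
                                         nongain = -0.2, loss = -0.5),
                      mediator_weights = c(promotion_focus = 1,
                                           food_involvement = 1,
                                           perceived_behavioral_control = 1,
                                           desensitization = -1)) {
  stopifnot(inherits(structure, "bn_structure"))
  msg <- .message_var(structure)
  z <- .outcome_var(structure)
  cards <- .cards(structure)
  cpts <- setNames(vector("list", length(structure$order)), structure$order)
  for (v in structure$order) {
    pa <- structure$parents[[v]]
    k <- cards[[v]]
    cats <- structure$variables[[v]]$categories
    if (!length(pa)) {
      prob <- matrix(1 / k, nrow = 1L, ncol = k,
                     dimnames = list("", cats))
    } else {
      shift <- if (v == z) outcome_shift else mediator_shift
      w <- if (v == z) outcome_weights else mediator_weights
      inter <- if (v == z) interactions else NULL
      grid <- as.matrix(do.call(expand.grid,
                                c(lapply(cards[pa], seq_len),
                                  list(KEEP.OUT.ATTRS = FALSE))))
      colnames(grid) <- pa
      framings <- if (!is.null(msg)) structure$variables[[msg]]$categories
      eta <- rep(0, nrow(grid))
      for (p0 in pa) {
        if (!is.null(msg) && p0 == msg) {
          eta <- eta + shift[framings][grid[, p0]]
        } else if (p0 %in% names(w)) {
          eta <- eta + w[[p0]] * (grid[, p0] - (cards[[p0]] + 1) / 2)
        }
      }
      if (!is.null(inter) && !is.null(msg) && msg %in% pa) {
        for (mod in intersect(colnames(inter), pa))
          eta <- eta +
            inter[framings, mod][grid[, msg]] *
            (grid[, mod] - (cards[[mod]] + 1) / 2)
      }
      a <- seq_len(k) - (k + 1) / 2
      logit <- -beta * outer(eta_scale * eta, a, `-`)^2
      prob <- exp(logit - apply(logit, 1L, max))
      prob <- prob / rowSums(prob)
      dimnames(prob) <- list(.config_keys(structure, pa), cats)
    }
    cpts[[v]] <- list(node = v, parents = pa, counts = prob, prob = prob,
                      alpha = 0)
  }
  class(cpts) <- "bn_cpts"
  cpts
}

.default_interactions <- function() {
  m <- rbind(gain    = c(-0.5, -0.5,  0.5),
             nonloss = c(-0.5,  0.5, -0.5),
             nongain = c( 0.5, -0.5, -0.5),
             loss    = c( 0.5,  0.5,  0.5))
  colnames(m) <- c("baseline_intention", "prevention_focus",
                   "perceived_severity")
  m
}

#' Variable specifications from a discretized study table
#'
#' Convenience builder: declares every listed column as a network variable
#' with its factor levels as ordered categories and the given slice tags.
#'
#' @param data Data frame of factors (e.g. from [apply_discretization()]).
#' @param t1 Character vector of Time-1 variable names.
#' @param t2 Character vector of Time-2 variable names.
#' @param message Name of the message-condition column.
#' @param outcome Name of the outcome column.
#' @return List of [bn_variable()] specs.
#' @export
study_variables <- function(data, t1, t2, message = "condition",
                            outcome = "delta_intention") {
  mk <- function(v, slice) {
    col <- data[[v]]
    if (is.null(col)) stop("data lacks column '", v, "'", call. = FALSE)
    if (!is.factor(col)) col <- factor(col)
    bn_variable(v, slice, levels(col))
  }
  c(lapply(t1, mk, slice = "T1"),
    list(mk(message, "MESSAGE")),
    lapply(t2, mk, slice = "T2"),
    list(mk(outcome, "OUTCOME")))
}
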