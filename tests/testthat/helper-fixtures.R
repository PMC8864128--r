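## Shared fixtures and independent oracles.

T1_VARS <- c("baseline_intention", "prevention_focus", "perceived_severity",
             "diffused_responsibility", "promotion_focus", "food_involvement",
             "perceived_behavioral_control", "desensitization")
FRAMINGS <- c("gain", "nonloss", "nongain", "loss")
OUTCOME_CATS <- c("high-negative", "low-negative", "neutral",
                  "low-positive", "high-positive")

## A random DAG over n nodes with random category counts; the last node in
## the sampled order is the OUTCOME (a sink), all others Time-1.
random_network <- function(seed, max_nodes = 7L, arc_prob = 0.4,
                           cards = 2:3) {
  set.seed(seed)
  n <- sample(3:max_nodes, 1L)
  nms <- paste0("v", seq_len(n))
  kk <- sample(cards, n, replace = TRUE)
  vars <- lapply(seq_len(n), function(i)
    bn_variable(nms[i], if (i == n) "OUTCOME" else "T1",
                paste0("c", seq_len(kk[i]))))
  arcs <- list()
  for (i in seq_len(n - 1L))
    for (j in seq((i + 1L), n))
      if (stats::runif(1) < arc_prob)
        arcs[[length(arcs) + 1L]] <- c(nms[i], nms[j])
  bn_structure(vars, if (length(arcs)) arcs else NULL)
}

## Random Dirichlet CPT rows, keyed by the documented '|'-joined parent
## labels (first declared parent varying fastest).
random_cpts <- function(structure, seed) {
  set.seed(seed)
  cpts <- list()
  for (v in structure$order) {
    pa <- structure$parents[[v]]
    cats <- structure$variables[[v]]$categories
    keys <- if (!length(pa)) "" else {
      g <- do.call(expand.grid, c(lapply(pa, function(p)
        structure$variables[[p]]$categories),
        list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
      do.call(paste, c(g, sep = "|"))
    }
    pr <- matrix(stats::rgamma(length(keys) * length(cats), 1), nrow = length(keys),
                 dimnames = list(keys, cats))
    pr <- pr / rowSums(pr)
    cpts[[v]] <- list(node = v, parents = pa, counts = pr, prob = pr,
                      alpha = 0)
  }
  class(cpts) <- "bn_cpts"
  cpts
}

## Brute-force full-joint table: one row per complete assignment, with the
## probability computed by direct CPT lookups through the label keys
## (independent of the package's index arithmetic).
brute_joint <- function(structure, cpts) {
  grid <- do.call(expand.grid, c(lapply(structure$order, function(v)
    structure$variables[[v]]$categories),
    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  names(grid) <- structure$order
  p <- rep(1, nrow(grid))
  for (v in structure$order) {
    pa <- structure$parents[[v]]
    key <- if (!length(pa)) rep("", nrow(grid)) else
      do.call(paste, c(grid[pa], sep = "|"))
    p <- p * cpts[[v]]$prob[cbind(match(key, rownames(cpts[[v]]$prob)),
                                  match(grid[[v]],
                                        colnames(cpts[[v]]$prob)))]
  }
  grid$p <- p
  grid
}

## Brute-force posterior of `target` given label evidence, from the joint.
brute_posterior <- function(joint, target, evidence) {
  keep <- rep(TRUE, nrow(joint))
  for (v in names(evidence)) keep <- keep & joint[[v]] == evidence[[v]]
  sub <- joint[keep, ]
  tapply(sub$p, sub[[target]], sum, default = 0) / sum(sub$p)
}

## The engineered ground truth for prototype checks: framing effects driven
## purely by sign-patterned interactions with the three reported moderators,
## so that (high, high, high) maximizes the loss-framing effect.
tailored_cpts <- function(structure = rpmc_network()) {
  inter <- rbind(gain    = c(-1, -1,  1),
                 nonloss = c(-1,  1, -1),
                 nongain = c( 1, -1, -1),
                 loss    = c( 1,  1,  1))
  colnames(inter) <- c("baseline_intention", "prevention_focus",
                       "perceived_severity")
  rpmc_cpts(structure, beta = 1, eta_scale = 0.6,
            outcome_shift = c(gain = 0, nonloss = 0, nongain = 0, loss = 0),
            outcome_weights = c(baseline_intention = 0, prevention_focus = 0,
                                perceived_severity = 0,
                                diffused_responsibility = 0,
                                systematic_processing = 0),
            interactions = inter)
}

## Deterministic toy categorical dataset over the reference variables.
small_reference_data <- function(n, seed, cpts = rpmc_cpts()) {
  set.seed(seed)
  sample_network(rpmc_network(), cpts, n)
}

arc_key <- function(structure)
  paste(sort(paste(structure$arcs[, 1L], structure$arcs[, 2L], sep = ">")),
        collapse = ";")
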