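#' Serialize a network structure (and optional CPTs) to JSON
#'
#' Schema: `{variables: [{name, slice, categories}], arcs: [[parent,
#' child]], cpts: {node: {"<parent labels joined by |>": [probs]}}}`, the
#' parent-configuration key using the declared parent order.
#'
#' @param structure A [bn_structure()].
#' @param path File path.
#' @param cpts Optional CPTs to embed.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, cpts = NULL) {
  stopifnot(inherits(structure, "bn_structure"))
  doc <- list(
    variables = lapply(structure$variables, function(v)
      list(name = v$name, slice = v$slice,
           categories = as.list(v$categories))),
    arcs = if (nrow(structure$arcs))
      lapply(seq_len(nrow(structure$arcs)), function(i)
        as.list(unname(structure$arcs[i, ]))) else list())
  names(doc$variables) <- NULL
  if (!is.null(cpts)) {
    doc$cpts <- lapply(structure$order, function(v) {
      pr <- cpts[[v]]$prob
      out <- lapply(seq_len(nrow(pr)), function(r) unname(pr[r, ]))
      ## parentless nodes have the empty configuration; JSON object keys
      ## cannot be empty, so it is written as "(root)"
      names(out) <- ifelse(nzchar(rownames(pr)), rownames(pr), "(root)")
      out
    })
    names(doc$cpts) <- structure$order
    doc$alpha <- cpts[[1L]]$alpha
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a network structure (and optional CPTs) from JSON
#'
#' Validates the document against the graph-class constraints and, when
#' CPTs are present, checks that every row sums to 1 (within 1e-9) and
#' names the offending node and configuration otherwise. The built-in
#' reference network is loadable by name: `load_structure("rpmc")`.
#'
#' @param path File path, or `"rpmc"` for the built-in reference network.
#' @return List with `structure` and `cpts` (`NULL` when the file has
#'   none).
#' @export
load_structure <- function(path) {
  if (identical(path, "rpmc"))
    return(list(structure = rpmc_network(), cpts = NULL))
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    stop("unreadable structure JSON: ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(doc$variables))
    stop("structure JSON invalid: missing field 'variables'", call. = FALSE)
  vars <- lapply(doc$variables, function(v) {
    if (is.null(v$name) || is.null(v$slice) || is.null(v$categories))
      stop("structure JSON invalid: a variable lacks name/slice/categories",
           call. = FALSE)
    if (!v$slice %in% names(.SLICES))
      stop("structure JSON invalid: unknown slice tag '", v$slice,
           "' for variable '", v$name, "'", call. = FALSE)
    bn_variable(v$name, v$slice, unlist(v$categories))
  })
  arcs <- if (length(doc$arcs))
    lapply(doc$arcs, function(a) c(a[[1L]], a[[2L]])) else NULL
  struct <- tryCatch(bn_structure(vars, arcs),
                     error = function(e)
                       stop("structure JSON invalid: ", conditionMessage(e),
                            call. = FALSE))
  cpts <- NULL
  if (!is.null(doc$cpts)) {
    alpha <- if (!is.null(doc$alpha)) doc$alpha else NA_real_
    cards <- .cards(struct)
    cpts <- stats::setNames(vector("list", length(struct$order)),
                            struct$order)
    for (v in struct$order) {
      rows <- doc$cpts[[v]]
      if (is.null(rows))
        stop("structure JSON invalid: no CPT for node '", v, "'",
             call. = FALSE)
      pa <- struct$parents[[v]]
      keys <- .config_keys(struct, pa)
      pr <- matrix(NA_real_, nrow = length(keys), ncol = cards[[v]],
                   dimnames = list(keys, struct$variables[[v]]$categories))
      for (r in seq_along(keys)) {
        row <- rows[[if (nzchar(keys[r])) keys[r] else "(root)"]]
        if (is.null(row) || length(row) != cards[[v]])
          stop("structure JSON invalid: CPT of '", v,
               "' lacks configuration '", keys[r], "'", call. = FALSE)
        pr[r, ] <- unlist(row)
      }
      bad <- which(abs(rowSums(pr) - 1) > 1e-9)
      if (length(bad))
        stop("structure JSON invalid: CPT row of '", v,
             "' does not sum to 1 (configuration '", keys[bad[1L]], "')",
             call. = FALSE)
      cpts[[v]] <- list(node = v, parents = pa, counts = pr, prob = pr,
                        alpha = alpha)
    }
    class(cpts) <- "bn_cpts"
  }
  list(structure = struct, cpts = cpts)
}

#' Deterministic per-stage seed derivation
#'
#' Each pipeline stage reseeds from the global seed and its own name, so a
#' stage can be rerun in isolation and reproduce the composed run exactly.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 65537 + h) %% 2147483647)
}

#' Configure a full pipeline run
#'
#' @param output_dir Directory for all stage outputs.
#' @param seed Global seed (mandatory); stage seeds derive from it via
#'   [stage_seed()].
#' @param cohort Generator settings ([cohort_config()]; its seed is
#'   overridden by the simulate stage seed).
#' @param structure `NULL` to elicit the structure from the data,
#'   `"rpmc"` for the built-in reference network, or a path to a
#'   structure JSON.
#' @param control Search settings ([search_control()]).
#' @param alpha CPT smoothing pseudo-count.
#' @param weights Utility weights.
#' @param q Prototype quantile fraction.
#' @param embed Also compute the t-SNE embedding (default `FALSE`; it is
#'   visualization only and costly at population scale).
#' @param t1,t2 Variable rosters used for the network (defaults: the
#'   reference network's eight Time-1 antecedents and the
#'   systematic-processing mediator).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, seed,
                            cohort = cohort_config(seed = 0L),
                            structure = "rpmc",
                            control = search_control(),
                            alpha = 1,
                            weights = utility_weights(),
                            q = 0.02,
                            embed = FALSE,
                            t1 = c(.RPMC_T1_DIRECT, .RPMC_T1_MEDIATED),
                            t2 = "systematic_processing") {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  out <- list(output_dir = output_dir, seed = as.integer(seed),
              cohort = cohort, structure = structure, control = control,
              alpha = alpha, weights = weights, q = q,
              embed = isTRUE(embed), t1 = t1, t2 = t2)
  class(out) <- "pipeline_config"
  out
}

#' Run the full analysis pipeline
#'
#' simulate -> exclude -> delta -> discretize -> elicit (or load a fixed
#' structure) -> fit -> profile -> prototypes, writing every stage output
#' plus a JSON manifest (seeds, versions, per-file MD5 checksums) under
#' `config$output_dir`. Identical config and seed give identical manifests.
#' A failing stage aborts with the stage named and leaves a
#' `<stage>.partial` marker.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted `model`, the `profile`, the
#'   `prototypes`, the written `files`, and the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out_path <- function(f) file.path(config$output_dir, f)
  files <- character()
  seeds <- list()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      file.create(out_path(paste0(stage, ".partial")))
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## simulate
  seeds$simulate <- stage_seed(config$seed, "simulate")
  cohort <- run_stage("simulate", {
    cc <- config$cohort
    cc$seed <- seeds$simulate
    co <- simulate_cohort(cc)
    write_cohort(co, out_path("cohort.csv"))
    co
  })
  files <- c(files, "cohort.csv")

  ## exclude (delta intention is already constructed by the generator)
  filtered <- run_stage("exclude", {
    ex <- apply_exclusions(cohort, config$cohort$low_meat_threshold)
    write_cohort(ex$cohort, out_path("cohort_filtered.csv"))
    jsonlite::write_json(as.list(ex$counts), out_path("exclusions.json"),
                         auto_unbox = TRUE)
    ex$cohort
  })
  files <- c(files, "cohort_filtered.csv", "exclusions.json")

  ## discretize
  disc <- run_stage("discretize", {
    vars <- c(config$t1, config$t2, "delta_intention")
    map <- fit_discretization(filtered[vars])
    write_discretization(map, out_path("discretization.json"))
    dd <- apply_discretization(filtered[c(vars, "condition")], map)
    write_cohort(dd, out_path("cohort_categorical.csv"))
    dd
  })
  files <- c(files, "discretization.json", "cohort_categorical.csv")

  ## elicit or load, then fit
  model <- run_stage("fit", {
    if (is.null(config$structure)) {
      vars <- study_variables(disc, t1 = config$t1, t2 = config$t2)
      framing_dbn(disc, variables = vars, alpha = config$alpha,
                  control = config$control, weights = config$weights)
    } else {
      struct <- if (inherits(config$structure, "bn_structure"))
        config$structure else load_structure(config$structure)$structure
      framing_dbn(disc, structure = struct, alpha = config$alpha,
                  weights = config$weights)
    }
  })
  run_stage("fit", write_structure(model$structure,
                                   out_path("structure.json"), model$cpts))
  files <- c(files, "structure.json")

  ## profile the enumerated population
  profile <- run_stage("profile", {
    pr <- profile_population(model, weights = config$weights)
    write_profile(pr, out_path("population.csv"))
    pr
  })
  files <- c(files, "population.csv")

  if (config$embed) {
    seeds$embed <- stage_seed(config$seed, "embed")
    run_stage("embed", {
      emb <- embed_population(profile, seed = seeds$embed)
      utils::write.csv(cbind(as.data.frame(profile), emb),
                       out_path("embedding.csv"), row.names = FALSE)
    })
    files <- c(files, "embedding.csv")
  }

  ## prototypes
  prototypes <- run_stage("prototypes", {
    pt <- extract_prototypes(profile, q = config$q)
    write_prototypes(pt, out_path("prototypes.json"))
    pt
  })
  files <- c(files, "prototypes.json")

  manifest <- list(
    package = as.character(utils::packageVersion("framecast")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stage_seeds = seeds,
    checksums = as.list(tools::md5sum(vapply(files, out_path, ""))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE)
  files <- c(files, "manifest.json")

  invisible(list(model = model, profile = profile, prototypes = prototypes,
                 files = vapply(files, out_path, ""), manifest = manifest))
}
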