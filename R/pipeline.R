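#' Read and validate a pipeline run configuration
#'
#' Run configurations are YAML with explicit unit suffixes in key names
#' (`spacing_nm`, `mean_volume_um3`). Exactly one input mode is allowed:
#' `synthetic` (a list of generator `groups`) or `stacks` (a list of
#' TIFF + sidecar paths). See [run_pipeline()] for the schema.
#'
#' @param path YAML file path.
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  validate_run_config(yaml::read_yaml(path))
}

validate_run_config <- function(config) {
  has_groups <- length(config$groups) > 0
  has_stacks <- length(config$stacks) > 0
  mode <- config$mode %||% if (has_stacks) "stacks" else "synthetic"
  if (!mode %in% c("synthetic", "stacks"))
    stop("mode must be 'synthetic' or 'stacks'", call. = FALSE)
  if (has_groups && has_stacks)
    stop("exactly one input mode: give either `groups` or `stacks`, not both",
         call. = FALSE)
  if (mode == "synthetic" && !has_groups)
    stop("synthetic mode needs at least one generator group", call. = FALSE)
  if (mode == "stacks" && !has_stacks)
    stop("stacks mode needs at least one stack entry", call. = FALSE)
  config$mode <- mode
  an <- config$analysis %||% list()
  an$smooth <- an$smooth %||% TRUE
  an$sigma_vox <- an$sigma_vox %||% c(1.5, 1.5, 1.5)
  an$exclude_boundary <- an$exclude_boundary %||% TRUE
  an$exact_test_max_n <- an$exact_test_max_n %||% 12
  an$fdr_q <- an$fdr_q %||% 0.05
  an$measure_diameter <- an$measure_diameter %||% TRUE
  if (!is.finite(an$fdr_q) || an$fdr_q <= 0 || an$fdr_q >= 1)
    stop("analysis$fdr_q must lie in (0, 1)", call. = FALSE)
  config$analysis <- an
  config$spacing_nm <- config$spacing_nm %||% c(100, 100, 100)
  config$seed <- config$seed %||% 1L
  if (mode == "synthetic") {
    for (g in config$groups) {
      for (f in c("region", "age", "compartment", "n_mito", "mean_volume_um3"))
        if (is.null(g[[f]])) stop("group is missing field `", f, "`", call. = FALSE)
      if (!g$compartment %in% c("axon", "dendrite", "soma"))
        stop("unknown compartment: ", g$compartment, call. = FALSE)
    }
  } else {
    missing <- Filter(function(s) !file.exists(s$tiff) || !file.exists(s$sidecar),
                      config$stacks)
    if (length(missing))
      stop("stack inputs not found: ",
           paste(vapply(missing, function(s) s$tiff, character(1)), collapse = ", "),
           call. = FALSE)
  }
  structure(config, class = "run_config")
}

# compartment-appropriate scene geometry and grid for one generator group
scene_plan <- function(g, spacing_nm) {
  total <- g$n_mito * g$mean_volume_um3
  sp <- spacing_nm / 1e3
  geom <- g$geometry %||% list()
  if (g$compartment %in% c("axon", "dendrite")) {
    radius <- geom$radius_um %||% if (g$compartment == "axon") 0.5 else 0.9
    mvd <- g$target_mvd %||% 0.12
    len <- total / (pi * radius^2 * mvd)
    dims <- c(ceiling(len / sp[1]) + 6,
              ceiling(2 * radius / sp[2]) + 8,
              ceiling(2 * radius / sp[3]) + 8)
    geom$radius_um <- radius
  } else {
    mvd <- g$target_mvd %||% 0.06
    v_soma <- total / mvd
    s <- (v_soma / (4 / 3 * pi * 1.2))^(1 / 3)
    semi <- geom$semi_axes_um %||% (c(1.2, 1, 1) * s)
    dims <- ceiling(2 * semi / sp) + 8
    geom$semi_axes_um <- semi
    geom$nucleus_scale <- geom$nucleus_scale %||% 0.55
  }
  if (!is.null(g$dims)) dims <- g$dims
  list(grid = voxel_grid(spacing_nm, dims), geometry = geom)
}

with_stage <- function(stage, id, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = unique(c(setdiff(class(e), "simpleError"))),
                   list(message = sprintf("stage '%s' [%s]: %s", stage, id,
                                          conditionMessage(e)),
                        call = NULL)))
  })
}

#' Pairwise and omnibus group comparisons with two-stage FDR
#'
#' The comparison layer applied to a per-organelle table: within each
#' region x age panel that has at least two compartments, an omnibus
#' Kruskal-Wallis test across compartments plus all pairwise Mann-Whitney
#' contrasts, separately for volume and MCI. Each (panel, metric) set of
#' pairwise p-values is one FDR family, corrected with the two-stage
#' Benjamini-Krieger-Yekutieli step-up at level `q`.
#'
#' @param organelles data frame from [measure_stack()] (columns `region`,
#'   `compartment`, `age`, `V_um3`, `MCI`).
#' @param q FDR level.
#' @param exact_max_n Mann-Whitney exact-path cutoff (combined n).
#' @return data frame: `region`, `age`, `metric`, `test`, `contrast`,
#'   `statistic`, `p`, `q_adj`, `reject`.
#' @export
compare_groups <- function(organelles, q = 0.05, exact_max_n = 12) {
  panels <- split(organelles,
                  interaction(organelles$region, organelles$age, drop = TRUE, sep = "|"))
  rows <- list()
  for (pn in names(panels)) {
    d <- panels[[pn]]
    comps <- sort(unique(d$compartment))
    if (length(comps) < 2) next
    reg <- d$region[1]; age <- d$age[1]
    for (metric in c("V_um3", "MCI")) {
      vals <- lapply(comps, function(cp) d[[metric]][d$compartment == cp])
      names(vals) <- comps
      if (length(comps) >= 2 && sum(lengths(vals) > 0) >= 2) {
        kw <- kruskal_wallis(vals)
        rows[[length(rows) + 1]] <- data.frame(
          region = reg, age = age, metric = metric, test = "kruskal_wallis",
          contrast = "omnibus", statistic = kw$H, p = kw$p,
          q_adj = NA_real_, reject = NA, stringsAsFactors = FALSE)
      }
      prs <- utils::combn(comps, 2, simplify = FALSE)
      mw <- lapply(prs, function(pr)
        mann_whitney(vals[[pr[1]]], vals[[pr[2]]], exact_max_n = exact_max_n))
      ps <- vapply(mw, `[[`, numeric(1), "p")
      adj <- bky_two_stage(ps, q = q)
      for (i in seq_along(prs)) {
        rows[[length(rows) + 1]] <- data.frame(
          region = reg, age = age, metric = metric, test = "mann_whitney",
          contrast = paste(prs[[i]][1], "vs", prs[[i]][2]),
          statistic = mw[[i]]$U, p = ps[i],
          q_adj = adj$qvalue[i], reject = adj$reject[i], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = character(0), age = character(0), metric = character(0),
               test = character(0), contrast = character(0), statistic = numeric(0),
               p = numeric(0), q_adj = numeric(0), reject = logical(0))
  rownames(out) <- NULL
  out
}

#' Run the full morphometry pipeline
#'
#' Orchestrates one analysis run: generate synthetic compartment scenes (or
#' ingest labeled stacks), measure every organelle and compartment,
#' aggregate by region x compartment x age, and emit the per-organelle,
#' per-compartment, comparison and mitotype tables plus a JSON run
#' manifest. Deterministic under a fixed seed: the master seed seeds the
#' R stream from which one child seed per group is drawn (in listed order)
#' and logged in the manifest.
#'
#' Config schema (YAML or list): `mode` (`synthetic`/`stacks`), `seed`,
#' `spacing_nm` (length 3), `analysis` (`smooth`, `sigma_vox`,
#' `exclude_boundary`, `exact_test_max_n`, `fdr_q`, `measure_diameter`),
#' and `groups` (each: `region`, `age`, `compartment`, `n_mito`,
#' `mean_volume_um3`, optional `cv`, `shape_mix`, `target_mvd`, `dims`,
#' `geometry`) or `stacks` (each: `tiff`, `sidecar`).
#'
#' @param config a `run_config` (from [read_run_config()]) or a plain list.
#' @param seed optional master seed overriding the config's.
#' @param output_dir optional directory for the CSV/JSON bundle; created if
#'   needed. `NULL` skips file output.
#' @return (invisibly) list with `organelles`, `compartments`,
#'   `comparisons`, `mitotypes`, `manifest`.
#' @export
run_pipeline <- function(config, seed = NULL, output_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  if (!is.null(seed)) config$seed <- seed
  output_dir <- output_dir %||% config$output_dir
  an <- config$analysis
  organelles <- list()
  compartments <- list()
  child_seeds <- integer(0)

  if (config$mode == "synthetic") {
    n_groups <- length(config$groups)
    child_seeds <- with_seed(config$seed, sample.int(2^31 - 2, n_groups))
    for (i in seq_len(n_groups)) {
      g <- config$groups[[i]]
      id <- paste(g$region, g$age, g$compartment, sep = "-")
      plan <- scene_plan(g, config$spacing_nm)
      cfg <- population_config(n = g$n_mito, mean_volume_um3 = g$mean_volume_um3,
                               cv = g$cv %||% 0.8,
                               shape_mix = g$shape_mix %||%
                                 eval(formals(population_config)$shape_mix),
                               max_volume_um3 = g$max_volume_um3 %||%
                                 (if (g$compartment == "soma") 1.2 else Inf),
                               seed = child_seeds[i])
      sc <- with_stage("generate", id,
                       build_compartment_scene(g$compartment, cfg, plan$grid,
                                               region = g$region, age = g$age,
                                               geometry = plan$geometry))
      org <- with_stage("measure", id,
                        measure_stack(sc$volume, smooth = an$smooth,
                                      sigma_vox = an$sigma_vox,
                                      exclude_boundary = an$exclude_boundary))
      comp <- with_stage("summarize", id,
                         summarize_compartment(sc$volume, organelles = org,
                                               measure_diam = an$measure_diameter))
      org$stack_id <- id
      comp$stack_id <- id
      organelles[[id]] <- org
      compartments[[id]] <- comp
    }
  } else {
    for (s in config$stacks) {
      id <- s$id %||% basename(s$tiff)
      vol <- with_stage("read", id, read_label_stack(s$tiff, s$sidecar))
      org <- with_stage("measure", id,
                        measure_stack(vol, smooth = an$smooth,
                                      sigma_vox = an$sigma_vox,
                                      exclude_boundary = an$exclude_boundary))
      comp <- with_stage("summarize", id,
                         summarize_compartment(vol, organelles = org,
                                               measure_diam = an$measure_diameter))
      org$stack_id <- id
      comp$stack_id <- id
      organelles[[id]] <- org
      compartments[[id]] <- comp
    }
  }

  organelles <- do.call(rbind, c(organelles, list(make.row.names = FALSE)))
  compartments <- do.call(rbind, c(compartments, list(make.row.names = FALSE)))
  comparisons <- with_stage("compare", "all",
                            compare_groups(organelles, q = an$fdr_q,
                                           exact_max_n = an$exact_test_max_n))
  mitotypes <- with_stage("mitotype", "all",
                          mitotype_summary(organelles, c("region", "compartment", "age")))
  manifest <- list(seed = config$seed, child_seeds = child_seeds,
                   mode = config$mode, spacing_nm = config$spacing_nm,
                   analysis = an,
                   package = "mitomorph",
                   version = as.character(utils::packageVersion("mitomorph")),
                   n_stacks = length(unique(organelles$stack_id)),
                   n_organelles = nrow(organelles))

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(organelles, file.path(output_dir, "organelles.csv"),
                     row.names = FALSE)
    utils::write.csv(compartments, file.path(output_dir, "compartments.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons, file.path(output_dir, "comparisons.csv"),
                     row.names = FALSE)
    utils::write.csv(mitotypes, file.path(output_dir, "mitotypes.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(organelles = organelles, compartments = compartments,
                 comparisons = comparisons, mitotypes = mitotypes,
                 manifest = manifest))
}
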