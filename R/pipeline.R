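#' Validate a pipeline configuration file
#'
#' Checks a YAML run configuration for unknown keys, missing referenced
#' files, and inconsistent fragment-length bins. Unknown keys are warnings;
#' the other problems invalidate the config.
#'
#' @param path path to a YAML configuration (see the bundled
#'   `demo_config.yaml` under `inst/extdata`).
#' @return A `config_report` list with elements `valid`, `errors`,
#'   `warnings` and the parsed `config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  errors <- character(0); warnings <- character(0)
  known <- c("simulation", "fragments", "bins", "flank", "vplot_max_offset",
             "alpha", "seed", "outdir", "conditions", "anchor_indices",
             "norm_constant")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    warnings <- c(warnings, paste("unknown key(s):",
                                  paste(unknown, collapse = ", ")))
  if (is.null(cfg$simulation) && is.null(cfg$fragments))
    errors <- c(errors, "config needs a `simulation` block or `fragments` paths")
  if (!is.null(cfg$fragments)) {
    missing <- unlist(cfg$fragments)[!file.exists(unlist(cfg$fragments))]
    if (length(missing))
      errors <- c(errors, paste("missing fragment file(s):",
                                paste(missing, collapse = ", ")))
  }
  for (b in cfg$bins) {
    if (is.null(b$min) || is.null(b$max) || b$min > b$max)
      errors <- c(errors, paste0("bad bin: ",
                                 paste(unlist(b), collapse = ":")))
  }
  if (!is.null(cfg$alpha) && (cfg$alpha <= 0 || cfg$alpha >= 1))
    errors <- c(errors, "`alpha` must lie in (0, 1)")
  structure(list(valid = length(errors) == 0L, errors = errors,
                 warnings = warnings, config = cfg),
            class = "config_report")
}

#' @export
print.config_report <- function(x, ...) {
  cat("Configuration:", if (x$valid) "valid" else "INVALID", "\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order: `simulate` (genome +
#' per-condition fragment BEDs), `coverage` (per-bin bedGraph tracks),
#' `vplot` (dyad-anchored V-plot TSV per condition), `profile` (+1-anchored
#' metagene TSV per bin and condition), `shift_test` (rotational-shift
#' table, each mutant condition vs the first condition) and writes a
#' manifest recording parameters and md5 checksums of every artifact.
#' Stages communicate only via files, so any stage can be fed externally
#' produced fragments in place of the simulation.
#'
#' @param config path to a YAML config, or a `config_report` from
#'   [validate_config()].
#' @param stages subset of stages to run (dependencies must already have
#'   artifacts on disk).
#' @param outdir overrides the config's output directory.
#' @param seed overrides the config's seed.
#' @return Invisibly, the manifest (also written as `manifest.yaml`).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "coverage", "vplot",
                                    "profile", "shift_test"),
                         outdir = NULL, seed = NULL) {
  rep <- if (inherits(config, "config_report")) config
         else validate_config(config)
  if (!rep$valid)
    stop("invalid configuration:\n  ", paste(rep$errors, collapse = "\n  "))
  cfg <- rep$config
  stages <- match.arg(stages, several.ok = TRUE)
  outdir <- outdir %||% cfg$outdir %||% "mnassp_out"
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  bins <- lapply(cfg$bins %||% list(list(min = 0, max = 60),
                                    list(min = 142, max = 152)),
                 function(b) length_bin(b$min, b$max, b$label %||% NULL))
  flank <- cfg$flank %||% 1000L
  alpha <- cfg$alpha %||% 0.05
  conditions <- cfg$conditions %||% list(list(name = "WT", preset = "WT"))
  cond_names <- vapply(conditions, function(cd) cd$name, character(1))
  artifacts <- character(0)
  log_stage <- function(stage, msg)
    message(sprintf("[%s] seed=%d %s", stage, seed, msg))

  genome_rds <- file.path(outdir, "genome")  # plain-text BED tracks
  frag_paths <- stats::setNames(
    file.path(outdir, paste0("fragments_", cond_names, ".bed")), cond_names)

  genome <- NULL
  build_genome <- function() {
    sim <- cfg$simulation
    generate_genome(sim$n_genes %||% 50L, seed = seed,
                    spacing_bp = sim$spacing_bp %||% 165L,
                    ndr_width_bp = sim$ndr_width_bp %||% 140L)
  }

  if ("simulate" %in% stages) {
    if (is.null(cfg$simulation)) stop("`simulate` stage needs a simulation block")
    genome <- build_genome()
    paths <- write_genome_tracks(genome, genome_rds)
    artifacts <- c(artifacts, paths)
    n_frag <- cfg$simulation$n_fragments %||% 20000L
    for (i in seq_along(conditions)) {
      cd <- conditions[[i]]
      params <- if (!is.null(cd$preset)) mutant_presets(cd$preset)
                else condition_params()
      fs <- simulate_digestion(genome, params, n_frag,
                               seed = seed + i, sample_id = cd$name)
      write_fragments_bed(fs, frag_paths[[cd$name]])
      artifacts <- c(artifacts, frag_paths[[cd$name]])
      log_stage("simulate", sprintf("condition=%s fragments=%d",
                                    cd$name, nrow(fs)))
    }
  }

  need_frags <- function() {
    missing <- frag_paths[!file.exists(frag_paths)]
    if (length(missing))
      stop("missing fragment artifact(s): ",
           paste(missing, collapse = ", "),
           " - run the `simulate` stage first")
    if (is.null(genome)) genome <<- build_genome()
    lapply(frag_paths, read_fragments_bed, genome = genome)
  }

  if ("coverage" %in% stages) {
    sets <- need_frags()
    for (nm in names(sets)) {
      nf <- normalization_factor(nrow(sets[[nm]]),
                                 cfg$norm_constant %||% 139712364)
      for (b in bins) {
        tr <- fragment_coverage(sets[[nm]], genome$chrom_sizes, nf, b)
        p <- file.path(outdir, sprintf("coverage_%s_%s.bedgraph", nm, b$label))
        write_bedgraph(tr, p)
        artifacts <- c(artifacts, p)
        log_stage("coverage", sprintf("condition=%s bin=%s", nm, b$label))
      }
    }
  }

  if ("vplot" %in% stages) {
    sets <- need_frags()
    anchors <- dyad_anchors(genome, cfg$anchor_indices %||% 1:10)
    for (nm in names(sets)) {
      vp <- build_vplot(sets[[nm]], anchors,
                        max_offset = cfg$vplot_max_offset %||% 500L)
      p <- file.path(outdir, sprintf("vplot_%s.tsv", nm))
      write_matrix_tsv(vp, p, row_label = "offset")
      artifacts <- c(artifacts, p)
      log_stage("vplot", sprintf("condition=%s argmax=(%g,%g)", nm,
                                 vplot_argmax(vp)[1], vplot_argmax(vp)[2]))
    }
  }

  if ("profile" %in% stages) {
    sets <- need_frags()
    anchors <- dyad_anchors(genome, 1L)
    for (nm in names(sets)) {
      nf <- normalization_factor(nrow(sets[[nm]]),
                                 cfg$norm_constant %||% 139712364)
      for (b in bins) {
        pr <- metagene_profile(sets[[nm]], anchors, genome$chrom_sizes,
                               flank = flank, bin = b, norm_factor = nf)
        p <- file.path(outdir, sprintf("profile_%s_%s.tsv", nm, b$label))
        utils::write.table(pr, p, sep = "\t", quote = FALSE, row.names = FALSE)
        artifacts <- c(artifacts, p)
        log_stage("profile", sprintf("condition=%s bin=%s", nm, b$label))
      }
    }
  }

  if ("shift_test" %in% stages) {
    sets <- need_frags()
    if (length(sets) < 2L)
      stop("`shift_test` needs at least two conditions (WT first)")
    nuc_bin <- length_bin(142, 152)
    dy <- dyad_anchors(genome, 1:10)
    ztab <- lapply(sets, function(fs) {
      nf <- normalization_factor(nrow(fs), cfg$norm_constant %||% 139712364)
      tr <- midpoint_coverage(fs, genome$chrom_sizes, nf, nuc_bin)
      zscore_rows(rotational_occupancy(tr, dy))
    })
    wt <- ztab[[1L]]
    for (nm in names(sets)[-1L]) {
      st <- shift_test(ztab[[nm]], wt, alpha = alpha)
      p <- file.path(outdir, sprintf("shift_%s_vs_%s.tsv", nm, names(sets)[1]))
      utils::write.table(st, p, sep = "\t", quote = FALSE, row.names = FALSE)
      artifacts <- c(artifacts, p)
      log_stage("shift_test", sprintf("%s vs %s: %d significant cells",
                                      nm, names(sets)[1], sum(st$significant)))
    }
  }

  param_hash <- unname(tools::md5sum(write_yaml_tmp(cfg)))
  manifest <- list(
    seed = seed,
    parameter_hash = param_hash,
    stages = stages,
    artifacts = lapply(stats::setNames(nm = artifacts), function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}

write_yaml_tmp <- function(x) {
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(x, tmp)
  tmp
}
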