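# End-to-end orchestration: simulate (optional) -> copy number -> somatic
# -> normalize -> histone subtype -> screen -> associations, with a
# machine-readable run manifest and deterministic outputs under a fixed
# seed.

.pipeline_keys <- list(
  top = c("seed", "out_dir", "simulate", "inputs", "cnv", "somatic",
          "histone", "screen", "verbosity"),
  simulate = "any",                      # forwarded to sim_config()
  inputs = c("expression", "annotation", "depth_dir", "sites", "phenotypes",
             "samples"),
  cnv = c("alpha", "n_perm", "min_bins"),
  somatic = c("alpha", "min_alt_t", "max_alt_n"),
  histone = c("catalog", "min_detect"),
  screen = c("cor_threshold", "min_expr", "extra_copy_threshold", "max_len",
             "min_dd_samples", "require_dd_gt_wd", "scope", "family_mode")
)

#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent named list) with a
#' master `seed`, an `out_dir`, and optional `simulate`, `inputs`, `cnv`,
#' `somatic`, `histone` and `screen` parameter blocks. Unknown keys are
#' rejected with the offending key named; the structure round-trips
#' losslessly through YAML.
#'
#' @param config Path to a YAML file or a named list.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop_lps("pipeline_config: no such config file: ", config)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .pipeline_keys$top)
  if (length(unknown) > 0) {
    stop_lps("pipeline_config: unknown key `", unknown[1], "`")
  }
  for (blk in c("inputs", "cnv", "somatic", "histone", "screen")) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), .pipeline_keys[[blk]])
      if (length(bad) > 0) {
        stop_lps("pipeline_config: unknown key `", blk, ".", bad[1], "`")
      }
    }
  }
  if (!is.null(config$simulate)) {
    bad <- setdiff(names(config$simulate), names(formals(sim_config)))
    if (length(bad) > 0) {
      stop_lps("pipeline_config: unknown key `simulate.", bad[1], "`")
    }
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) stop_lps("pipeline_config: `out_dir` is required")
  structure(config, class = "pipeline_config")
}

# load user-supplied inputs, aborting with the missing path named
load_inputs <- function(inp) {
  need <- c("expression", "annotation", "depth_dir", "sites", "phenotypes",
            "samples")
  for (f in need) {
    if (is.null(inp[[f]])) stop_lps("inputs: `", f, "` is required")
    if (!file.exists(inp[[f]])) stop_lps("inputs: file not found: ", inp[[f]])
  }
  samples <- readr::read_tsv(inp$samples, show_col_types = FALSE,
                             progress = FALSE)
  tumors <- samples$sample[samples$group != "normal"]
  depth <- purrr::map(tumors, function(s) {
    ft <- file.path(inp$depth_dir, paste0(s, ".tumor.tsv"))
    fn <- file.path(inp$depth_dir, paste0(s, ".normal.tsv"))
    for (f in c(ft, fn)) {
      if (!file.exists(f)) stop_lps("inputs: depth file not found: ", f)
    }
    list(tumor = mutate(read_depth_tsv(ft), sample = s),
         normal = mutate(read_depth_tsv(fn), sample = s))
  })
  ann <- read_bed(inp$annotation)
  list(
    counts = read_expression_tsv(inp$expression),
    annotation = ann,
    sample_info = samples,
    depth_tumor = bind_rows(purrr::map(depth, "tumor")),
    depth_normal = bind_rows(purrr::map(depth, "normal")),
    sites = read_sites_tsv(inp$sites),
    phenotypes = readr::read_tsv(inp$phenotypes, show_col_types = FALSE,
                                 progress = FALSE)
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate (when a `simulate` block is present, otherwise user
#' inputs are read from the `inputs` block) -> per-tumor copy-number
#' estimation, segmentation and focal-amplification calls -> somatic
#' candidate calling and burden -> normalization -> histone scoring and
#' DD subtype classification -> TF driver screen -> score/phenotype and
#' score/SCNA-burden associations. Every stage's outputs are written under
#' `out_dir`; a JSON manifest records the seed, config hash, per-stage
#' wall time and every file written. A stage failure aborts with the stage
#' name, after renaming that stage's partial outputs to `*.partial`.
#'
#' Outputs are byte-identical across reruns with the same seed and config
#' (the manifest, which carries timings, is excluded from that guarantee).
#'
#' @param config A [pipeline_config()], path to one, or a named list.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  verbose <- isTRUE(config$verbosity %||% TRUE)
  say <- function(...) if (verbose) inform(paste0(...))

  manifest <- list(seed = seed,
                   config_hash = rlang::hash(unclass(config)),
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("lipodriver")),
                   stages = list())
  stage_files <- character()

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    stage_files <<- character()
    res <- tryCatch(fun(), error = function(e) {
      for (f in stage_files) {
        if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
      }
      stop_lps("pipeline stage `", name, "` failed: ", conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
      files = unname(stage_files)
    )
    say("stage ", name, " done")
    res
  }
  reg <- function(path) {
    stage_files <<- c(stage_files, path)
    path
  }

  # --- stage 1: data ------------------------------------------------------
  data <- run_stage("simulate", function() {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      sim_args$seed <- sim_args$seed %||% seed
      cfg <- do.call(sim_config, sim_args)
      sim <- simulate_cohort(cfg)
      write_cohort(sim$cohort, reg(file.path(out_dir, "cohort")))
      sim$cohort
    } else {
      load_inputs(config$inputs %||% list())
    }
  })
  sample_info <- data$sample_info
  tumors <- sample_info$sample[sample_info$group != "normal"]
  dd <- sample_info$sample[sample_info$group == "DD"]

  # --- stage 2: copy number ----------------------------------------------
  cnv_par <- config$cnv %||% list()
  seg_dir <- file.path(out_dir, "segments")
  segments <- run_stage("cnv", function() {
    dir.create(seg_dir, showWarnings = FALSE)
    segs <- purrr::map_dfr(tumors, function(s) {
      cp <- coverage_to_copy(
        data$depth_tumor[data$depth_tumor$sample == s,
                         c("chrom", "start", "end", "depth")],
        data$depth_normal[data$depth_normal$sample == s,
                          c("chrom", "start", "end", "depth")]
      )
      sg <- segment_copy_number(cp,
                                alpha = cnv_par$alpha %||% 0.01,
                                n_perm = cnv_par$n_perm %||% 1000,
                                min_bins = cnv_par$min_bins %||% 3,
                                seed = substream_seed(seed, paste0("seg_", s)))
      sg$sample <- s
      write_bed(sg[, c("chrom", "start", "end", "copies", "n_bins")],
                reg(file.path(seg_dir, paste0(s, ".seg.bed"))))
      sg
    })
    segs
  })

  # --- stage 3: somatic ---------------------------------------------------
  som_par <- config$somatic %||% list()
  somatic <- run_stage("somatic", function() {
    calls <- purrr::map_dfr(tumors, function(s) {
      out <- call_somatic_candidates(
        data$sites[data$sites$sample == s, ],
        alpha = som_par$alpha %||% 0.01,
        min_alt_t = som_par$min_alt_t %||% 4,
        max_alt_n = som_par$max_alt_n %||% 1
      )
      out
    })
    write_tsv_plain(calls, reg(file.path(out_dir, "somatic_calls.tsv")),
                    comment = "#coords=1-based")
    burdens <- calls |>
      group_by(.data$sample) |>
      summarise(burden = sum(.data$pass), .groups = "drop")
    write_tsv_plain(burdens, reg(file.path(out_dir, "mutation_burden.tsv")))
    list(calls = calls, burdens = burdens)
  })

  # --- stage 4: normalize -------------------------------------------------
  norm <- run_stage("normalize", function() {
    nm <- size_factor_normalize(data$counts, pseudocount = 0)
    write_expression_tsv(nm$normalized,
                         reg(file.path(out_dir, "normalized.tsv")))
    write_tsv_plain(nm$size_factors,
                    reg(file.path(out_dir, "size_factors.tsv")))
    nm
  })

  # --- stage 5: histone subtype ------------------------------------------
  hist_par <- config$histone %||% list()
  catalog <- if (!is.null(hist_par$catalog)) {
    rd_hist_catalog(hist_par$catalog)
  } else {
    rd_hist_catalog()
  }
  hist_res <- run_stage("histone", function() {
    sc <- histone_score(norm$normalized, catalog)
    write_tsv_plain(sc$overall, reg(file.path(out_dir, "histone_scores.tsv")))
    sub <- classify_hist_subtype(norm$normalized, catalog, dd)
    write_tsv_plain(sub$labels, reg(file.path(out_dir, "hist_subtypes.tsv")))
    list(scores = sc, subtype = sub)
  })

  # --- stage 6: screen ----------------------------------------------------
  scr_par <- config$screen %||% list()
  screen_res <- run_stage("screen", function() {
    scfg <- do.call(screen_config, scr_par)
    res <- run_screen(norm$normalized, data$annotation, segments,
                      sample_info, catalog, scfg)
    write_tsv_plain(res$candidates,
                    reg(file.path(out_dir, "screen_candidates.tsv")))
    write_tsv_plain(res$funnel, reg(file.path(out_dir, "screen_funnel.tsv")))
    res
  })

  # --- stage 7: associations ---------------------------------------------
  assoc <- run_stage("associations", function() {
    scores <- hist_res$scores$overall
    tum_scores <- scores[scores$sample %in% tumors, ]
    rows <- list()
    for (v in c("mitotic_index", "ki67")) {
      rows[[v]] <- phenotype_correlation(tum_scores, data$phenotypes, v)
    }
    burden_tbl <- segments |>
      group_by(.data$sample) |>
      summarise(scna_burden = scna_burden(dplyr::pick(dplyr::everything())),
                .groups = "drop")
    ph <- inner_join(burden_tbl, tibble(sample = tumors), by = "sample")
    rows$scna <- phenotype_correlation(tum_scores, ph, "scna_burden")
    out <- bind_rows(rows)
    write_tsv_plain(out, reg(file.path(out_dir, "associations.tsv")))
    out
  })

  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("pipeline complete: ", length(manifest$stages), " stages")
  invisible(list(manifest = manifest, segments = segments,
                 somatic = somatic, normalized = norm,
                 histone = hist_res, screen = screen_res,
                 associations = assoc))
}
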