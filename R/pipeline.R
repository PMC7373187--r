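#' Condition presets for the three imaging samples
#'
#' Maps a condition label to the generator parameters that emulate it:
#' `"dna"` (no protein) forms occasional random crossings and no bound
#' protein; `"gapr"` (wild-type bridging protein) forms junctions more often
#' and every junction carries protein height; `"mutant"` (DNA-binding
#' deficient) behaves nearly like bare DNA, with residual binding occupying a
#' small fraction of junctions.
#'
#' @param condition `"dna"`, `"gapr"` or `"mutant"`.
#' @return List with a [bridging_config()] and `h_protein_add` (nm).
#' @export
condition_preset <- function(condition = c("dna", "gapr", "mutant")) {
  condition <- match.arg(condition)
  switch(condition,
    dna = list(bridging = bridging_config(0.10, 0.05, 0),
               h_protein_add = 0),
    gapr = list(bridging = bridging_config(0.35, 0.15, 1),
                h_protein_add = 0.50),
    mutant = list(bridging = bridging_config(0.12, 0.06, 0.18),
                  h_protein_add = 0.50))
}

#' Pipeline run configuration
#'
#' A single bundle of every stage parameter plus the master seed, so that a
#' full simulate-flatten-segment-trace-summarize run is reproducible from one
#' object. Round-trips losslessly through YAML via [write_run_config()] /
#' [read_run_config()].
#'
#' @param conditions Conditions to simulate (subset of dna/gapr/mutant).
#' @param n_images Images per condition.
#' @param n_px Image width in pixels (field is 1 x 1 um).
#' @param density_class `"low"` or `"high"` molecule density.
#' @param seed Master seed; all per-image seeds derive from it.
#' @param field_size_nm Scan size in nm.
#' @param n_bp,persistence_length,segment_length Chain model parameters.
#' @param h_dna,h_overlap_add,tip_sigma,noise_sigma,background_coeff_scale
#'   Render parameters (see [render_params()]).
#' @param flatten_orders,n_iter,mask_k Flattening parameters.
#' @param k,min_area_px Segmentation parameters.
#' @param L0,tol,r_merge,window_r,excl_r Tracing parameters.
#' @export
run_config <- function(conditions = c("dna", "gapr", "mutant"),
                       n_images = 2L, n_px = 256L,
                       density_class = "high", seed = 1L,
                       field_size_nm = 1000,
                       n_bp = 1000L, persistence_length = 50,
                       segment_length = 2,
                       h_dna = 1.0, h_overlap_add = 0.86, tip_sigma = 3.0,
                       noise_sigma = 0.08, background_coeff_scale = 0.3,
                       flatten_orders = c(0, 1, 2), n_iter = 3L, mask_k = 3,
                       k = 3, min_area_px = 30L,
                       L0 = 340, tol = 0.25, r_merge = 4,
                       window_r = 3, excl_r = 8) {
  conditions <- match.arg(conditions, c("dna", "gapr", "mutant"),
                          several.ok = TRUE)
  density_class <- match.arg(density_class, c("low", "high"))
  cfg <- list(
    schema_version = 1L,
    conditions = conditions, n_images = as.integer(n_images),
    n_px = as.integer(n_px), density_class = density_class,
    seed = as.integer(seed), field_size_nm = field_size_nm,
    n_bp = as.integer(n_bp), persistence_length = persistence_length,
    segment_length = segment_length,
    h_dna = h_dna, h_overlap_add = h_overlap_add, tip_sigma = tip_sigma,
    noise_sigma = noise_sigma,
    background_coeff_scale = background_coeff_scale,
    flatten_orders = flatten_orders, n_iter = as.integer(n_iter),
    mask_k = mask_k, k = k, min_area_px = as.integer(min_area_px),
    L0 = L0, tol = tol, r_merge = r_merge,
    window_r = window_r, excl_r = excl_r)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg[setdiff(names(cfg), "schema_version")])
}

#' Run the full simulation and analysis pipeline
#'
#' End-to-end driver: for each condition, simulates seeded synthetic scenes,
#' renders height maps, flattens them scanline-by-scanline, segments on the
#' automatic height cutoff, traces molecules and junctions, and aggregates
#' per-condition summaries plus pairwise junction-height t tests against the
#' protein-free condition. Deterministic given the config: per-image seeds
#' derive from the master seed, so two runs produce identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory for CSV outputs (`molecules.csv`,
#'   `junctions.csv`, `summary.csv`, `comparisons.csv`, `config.yaml`,
#'   `log.txt`).
#' @return List with `molecules`, `junctions` (pooled tables), `summaries`
#'   (per condition), `comparisons` (data frame), `capture` (per-image
#'   capture fractions), `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (config$n_images < 1L) {
    warning("config requests 0 images; returning an empty summary")
    return(list(molecules = NULL, junctions = NULL, summaries = list(),
                comparisons = data.frame(), capture = data.frame(),
                config = config))
  }
  n_range <- if (config$density_class == "low") 4:7 else 8:15
  all_m <- list(); all_j <- list(); caps <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    preset <- condition_preset(cond)
    for (im in seq_len(config$n_images)) {
      sseed <- derive_seed(config$seed, ci * 100L + im)
      n_chains <- with_seed(sseed, sample(n_range, 1L))
      scene <- place_molecules(
        n_chains, config$field_size_nm, config$density_class,
        bridging = preset$bridging, seed = sseed + 1L,
        n_bp = config$n_bp,
        persistence_length = config$persistence_length,
        segment_length = config$segment_length)
      rp <- render_params(
        pixel_size_nm = config$field_size_nm / config$n_px,
        h_dna = config$h_dna, h_overlap_add = config$h_overlap_add,
        h_protein_add = preset$h_protein_add,
        tip_sigma = config$tip_sigma, noise_sigma = config$noise_sigma,
        background_coeff_scale = config$background_coeff_scale,
        seed = sseed + 2L)
      map <- render_height_map(scene, rp)
      flat <- flatten_image(map, orders = config$flatten_orders,
                            n_iter = config$n_iter, mask_k = config$mask_k)
      res <- analyze_image(flat, k = config$k,
                           min_area_px = config$min_area_px,
                           L0 = config$L0, tol = config$tol,
                           r_merge = config$r_merge,
                           window_r = config$window_r,
                           excl_r = config$excl_r)
      cap <- capture_fraction(scene, res$components)
      if (nrow(res$molecules)) {
        res$molecules <- cbind(condition = cond, image = im, res$molecules)
        all_m[[length(all_m) + 1L]] <- res$molecules
      }
      if (nrow(res$junctions)) {
        res$junctions <- cbind(condition = cond, image = im, res$junctions)
        all_j[[length(all_j) + 1L]] <- res$junctions
      }
      caps[[length(caps) + 1L]] <- data.frame(
        condition = cond, image = im, n_molecules_truth = length(scene$chains),
        capture_fraction = cap$fraction)
    }
  }
  molecules <- do.call(rbind, all_m)
  junctions <- if (length(all_j)) do.call(rbind, all_j) else data.frame(
    condition = character(0), image = integer(0), component_id = integer(0),
    row = numeric(0), col = numeric(0), x_nm = numeric(0), y_nm = numeric(0),
    degree = integer(0), jtype = character(0), height_diff_nm = numeric(0))
  summaries <- lapply(config$conditions, function(cond) {
    m <- molecules[molecules$condition == cond, , drop = FALSE]
    j <- junctions[junctions$condition == cond, , drop = FALSE]
    summarize_sample(m, j, cond, config$density_class)
  })
  names(summaries) <- config$conditions
  ## pairwise junction-height comparisons against the protein-free condition
  comparisons <- list()
  if ("dna" %in% config$conditions) {
    ref <- junctions$height_diff_nm[junctions$condition == "dna"]
    ref <- ref[is.finite(ref)]
    for (cond in setdiff(config$conditions, "dna")) {
      x <- junctions$height_diff_nm[junctions$condition == cond]
      x <- x[is.finite(x)]
      if (length(ref) >= 2 && length(x) >= 2) {
        tt <- unpaired_t_test(x, ref)
        comparisons[[length(comparisons) + 1L]] <- data.frame(
          a = cond, b = "dna", n_a = length(x), n_b = length(ref),
          mean_a = mean(x), mean_b = mean(ref),
          t = tt$t, df = tt$df, p = tt$p)
      }
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons)
    else data.frame()
  capture <- do.call(rbind, caps)
  out <- list(molecules = molecules, junctions = junctions,
              summaries = summaries, comparisons = comparisons,
              capture = capture, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

summary_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s)
    data.frame(condition = s$condition, density_class = s$density_class,
               n_molecules = s$n_molecules, n_junctions = s$n_junctions,
               n_intra = s$n_intra, n_inter = s$n_inter,
               n_ambiguous = s$n_ambiguous,
               pct_molecules_with_junction = s$pct_molecules_with_junction,
               pct_intra = s$pct_intra, pct_inter = s$pct_inter,
               mean_height_diff = s$mean_height_diff,
               sem_height_diff = s$sem_height_diff,
               n_height = s$n_height)))
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) utils::write.csv(
    df, file.path(out_dir, name), row.names = FALSE)
  wr(result$molecules, "molecules.csv")
  wr(result$junctions, "junctions.csv")
  wr(summary_table(result$summaries), "summary.csv")
  wr(result$comparisons, "comparisons.csv")
  wr(result$capture, "capture.csv")
  write_run_config(result$config, file.path(out_dir, "config.yaml"))
  writeLines(c(
    paste0("afmbridge version: ",
           as.character(utils::packageVersion("afmbridge"))),
    paste0("master seed: ", result$config$seed),
    paste0("conditions: ", paste(result$config$conditions, collapse = ", ")),
    paste0("images per condition: ", result$config$n_images),
    paste0("density class: ", result$config$density_class)),
    file.path(out_dir, "log.txt"))
  invisible(out_dir)
}
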