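# End-to-end orchestration on a synthetic scene: simulate -> differential
# peaks -> location/responsive calls -> DIC extraction -> LC/HC split ->
# Hi-C metrics -> loop statistics -> feature matrix + supervised model.
# One config seed fans out to per-stage derived seeds.

default_config <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    tau = 0.5,
    pseudocount = 1,
    fit_method = "theilsen",
    ratio_threshold = 1.2,
    lfc_threshold = 0,
    flank = 10000,
    min_gene_length = 20000,
    width_cap = 3000,
    tss_window = 10000,
    min_rad21 = 0,
    hic = list(window = 10000, local_cutoff = 250000, square_width = 4L,
               apa_radius = 5L, run = TRUE),
    ml = list(test_chroms = "chr2", folds = 5L, k_neighbors = 5L, run = TRUE),
    sim = list()
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), rejects unknown keys, fills
#' defaults, and checks that every threshold is positive.
#'
#' @param config Path to a YAML file, a list, or NULL for all defaults.
#' @return The normalized config list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- if (file.exists(config)) yaml::read_yaml(config) else
      stop("config file not found: ", config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0) stop("unknown config key(s): ",
                                paste(unknown, collapse = ", "))
  for (sub in c("hic", "ml")) {
    if (!is.null(config[[sub]])) {
      bad <- setdiff(names(config[[sub]]), names(def[[sub]]))
      if (length(bad) > 0) stop("unknown config key(s): ",
                                paste(paste0(sub, ".", bad), collapse = ", "))
      def[[sub]][names(config[[sub]])] <- config[[sub]]
      config[[sub]] <- NULL
    }
  }
  if (!is.null(config$sim)) {
    bad <- setdiff(names(config$sim), names(formals(sim_params)))
    if (length(bad) > 0) stop("unknown sim parameter(s): ",
                              paste(bad, collapse = ", "))
  }
  def[names(config)] <- config
  cfg <- def
  for (key in c("tau", "pseudocount", "ratio_threshold", "flank",
                "min_gene_length", "width_cap", "tss_window")) {
    if (!is.numeric(cfg[[key]]) || (key != "flank" && cfg[[key]] <= 0) ||
        cfg[[key]] < 0) {
      stop("config: ", key, " must be positive")
    }
  }
  if (is.null(cfg$seed)) stop("config: seed is required")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full pipeline on a synthetic scene
#'
#' Executes the stages in dependency order, writes the main outputs (DIC
#' BED with subtype in the name field, responsive-gene TSV, feature-matrix
#' TSV) when \code{output_dir} is set, and returns a manifest with per-stage
#' timings and output checksums. Identical config + seed reproduce identical
#' checksums.
#'
#' @param config A config list/path accepted by \code{\link{validate_config}}.
#' @return List: \code{results} (per-stage objects) and \code{manifest}
#'   (stage status, seconds, checksums, thresholds used).
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- validate_config(config)
  results <- list()
  manifest <- list(config = cfg, stages = list(), checksums = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok",
                                     seconds = proc.time()[["elapsed"]] - t0)
    val
  }

  sim_args <- c(list(seed = cfg$seed), cfg$sim)
  params <- do.call(sim_params, sim_args)

  results$scene <- t_stage("simulate",
                           simulate_scene(params, contacts = isTRUE(cfg$hic$run)))
  scene <- results$scene

  results$peaks <- t_stage("diffpeaks", diff_peaks(
    scene$sites, tau = cfg$tau, pseudocount = cfg$pseudocount,
    method = cfg$fit_method))

  results$regions <- t_stage("regions", derive_intragenic_regions(
    scene$genes, flank = cfg$flank, min_length = cfg$min_gene_length))

  results$locations <- t_stage("classify", classify_site_location(
    scene$sites, scene$genes, results$regions, tss_window = cfg$tss_window))

  results$responsive <- t_stage("responsive", call_responsive_genes(
    scene$elongation, scene$expression,
    ratio_threshold = cfg$ratio_threshold, lfc_threshold = cfg$lfc_threshold))

  results$dics <- t_stage("extract-dics", extract_dics(
    results$peaks, results$locations, results$responsive,
    width_cap = cfg$width_cap, tau = cfg$tau))

  dic_rows <- which(results$dics$is_dic)
  results$subtypes <- t_stage("split-lc-hc", {
    cof <- scene$cofactors[match(results$dics$name[dic_rows],
                                 scene$cofactors$name), ]
    split_lc_hc(cof$name, cof$ctcf_density, cof$rad21_density,
                min_rad21 = cfg$min_rad21)
  })

  if (isTRUE(cfg$hic$run)) {
    results$dlr <- t_stage("hic-dlr", compute_dlr(
      scene$hic$map_a, scene$hic$map_b, window = cfg$hic$window,
      local_cutoff = cfg$hic$local_cutoff))
    results$insulation <- t_stage("hic-insulation", compute_insulation(
      scene$hic$map_a, square_width = cfg$hic$square_width))
    results$apa <- t_stage("hic-apa", compare_apa(
      scene$hic$map_a, scene$hic$map_b,
      scene$hic$loops[scene$hic$loops$at_dic, ],
      radius = cfg$hic$apa_radius))
    results$occurrence <- t_stage("loops", {
      dic_names <- results$dics$name[dic_rows]
      loop_occurrence(list(
        dic = scene$sites[scene$sites$name %in% dic_names, ],
        other = scene$sites[!(scene$sites$name %in% dic_names), ]),
        scene$hic$loops)
    })
  }

  if (isTRUE(cfg$ml$run)) {
    results$features <- t_stage("features", {
      tf_cols <- setdiff(names(scene$cofactors),
                         c("name", "ctcf_density", "rad21_density"))
      X <- as.matrix(scene$cofactors[, tf_cols])
      rownames(X) <- scene$cofactors$name
      list(X = X, chrom = scene$sites$chrom, binary_cols = tf_cols)
    })
    results$model <- t_stage("train", {
      ft <- results$features
      y <- as.integer(results$dics$is_dic)
      split <- make_split(ft$chrom, cfg$ml$test_chroms,
                          folds = cfg$ml$folds, seed = cfg$seed)
      bal <- smote_oversample(ft$X[!split$test, , drop = FALSE],
                              y[!split$test],
                              k_neighbors = cfg$ml$k_neighbors,
                              seed = cfg$seed, binary_cols = ft$binary_cols)
      model <- train_logistic(bal$X, bal$y, penalty = "none")
      prob <- predict_logistic(model, ft$X[split$test, , drop = FALSE])
      list(model = model, split = split,
           evaluation = evaluate_classifier(prob, y[split$test]),
           importance = feature_importance(model))
    })
  }

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    dic_bed <- scene$sites[match(results$dics$name[dic_rows],
                                 scene$sites$name), ]
    st <- results$subtypes$subtype[match(dic_bed$name, results$subtypes$name)]
    dic_bed$name <- paste0(dic_bed$name, ":", as.character(st))
    paths <- list(
      dics = file.path(cfg$output_dir, "dics.bed"),
      responsive = file.path(cfg$output_dir, "responsive_genes.tsv"),
      regions = file.path(cfg$output_dir, "intragenic_regions.bed"),
      config = file.path(cfg$output_dir, "config.yaml"))
    write_bed(dic_bed, paths$dics)
    utils::write.table(results$responsive, paths$responsive, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    reg <- results$regions
    writeLines(paste(reg$chrom, format_plain(reg$start),
                     format_plain(reg$end), reg$gene_id, sep = "\t"),
               paths$regions)
    if (!is.null(results$features)) {
      paths$features <- file.path(cfg$output_dir, "feature_matrix.tsv")
      fm <- data.frame(name = rownames(results$features$X),
                       chrom = results$features$chrom,
                       results$features$X, check.names = FALSE)
      utils::write.table(fm, paths$features, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    yaml::write_yaml(cfg, paths$config)
    manifest$checksums <- lapply(paths, function(p) unname(tools::md5sum(p)))
  }

  manifest$thresholds <- cfg[c("tau", "ratio_threshold", "flank",
                               "min_gene_length", "width_cap", "tss_window")]
  list(results = results, manifest = manifest)
}
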