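#' End-to-end pipeline
#'
#' Runs the full analysis from loaded or simulated inputs: rarefaction,
#' alpha/beta diversity, grassland-type group statistics, distance-decay
#' fits with slope contrasts, three-way variance partitioning, the IDEN
#' network chain per microbial domain plus the combined network, topology
#' and stability, and the connectivity partial-Mantel screen. All stochastic
#' steps derive child seeds from `cfg$seed`; the configuration and per-stage
#' counts are serialized next to the outputs.
#'
#' @name pipeline
NULL

#' Default run configuration
#'
#' @param seed master seed.
#' @param out_dir output directory (`NULL` = return results only).
#' @param simulate a [generator_config()] (defaults to one built from
#'   `seed`); alternatively supply `inputs` with file paths.
#' @param inputs optional list of paths: `grass`, `archaea`, `bacteria`,
#'   `fungi` (count TSVs), `frame` (metadata TSV), `orientation`.
#' @param rarefaction_depths named depths per domain; `NA` skips rarefying a
#'   domain. Defaults use the 16S/ITS normalization depths scaled to the
#'   simulated library sizes when simulating.
#' @param r_threshold,p_threshold network thresholds.
#' @param n_perm,n_boot,sparcc_inner,boot_inner,lted_perm,n_null iteration
#'   counts for the stochastic machinery.
#' @param vpa_blocks variable lists for the three VPA blocks.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = NULL, simulate = NULL,
                       inputs = NULL,
                       rarefaction_depths = NULL,
                       r_threshold = 0.3, p_threshold = 0.05,
                       n_perm = 999L, n_boot = 100L, sparcc_inner = 20L,
                       boot_inner = 5L, lted_perm = 99L, n_null = 100L,
                       vpa_blocks = list(
                         productivity = c("CD", "DB", "S"),
                         diversity = c("grass_margalef", "grass_shannon",
                                       "grass_pielou"),
                         soil = c("pH", "TN", "TP", "SMC"))) {
  if (is.null(simulate) && is.null(inputs))
    simulate <- generator_config(seed = seed)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulate = simulate, inputs = inputs,
                 rarefaction_depths = rarefaction_depths,
                 r_threshold = r_threshold, p_threshold = p_threshold,
                 n_perm = n_perm, n_boot = n_boot,
                 sparcc_inner = sparcc_inner, boot_inner = boot_inner,
                 lted_perm = lted_perm, n_null = n_null,
                 vpa_blocks = vpa_blocks), class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#' @param path config file; top-level keys are [run_config()] arguments,
#'   with `simulate` holding [generator_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("[.]ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- cfg$simulate
  cfg$simulate <- NULL
  rc <- do.call(run_config, cfg)
  if (!is.null(sim)) {
    if (is.null(sim$seed)) sim$seed <- rc$seed
    rc$simulate <- do.call(generator_config, sim)
  }
  rc
}

load_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    study <- generate_study(cfg$simulate)
    return(study)
  }
  orient <- cfg$inputs$orientation %||% "samples_rows"
  tables <- list()
  for (dom in c("grass", "archaea", "bacteria", "fungi"))
    if (!is.null(cfg$inputs[[dom]]))
      tables[[dom]] <- read_count_table(cfg$inputs[[dom]], dom, orient)
  frame <- read_sample_frame(cfg$inputs$frame)
  list(frame = frame, tables = tables, truth = NULL, cfg = NULL)
}

#' Run the full pipeline
#'
#' @param cfg a [run_config()].
#' @return list of per-stage results: `bundle`, `alpha`, `beta`,
#'   `group_tests`, `permanova`, `ddr`, `slope_contrasts`, `vpa`,
#'   `networks`, `topology`, `stability`, `connectivity_mantel`, `log`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log <- list(seed = cfg$seed, started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              package_version = as.character(utils::packageVersion("graminet")))
  study <- load_inputs(cfg)
  if (is.null(study$tables$grass)) stop("stage load: grass table required")
  mic_doms <- intersect(c("archaea", "bacteria", "fungi"), names(study$tables))
  if (!length(mic_doms)) stop("stage load: no microbial tables")

  # rarefaction (per domain; fungal sample loss handled per-domain)
  depths <- cfg$rarefaction_depths
  tables <- study$tables
  dropped <- list()
  for (dom in names(tables)) {
    dep <- depths[[dom]] %||% NA
    if (!is.na(dep)) {
      rr <- rarefy_table(tables[[dom]], dep, seed = derive_seed(cfg$seed, dom))
      tables[[dom]] <- rr$table
      dropped[[dom]] <- rr$dropped
    }
  }
  log$rarefaction_dropped <- dropped

  # per-domain aligned bundles (tables keep their own sample sets)
  frame <- study$frame
  bundles <- lapply(mic_doms, function(dom)
    align_bundle(list(grass = tables$grass, microbe = tables[[dom]]), frame))
  names(bundles) <- mic_doms

  # alpha diversity + group letters, beta diversity + PERMANOVA
  alpha <- lapply(tables, alpha_diversity)
  group_tests <- list()
  if ("grassland_type" %in% names(frame)) {
    for (dom in names(alpha)) {
      al <- alpha[[dom]]
      ty <- frame[al$sample_id, "grassland_type"]
      group_tests[[dom]] <- lapply(
        c(richness = "richness", shannon = "shannon", pielou = "pielou"),
        function(v) tryCatch(kruskal_letters(al[[v]], ty),
                             error = function(e) conditionMessage(e)))
    }
  }
  beta <- lapply(tables, bray_curtis_matrix)
  perm <- lapply(names(beta), function(dom) {
    ty <- frame[rownames(beta[[dom]]), "grassland_type"]
    if (is.null(ty) || length(unique(ty)) < 2L) return(NULL)
    permanova(beta[[dom]], ty, n_perm = cfg$n_perm,
              seed = derive_seed(cfg$seed, paste0("perm", dom)))
  })
  names(perm) <- names(beta)

  # distance-decay: geographic + divergence predictors, slope contrasts
  geo <- geographic_distance_matrix(frame)
  ddr <- lapply(names(beta), function(dom) {
    fit_ddr(beta[[dom]], dm_subset(geo, rownames(beta[[dom]])), group = dom,
            n_perm = cfg$n_perm, seed = derive_seed(cfg$seed, paste0("ddr", dom)))
  })
  names(ddr) <- names(beta)
  contrasts <- if (length(ddr) >= 2L) compare_slopes(ddr) else NULL

  # VPA per microbial domain
  galpha <- alpha$grass
  frame_ext <- as.data.frame(frame)
  frame_ext$grass_margalef <- galpha[frame$sample_id, "margalef"]
  frame_ext$grass_shannon <- galpha[frame$sample_id, "shannon"]
  frame_ext$grass_pielou <- ifelse(is.na(galpha[frame$sample_id, "pielou"]), 0,
                                   galpha[frame$sample_id, "pielou"])
  vpa <- lapply(mic_doms, function(dom) {
    tab <- bundles[[dom]]$tables$microbe
    fe <- frame_ext[rownames(tab), ]
    pick <- function(vars) fe[, intersect(vars, names(fe)), drop = FALSE]
    vpa_three_way(tab,
                  pick(cfg$vpa_blocks$productivity),
                  pick(cfg$vpa_blocks$diversity),
                  pick(cfg$vpa_blocks$soil))
  })
  names(vpa) <- mic_doms

  # IDEN chain per domain + combined network
  idens <- lapply(mic_doms, function(dom) {
    b <- bundles[[dom]]
    build_iden(b$tables$grass, b$tables$microbe, b$frame,
               dm_subset(geo, b$frame$sample_id),
               r_threshold = cfg$r_threshold, p_threshold = cfg$p_threshold,
               n_inner = cfg$sparcc_inner, n_boot = cfg$n_boot,
               boot_inner = cfg$boot_inner, lted_perm = cfg$lted_perm,
               seed = derive_seed(cfg$seed, paste0("iden", dom)))
  })
  names(idens) <- mic_doms
  networks <- lapply(idens, `[[`, "network")
  networks$combined <- combine_networks(networks)
  log$network_stages <- lapply(idens, `[[`, "stages")

  # topology + stability
  topology <- lapply(networks, function(n)
    if (nrow(n$edges)) topology_summary(n) else NULL)
  stability <- lapply(names(networks), function(nm) {
    n <- networks[[nm]]
    if (nrow(n$edges) < 2L) return(NULL)
    list(attack = attack_tolerance(n, "random",
                                   seed = derive_seed(cfg$seed, paste0("att", nm))),
         vulnerability = vulnerability(n),
         null = null_model_ensemble(n, n_null = cfg$n_null,
                                    seed = derive_seed(cfg$seed, paste0("null", nm))))
  })
  names(stability) <- names(networks)

  # connectivity vs productivity/diversity/soil (partial Mantel screen)
  conn_mantel <- NULL
  comb <- networks$combined
  if (nrow(comb$edges)) {
    samp <- sort(Reduce(intersect, lapply(bundles, function(b) b$frame$sample_id)))
    tabs <- c(list(grass = tables$grass[samp, , drop = FALSE]),
              lapply(mic_doms, function(d) tables[[d]][samp, , drop = FALSE]))
    prof <- sample_connectivity_profile(comb, tabs)
    fe <- frame_ext[samp, ]
    conn_mantel <- connectivity_mantel_screen(
      prof$dm, fe,
      variables = list(productivity = c("H", "CD", "S", "FB", "DB"),
                       diversity = c("grass_margalef", "grass_shannon",
                                     "grass_pielou"),
                       soil = c("pH", "CEC", "OM", "TN", "TP", "TC", "SMC")),
      geo_dm = dm_subset(geo, samp), n_perm = cfg$n_perm,
      seed = derive_seed(cfg$seed, "connmantel"))
  }

  res <- list(bundle = list(frame = frame, tables = tables,
                            truth = study$truth),
              alpha = alpha, beta = beta, group_tests = group_tests,
              permanova = perm, ddr = ddr, slope_contrasts = contrasts,
              vpa = vpa, networks = networks, topology = topology,
              stability = stability, connectivity_mantel = conn_mantel,
              log = log)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg)
  res
}

write_pipeline_outputs <- function(res, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, ...)
  write_sample_frame(res$bundle$frame, out("sample_frame.tsv"))
  for (dom in names(res$bundle$tables))
    write_count_table(res$bundle$tables[[dom]], out(paste0("counts_", dom, ".tsv")))
  for (dom in names(res$alpha))
    write.table(res$alpha[[dom]], out(paste0("alpha_", dom, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  for (dom in names(res$beta))
    write.table(data.frame(sample_id = rownames(res$beta[[dom]]),
                           unclass(res$beta[[dom]]), check.names = FALSE),
                out(paste0("bray_curtis_", dom, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  ddr_tab <- do.call(rbind, lapply(res$ddr, function(f)
    data.frame(group = f$group, slope = f$slope, intercept = f$intercept,
               r2 = f$r2, p_ols = f$p_ols, p_perm = f$p_perm,
               n_pairs = f$n_pairs)))
  write.table(ddr_tab, out("ddr_fits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(res$slope_contrasts))
    write.table(res$slope_contrasts, out("ddr_slope_contrasts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  vpa_tab <- do.call(rbind, lapply(names(res$vpa), function(d) {
    v <- res$vpa[[d]]
    data.frame(domain = d, a_productivity = v$a, b_diversity = v$b,
               c_soil = v$c, ab = v$ab, ac = v$ac, bc = v$bc, abc = v$abc,
               total_explained = v$total_explained, residual = v$residual)
  }))
  write.table(vpa_tab, out("vpa.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (nm in names(res$networks))
    write_edge_list(res$networks[[nm]], out(paste0("edges_", nm, ".tsv")))
  if (!is.null(res$connectivity_mantel))
    write.table(res$connectivity_mantel, out("connectivity_mantel.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    seed = cfg$seed,
    permanova = lapply(res$permanova, function(p)
      if (is.null(p)) NULL else p[c("f", "r2", "p")]),
    topology = res$topology,
    robustness = lapply(res$stability, function(s)
      if (is.null(s)) NULL else list(robustness = s$attack$robustness,
                                     vulnerability = s$vulnerability,
                                     null_p_greater_emp = s$null$p_less)),
    log = res$log)
  jsonlite::write_json(summary, out("run_summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(res)
}
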