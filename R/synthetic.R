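#' Synthetic grassland transect communities with planted ground truth
#'
#' Emulates a multi-site alpine-grassland transect study design: 16 sites
#' (2 alpine swamp meadow, 4 alpine meadow, 6 alpine steppe, 4 temperate
#' steppe) x 3 replicates along a ~2,121 km transect, with altitude
#' decreasing and mean annual temperature increasing along the transect,
#' soil and grass biophysical variables drawn from grassland-type-specific
#' normal distributions, grass species with Gaussian niches (narrow breadth,
#' so grass turnover is steepest), and microbial communities whose latent
#' log-abundances combine a domain-specific spatial niche, planted
#' grass-host links, environmental drivers, and Gaussian noise. Counts are
#' drawn multinomially with lognormal library sizes, so the data are
#' genuinely compositional. Every stochastic sub-step derives a child seed
#' from the single master seed.
#'
#' @name synthetic-community
NULL

# Grassland-type reference distributions (mean, sd) for the landscape
# variables; types ordered along the transect from wettest/highest (ASM)
# to warmest/lowest (TS).
TYPE_PARAMS <- local({
  p <- list(
    pH  = list(ASM = c(7.21, 0.57), AM = c(7.02, 0.58), AS = c(8.07, 0.11), TS = c(8.12, 0.17)),
    CEC = list(ASM = c(25.51, 14.59), AM = c(27.09, 15.94), AS = c(6.60, 3.99), TS = c(11.94, 2.32)),
    OM  = list(ASM = c(86.05, 22.55), AM = c(131.30, 75.35), AS = c(44.43, 25.66), TS = c(46.25, 15.50)),
    TN  = list(ASM = c(3.40, 1.26), AM = c(4.35, 1.58), AS = c(1.84, 1.06), TS = c(2.55, 1.50)),
    TP  = list(ASM = c(0.57, 0.22), AM = c(0.73, 0.12), AS = c(0.43, 0.09), TS = c(0.71, 0.04)),
    TC  = list(ASM = c(5.30, 1.55), AM = c(8.55, 4.62), AS = c(3.55, 1.59), TS = c(3.31, 0.85)),
    SMC = list(ASM = c(50.75, 18.72), AM = c(30.31, 11.39), AS = c(14.45, 7.52), TS = c(15.26, 11.83)),
    H   = list(ASM = c(11.49, 4.16), AM = c(4.18, 2.73), AS = c(8.14, 8.40), TS = c(20.49, 5.09)),
    CD  = list(ASM = c(93.00, 11.91), AM = c(76.75, 11.74), AS = c(55.44, 15.56), TS = c(49.25, 20.76)),
    S   = list(ASM = c(9.67, 2.25), AM = c(11.92, 5.08), AS = c(6.56, 1.54), TS = c(5.42, 2.67)),
    FB  = list(ASM = c(388.13, 223.69), AM = c(361.10, 263.06), AS = c(216.49, 227.82), TS = c(266.03, 151.47)),
    DB  = list(ASM = c(187.20, 111.52), AM = c(124.70, 76.41), AS = c(107.80, 85.87), TS = c(136.73, 58.73)),
    MAT = list(ASM = c(-0.47, 0.93), AM = c(-0.19, 0.75), AS = c(0.34, 1.69), TS = c(3.66, 0.20)),
    altitude = list(ASM = c(4445.67, 234.42), AM = c(4187.58, 122.47),
                    AS = c(4014.89, 390.24), TS = c(3232.25, 67.45)))
  p
})

#' Generator configuration
#'
#' @param n_sites sites along the transect (default 16; with the default
#'   type split 2/4/6/4 scaled proportionally for other values).
#' @param replicates_per_site default 3.
#' @param n_grass_species default 30.
#' @param n_taxa named vector of microbial richness (archaea 150,
#'   bacteria 600, fungi 300).
#' @param transect_length_km default 2121.
#' @param library_meanlog,library_sdlog named lognormal library-size
#'   parameters per table.
#' @param noise_scale sd of the latent Gaussian noise (default 1.4; large
#'   relative to the niche signal so that taxa without a shared driver rarely
#'   exceed the association filter by chance).
#' @param grass_noise sd of the grass latent log-abundance noise (default
#'   1.0): grass species are spatially structured but not deterministic, so
#'   grass-grass correlations stay moderate.
#' @param grass_patchiness probability that a species inside its niche is
#'   nevertheless absent from a given site (default 0.35): real stands are
#'   patchy, which keeps grass occupancy from being a deterministic function
#'   of transect position.
#' @param link_density expected fraction of grass x microbe pairs carrying a
#'   planted direct link (default 0.005).
#' @param link_strength_range planted link strengths (default 0.8-1.2).
#' @param positive_links_only plant only positive links (default TRUE).
#' @param env_taxa_fraction fraction of microbes driven by environmental
#'   variables (default 0.35), disjoint from host-linked microbes.
#' @param env_block_weights relative driver weights of the productivity,
#'   soil and diversity blocks (defaults 1, 0.6, 0.15: productivity
#'   strongest, diversity weakest).
#' @param niche_breadth_frac Gaussian niche breadth as a fraction of the
#'   transect per organism group; grass narrowest so its distance-decay is
#'   steepest.
#' @param niche_amplitude spatial-niche amplitude (latent log-abundance sd)
#'   per microbial domain; together with breadth this plants the turnover
#'   ordering grass > archaea > bacteria > fungi.
#' @param seed master seed (mandatory).
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_sites = 16L, replicates_per_site = 3L,
                             n_grass_species = 30L,
                             n_taxa = c(archaea = 150L, bacteria = 600L,
                                        fungi = 300L),
                             transect_length_km = 2121,
                             library_meanlog = c(grass = log(5000),
                                                 archaea = log(35000),
                                                 bacteria = log(35000),
                                                 fungi = log(12500)),
                             library_sdlog = c(grass = 0.3, archaea = 0.22,
                                               bacteria = 0.22, fungi = 0.2),
                             noise_scale = 1.4,
                             grass_noise = 1.0,
                             grass_patchiness = 0.35,
                             link_density = 0.005,
                             link_strength_range = c(0.8, 1.2),
                             positive_links_only = TRUE,
                             env_taxa_fraction = 0.35,
                             env_block_weights = c(productivity = 1,
                                                   soil = 0.6,
                                                   diversity = 0.15),
                             niche_breadth_frac = c(grass = 0.20,
                                                    archaea = 0.25,
                                                    bacteria = 0.40,
                                                    fungi = 0.65),
                             niche_amplitude = c(archaea = 1.2,
                                                 bacteria = 0.85,
                                                 fungi = 0.25),
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_sites >= 1, replicates_per_site >= 1, n_grass_species >= 1,
            all(n_taxa >= 1), transect_length_km > 0, noise_scale >= 0,
            link_density >= 0, env_taxa_fraction >= 0)
  structure(list(
    n_sites = as.integer(n_sites),
    replicates_per_site = as.integer(replicates_per_site),
    n_grass_species = as.integer(n_grass_species),
    n_taxa = n_taxa, transect_length_km = transect_length_km,
    library_meanlog = library_meanlog, library_sdlog = library_sdlog,
    noise_scale = noise_scale, grass_noise = grass_noise,
    grass_patchiness = grass_patchiness, link_density = link_density,
    link_strength_range = link_strength_range,
    positive_links_only = positive_links_only,
    env_taxa_fraction = env_taxa_fraction,
    env_block_weights = env_block_weights,
    niche_breadth_frac = niche_breadth_frac,
    niche_amplitude = niche_amplitude,
    seed = as.integer(seed)), class = "generator_config")
}

# split sites over types proportionally to the reference design 2/4/6/4
site_type_split <- function(n_sites) {
  base <- c(ASM = 2, AM = 4, AS = 6, TS = 4)
  k <- floor(n_sites * base / sum(base))
  while (sum(k) < n_sites) k[which.max(base / sum(base) - k / n_sites)] <-
    k[which.max(base / sum(base) - k / n_sites)] + 1
  k
}

#' Generate the landscape (sample metadata) for a synthetic transect
#'
#' @param cfg a [generator_config()].
#' @return A [sample_frame()] with a `position_km` column (distance along
#'   the transect, used by the community generators).
#' @export
generate_landscape <- function(cfg) {
  with_seed(derive_seed(cfg$seed, "landscape"), {
    n_sites <- cfg$n_sites
    split <- site_type_split(n_sites)
    types <- rep(names(split), split)
    pos_site <- if (n_sites == 1L) cfg$transect_length_km / 2 else
      seq(0, cfg$transect_length_km, length.out = n_sites)
    # map transect positions onto coordinates: start at the reference SW
    # corner, heading NE, scaled so end-to-end haversine length matches
    lat0 <- 33.202; lon0 <- 95.565
    dlat <- 2.727; dlon <- 5.354
    base_frame <- data.frame(sample_id = c("a", "b"),
                             latitude = c(lat0, lat0 + dlat),
                             longitude = c(lon0, lon0 + dlon))
    base_km <- geographic_distance_matrix(sample_frame(base_frame))[1, 2]
    sc <- cfg$transect_length_km / base_km
    rows <- list()
    for (s in seq_len(n_sites)) {
      ty <- types[s]
      site_vals <- vapply(TYPE_PARAMS, function(p)
        rnorm(1, p[[ty]][1], p[[ty]][2] * sqrt(0.7)), 0)
      for (r in seq_len(cfg$replicates_per_site)) {
        pos <- pos_site[s] + rnorm(1, 0, 1)                  # ~1 km jitter
        pos <- min(max(pos, 0), cfg$transect_length_km)
        f <- pos / cfg$transect_length_km
        rep_vals <- vapply(names(TYPE_PARAMS), function(v)
          site_vals[v] + rnorm(1, 0, TYPE_PARAMS[[v]][[ty]][2] * sqrt(0.3)), 0)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("S%02d_%d", s, r),
          site_id = sprintf("site%02d", s),
          grassland_type = ty,
          latitude = lat0 + f * dlat * sc + rnorm(1, 0, 0.002),
          longitude = lon0 + f * dlon * sc + rnorm(1, 0, 0.002),
          position_km = pos,
          altitude = rep_vals["altitude"],
          MAT = rep_vals["MAT"],
          pH = max(rep_vals["pH"], 4),
          CEC = max(rep_vals["CEC"], 0.5),
          OM = max(rep_vals["OM"], 1),
          TN = max(rep_vals["TN"], 0.05),
          TP = max(rep_vals["TP"], 0.02),
          TC = max(rep_vals["TC"], 0.1),
          SMC = min(max(rep_vals["SMC"], 1), 100),
          H = max(rep_vals["H"], 0.5),
          CD = min(max(rep_vals["CD"], 1), 100),
          S = max(1, round(rep_vals["S"])),
          FB = max(rep_vals["FB"], 5),
          DB = max(rep_vals["DB"], 2))
      }
    }
    sample_frame(do.call(rbind, rows))
  })
}

#' Generate the grass community
#'
#' Species have Gaussian niches along the transect with narrow breadth;
#' per-sample realized richness tracks the landscape's S by retaining the
#' top-abundance species. Latent (pre-sampling) relative abundances are
#' attached as `attr(, "latent")` for ground-truth computations.
#'
#' @param frame landscape from [generate_landscape()].
#' @param cfg the [generator_config()].
#' @return A [count_table()] with domain `"grass"`.
#' @export
generate_grass_community <- function(frame, cfg) {
  with_seed(derive_seed(cfg$seed, "grass"), {
    L <- cfg$transect_length_km
    ns <- cfg$n_grass_species
    breadth <- cfg$niche_breadth_frac[["grass"]] * L
    opt <- seq(-0.05 * L, 1.05 * L, length.out = ns)
    amp <- rnorm(ns, 0, 0.5)
    pos <- frame$position_km
    lam <- exp(outer(pos, opt, function(p, o) -(p - o)^2 / (2 * breadth^2)) +
                 matrix(amp, length(pos), ns, byrow = TRUE) +
                 matrix(rnorm(length(pos) * ns, 0, cfg$grass_noise),
                        length(pos), ns))
    # site-level patchiness: a species can be absent from a stand even
    # inside its niche, so occupancy is not deterministic in position
    if (cfg$grass_patchiness > 0) {
      sites <- unique(frame$site_id)
      occ <- matrix(rbinom(length(sites) * ns, 1, 1 - cfg$grass_patchiness),
                    length(sites), ns, dimnames = list(sites, NULL))
      lam_full <- lam
      lam <- lam * occ[frame$site_id, ]
      for (i in which(rowSums(lam > 0) < 2L)) {  # a stand is never empty
        top <- order(lam_full[i, ], decreasing = TRUE)[1:2]
        lam[i, top] <- lam_full[i, top]
      }
    }
    # realized richness follows the landscape's S: keep the top species
    n_keep <- pmin(ns, pmax(2L, round(frame$S * 1.3)))
    for (i in seq_len(nrow(lam))) {
      drop <- order(lam[i, ], decreasing = TRUE)[-seq_len(n_keep[i])]
      lam[i, drop] <- 0
    }
    latent <- lam / rowSums(lam)
    libs <- pmax(200, round(rlnorm(nrow(lam), cfg$library_meanlog[["grass"]],
                                   cfg$library_sdlog[["grass"]])))
    counts <- t(vapply(seq_len(nrow(lam)), function(i)
      drop(rmultinom(1, libs[i], latent[i, ])), numeric(ns)))
    dimnames(counts) <- list(frame$sample_id, sprintf("grass_%02d", seq_len(ns)))
    dimnames(latent) <- dimnames(counts)
    out <- count_table(counts, "grass")
    attr(out, "latent") <- latent
    attr(out, "library_sizes") <- setNames(libs, frame$sample_id)
    attr(out, "stand_biomass") <- setNames(rowSums(lam), frame$sample_id)
    out
  })
}

ENV_BLOCK_VARS <- list(productivity = c("CD", "DB", "S"),
                       soil = c("pH", "TN", "TP", "SMC"),
                       diversity = c("grass_shannon", "grass_margalef",
                                     "grass_pielou"))

#' Generate microbial communities with planted ground truth
#'
#' Each microbe's latent log-abundance is baseline + (for host-linked taxa)
#' link strength x standardized host-grass log-abundance + (for env-driven
#' taxa, disjoint by construction) coefficients x standardized environmental
#' variables + (for the rest) a domain-breadth Gaussian spatial niche, plus
#' Gaussian noise. Counts are multinomial with lognormal library sizes.
#'
#' @param frame landscape from [generate_landscape()].
#' @param grass_table grass community from [generate_grass_community()].
#' @param cfg the [generator_config()].
#' @return list: `tables` (named [count_table()] per domain), `truth` (a
#'   `ground_truth` list: `direct_links`, `env_driven_pairs`, `ddr_slopes`,
#'   `vpa_weights`).
#' @export
generate_microbial_communities <- function(frame, grass_table, cfg) {
  stopifnot(identical(rownames(grass_table), frame$sample_id))
  L <- cfg$transect_length_km
  pos <- frame$position_km
  nsamp <- nrow(frame)
  glat <- attr(grass_table, "latent")
  if (is.null(glat)) glat <- unclass(grass_table) / rowSums(grass_table)
  g_alpha <- alpha_diversity(grass_table)
  env_table <- data.frame(CD = frame$CD, DB = frame$DB, S = frame$S,
                          pH = frame$pH, TN = frame$TN, TP = frame$TP,
                          SMC = frame$SMC,
                          grass_shannon = g_alpha$shannon,
                          grass_margalef = g_alpha$margalef,
                          grass_pielou = ifelse(is.na(g_alpha$pielou), 0,
                                                g_alpha$pielou))
  zscore <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  envz <- as.data.frame(lapply(env_table, zscore))
  host_signal <- apply(log(glat + 1e-6), 2L, zscore)
  tables <- list()
  links <- list(); env_pairs <- list()
  ddr_true <- c(grass = latent_ddr_slope(glat, frame))
  for (dom in names(cfg$n_taxa)) {
    nm <- cfg$n_taxa[[dom]]
    res <- with_seed(derive_seed(cfg$seed, paste0("microbe_", dom)), {
      taxa <- sprintf("%s_%03d", dom, seq_len(nm))
      baseline <- rnorm(nm, 0, 1)
      y <- matrix(baseline, nsamp, nm, byrow = TRUE)
      n_links <- round(cfg$link_density * ncol(grass_table) * nm)
      n_env <- round(cfg$env_taxa_fraction * nm)
      linked_idx <- if (n_links > 0) sample.int(nm, n_links) else integer(0)
      env_idx <- if (n_env > 0)
        sample(setdiff(seq_len(nm), linked_idx), n_env) else integer(0)
      rest_idx <- setdiff(seq_len(nm), c(linked_idx, env_idx))
      dom_links <- NULL
      if (length(linked_idx)) {
        hosts <- sample.int(ncol(grass_table), length(linked_idx),
                            replace = TRUE)
        strength <- runif(length(linked_idx), cfg$link_strength_range[1L],
                          cfg$link_strength_range[2L])
        sgn <- if (cfg$positive_links_only) rep(1L, length(linked_idx))
               else sample(c(-1L, 1L), length(linked_idx), replace = TRUE)
        for (k in seq_along(linked_idx))
          y[, linked_idx[k]] <- y[, linked_idx[k]] +
            sgn[k] * strength[k] * 2 * host_signal[, hosts[k]]
        dom_links <- data.frame(
          grass_taxon = colnames(grass_table)[hosts],
          microbe_taxon = taxa[linked_idx],
          sign = sgn, strength = strength, domain = dom)
      }
      dom_env <- NULL
      if (length(env_idx)) {
        blocks <- sample(names(cfg$env_block_weights), length(env_idx),
                         replace = TRUE,
                         prob = cfg$env_block_weights / sum(cfg$env_block_weights))
        vars <- vapply(blocks, function(b) sample(ENV_BLOCK_VARS[[b]], 1L), "")
        coefs <- cfg$env_block_weights[blocks] * 2 *
          sample(c(-1, 1), length(env_idx), replace = TRUE)
        for (k in seq_along(env_idx))
          y[, env_idx[k]] <- y[, env_idx[k]] + coefs[k] * envz[[vars[k]]]
        dom_env <- data.frame(taxon = taxa[env_idx], variable = vars,
                              coefficient = unname(coefs), block = blocks,
                              domain = dom)
      }
      if (length(rest_idx)) {
        breadth <- cfg$niche_breadth_frac[[dom]] * L
        opt <- runif(length(rest_idx), -0.05 * L, 1.05 * L)
        niche <- outer(pos, opt, function(p, o) -(p - o)^2 / (2 * breadth^2))
        # centre, then scale the niche term to the domain's amplitude
        # (average sd across taxa); amplitude sets how strongly the domain
        # turns over in space, hence the planted turnover-rate ordering
        niche <- scale(niche, scale = FALSE)
        nsd <- mean(apply(niche, 2L, sd))
        amp <- cfg$niche_amplitude[[dom]]
        if (nsd > 0) niche <- amp * niche / nsd
        y[, rest_idx] <- y[, rest_idx] + niche
      }
      latent_clean <- exp(y)  # noiseless latent (measurement truth)
      y <- y + matrix(rnorm(nsamp * nm, 0, cfg$noise_scale), nsamp, nm)
      lat <- exp(y)
      rel <- lat / rowSums(lat)
      libs <- pmax(500, round(rlnorm(nsamp, cfg$library_meanlog[[dom]],
                                     cfg$library_sdlog[[dom]])))
      counts <- t(vapply(seq_len(nsamp), function(i)
        drop(rmultinom(1, libs[i], rel[i, ])), numeric(nm)))
      dimnames(counts) <- list(frame$sample_id, taxa)
      dimnames(rel) <- dimnames(counts)
      list(counts = counts, rel = rel, libs = libs,
           links = dom_links, env = dom_env)
    })
    tab <- count_table(res$counts, dom)
    attr(tab, "latent") <- res$rel
    attr(tab, "library_sizes") <- setNames(res$libs, frame$sample_id)
    tables[[dom]] <- tab
    if (!is.null(res$links)) links[[dom]] <- res$links
    if (!is.null(res$env)) env_pairs[[dom]] <- res$env
    ddr_true[[dom]] <- latent_ddr_slope(res$rel, frame)
  }
  truth <- structure(list(
    direct_links = if (length(links)) do.call(rbind, links) else
      data.frame(grass_taxon = character(0), microbe_taxon = character(0),
                 sign = integer(0), strength = numeric(0),
                 domain = character(0)),
    env_driven_pairs = if (length(env_pairs)) do.call(rbind, env_pairs) else NULL,
    ddr_slopes = ddr_true,
    vpa_weights = cfg$env_block_weights / sum(cfg$env_block_weights)),
    class = "ground_truth")
  rownames(truth$direct_links) <- NULL
  list(tables = tables, truth = truth)
}

# true turnover: Bray-Curtis of latent relative abundances regressed on
# geographic distance (no count sampling = measurement-free slope)
latent_ddr_slope <- function(rel, frame) {
  bc <- bray_curtis_matrix(rel * 1e6 + 1e-12)  # BC is scale-free
  geo <- geographic_distance_matrix(frame)
  x <- upper_vec(unclass(geo)); y <- upper_vec(unclass(bc))
  if (sd(x) == 0) return(NA_real_)
  unname(coef(lm(y ~ x))[2L]) * 1000  # per 1000 km
}

#' Generate the full synthetic study bundle
#'
#' @param cfg a [generator_config()].
#' @return list: `frame`, `tables` (grass + per-domain microbial tables),
#'   `truth`, `cfg`.
#' @export
generate_study <- function(cfg) {
  frame <- generate_landscape(cfg)
  grass <- generate_grass_community(frame, cfg)
  # measured stand variables reflect the realized vegetation: blend the
  # type-level draws with the community's standing crop so cover and
  # biomass are measurements of the stand, not independent covariates
  B <- attr(grass, "stand_biomass")
  if (!is.null(B) && sd(log(B)) > 0) {
    z <- as.numeric(scale(log(B)))
    mix <- function(x, lo, hi) {
      v <- 0.55 * x + 0.45 * (mean(x) + z * sd(x))
      pmin(pmax(v, lo), hi)
    }
    frame$CD <- mix(frame$CD, 1, 100)
    frame$FB <- mix(frame$FB, 5, Inf)
    frame$DB <- mix(frame$DB, 2, Inf)
  }
  mic <- generate_microbial_communities(frame, grass, cfg)
  list(frame = frame,
       tables = c(list(grass = grass), mic$tables),
       truth = mic$truth, cfg = cfg)
}

#' Precision/recall of recovered direct links against planted truth
#'
#' @param net a `bipartite_network` (or list of them; edges pooled).
#' @param truth a `ground_truth`.
#' @return list: `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
evaluate_link_recovery <- function(net, truth) {
  nets <- if (inherits(net, "bipartite_network")) list(net) else net
  edges <- unique(do.call(rbind, lapply(nets, function(n)
    n$edges[, c("plant", "microbe")])))
  planted <- unique(paste(truth$direct_links$grass_taxon,
                          truth$direct_links$microbe_taxon))
  got <- unique(paste(edges$plant, edges$microbe))
  tp <- length(intersect(got, planted))
  list(precision = if (length(got)) tp / length(got) else NA_real_,
       recall = if (length(planted)) tp / length(planted) else NA_real_,
       tp = tp, fp = length(got) - tp, fn = length(planted) - tp)
}
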