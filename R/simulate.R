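#' Configuration of the synthetic-data generators
#'
#' Bundles and validates every parameter of the synthetic inputs: planted
#' co-overexpression modules with experiment-specific activation patterns,
#' planted clade-specific losses and strong/mild sequence divergences,
#' planted phylogenetic-profile patterns, and planted network communities.
#' One integer seed drives one dedicated pseudo-random stream per generator
#' (fixed offsets), so adding draws to one generator does not perturb the
#' others.
#'
#' @param n_genes Number of simulated genes. Default 600.
#' @param n_experiments Number of DE experiments. Default 10.
#' @param module_specs List of module descriptions, each a list with
#'   `size` (gene count), `active` (integer experiment indices) and
#'   `activation_prob` (probability a module gene is overexpressed in each
#'   active experiment). Module genes occupy the first genes, in order.
#' @param background_overexpr_prob Probability that a background gene is
#'   overexpressed in exactly one (uniformly chosen) experiment; background
#'   genes never exceed the thresholds in more than one experiment.
#'   Default 0.2.
#' @param n_focal_species,n_reference_species Species per contrast clade in
#'   the clade tables. Default 10 each.
#' @param n_profile_species Species in the phylogenetic-profile panel.
#'   Default 120.
#' @param planted_losses,planted_high_div,planted_mild_div Counts of genes
#'   planted as clade-specific losses, strong divergences and mild
#'   divergences (disjoint, taken from the start of the gene list).
#'   Defaults 40 / 15 / 45.
#' @param community_sizes Sizes of planted network communities (each >= 3).
#'   Default `c(30, 25, 20, 15)`.
#' @param intra_edge_prob,inter_edge_prob Edge probabilities within and
#'   between planted communities (`intra > inter`). Defaults 0.9 / 0.02.
#' @param profile_flip_noise Probability a profile cell is flipped.
#'   Default 0.05.
#' @param seed Integer master seed. Default 1.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 600L,
                              n_experiments = 10L,
                              module_specs = default_module_specs(),
                              background_overexpr_prob = 0.2,
                              n_focal_species = 10L,
                              n_reference_species = 10L,
                              n_profile_species = 120L,
                              planted_losses = 40L,
                              planted_high_div = 15L,
                              planted_mild_div = 45L,
                              community_sizes = c(30L, 25L, 20L, 15L),
                              intra_edge_prob = 0.9,
                              inter_edge_prob = 0.02,
                              profile_flip_noise = 0.05,
                              seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  n_experiments <- check_count(n_experiments, "n_experiments", min = 2L)
  check_fraction(background_overexpr_prob, "background_overexpr_prob")
  check_fraction(intra_edge_prob, "intra_edge_prob")
  check_fraction(inter_edge_prob, "inter_edge_prob")
  check_fraction(profile_flip_noise, "profile_flip_noise")
  n_focal_species <- check_count(n_focal_species, "n_focal_species")
  n_reference_species <- check_count(n_reference_species, "n_reference_species")
  n_profile_species <- check_count(n_profile_species, "n_profile_species")
  planted_losses <- check_count(planted_losses, "planted_losses")
  planted_high_div <- check_count(planted_high_div, "planted_high_div")
  planted_mild_div <- check_count(planted_mild_div, "planted_mild_div")
  community_sizes <- check_count(community_sizes, "community_sizes")
  for (m in module_specs) {
    check_count(m$size, "module size", min = 1L)
    check_fraction(m$activation_prob, "activation_prob")
    if (any(m$active < 1L | m$active > n_experiments)) {
      stop2("module active experiments out of range",
            class = "ciliascreen_config_error")
    }
  }
  if (sum(vapply(module_specs, function(m) m$size, numeric(1))) > n_genes) {
    stop2("sum of module sizes exceeds n_genes",
          class = "ciliascreen_config_error")
  }
  if (planted_losses + planted_high_div + planted_mild_div > n_genes) {
    stop2("planted conservation categories exceed n_genes",
          class = "ciliascreen_config_error")
  }
  structure(list(
    n_genes = n_genes, n_experiments = n_experiments,
    module_specs = module_specs,
    background_overexpr_prob = background_overexpr_prob,
    n_focal_species = n_focal_species,
    n_reference_species = n_reference_species,
    n_profile_species = n_profile_species,
    planted_losses = planted_losses, planted_high_div = planted_high_div,
    planted_mild_div = planted_mild_div,
    community_sizes = community_sizes,
    intra_edge_prob = intra_edge_prob, inter_edge_prob = inter_edge_prob,
    profile_flip_noise = profile_flip_noise,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_module_specs <- function() {
  list(
    list(size = 40L, active = c(1L, 2L, 3L), activation_prob = 0.9),
    list(size = 40L, active = c(3L, 4L, 5L), activation_prob = 0.9),
    list(size = 40L, active = c(5L, 6L, 7L, 8L), activation_prob = 0.9),
    list(size = 40L, active = c(7L, 8L, 9L, 10L), activation_prob = 0.9),
    list(size = 40L, active = c(1L, 2L, 9L, 10L), activation_prob = 0.9)
  )
}

gene_ids <- function(n) sprintf("G%05d", seq_len(n))
experiment_ids <- function(n) sprintf("E%02d", seq_len(n))

# Dedicated stream offsets, one per generator.
.stream <- c(de = 101L, clade = 211L, profiles = 307L, network = 401L,
             annotations = 503L)

#' Simulate differential-expression result tables with planted modules
#'
#' Genes of a planted module are overexpressed (logFC in `[1.5, 4]`,
#' p-value in `[1e-6, 0.01]`) in each of the module's active experiments
#' with probability `activation_prob`, and sub-threshold everywhere else.
#' Background genes are overexpressed in at most one experiment.
#'
#' @param config A [simulation_config()].
#' @return List with `tables` (named list of data frames `gene_id`, `logfc`,
#'   `pvalue`, one per experiment) and `truth` (data frame `gene`, `module`;
#'   `"background"` for unplanted genes).
#' @export
simulate_de_experiments <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + .stream[["de"]])
  n <- config$n_genes
  ne <- config$n_experiments
  genes <- gene_ids(n)
  exps <- experiment_ids(ne)

  module <- rep("background", n)
  pos <- 0L
  for (mi in seq_along(config$module_specs)) {
    sz <- config$module_specs[[mi]]$size
    module[(pos + 1L):(pos + sz)] <- sprintf("M%d", mi)
    pos <- pos + sz
  }

  logfc <- matrix(stats::runif(n * ne, -1, 0.9), n, ne)
  pval <- matrix(stats::runif(n * ne, 0.06, 1), n, ne)
  for (mi in seq_along(config$module_specs)) {
    spec <- config$module_specs[[mi]]
    rows <- which(module == sprintf("M%d", mi))
    for (e in spec$active) {
      on <- stats::runif(length(rows)) < spec$activation_prob
      logfc[rows[on], e] <- stats::runif(sum(on), 1.5, 4)
      pval[rows[on], e] <- stats::runif(sum(on), 1e-6, 0.01)
    }
  }
  bg <- which(module == "background")
  on <- stats::runif(length(bg)) < config$background_overexpr_prob
  pick <- sample.int(ne, sum(on), replace = TRUE)
  logfc[cbind(bg[on], pick)] <- stats::runif(sum(on), 1.5, 4)
  pval[cbind(bg[on], pick)] <- stats::runif(sum(on), 1e-6, 0.01)

  tables <- lapply(seq_len(ne), function(e) {
    data.frame(gene_id = genes, logfc = logfc[, e], pvalue = pval[, e],
               stringsAsFactors = FALSE)
  })
  names(tables) <- exps
  list(tables = tables,
       truth = data.frame(gene = genes, module = module,
                          stringsAsFactors = FALSE))
}

# Fixed reference-identity profile: mean 90, known spread. Planted focal
# identities are set an exact number of reference SDs below the reference
# mean, so the classifier recovers categories deterministically.
.ref_identity_profile <- function(n_ref) {
  base <- c(88, 92, 90, 89, 91, 90, 87, 93, 90, 90)
  rep_len(base, n_ref)
}

#' Simulate clade-contrast ortholog presence and identity tables
#'
#' Plants `planted_losses` genes with no focal-clade ortholog (full
#' reference support), `planted_high_div` genes with focal identities far
#' beyond the high-divergence threshold (score 6 reference SDs), and
#' `planted_mild_div` genes between the thresholds (score 2.25); remaining
#' genes are conserved (|score| <= 0.5). Margins are at least twice the
#' classifier threshold gap, so category recovery is exact, not
#' probabilistic.
#'
#' @param config A [simulation_config()] with both clade sizes >= 2.
#' @return List with `clade_table` (data frame per [classify_gene()], list
#'   columns for identities) and `truth` (data frame `gene`, `category`).
#' @export
simulate_clade_tables <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_focal_species < 2L || config$n_reference_species < 2L) {
    stop2("both clades need >= 2 species for divergence statistics",
          class = "ciliascreen_config_error")
  }
  set.seed(config$seed + .stream[["clade"]])
  n <- config$n_genes
  genes <- gene_ids(n)
  nf <- config$n_focal_species
  nr <- config$n_reference_species
  nl <- config$planted_losses
  nh <- config$planted_high_div
  nm <- config$planted_mild_div

  category <- rep("CONSERVED", n)
  if (nl > 0) category[seq_len(nl)] <- "ABSENT"
  if (nh > 0) category[nl + seq_len(nh)] <- "HIGH_DIVERGENCE"
  if (nm > 0) category[nl + nh + seq_len(nm)] <- "MILD_DIVERGENCE"

  ref_ids <- .ref_identity_profile(nr)
  ref_mean <- mean(ref_ids)
  ref_sd <- stats::sd(ref_ids)
  target_d <- ifelse(category == "HIGH_DIVERGENCE", 6,
              ifelse(category == "MILD_DIVERGENCE", 2.25,
                     stats::runif(n, -0.5, 0.5)))
  focal_val <- ref_mean - target_d * ref_sd

  clade_table <- data.frame(
    gene = genes,
    focal_presence = ifelse(category == "ABSENT", 0L, nf),
    n_focal = nf,
    ref_presence = nr,
    n_ref = nr,
    stringsAsFactors = FALSE
  )
  clade_table$focal_identities <- lapply(seq_len(n), function(i) {
    if (category[i] == "ABSENT") numeric(0) else rep(focal_val[i], nf)
  })
  clade_table$ref_identities <- rep(list(ref_ids), n)
  list(clade_table = clade_table,
       truth = data.frame(gene = genes, category = category,
                          stringsAsFactors = FALSE))
}

#' Build a nested synthetic eukaryotic species panel
#'
#' Deterministic panel with three nested label levels (supergroup,
#' phylum-level clade, subclade), ciliation flags (fungi, plants and
#' nematodes are non-ciliated) and a focal bony-fish subclade.
#'
#' @param n_species Panel size (>= 20).
#' @return Data frame `species`, `supergroup`, `clade`, `subclade`,
#'   `ciliated`, `focal`.
#' @export
make_species_panel <- function(n_species) {
  n_species <- check_count(n_species, "n_species", min = 20L)
  # proportions loosely mirroring a eukaryote-wide ortholog panel
  n_fungi <- max(2L, round(0.15 * n_species))
  n_plants <- max(2L, round(0.15 * n_species))
  n_protist <- max(2L, round(0.10 * n_species))
  n_metazoa <- n_species - n_fungi - n_plants - n_protist
  n_nema <- max(2L, round(0.12 * n_metazoa))
  n_arthro <- max(2L, round(0.15 * n_metazoa))
  n_cnid <- max(1L, round(0.08 * n_metazoa))
  n_chordata <- n_metazoa - n_nema - n_arthro - n_cnid
  n_focal <- max(2L, round(0.20 * n_chordata))
  n_eutel <- max(2L, round(0.20 * n_chordata))
  n_mamm <- max(2L, round(0.25 * n_chordata))
  n_amph <- max(1L, round(0.15 * n_chordata))
  n_aves <- n_chordata - n_focal - n_eutel - n_mamm - n_amph

  sup <- c(rep("Fungi", n_fungi), rep("Archaeplastida", n_plants),
           rep("SAR", n_protist), rep("Metazoa", n_metazoa))
  clade <- c(rep("Ascomycota", n_fungi), rep("Streptophyta", n_plants),
             rep("Ciliophora", n_protist),
             rep("Nematoda", n_nema), rep("Arthropoda", n_arthro),
             rep("Cnidaria", n_cnid), rep("Chordata", n_chordata))
  sub <- c(rep("Ascomycota", n_fungi), rep("Streptophyta", n_plants),
           rep("Ciliophora", n_protist),
           rep("Nematoda", n_nema), rep("Arthropoda", n_arthro),
           rep("Cnidaria", n_cnid),
           rep("Otomorpha", n_focal), rep("Euteleosteomorpha", n_eutel),
           rep("Mammalia", n_mamm), rep("Amphibia", n_amph),
           rep("Aves", n_aves))
  data.frame(
    species = sprintf("sp%04d", seq_len(n_species)),
    supergroup = sup, clade = clade, subclade = sub,
    ciliated = !(sup %in% c("Fungi", "Archaeplastida") | sub == "Nematoda"),
    focal = sub == "Otomorpha",
    stringsAsFactors = FALSE
  )
}

# Block order matters: the first block coincides with the genes planted as
# focal-clade losses/divergences in simulate_clade_tables, which in a real
# screen are exactly the genes expected to lack focal-clade orthologs.
.profile_pattern_levels <- c("ABSENT_FOCAL_CLADE", "ABSENT_NONCILIATED",
                             "CHORDATE_RESTRICTED", "METAZOA_RESTRICTED",
                             "PRESENT_BROADLY")

#' Simulate gene-by-species phylogenetic profiles with planted patterns
#'
#' Genes receive one of five planted clade patterns (cycled in equal
#' blocks): present everywhere, absent in non-ciliated clades, absent in
#' the focal clade only, chordate-restricted, metazoan-restricted. Noise
#' flips each cell independently with probability `profile_flip_noise`.
#'
#' @param config A [simulation_config()].
#' @return List with `matrix` (0/1 genes x species), `panel` (species
#'   panel, see [make_species_panel()]) and `truth` (data frame `gene`,
#'   `pattern`).
#' @export
simulate_profiles <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + .stream[["profiles"]])
  n <- config$n_genes
  genes <- gene_ids(n)
  panel <- make_species_panel(config$n_profile_species)
  ns <- nrow(panel)

  base <- rbind(
    PRESENT_BROADLY = rep(1L, ns),
    ABSENT_NONCILIATED = as.integer(panel$ciliated),
    ABSENT_FOCAL_CLADE = as.integer(!panel$focal),
    CHORDATE_RESTRICTED = as.integer(panel$clade == "Chordata"),
    METAZOA_RESTRICTED = as.integer(panel$supergroup == "Metazoa")
  )
  pattern <- .profile_pattern_levels[(seq_len(n) - 1L) %/%
                                       ceiling(n / 5) + 1L]
  m <- base[pattern, , drop = FALSE]
  dimnames(m) <- list(genes, panel$species)
  if (config$profile_flip_noise > 0) {
    flip <- matrix(stats::runif(n * ns) < config$profile_flip_noise, n, ns)
    m[flip] <- 1L - m[flip]
  }
  list(matrix = m, panel = panel,
       truth = data.frame(gene = genes, pattern = pattern,
                          stringsAsFactors = FALSE))
}

#' Simulate a scored interaction network with planted communities
#'
#' Stochastic block model over the first `sum(community_sizes)` genes:
#' within-community pairs are connected with probability `intra_edge_prob`
#' and scores in `[0.9, 1]`; between-community pairs with probability
#' `inter_edge_prob` and scores in `[0.5, 0.85]`.
#'
#' @param config A [simulation_config()] with all community sizes >= 3 and
#'   `intra_edge_prob > inter_edge_prob`.
#' @return List with `edges` (data frame `gene_a`, `gene_b`, `score`) and
#'   `truth` (data frame `gene`, `community`).
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (any(config$community_sizes < 3L)) {
    stop2("community sizes must be >= 3", class = "ciliascreen_config_error")
  }
  if (config$intra_edge_prob <= config$inter_edge_prob) {
    stop2("intra_edge_prob must exceed inter_edge_prob",
          class = "ciliascreen_config_error")
  }
  set.seed(config$seed + .stream[["network"]])
  sizes <- config$community_sizes
  n <- sum(sizes)
  if (n > config$n_genes) {
    stop2("community sizes exceed n_genes", class = "ciliascreen_config_error")
  }
  genes <- gene_ids(config$n_genes)[seq_len(n)]
  community <- rep(seq_along(sizes), sizes)

  pairs <- utils::combn(n, 2L)
  same <- community[pairs[1L, ]] == community[pairs[2L, ]]
  p <- ifelse(same, config$intra_edge_prob, config$inter_edge_prob)
  on <- stats::runif(ncol(pairs)) < p
  score <- numeric(sum(on))
  same_on <- same[on]
  score[same_on] <- stats::runif(sum(same_on), 0.9, 1)
  score[!same_on] <- stats::runif(sum(!same_on), 0.5, 0.85)
  edges <- data.frame(gene_a = genes[pairs[1L, on]],
                      gene_b = genes[pairs[2L, on]],
                      score = score, stringsAsFactors = FALSE)
  list(edges = edges,
       truth = data.frame(gene = genes, community = community,
                          stringsAsFactors = FALSE))
}

#' Simulate a gene-to-term annotation map with planted enrichments
#'
#' @param config A [simulation_config()].
#' @param planted Named list: term id -> character vector of genes fully
#'   annotated with that term (the planted enrichments).
#' @param n_background_terms Number of random background terms. Default 20.
#' @param term_size Genes per background term. Default 15.
#' @return Data frame `term_id`, `term_name`, `gene`.
#' @export
simulate_annotations <- function(config, planted = list(),
                                 n_background_terms = 20L, term_size = 15L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + .stream[["annotations"]])
  genes <- gene_ids(config$n_genes)
  rows <- list()
  for (t in names(planted)) {
    rows[[t]] <- data.frame(term_id = t, term_name = t, gene = planted[[t]],
                            stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_background_terms)) {
    t <- sprintf("BG%04d", i)
    rows[[t]] <- data.frame(
      term_id = t, term_name = t,
      gene = sort(sample(genes, min(term_size, length(genes)))),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
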