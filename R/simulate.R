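# Synthetic multi-omic data with planted ground truth.
#
# Every input the pipeline consumes can be generated here: a factor-model
# expression matrix with planted coexpression modules whose latent factors
# partially drive simulated blood-pressure traits; an eSNP map whose
# causal-module eSNPs carry inflated GWAS association; block-structured LD;
# a scale-free interaction network with planted key-driver hubs; and a
# knockout-style mouse DE list concentrated in one hub's neighborhood.
# Identical seed + config give byte-identical outputs; each stage draws from
# its own sub-stream (see stage_seed) so stages can be regenerated alone.

#' Default simulation configuration
#'
#' Returns the configuration describing the study conditions the generator
#' emulates: 200 unrelated samples, six planted modules (within-module
#' correlation 0.6) over 600 genes, weak module-trait coupling (|r| ~ 0.1,
#' the regime blood transcriptome studies operate in), four of the six
#' modules designated genetically causal with GWAS non-centrality 30 on
#' their eSNPs, block LD (3-SNP blocks), a 2000-node preferential-attachment
#' interaction network carrying the measured gene symbols with one planted
#' key-driver hub per causal module, and a knockout DE list perturbing 40%
#' of the first hub's 3-layer neighborhood against a 15% background rate.
#'
#' @param seed integer; mandatory for every downstream generator call.
#' @param ... named overrides of any top-level field.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_samples = 200L,
    module_spec = data.frame(
      name = paste0("M", 1:6),
      size = c(50L, 45L, 40L, 35L, 30L, 30L),
      within_cor = rep(0.6, 6),
      trait_effect = c(0.10, 0.10, 0.10, 0.10, 0.00, 0.10),
      stringsAsFactors = FALSE
    ),
    n_null_genes = 370L,
    covariate_effects = c(age = 0.25, sex = 0.10, bmi = 0.20),
    cell_effect_fraction = 0.4,
    cell_effect_strength = 0.45,
    dbp_rho = 0.6,
    n_snps = 3000L,
    ld_block_size = 3L,
    ld_flip_noise = 0.03,
    ld_panel_n = 400L,
    maf_range = c(0.1, 0.4),
    esnps_per_gene = 2L,
    causal_modules = paste0("M", 1:4),
    gwas_noncentrality = 30,
    network = list(n_nodes = 2000L, attachment_k = 1L,
                   planted_kd_count = 4L, kd_neighborhood_enrichment = 0.9,
                   stuff_all_layers = FALSE),
    mouse_de = list(target_kd = NULL, perturb_fraction = 0.4,
                    background_fraction = 0.15)
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (is.null(cfg$seed)) nd_stop("sim_config: seed is mandatory", "netdriver_config_error")
  ms <- cfg$module_spec
  if (any(ms$within_cor > 0.99))
    nd_stop("sim_config: within-correlation target > 0.99 is infeasible",
            "netdriver_config_error")
  if (any(ms$within_cor <= 0 & ms$size > 0) && any(ms$within_cor < 0))
    nd_stop("sim_config: within_cor must be in (0,1)", "netdriver_config_error")
  fr <- c(cfg$cell_effect_fraction, cfg$network$kd_neighborhood_enrichment,
          cfg$mouse_de$perturb_fraction, cfg$mouse_de$background_fraction)
  if (any(fr < 0 | fr > 1))
    nd_stop("sim_config: fractions must lie in [0,1]", "netdriver_config_error")
  if (!all(cfg$causal_modules %in% ms$name))
    nd_stop("sim_config: causal_modules not in module_spec", "netdriver_config_error")
  load2 <- sum(ms$trait_effect^2) + sum(cfg$covariate_effects^2)
  if (load2 >= 1)
    nd_stop("sim_config: trait loadings leave no residual variance",
            "netdriver_config_error")
  invisible(cfg)
}

n_genes_of <- function(cfg) sum(cfg$module_spec$size) + cfg$n_null_genes

# Per-gene cell-type component: a random direction over the standardized
# cell proportions, itself standardized so the planted cell variance is
# exactly the configured strength squared (cell proportions are
# compositional, so an unnormalized random direction can fall in their
# degenerate dimension and silently lose variance).
cell_component <- function(zcells, affected) {
  if (!affected) return(0)
  w <- stats::rnorm(ncol(zcells))
  comp <- as.numeric(zcells %*% w)
  sdc <- stats::sd(comp)
  if (sdc < 1e-12) return(0)
  comp / sdc
}

#' Simulate expression, phenotypes, and module ground truth
#'
#' Gene g in module m follows `x_gi = sqrt(w_m) f_mi + s c_gi + e_gi`, where
#' `f_m` is the module's latent factor, `w_m` the within-module correlation
#' target (so any two clean module genes correlate at ~`w_m`), and `c_g` an
#' optional standardized cell-type component planted in a configurable
#' fraction of genes. Null genes are pure noise. SBP is
#' `sum_m r_m f_m + covariates + noise` on a standardized scale (then mapped
#' to mm Hg), so `r_m` is the planted factor-trait correlation; DBP shares
#' the SBP core at correlation `dbp_rho`; hypertension is the clinical
#' threshold rule SBP >= 140 or DBP >= 90.
#'
#' @param cfg a [sim_config()].
#' @return list with `expr` (genes x samples matrix), `phen` (data.frame),
#'   and `truth` (partition, loadings, causal modules, factors).
#' @export
gen_expression <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, "expression"))
  n <- cfg$n_samples
  ms <- cfg$module_spec
  G <- n_genes_of(cfg)
  genes <- sprintf("GENE%04d", seq_len(G))
  samples <- sprintf("S%04d", seq_len(n))

  # covariates
  age <- stats::rnorm(n, 50, 10)
  sex <- stats::rbinom(n, 1, 0.5)
  bmi <- stats::rnorm(n, 27, 4)
  cohort <- sample(c("offspring", "gen3"), n, replace = TRUE)
  cell_raw <- cbind(stats::rgamma(n, 10), stats::rgamma(n, 5), stats::rgamma(n, 3))
  cells <- cell_raw / rowSums(cell_raw)
  colnames(cells) <- paste0("cell_", c("neut", "lymph", "mono"))
  zcells <- scale(cells)

  # planted module factors
  f <- matrix(stats::rnorm(nrow(ms) * n), nrow(ms), n,
              dimnames = list(ms$name, samples))

  partition <- rep("null", G); names(partition) <- genes
  idx <- 1L
  expr <- matrix(0, G, n, dimnames = list(genes, samples))
  cell_affected <- stats::runif(G) < cfg$cell_effect_fraction
  s <- cfg$cell_effect_strength
  for (m in seq_len(nrow(ms))) {
    sz <- ms$size[m]
    if (sz == 0L) next
    rows <- idx:(idx + sz - 1L)
    partition[rows] <- ms$name[m]
    lam <- sqrt(ms$within_cor[m])
    for (g in rows) {
      cellvar <- if (cell_affected[g]) s^2 else 0
      evar <- 1 - ms$within_cor[m] - cellvar
      if (evar < 0) nd_stop("sim_config: within_cor + cell effect exceed unit variance",
                            "netdriver_config_error")
      expr[g, ] <- lam * f[m, ] + s * cell_component(zcells, cell_affected[g]) +
        sqrt(evar) * stats::rnorm(n)
    }
    idx <- idx + sz
  }
  for (g in seq.int(idx, length.out = cfg$n_null_genes)) {
    cellvar <- if (cell_affected[g]) s^2 else 0
    expr[g, ] <- s * cell_component(zcells, cell_affected[g]) +
      sqrt(1 - cellvar) * stats::rnorm(n)
  }

  # traits on a standardized core scale
  beta <- cfg$covariate_effects
  zc <- cbind(age = as.numeric(scale(age)), sex = as.numeric(scale(sex)),
              bmi = as.numeric(scale(bmi)))
  core_sig <- as.numeric(ms$trait_effect %*% f) +
    as.numeric(zc[, names(beta), drop = FALSE] %*% beta)
  resvar <- 1 - sum(ms$trait_effect^2) - sum(beta^2)
  sbp_core <- core_sig + sqrt(resvar) * stats::rnorm(n)
  rho <- cfg$dbp_rho
  dbp_core <- rho * sbp_core + sqrt(1 - rho^2) * stats::rnorm(n)
  sbp <- 120 + 15 * sbp_core
  dbp <- 80 + 10 * dbp_core

  phen <- data.frame(sample_id = samples, sbp = sbp, dbp = dbp,
                     htn = as.integer(sbp >= 140 | dbp >= 90),
                     age = age, sex = sex, bmi = bmi,
                     cells, cohort = cohort,
                     stringsAsFactors = FALSE, check.names = FALSE)
  truth <- list(
    true_partition = partition,
    true_trait_loadings = stats::setNames(ms$trait_effect, ms$name),
    true_causal_modules = cfg$causal_modules,
    factors = f,
    cell_affected = stats::setNames(cell_affected, genes)
  )
  list(expr = expr, phen = phen, truth = truth)
}

#' Simulate eSNPs, GWAS summary statistics, and LD dosages
#'
#' SNPs come in LD blocks built by copying a block-seed dosage vector with a
#' small per-sample flip probability, so within-block r2 is high (>= ~0.8)
#' and across-block r2 is ~0. Each gene receives `esnps_per_gene` distinct
#' SNPs (the first cis, the rest trans). GWAS p-values for eSNPs of
#' causal-module genes are drawn from a non-central chi-square test
#' (non-centrality `gwas_noncentrality` for SBP, x0.7 for DBP); all other
#' SNPs are uniform.
#'
#' @param cfg a [sim_config()].
#' @param truth ground truth from [gen_expression()].
#' @return list with `esnp`, `gwas` data.frames, `dosages` (panel samples x
#'   SNPs matrix), and updated `truth` gaining `true_causal_snps`.
#' @export
gen_genetics <- function(cfg, truth) {
  set.seed(stage_seed(cfg$seed, "genetics"))
  G <- n_genes_of(cfg)
  if (cfg$n_snps < G * cfg$esnps_per_gene)
    nd_stop("gen_genetics: more eSNPs requested than SNPs available",
            "netdriver_config_error")
  n_snps <- cfg$n_snps
  snps <- sprintf("rs%05d", seq_len(n_snps))
  bs <- cfg$ld_block_size
  blocks <- rep(seq_len(ceiling(n_snps / bs)), each = bs)[seq_len(n_snps)]
  npanel <- cfg$ld_panel_n
  dosages <- matrix(0L, npanel, n_snps, dimnames = list(NULL, snps))
  for (b in unique(blocks)) {
    cols <- which(blocks == b)
    maf <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
    seedvec <- stats::rbinom(npanel, 2L, maf)
    for (j in seq_along(cols)) {
      if (j == 1L) { dosages[, cols[j]] <- seedvec; next }
      flip <- stats::runif(npanel) < cfg$ld_flip_noise
      v <- seedvec
      v[flip] <- stats::rbinom(sum(flip), 2L, maf)
      dosages[, cols[j]] <- v
    }
  }

  genes <- names(truth$true_partition)
  pool <- sample(snps)
  take <- matrix(pool[seq_len(G * cfg$esnps_per_gene)], nrow = G, byrow = TRUE)
  esnp <- data.frame(
    snp_id = as.vector(t(take)),
    gene_id = rep(genes, each = cfg$esnps_per_gene),
    kind = rep(c("cis", rep("trans", cfg$esnps_per_gene - 1L)), G),
    eqtl_p = 10^-stats::runif(G * cfg$esnps_per_gene, 3, 8),
    eqtl_fdr = stats::runif(G * cfg$esnps_per_gene, 0, 0.09),
    stringsAsFactors = FALSE
  )

  causal_genes <- genes[truth$true_partition %in% cfg$causal_modules]
  causal_snps <- unique(esnp$snp_id[esnp$gene_id %in% causal_genes])
  ncp <- cfg$gwas_noncentrality
  draw_p <- function(ids, ncp_trait) {
    p <- stats::runif(n_snps)
    if (ncp_trait > 0 && length(ids)) {
      i <- match(ids, snps)
      p[i] <- stats::pchisq(stats::rchisq(length(i), df = 1, ncp = ncp_trait),
                            df = 1, lower.tail = FALSE)
    }
    pmax(p, 1e-300)
  }
  gwas <- data.frame(
    snp_id = snps,
    chr = (blocks - 1L) %% 22L + 1L,
    pos = seq_len(n_snps) * 1000L,
    p_sbp = draw_p(causal_snps, ncp),
    p_dbp = draw_p(causal_snps, ncp * 0.7),
    stringsAsFactors = FALSE
  )
  truth$true_causal_snps <- causal_snps
  list(esnp = esnp, gwas = gwas, dosages = dosages, truth = truth)
}

# Outer-shell placement slots of a prospective hub: nodes at distance
# exactly 3, one per branch (subtree under one hub neighbor). The hub's
# depth-3 neighborhood collects every slot; any other node sees at most
# its own branch's single one (plus the hub's own label), which keeps all
# non-hub enrichment tests in the null.
hub_slots <- function(g, v) {
  d <- as.numeric(igraph::distances(g, v))
  shell3 <- which(d == 3L)
  if (!length(shell3)) return(integer())
  branch_of <- function(x) {
    while (d[x] > 1L) {
      nb <- as.integer(igraph::neighbors(g, x))
      x <- nb[d[nb] == d[x] - 1L][1L]
    }
    x
  }
  branch <- vapply(shell3, branch_of, 1L)
  vapply(split(shell3, branch), function(s) resample(s, 1L), 1L,
         USE.NAMES = FALSE)
}

#' Simulate a scale-free interaction network with planted key drivers
#'
#' One preferential-attachment (Barabasi-Albert) component is grown per
#' planted key driver, plus a background component, joined by sparse bridge
#' edges; each hub is the top-degree node of its component, so every hub
#' owns a deep branch system and hubs are well separated. Gene symbols are
#' then assigned to nodes so that each hub's 3-step neighborhood is
#' enriched for its module's genes (one hub per causal module): a fraction
#' `kd_neighborhood_enrichment` of the hub's 3rd-shell positions — at most
#' one per branch, i.e. per subtree hanging off a hub neighbor — receives
#' module genes, the hub itself carries a measured gene from outside the
#' causal modules, and the remaining non-causal measured genes are
#' scattered over random nodes. Placing the planted genes on the outer
#' shell, spread one-per-branch, makes the hub the unique node whose
#' depth-3 neighborhood collects them all — any other node only ever sees
#' its own branch's single one — so key-driver recovery has a well-defined
#' positive set. With `stuff_all_layers = TRUE` the whole <=3-step
#' neighborhood is filled at the enrichment rate instead (outermost layer
#' first), which at rate 1 yields a neighborhood fully contained in the
#' causal set. Nodes beyond the measured genes carry filler symbols
#' (`NODE####`), mirroring interaction databases that cover genes outside
#' any one expression panel.
#'
#' @param cfg a [sim_config()].
#' @param truth ground truth from [gen_expression()].
#' @return list with `network` (igraph, nodes named by gene symbol) and
#'   updated `truth` gaining `true_kds` (named by module).
#' @export
gen_network <- function(cfg, truth) {
  set.seed(stage_seed(cfg$seed, "network"))
  nw <- cfg$network
  genes <- names(truth$true_partition)
  n_kd <- nw$planted_kd_count
  if (n_kd == 0L) {
    g <- igraph::sample_pa(nw$n_nodes, power = 1, m = nw$attachment_k,
                           directed = FALSE)
    kd_nodes <- integer(0)
  } else {
    # one preferential-attachment component per planted hub plus a
    # background component, joined by sparse bridges: each hub is the
    # top-degree node of its own component and so owns a deep branch
    # system; the union of components keeps the power-law degree mix
    comp_n <- nw$n_nodes %/% (n_kd + 1L)
    sizes <- c(rep(comp_n, n_kd), nw$n_nodes - n_kd * comp_n)
    comps <- lapply(sizes, function(s)
      igraph::sample_pa(s, power = 1, m = nw$attachment_k, directed = FALSE))
    g <- do.call(igraph::disjoint_union, comps)
    offsets <- cumsum(c(0L, sizes[-length(sizes)]))
    # hub of a component = the high-degree node with the most outer-shell
    # placement slots (branches can be shallow, so raw degree is not enough)
    kd_nodes <- vapply(seq_len(n_kd), function(i) {
      cand <- offsets[i] + order(igraph::degree(comps[[i]]),
                                 decreasing = TRUE)[1:12]
      cand[which.max(vapply(cand, function(v)
        length(hub_slots(g, v)), 1L))]
    }, 1L)
    bg_nodes <- offsets[n_kd + 1L] + seq_len(sizes[n_kd + 1L])
    for (i in seq_len(n_kd)) {
      comp_nodes <- offsets[i] + seq_len(sizes[i])
      d_hub <- as.numeric(igraph::distances(g, kd_nodes[i], comp_nodes))
      far <- comp_nodes[d_hub >= 4L]
      src <- if (length(far)) resample(far, 1L) else resample(comp_nodes, 1L)
      g <- igraph::add_edges(g, c(src, resample(bg_nodes, 1L)))
    }
  }

  labels <- rep(NA_character_, nw$n_nodes)
  rate <- nw$kd_neighborhood_enrichment
  mods <- cfg$causal_modules
  pools <- lapply(mods, function(m) resample(genes[truth$true_partition == m]))
  names(pools) <- mods
  null_pool <- resample(genes[truth$true_partition == "null"])
  kd_module <- if (n_kd > 0L) mods[(seq_len(n_kd) - 1L) %% length(mods) + 1L]
               else character()

  for (i in seq_along(kd_nodes)) {
    v <- kd_nodes[[i]]; m <- kd_module[[i]]
    if (!length(pools[[m]])) next
    # the hub itself carries a measured gene from outside the causal
    # modules: its neighborhood is enriched for the module without the hub
    # label adding a set member that nearby nodes would co-count
    if (length(null_pool)) {
      labels[v] <- null_pool[1L]; null_pool <- null_pool[-1L]
    }
    d <- as.numeric(igraph::distances(g, v))
    if (isTRUE(nw$stuff_all_layers)) {
      targets <- order(d, decreasing = TRUE)
      targets <- targets[d[targets] >= 1L & d[targets] <= 3L]
      targets <- targets[is.na(labels[targets])]
      hit <- targets[stats::runif(length(targets)) < rate]
    } else {
      slots <- hub_slots(g, v)
      slots <- slots[is.na(labels[slots])]
      slots <- resample(slots)
      hit <- slots[seq_len(round(rate * length(slots)))]
    }
    n_take <- min(length(hit), length(pools[[m]]))
    if (n_take > 0L) {
      labels[hit[seq_len(n_take)]] <- pools[[m]][seq_len(n_take)]
      pools[[m]] <- pools[[m]][-seq_len(n_take)]
    }
  }

  # scatter the remaining measured genes over random unlabeled nodes and
  # fill the rest with filler symbols; causal-module genes that did not get
  # a planted position stay out of the network entirely (interaction
  # databases only ever cover part of an expression panel), so each planted
  # hub's module signal is not diluted by randomly scattered members
  placed <- labels[!is.na(labels)]
  unplaced <- setdiff(genes, placed)
  if (n_kd > 0L && !isTRUE(nw$stuff_all_layers))
    unplaced <- setdiff(unplaced,
                        genes[truth$true_partition %in% cfg$causal_modules])
  rest <- resample(unplaced)
  open <- which(is.na(labels))
  if (length(rest) > length(open))
    nd_stop("gen_network: fewer nodes than gene symbols", "netdriver_config_error")
  labels[resample(open, length(rest))] <- rest
  open <- which(is.na(labels))
  labels[open] <- sprintf("NODE%04d", seq_along(open))
  igraph::V(g)$name <- labels
  igraph::graph_attr(g, "name") <- "synthetic_ppi"
  truth$true_kds <- stats::setNames(labels[kd_nodes], kd_module)
  list(network = g, truth = truth)
}

#' Simulate a knockout-perturbation mouse DE list and ortholog map
#'
#' Orthologs are 1:1 by construction (human symbol lower-cased with a
#' capitalized first letter). Genes inside the target key driver's 3-layer
#' network neighborhood are called differentially expressed with probability
#' `perturb_fraction`, all others with `background_fraction`; q-values are
#' drawn consistent with the calls (DE: U(0, 0.05), non-DE: U(0.05, 1)).
#'
#' @param cfg a [sim_config()].
#' @param truth ground truth from [gen_network()].
#' @param network igraph network from [gen_network()].
#' @return list with `mouse_de` data.frame, `orthologs` named vector
#'   (mouse -> human), and updated `truth` gaining `true_perturbed_genes`.
#' @export
gen_mouse_de <- function(cfg, truth, network) {
  set.seed(stage_seed(cfg$seed, "mouse"))
  md <- cfg$mouse_de
  target <- md$target_kd
  if (is.null(target)) target <- truth$true_kds[[1L]]
  if (!target %in% igraph::V(network)$name)
    nd_stop("gen_mouse_de: target KD not in network", "netdriver_config_error")
  nbhd <- kd_neighborhood(network, target, depth = 3L)
  genes <- names(truth$true_partition)
  mouse_ids <- paste0(toupper(substr(genes, 1, 1)),
                      tolower(substr(genes, 2, nchar(genes))))
  orthologs <- stats::setNames(genes, mouse_ids)
  in_nbhd <- genes %in% nbhd
  p_de <- ifelse(in_nbhd, md$perturb_fraction, md$background_fraction)
  de <- stats::runif(length(genes)) < p_de
  q <- ifelse(de, stats::runif(length(genes), 0, 0.05),
              stats::runif(length(genes), 0.05, 1))
  # keep q strictly below/above the 0.05 call boundary
  q[de & q >= 0.05] <- 0.049
  mouse_de <- data.frame(mouse_gene_id = mouse_ids, q_value = q,
                         direction = sample(c(-1L, 1L), length(genes),
                                            replace = TRUE),
                         stringsAsFactors = FALSE)
  truth$true_perturbed_genes <- genes[de]
  truth$mouse_target_kd <- target
  list(mouse_de = mouse_de, orthologs = orthologs, truth = truth)
}

#' Generate the full synthetic input bundle
#'
#' Runs all four generators and, when `outdir` is given, writes every input
#' table the pipeline consumes (expression, phenotypes, eSNPs, GWAS,
#' dosages, network edge list, mouse DE, orthologs) plus `truth.json`.
#'
#' @param cfg a [sim_config()].
#' @param outdir optional directory to write files into.
#' @return invisible list with all simulated objects and `truth`.
#' @export
simulate_all <- function(cfg, outdir = NULL) {
  ex <- gen_expression(cfg)
  gn <- gen_genetics(cfg, ex$truth)
  nt <- gen_network(cfg, gn$truth)
  mo <- gen_mouse_de(cfg, nt$truth, nt$network)
  out <- list(expr = ex$expr, phen = ex$phen, esnp = gn$esnp, gwas = gn$gwas,
              dosages = gn$dosages, network = nt$network,
              mouse_de = mo$mouse_de, orthologs = mo$orthologs,
              truth = mo$truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_expression(out$expr, file.path(outdir, "expression.tsv"))
    write_phenotypes(out$phen, file.path(outdir, "phenotypes.tsv"))
    write_tsv(out$esnp, file.path(outdir, "esnp.tsv"))
    write_tsv(out$gwas, file.path(outdir, "gwas.tsv"))
    dos <- data.frame(sample_id = sprintf("P%04d", seq_len(nrow(out$dosages))),
                      out$dosages, check.names = FALSE)
    write_tsv(dos, file.path(outdir, "dosages.tsv"))
    write_network(out$network, file.path(outdir, "network.tsv"))
    write_tsv(out$mouse_de, file.path(outdir, "mouse_de.tsv"))
    write_tsv(data.frame(mouse_gene_id = names(out$orthologs),
                         human_gene_id = unname(out$orthologs),
                         stringsAsFactors = FALSE),
              file.path(outdir, "orthologs.tsv"))
    tr <- out$truth
    tr$factors <- NULL
    tr$true_partition <- as.list(tr$true_partition)
    tr$cell_affected <- as.list(tr$cell_affected)
    jsonlite::write_json(tr, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
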