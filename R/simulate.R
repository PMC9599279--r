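#' Configuration for the synthetic network generator
#'
#' Defines a taxonomy-structured population of reference phage genomes
#' (as protein-cluster profiles) and vOTUs derived from them, with known
#' ground-truth lineages. Each genus gets a private core PC set
#' (`genus_core_frac` of the genome), each family a shared family core
#' (`family_core_frac`); the remaining PCs are genome-private. vOTUs copy
#' a uniformly chosen parent reference, lose each PC independently with
#' probability `dropout`, and gain `noise_pcs` fresh PCs of their own.
#'
#' @param n_families,genera_per_family,genomes_per_genus Population shape.
#' @param pcs_per_genome Protein clusters per reference genome.
#' @param genus_core_frac,family_core_frac Fractions of the genome held
#'   in the genus/family core sets (their sum must be at most 1).
#' @param n_votus Number of vOTUs to derive.
#' @param dropout Per-PC loss probability when deriving a vOTU.
#' @param noise_pcs Fresh (unshared) PCs added per vOTU.
#' @param status_overrides Named numeric vector of vOTU fractions to
#'   force into non-default statuses, names among `Overlap`, `Outlier`,
#'   `Clustered/Singleton` (e.g. `c(Overlap = 0.1)`). Overlap and Outlier
#'   vOTUs get their cluster field blanked, as clustering would leave
#'   them unplaced.
#' @param threshold Edge score threshold passed to [build_network()].
#' @param seed Integer seed; equal seed and config give byte-identical
#'   fixtures.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_families = 2L, genera_per_family = 3L,
                       genomes_per_genus = 4L, pcs_per_genome = 30L,
                       genus_core_frac = 0.4, family_core_frac = 0.2,
                       n_votus = 60L, dropout = 0, noise_pcs = 0L,
                       status_overrides = numeric(0),
                       threshold = 1, seed = 42L) {
  cfg <- list(n_families = as.integer(n_families),
              genera_per_family = as.integer(genera_per_family),
              genomes_per_genus = as.integer(genomes_per_genus),
              pcs_per_genome = as.integer(pcs_per_genome),
              genus_core_frac = genus_core_frac,
              family_core_frac = family_core_frac,
              n_votus = as.integer(n_votus),
              dropout = dropout, noise_pcs = as.integer(noise_pcs),
              status_overrides = status_overrides,
              threshold = threshold, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_families >= 1, genera_per_family >= 1,
              genomes_per_genus >= 1, pcs_per_genome >= 1, n_votus >= 0,
              noise_pcs >= 0, threshold >= 0)
    if (genus_core_frac < 0 || family_core_frac < 0 ||
        genus_core_frac + family_core_frac > 1) {
      stop("core fractions must be non-negative and sum to at most 1",
           call. = FALSE)
    }
    if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)",
                                          call. = FALSE)
    if (length(status_overrides)) {
      ok <- c("Overlap", "Outlier", "Clustered/Singleton")
      if (is.null(names(status_overrides)) ||
          !all(names(status_overrides) %in% ok)) {
        stop("status_overrides names must be among: ",
             paste(sQuote(ok), collapse = ", "), call. = FALSE)
      }
      if (any(status_overrides < 0) || sum(status_overrides) > 1) {
        stop("status_overrides fractions must be in [0, 1] and sum <= 1",
             call. = FALSE)
      }
    }
  })
  structure(cfg, class = "sim_config")
}

.sim_hosts <- c("Escherichia coli", "Salmonella enterica",
                "Klebsiella pneumoniae", "Bacillus subtilis",
                "Staphylococcus aureus", "Pseudomonas aeruginosa")

#' Generate a synthetic gene-sharing network with known ground truth
#'
#' Builds reference PC profiles structured by the configured taxonomy,
#' derives vOTUs from them, scores all profiles into a weighted network
#' with [build_network()], and writes cluster/subcluster labels straight
#' from the ground truth (cluster = family index, subcluster = genus
#' index) — clustering is an input to the classifier, so fixtures control
#' it exactly rather than re-deriving it.
#'
#' @param cfg A [sim_config()].
#' @return List with `profiles` (named list of PC sets), `ref_taxonomy`,
#'   `overview`, `ground_truth` (data frames), `edges`, `ctx` (from
#'   [build_network()]) and `config`.
#' @export
simulate_network <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(cfg$seed)
  n_gcore <- round(cfg$genus_core_frac * cfg$pcs_per_genome)
  n_fcore <- round(cfg$family_core_frac * cfg$pcs_per_genome)
  n_priv <- cfg$pcs_per_genome - n_gcore - n_fcore

  profiles <- list()
  gt <- list()
  ref_rows <- list()
  for (f in seq_len(cfg$n_families)) {
    fam_core <- sprintf("pc_fam%d_core_%03d", f, seq_len(n_fcore))
    family <- sprintf("Fam%dviridae", f)
    for (g in seq_len(cfg$genera_per_family)) {
      gen_core <- sprintf("pc_fam%d_gen%d_core_%03d", f, g, seq_len(n_gcore))
      subfamily <- sprintf("Fam%dgen%dvirinae", f, g)
      genus <- sprintf("Fam%dgen%dvirus", f, g)
      for (k in seq_len(cfg$genomes_per_genus)) {
        acc <- sprintf("REF_f%dg%d_%02d", f, g, k)
        priv <- sprintf("pc_fam%d_gen%d_g%d_priv_%03d", f, g, k,
                        seq_len(n_priv))
        profiles[[acc]] <- c(fam_core, gen_core, priv)
        host <- .sim_hosts[((f - 1) * cfg$genera_per_family + g - 1) %%
                             length(.sim_hosts) + 1]
        ref_rows[[acc]] <- data.frame(
          accession = acc, realm = "Duplodnaviria", phylum = "Uroviricota",
          class = "Caudoviricetes", order = "Caudovirales",
          family = family, subfamily = subfamily, genus = genus,
          host = host, stringsAsFactors = FALSE)
        gt[[acc]] <- data.frame(
          id = acc, kind = "reference", parent = NA_character_,
          family = family, subfamily = subfamily, genus = genus,
          cluster = sprintf("VC_%d", f),
          subcluster = sprintf("VC_%d_%d", f, g), stringsAsFactors = FALSE)
      }
    }
  }
  ref_taxonomy <- do.call(rbind, unname(ref_rows))
  ref_ids <- ref_taxonomy$accession

  votu_ids <- if (cfg$n_votus > 0) {
    sprintf("vOTU_%03d", seq_len(cfg$n_votus))
  } else character(0)
  parents <- if (cfg$n_votus > 0) {
    ref_ids[sample.int(length(ref_ids), cfg$n_votus, replace = TRUE)]
  } else character(0)
  for (v in seq_along(votu_ids)) {
    prof <- profiles[[parents[v]]]
    if (cfg$dropout > 0) {
      prof <- prof[stats::runif(length(prof)) >= cfg$dropout]
    }
    if (cfg$noise_pcs > 0) {
      prof <- c(prof, sprintf("pc_noise_votu%03d_%03d", v,
                              seq_len(cfg$noise_pcs)))
    }
    profiles[[votu_ids[v]]] <- prof
    pg <- gt[[parents[v]]]
    gt[[votu_ids[v]]] <- data.frame(
      id = votu_ids[v], kind = "votu", parent = parents[v],
      family = pg$family, subfamily = pg$subfamily, genus = pg$genus,
      cluster = pg$cluster, subcluster = pg$subcluster,
      stringsAsFactors = FALSE)
  }
  ground_truth <- do.call(rbind, unname(gt))
  rownames(ground_truth) <- NULL

  status <- stats::setNames(rep("Clustered", nrow(ground_truth)),
                            ground_truth$id)
  cluster <- stats::setNames(ground_truth$cluster, ground_truth$id)
  subcluster <- stats::setNames(ground_truth$subcluster, ground_truth$id)
  if (length(cfg$status_overrides) && cfg$n_votus > 0) {
    pool <- votu_ids
    for (lab in names(cfg$status_overrides)) {
      k <- floor(cfg$status_overrides[[lab]] * cfg$n_votus)
      if (k < 1) next
      pick <- sample(pool, min(k, length(pool)))
      pool <- setdiff(pool, pick)
      status[pick] <- lab
      if (lab %in% c("Overlap", "Outlier")) {
        cluster[pick] <- NA_character_
        subcluster[pick] <- NA_character_
      }
    }
  }
  overview <- data.frame(
    genome = ground_truth$id, status = unname(status[ground_truth$id]),
    overlap_count = ifelse(status[ground_truth$id] == "Overlap", 2L,
                           NA_integer_),
    cluster_id = unname(cluster[ground_truth$id]),
    subcluster_id = unname(subcluster[ground_truth$id]),
    stringsAsFactors = FALSE)

  net <- build_network(profiles, threshold = cfg$threshold)
  list(profiles = profiles, ref_taxonomy = ref_taxonomy,
       overview = overview, ground_truth = ground_truth,
       edges = net$edges, ctx = net$ctx, config = cfg)
}

#' Write a simulated fixture to disk
#'
#' Emits the four files every other module consumes: the edge list
#' (`network.ntw`, vConTACT2 dialect), the clustering overview
#' (`overview.csv`), the reference taxonomy (`reference_taxonomy.csv`),
#' the ground truth (`ground_truth.csv`), plus a JSON manifest of the
#' configuration. All files parse cleanly through the package readers;
#' equal seed and config give byte-identical files.
#'
#' @param sim Output of [simulate_network()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the file paths written.
#' @export
emit_fixture <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(network = file.path(out_dir, "network.ntw"),
             overview = file.path(out_dir, "overview.csv"),
             taxonomy = file.path(out_dir, "reference_taxonomy.csv"),
             ground_truth = file.path(out_dir, "ground_truth.csv"),
             manifest = file.path(out_dir, "manifest.json"))
  writeLines(sprintf("%s %s %.6f", sim$edges$source, sim$edges$target,
                     sim$edges$weight), paths[["network"]])
  ov <- sim$overview
  vc <- ifelse(is.na(ov$subcluster_id),
               ifelse(is.na(ov$cluster_id), "", ov$cluster_id),
               ov$subcluster_id)
  status <- mapply(format_cluster_status, ov$status, ov$overlap_count,
                   USE.NAMES = FALSE)
  utils::write.csv(
    data.frame(Genome = ov$genome, `VC Status` = status, VC = vc,
               check.names = FALSE, stringsAsFactors = FALSE),
    paths[["overview"]], row.names = FALSE, quote = TRUE, eol = "\n")
  rt <- sim$ref_taxonomy
  names(rt) <- c("Accession", "Realm", "Phylum", "Class", "Order",
                 "Family", "Subfamily", "Genus", "Host")
  utils::write.csv(rt, paths[["taxonomy"]], row.names = FALSE,
                   quote = TRUE, eol = "\n")
  utils::write.csv(sim$ground_truth, paths[["ground_truth"]],
                   row.names = FALSE, quote = TRUE, eol = "\n")
  cfg <- unclass(sim$config)
  cfg$status_overrides <- as.list(cfg$status_overrides)
  jsonlite::write_json(cfg, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}

#' Genus-recovery statistics against simulated ground truth
#'
#' For vOTUs directly connected to at least one reference of their true
#' genus, the fraction whose classified genus equals the ground truth.
#'
#' @param sim Output of [simulate_network()].
#' @param results Output of [classify_all()] on the assembled fixture.
#' @return List: `eligible` (vOTUs with a same-genus reference neighbor),
#'   `recovered`, `rate` (NaN when no vOTU is eligible), and
#'   `classified` (vOTUs with any level other than unclassified).
#' @export
recovery_stats <- function(sim, results) {
  gt <- sim$ground_truth
  rownames(gt) <- gt$id
  refs <- gt$id[gt$kind == "reference"]
  adj <- rbind(as.matrix(sim$edges[, c("source", "target")]),
               as.matrix(sim$edges[, c("target", "source")]))
  eligible <- recovered <- 0L
  for (i in seq_len(nrow(results))) {
    v <- results$votu[i]
    nb <- adj[adj[, 1] == v, 2]
    nb_ref <- intersect(nb, refs)
    if (!length(nb_ref)) next
    if (!gt[v, "genus"] %in% gt[nb_ref, "genus"]) next
    eligible <- eligible + 1L
    if (!is.na(results$genus[i]) && results$genus[i] == gt[v, "genus"]) {
      recovered <- recovered + 1L
    }
  }
  list(eligible = eligible, recovered = recovered,
       rate = recovered / eligible,
       classified = sum(results$level != "unclassified"))
}
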