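#' Configuration for the synthetic network generator
#'
#' Describes a stochastic block model whose communities sit on a 1-D
#' core-periphery axis (community 0 = core), with per-community ER and age
#' centers increasing core to periphery. This emulates the structure the
#' analysis assumes in real regulatory networks: cold/old genes clustered
#' in central communities, hot/young genes toward the periphery, edge-level
#' ER/age assortativity, and annotation sets nested within communities.
#'
#' Between-community edge probability interpolates log-linearly from
#' `p_out_core` to `p_out_far` with the pair's mean position on the axis,
#' so the core community is denser to every other community than any more
#' peripheral community is.
#'
#' @param n_communities number of communities
#' @param sizes community sizes (recycled to `n_communities`)
#' @param p_in within-community edge probability
#' @param p_out_core,p_out_far between-community probability at the core
#'   and at the far periphery
#' @param directed_fraction fraction of generated edges that are strictly
#'   directed (random orientation); the rest are undirected
#' @param er_centers per-community ER centers (substitutions/site/By,
#'   increasing core to periphery)
#' @param er_sd gene-level ER standard deviation
#' @param age_centers per-community age centers (integers in 0..12,
#'   increasing core to periphery)
#' @param age_sd gene-level age standard deviation
#' @param sets_per_community annotation sets planted per community
#' @param set_fraction fraction of a community sampled into each set
#' @param leakage expected fraction of a set drawn from outside its home
#'   community
#' @param seed integer seed; the generator is fully determined by it
#' @return object of class `synth_config`
#' @export
synth_config <- function(n_communities = 4L, sizes = 75L, p_in = 0.15,
                         p_out_core = 0.05, p_out_far = 0.005,
                         directed_fraction = 0.5,
                         er_centers = c(0.5, 1, 2, 3), er_sd = 0.5,
                         age_centers = c(2, 5, 8, 11), age_sd = 1.5,
                         sets_per_community = 3L, set_fraction = 0.4,
                         leakage = 0.05, seed = 1L) {
  sizes <- rep_len(as.integer(sizes), n_communities)
  er_centers <- rep_len(er_centers, n_communities)
  age_centers <- rep_len(age_centers, n_communities)
  stopifnot(all(sizes > 0), sum(sizes) > 0,
            p_in >= 0, p_in <= 1, p_out_core >= 0, p_out_core <= 1,
            p_out_far >= 0, p_out_far <= 1,
            directed_fraction >= 0, directed_fraction <= 1,
            all(er_centers >= 0), all(age_centers >= 0), all(age_centers <= 12),
            set_fraction > 0, leakage >= 0, leakage < 1)
  structure(list(n_communities = as.integer(n_communities), sizes = sizes,
                 p_in = p_in, p_out_core = p_out_core, p_out_far = p_out_far,
                 directed_fraction = directed_fraction,
                 er_centers = er_centers, er_sd = er_sd,
                 age_centers = age_centers, age_sd = age_sd,
                 sets_per_community = as.integer(sets_per_community),
                 set_fraction = set_fraction, leakage = leakage,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Between-community density interpolates with the pair's mean position on
# the core-periphery axis, so the core community is denser to every other
# community than any more peripheral community is.
block_prob <- function(a, b, cfg) {
  if (a == b) return(cfg$p_in)
  K <- cfg$n_communities
  u <- if (K > 1) (a + b) / (2 * (K - 1)) else 1
  if (cfg$p_out_core == 0 || cfg$p_out_far == 0)
    return(cfg$p_out_core * (1 - u) + cfg$p_out_far * u)
  exp((1 - u) * log(cfg$p_out_core) + u * log(cfg$p_out_far))
}

#' Generate a synthetic network with planted evolutionary structure
#'
#' Samples the stochastic block model described by the config, assigns each
#' gene an ER drawn from a normal centered on its community's ER center
#' (clamped at 0) and an age from a rounded normal clamped to 0..12, and
#' plants annotation sets mostly inside their home community. Fully
#' deterministic given `config$seed`.
#'
#' @param config synth_config
#' @return object of class `synth_bundle`: `network` (gene_network),
#'   `annotation` (evo_annotation), `partition` (planted
#'   community_partition, with Q evaluated on the generated network),
#'   `sets` (gene_set_collection), `config`
#' @export
generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_impl(config))
}

generate_impl <- function(cfg) {
  K <- cfg$n_communities
  n <- sum(cfg$sizes)
  genes <- sprintf("G%04d", seq_len(n))
  memb <- rep(seq_len(K) - 1L, cfg$sizes)

  edge_rows <- list()
  for (a in seq_len(K) - 1L) for (b in a:(K - 1L)) {
    ia <- which(memb == a); ib <- which(memb == b)
    if (a == b) {
      if (length(ia) < 2L) next
      pr <- t(utils::combn(ia, 2L))
    } else {
      pr <- as.matrix(expand.grid(ia, ib))
    }
    keep <- stats::runif(nrow(pr)) < block_prob(a, b, cfg)
    pr <- pr[keep, , drop = FALSE]
    if (nrow(pr) == 0L) next
    is_dir <- stats::runif(nrow(pr)) < cfg$directed_fraction
    flip <- is_dir & stats::runif(nrow(pr)) < 0.5
    s <- ifelse(flip, pr[, 2L], pr[, 1L])
    t2 <- ifelse(flip, pr[, 1L], pr[, 2L])
    edge_rows[[length(edge_rows) + 1L]] <-
      data.frame(source = genes[s], target = genes[t2], weight = 1,
                 directed = is_dir, stringsAsFactors = FALSE)
  }
  ed <- do.call(rbind, edge_rows)
  net <- gene_network(ed, nodes = genes)

  er <- pmax(stats::rnorm(n, cfg$er_centers[memb + 1L], cfg$er_sd), 0)
  age <- pmin(pmax(as.integer(round(stats::rnorm(n, cfg$age_centers[memb + 1L],
                                                 cfg$age_sd))), 0L), 12L)
  ann <- evo_annotation(er = stats::setNames(er, genes),
                        age = stats::setNames(age, genes))

  sets <- list(); cats <- character()
  cat_cycle <- c("P", "L", "B", "C")
  for (c in seq_len(K) - 1L) {
    home <- genes[memb == c]
    for (s in seq_len(cfg$sets_per_community)) {
      size <- max(5L, round(cfg$set_fraction * length(home)))
      n_leak <- stats::rbinom(1L, size, cfg$leakage)
      n_home <- min(size - n_leak, length(home))
      members <- sample(home, n_home)
      if (n_leak > 0L)
        members <- c(members, sample(setdiff(genes, home), n_leak))
      nm <- sprintf("SET_C%d_%d", c, s)
      sets[[nm]] <- members
      cats <- c(cats, cat_cycle[(c + s - 1L) %% 4L + 1L])
    }
  }
  gsc <- gene_set_collection(sets, cats)
  part <- community_partition(stats::setNames(memb, genes), net)
  structure(list(network = net, annotation = ann, partition = part,
                 sets = gsc, config = cfg),
            class = "synth_bundle")
}

#' Generate the topology-independent annotation null
#'
#' Same network, planted partition and annotation sets as [generate()], but
#' with the (ER, age) pairs randomly permuted across genes, destroying any
#' coupling between annotation and topology. Used for calibration: on this
#' bundle the edge-difference z-score should be near 0 and group labels
#' should be "average".
#'
#' @param config synth_config
#' @return synth_bundle
#' @export
null_generate <- function(config = synth_config()) {
  bundle <- generate(config)
  n <- length(bundle$annotation$genes)
  perm <- withr::with_seed(config$seed + 777L, sample.int(n))
  genes <- bundle$annotation$genes
  bundle$annotation <- evo_annotation(
    er = stats::setNames(unname(bundle$annotation$er)[perm], genes),
    age = stats::setNames(unname(bundle$annotation$age)[perm], genes))
  bundle
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat("synth_bundle:\n  ")
  print(x$network)
  cat("  ")
  print(x$annotation)
  cat("  ")
  print(x$partition)
  invisible(x)
}

#' Write a synthetic bundle to disk in the pipeline's input formats
#'
#' Writes `edges.tsv`, `er.tsv`, `age.tsv`, `sets.gmt` and
#' `truth_communities.tsv` under `dir`; the files round-trip through
#' [load_edge_list()], [load_annotation()] and [read_gmt()].
#'
#' @param bundle synth_bundle
#' @param dir output directory (created if missing)
#' @return invisible named vector of file paths
#' @export
write_synth_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synth_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# grnevo synthetic data; seed=%d", bundle$config$seed)
  paths <- c(edges = file.path(dir, "edges.tsv"),
             er = file.path(dir, "er.tsv"),
             age = file.path(dir, "age.tsv"),
             sets = file.path(dir, "sets.gmt"),
             truth = file.path(dir, "truth_communities.tsv"))
  write_edge_list(bundle$network, paths[["edges"]], header_lines = hdr)
  write_annotation(bundle$annotation, er_path = paths[["er"]],
                   age_path = paths[["age"]], header_lines = hdr)
  write_gmt(bundle$sets, paths[["sets"]], header_lines = hdr)
  con <- file(paths[["truth"]], "w")
  writeLines(c(hdr, "gene\tcommunity"), con)
  writeLines(sprintf("%s\t%d", names(bundle$partition$assignment),
                     unname(bundle$partition$assignment)), con)
  close(con)
  invisible(paths)
}
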