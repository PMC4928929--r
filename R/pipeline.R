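#' Pipeline run configuration
#'
#' Bundles input paths and analysis parameters for [run_all()]. Counts are
#' the scaled-down defaults under which the full pipeline on the default
#' synthetic data finishes in minutes; set `n_random = 20000` etc. for
#' publication-scale runs.
#'
#' @param edges path to the TSV edge list
#' @param er,age paths to the two-column annotation tables (either may be
#'   `NULL`)
#' @param sets path to a GMT gene-set file (or `NULL` to skip enrichment
#'   and IE stages)
#' @param out_dir output directory
#' @param n_random rewired replicates for the edge-difference test
#' @param n_sets random sets for the group mean test
#' @param n_controls shuffled-order controls for the SE curve
#' @param alpha one-tailed significance threshold for hot/cold/old/young
#' @param enrich_threshold adjusted-p cutoff for enrichment
#' @param enrich_top_k enriched sets reported per community
#' @param top_k number of largest communities analyzed
#' @param se_start,se_step SE-curve first window and increment;
#'   `se_start = NULL` uses min(500, half the annotated genes)
#' @param seed master seed, recorded in every output header
#' @return object of class `run_config`
#' @export
run_config <- function(edges, er = NULL, age = NULL, sets = NULL,
                       out_dir = "grnevo-out", n_random = 200L,
                       n_sets = 300L, n_controls = 100L, alpha = 1e-3,
                       enrich_threshold = 1e-4, enrich_top_k = 3L,
                       top_k = 10L, se_start = NULL, se_step = 10L,
                       seed = 1L) {
  stopifnot(n_random >= 1, n_sets >= 1, n_controls >= 1, top_k >= 1,
            se_step >= 1, alpha > 0, enrich_threshold > 0)
  structure(list(edges = edges, er = er, age = age, sets = sets,
                 out_dir = out_dir, n_random = as.integer(n_random),
                 n_sets = as.integer(n_sets), n_controls = as.integer(n_controls),
                 alpha = alpha, enrich_threshold = enrich_threshold,
                 enrich_top_k = as.integer(enrich_top_k),
                 top_k = as.integer(top_k),
                 se_start = if (is.null(se_start)) NULL else as.integer(se_start),
                 se_step = as.integer(se_step), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a flat key=value file
#'
#' Recognized keys are the arguments of [run_config()]; lines starting
#' with `#` are ignored.
#'
#' @param path config file path
#' @param ... overrides passed on to [run_config()]
#' @return run_config
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) < 2L))
    stop(sprintf("%s: malformed config line '%s'", path, lines[lengths(kv) < 2L][1]))
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  args <- as.list(vals)
  names(args) <- keys
  num_keys <- c("n_random", "n_sets", "n_controls", "alpha", "enrich_threshold",
                "enrich_top_k", "top_k", "se_start", "se_step", "seed")
  for (k in intersect(names(args), num_keys)) args[[k]] <- as.numeric(args[[k]])
  unknown <- setdiff(names(args), names(formals(run_config)))
  if (length(unknown))
    stop(sprintf("%s: unknown config key(s): %s", path, paste(unknown, collapse = ", ")))
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(run_config, args)
}

write_tsv_report <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cells <- vapply(seq_len(nrow(df)), function(i) {
      paste(vapply(df[i, , drop = FALSE], function(x) {
        if (is.numeric(x)) sprintf("%.10g", x) else as.character(x)
      }, ""), collapse = "\t")
    }, "")
    writeLines(cells, con)
  }
  invisible(path)
}

group_stats_row <- function(gs_er, gs_age, index, size) {
  data.frame(comm_index = index, num_genes = size,
             comm_er = gs_er$label, er_diff_in_mean = gs_er$diff_in_mean,
             er_p_value = gs_er$p,
             comm_age = gs_age$label, age_diff_in_mean = gs_age$diff_in_mean,
             age_p_value = gs_age$p,
             er_ks_stat = gs_er$ks_stat, age_ks_stat = gs_age$ks_stat,
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes annotate -> community detection -> community-level group stats
#' (ER and age) -> enrichment -> per-enriched-set group stats ->
#' centrality and correlations -> edge-difference null test -> efficiency
#' suite (SE curves and IE matrix), writing TSV reports into
#' `config$out_dir`. Every output carries a header with the package
#' version, the seed and a hash of the configuration; a rerun with the
#' same config is byte-identical.
#'
#' @param config run_config
#' @return invisible list of the computed objects and output paths
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop(sprintf("stage '%s' failed: %s",
                                              name, conditionMessage(e)),
                                      call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_path <- file.path(config$out_dir, "run_config.txt")
  scalar_cfg <- config[!vapply(config, is.null, TRUE)]
  writeLines(sprintf("%s=%s", names(scalar_cfg),
                     vapply(scalar_cfg, function(x) paste(format(x), collapse = ","), "")),
             cfg_path)
  # hash excludes the output location so reruns elsewhere stay comparable
  hash_cfg <- scalar_cfg[setdiff(names(scalar_cfg), "out_dir")]
  hash_tmp <- tempfile()
  writeLines(sprintf("%s=%s", names(hash_cfg),
                     vapply(hash_cfg, function(x) paste(format(x), collapse = ","), "")),
             hash_tmp)
  cfg_hash <- unname(tools::md5sum(hash_tmp))
  unlink(hash_tmp)
  hdr <- c(sprintf("# grnevo %s", as.character(utils::packageVersion("grnevo"))),
           sprintf("# seed=%d", config$seed),
           sprintf("# config_md5=%s", cfg_hash))
  outp <- function(f) file.path(config$out_dir, f)

  g <- stage("load_network", load_edge_list(config$edges))
  ann <- stage("annotate", load_annotation(er_path = config$er, age_path = config$age))

  part <- stage("communities", detect_communities(g, seed = config$seed))
  write_tsv_report(data.frame(gene = names(part$assignment),
                              community = unname(part$assignment),
                              stringsAsFactors = FALSE),
                   outp("communities.tsv"), c(hdr, sprintf("# Q=%.10g", part$Q)))
  writeLines(c(hdr, spy_order(g, part)), outp("spy_order.txt"))

  comms <- stage("top_communities",
                 suppressWarnings(top_communities(part, config$top_k)))

  comm_rows <- stage("group_stats", do.call(rbind, lapply(names(comms), function(ci) {
    grp <- comms[[ci]]
    ann_genes <- intersect(grp, intersect(
      names(annotation_values(ann, "er")), names(annotation_values(ann, "age"))))
    if (length(ann_genes) < 2L) return(NULL)
    gs_er <- group_mean_test(g, ann, ann_genes, "er", n_sets = config$n_sets,
                             alpha = config$alpha,
                             seed = config$seed + as.integer(ci), name = ci)
    gs_age <- group_mean_test(g, ann, ann_genes, "age", n_sets = config$n_sets,
                              alpha = config$alpha,
                              seed = config$seed + as.integer(ci) + 500L, name = ci)
    group_stats_row(gs_er, gs_age, ci, length(grp))
  })))
  if (!is.null(comm_rows))
    write_tsv_report(comm_rows, outp("table1_communities.tsv"), hdr)

  gsc <- NULL; enr <- NULL
  if (!is.null(config$sets)) {
    gsc <- stage("read_sets", read_gmt(config$sets))
    enr <- stage("enrichment",
                 enrich_communities(comms, gsc, universe = g$nodes,
                                    threshold = config$enrich_threshold,
                                    top_k = config$enrich_top_k))
    write_tsv_report(enr, outp("enrichment.tsv"), hdr)
    if (!is.null(enr) && nrow(enr)) {
      set_rows <- stage("group_stats_sets", do.call(rbind, lapply(seq_len(nrow(enr)), function(i) {
        sn <- enr$set_name[i]
        grp <- intersect(gsc$sets[[sn]], intersect(
          names(annotation_values(ann, "er")), names(annotation_values(ann, "age"))))
        grp <- intersect(grp, g$nodes)
        if (length(grp) < 2L) return(NULL)
        gs_er <- group_mean_test(g, ann, grp, "er", n_sets = config$n_sets,
                                 alpha = config$alpha, seed = config$seed + 1000L + i,
                                 name = sn)
        gs_age <- group_mean_test(g, ann, grp, "age", n_sets = config$n_sets,
                                  alpha = config$alpha, seed = config$seed + 2000L + i,
                                  name = sn)
        row <- group_stats_row(gs_er, gs_age, enr$community[i], length(grp))
        cbind(data.frame(set_name = sn, category = enr$category[i],
                         benjamini = enr$p_adj[i], stringsAsFactors = FALSE), row)
      })))
      if (!is.null(set_rows))
        write_tsv_report(set_rows, outp("table1_groups.tsv"), hdr)
    }
  }

  ct <- stage("centrality", compute_centralities(g))
  write_tsv_report(ct, outp("centrality.tsv"), hdr)

  cors <- stage("correlations", {
    rows <- list()
    for (attr in c("er", "age")) {
      av <- annotation_values(ann, attr)
      if (length(intersect(ct$gene, names(av))) < 3L) next
      for (meas in c("degree_centrality", "pagerank", "betweenness")) {
        cv <- stats::setNames(ct[[meas]], ct$gene)
        rep <- tryCatch(suppressWarnings(correlate(cv, av, level = "gene",
                                                   attribute = attr)),
                        error = function(e) NULL)
        if (is.null(rep)) next
        rows[[length(rows) + 1L]] <-
          data.frame(level = "gene", measure = meas, attribute = attr,
                     pearson_r = rep$pearson_r, pearson_p = rep$pearson_p,
                     spearman_rho = rep$spearman_rho, spearman_p = rep$spearman_p,
                     n = rep$n, stringsAsFactors = FALSE)
      }
    }
    if (!is.null(gsc) && length(gsc$sets) >= 3L) {
      for (attr in c("er", "age")) {
        rep <- tryCatch(suppressWarnings(
          group_centrality_correlation(gsc$sets, ct, ann, "pagerank", attr)),
          error = function(e) NULL)
        if (is.null(rep)) next
        rows[[length(rows) + 1L]] <-
          data.frame(level = "group", measure = "pagerank", attribute = attr,
                     pearson_r = rep$pearson_r, pearson_p = rep$pearson_p,
                     spearman_rho = rep$spearman_rho, spearman_p = rep$spearman_p,
                     n = rep$n, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  if (!is.null(cors)) write_tsv_report(cors, outp("table3_correlations.tsv"), hdr)

  ediff <- stage("edge_diff", {
    rows <- list()
    for (attr in c("er", "age")) {
      if (!length(annotation_values(ann, attr))) next
      res <- edge_diff_test(g, ann, attr, n_random = config$n_random,
                            seed = config$seed + if (attr == "er") 31L else 37L)
      rows[[length(rows) + 1L]] <-
        data.frame(attribute = attr, n_edges = length(res$diffs),
                   width = res$width, null_mean = mean(res$null_widths),
                   null_sd = stats::sd(res$null_widths), z = res$z,
                   p_upper = res$p_upper, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  if (!is.null(ediff)) write_tsv_report(ediff, outp("edge_diff.tsv"), hdr)

  curves <- stage("se_curves", {
    out <- list()
    for (attr in c("er", "age")) {
      av <- annotation_values(ann, attr)
      n_ann <- length(intersect(g$nodes, names(av)))
      if (n_ann < 20L) next
      st <- if (is.null(config$se_start)) min(500L, max(10L, n_ann %/% 2L))
            else config$se_start
      if (st > n_ann) next
      crv <- cumulative_se_curve(g, ann, attr, start = st, step = config$se_step,
                                 n_controls = config$n_controls,
                                 seed = config$seed + 71L)
      write_tsv_report(data.frame(rank = crv$ranks, se = crv$se,
                                  control_mean = crv$control_mean,
                                  control_sd = crv$control_sd),
                       outp(sprintf("se_curve_%s.tsv", attr)), hdr)
      out[[attr]] <- crv
    }
    out
  })

  iem <- NULL
  if (!is.null(gsc) && length(gsc$sets) >= 2L &&
      length(annotation_values(ann, "age"))) {
    iem <- stage("ie_matrix", {
      keep <- lapply(gsc$sets, function(s) intersect(s, g$nodes))
      keep <- keep[lengths(keep) >= 2L]
      if (length(keep) < 2L) NULL
      else suppressWarnings(ie_matrix(g, keep, ann))
    })
    if (!is.null(iem)) {
      df <- as.data.frame(iem$matrix)
      df <- cbind(data.frame(group = rownames(iem$matrix),
                             mean_age = iem$mean_age, stringsAsFactors = FALSE), df)
      write_tsv_report(df, outp("ie_matrix.tsv"), hdr)
    }
  }

  invisible(list(network = g, annotation = ann, partition = part,
                 community_stats = comm_rows, enrichment = enr,
                 centrality = ct, correlations = cors, edge_diff = ediff,
                 se_curves = curves, ie = iem, out_dir = config$out_dir))
}

parse_cli_flags <- function(argv) {
  flags <- list(); positional <- character()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(argv) || startsWith(argv[i + 1L], "--"))
        stop(sprintf("flag --%s requires a value", key))
      flags[[key]] <- argv[i + 1L]
      i <- i + 2L
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = positional)
}

cli_usage <- function() {
  paste(c("usage: grnevo <subcommand> [--flag value ...]",
          "subcommands:",
          "  synth        --seed S --out DIR",
          "  annotate     --er F --age F --out FILE",
          "  communities  --edges F --out FILE [--seed S]",
          "  group-stats  --edges F --er F --age F --communities F --out FILE [--seed S]",
          "  enrich       --communities F --sets F --edges F --out FILE",
          "  centrality   --edges F --out FILE",
          "  efficiency   --edges F --sets F --age F --out FILE",
          "  rewire-test  --edges F --er F [--age F] --out FILE [--seed S]",
          "  report       --config F [--out DIR] [--seed S]",
          "  run-all      --config F [--out DIR] [--seed S]"),
        collapse = "\n")
}

read_partition_tsv <- function(path, g = NULL) {
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  community_partition(stats::setNames(tab$community, canonical_gene(tab$gene)), g)
}

#' Command-line entry point
#'
#' Maps shell subcommands onto the package's operations; used by the
#' `inst/scripts/grnevo` launcher. Returns an exit code rather than
#' calling `quit()`, so it is testable in-process.
#'
#' @param argv character vector of arguments (as from
#'   `commandArgs(trailingOnly = TRUE)`)
#' @return integer exit code (0 on success)
#' @export
cli <- function(argv) {
  res <- tryCatch({
    if (!length(argv)) stop(cli_usage())
    sub <- argv[1L]
    pf <- parse_cli_flags(argv[-1L])
    fl <- pf$flags
    need <- function(key) {
      if (is.null(fl[[key]])) stop(sprintf("subcommand '%s' requires --%s", sub, key))
      fl[[key]]
    }
    seed <- as.integer(if (is.null(fl$seed)) 1L else fl$seed)
    hdr <- sprintf("# grnevo %s seed=%d",
                   as.character(utils::packageVersion("grnevo")), seed)
    switch(sub,
      "synth" = {
        bundle <- generate(synth_config(seed = seed))
        write_synth_bundle(bundle, need("out"))
      },
      "annotate" = {
        ann <- load_annotation(er_path = fl$er, age_path = fl$age)
        df <- data.frame(gene = ann$genes, er = unname(ann$er),
                         age = unname(ann$age), stringsAsFactors = FALSE)
        write_tsv_report(df, need("out"), hdr)
      },
      "communities" = {
        g <- load_edge_list(need("edges"))
        part <- detect_communities(g, seed = seed)
        write_tsv_report(data.frame(gene = names(part$assignment),
                                    community = unname(part$assignment)),
                         need("out"), c(hdr, sprintf("# Q=%.10g", part$Q)))
      },
      "group-stats" = {
        g <- load_edge_list(need("edges"))
        ann <- load_annotation(er_path = fl$er, age_path = fl$age)
        part <- read_partition_tsv(need("communities"))
        comms <- suppressWarnings(top_communities(part, 10L))
        rows <- do.call(rbind, lapply(names(comms), function(ci) {
          grp <- intersect(comms[[ci]], intersect(
            names(annotation_values(ann, "er")), names(annotation_values(ann, "age"))))
          grp <- intersect(grp, g$nodes)
          if (length(grp) < 2L) return(NULL)
          group_stats_row(
            group_mean_test(g, ann, grp, "er", seed = seed + as.integer(ci), name = ci),
            group_mean_test(g, ann, grp, "age", seed = seed + as.integer(ci) + 500L, name = ci),
            ci, length(grp))
        }))
        write_tsv_report(rows, need("out"), hdr)
      },
      "enrich" = {
        g <- load_edge_list(need("edges"))
        part <- read_partition_tsv(need("communities"))
        gsc <- read_gmt(need("sets"))
        enr <- enrich_communities(suppressWarnings(top_communities(part, 10L)),
                                  gsc, universe = g$nodes)
        write_tsv_report(enr, need("out"), hdr)
      },
      "centrality" = {
        g <- load_edge_list(need("edges"))
        write_tsv_report(compute_centralities(g), need("out"), hdr)
      },
      "efficiency" = {
        g <- load_edge_list(need("edges"))
        gsc <- read_gmt(need("sets"))
        ann <- load_annotation(age_path = need("age"))
        keep <- lapply(gsc$sets, function(s) intersect(s, g$nodes))
        keep <- keep[lengths(keep) >= 2L]
        iem <- suppressWarnings(ie_matrix(g, keep, ann))
        df <- cbind(data.frame(group = rownames(iem$matrix),
                               mean_age = iem$mean_age, stringsAsFactors = FALSE),
                    as.data.frame(iem$matrix))
        write_tsv_report(df, need("out"), hdr)
      },
      "rewire-test" = {
        g <- load_edge_list(need("edges"))
        ann <- load_annotation(er_path = fl$er, age_path = fl$age)
        rows <- do.call(rbind, lapply(c("er", "age"), function(attr) {
          if (!length(annotation_values(ann, attr))) return(NULL)
          res <- edge_diff_test(g, ann, attr, seed = seed)
          data.frame(attribute = attr, n_edges = length(res$diffs),
                     width = res$width, null_mean = mean(res$null_widths),
                     null_sd = stats::sd(res$null_widths), z = res$z,
                     p_upper = res$p_upper, stringsAsFactors = FALSE)
        }))
        write_tsv_report(rows, need("out"), hdr)
      },
      "report" = ,
      "run-all" = {
        cfg <- read_run_config(need("config"))
        if (!is.null(fl$out)) cfg$out_dir <- fl$out
        if (!is.null(fl$seed)) cfg$seed <- seed
        run_all(cfg)
      },
      stop(sprintf("unknown subcommand '%s'\n%s", sub, cli_usage())))
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    1L
  })
  invisible(res)
}
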