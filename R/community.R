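#' Directed weighted modularity of a partition
#'
#' Modularity generalized to directed, weighted graphs:
#' \deqn{Q = \frac{1}{m}\sum_{ij}\left[W_{ij} - \frac{s_i^{out} s_j^{in}}{m}\right]\delta(c_i, c_j)}
#' where \eqn{W} is the directed expansion of the network, \eqn{s^{out}} and
#' \eqn{s^{in}} are weighted out/in strengths and \eqn{m} the total edge
#' weight. The trivial one-community partition has \eqn{Q = 0} exactly.
#'
#' @param g gene_network
#' @param partition named vector (gene -> community label) covering all
#'   nodes, or a `community_partition`
#' @return modularity Q in \[-1, 1\]
#' @export
directed_modularity <- function(g, partition) {
  if (inherits(partition, "community_partition")) partition <- partition$assignment
  memb <- partition[g$nodes]
  if (anyNA(memb)) {
    missing <- g$nodes[is.na(memb)][1]
    stop(sprintf("node '%s' missing from partition", missing))
  }
  ex <- directed_expansion(g)
  m <- g$m
  if (m <= 0) stop("network has no edges")
  within <- sum(ex$weight[memb[ex$source] == memb[ex$target]])
  s_out <- tapply(ex$weight, factor(ex$source, levels = g$nodes), sum, default = 0)
  s_in <- tapply(ex$weight, factor(ex$target, levels = g$nodes), sum, default = 0)
  labs <- factor(memb)
  S_out <- tapply(s_out, labs, sum)
  S_in <- tapply(s_in, labs, sum)
  within / m - sum(S_out * S_in) / m^2
}

#' Community partition of a gene network
#'
#' Wraps a gene -> community assignment together with the communities as
#' gene sets ordered by size descending (ties broken by lexicographically
#' smallest member) and the directed weighted modularity Q of the
#' assignment.
#'
#' @param assignment named vector gene -> community label
#' @param g gene_network used to compute Q (optional; Q is `NA` without it)
#' @return object of class `community_partition` with fields `assignment`
#'   (labels re-indexed 0..k-1 by size rank), `communities`, `Q`
#' @export
community_partition <- function(assignment, g = NULL) {
  genes <- names(assignment)
  if (is.null(genes)) stop("assignment must be a named vector")
  comms <- split(genes, as.character(unname(assignment)))
  comms <- lapply(comms, function(x) sort(x))
  ord <- order(-lengths(comms), vapply(comms, `[`, "", 1L))
  comms <- unname(comms[ord])
  assignment <- stats::setNames(rep(seq_along(comms) - 1L, lengths(comms)),
                                unlist(comms))
  assignment <- assignment[sort(names(assignment))]
  Q <- if (!is.null(g)) directed_modularity(g, assignment) else NA_real_
  structure(list(assignment = assignment, communities = comms, Q = Q),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d genes in %d communities (sizes %s), Q = %s\n",
              length(x$assignment), length(x$communities),
              paste(utils::head(lengths(x$communities), 10L), collapse = "/"),
              format(x$Q, digits = 4)))
  invisible(x)
}

#' Detect communities by directed weighted modularity
#'
#' Louvain-style greedy agglomeration maximizing [directed_modularity()]:
#' repeated local-move sweeps (node sweep order shuffled by `seed`, ties
#' broken by the lowest community id) followed by graph aggregation, until
#' modularity stops improving. Deterministic given `seed`.
#'
#' @param g gene_network
#' @param seed integer RNG seed governing sweep order
#' @return community_partition
#' @export
detect_communities <- function(g, seed = 1L) {
  if (g$n == 0L) stop("cannot detect communities in an empty network")
  ex <- directed_expansion(g)
  if (nrow(ex) == 0L) stop("cannot detect communities in an edgeless network")
  node_id <- stats::setNames(seq_len(g$n), g$nodes)
  src <- unname(node_id[ex$source]); tgt <- unname(node_id[ex$target])
  w <- ex$weight
  membership <- withr::with_seed(seed, louvain_directed(src, tgt, w, g$n))
  community_partition(stats::setNames(membership, g$nodes), g)
}

# Louvain on integer edge arrays; returns membership vector 1..k.
louvain_directed <- function(src, tgt, w, n) {
  m <- sum(w)
  memb_full <- seq_len(n)          # gene -> current supernode
  nn <- n
  repeat {
    comm <- local_move_phase(src, tgt, w, nn, m)
    comm <- match(comm, sort(unique(comm)))
    memb_full <- comm[memb_full]
    if (max(comm) == nn) break     # no merges at this level
    # aggregate communities into supernodes (self-loops kept)
    asrc <- comm[src]; atgt <- comm[tgt]
    nn <- max(comm)
    key <- (asrc - 1) * nn + atgt
    agg <- rowsum(w, key)
    keyu <- as.numeric(rownames(agg)) - 1
    src <- as.integer(keyu %/% nn + 1)
    tgt <- as.integer(keyu %% nn + 1)
    w <- as.numeric(agg)
  }
  memb_full
}

local_move_phase <- function(src, tgt, w, n, m) {
  s_out <- as.numeric(tapply(w, factor(src, levels = seq_len(n)), sum, default = 0))
  s_in <- as.numeric(tapply(w, factor(tgt, levels = seq_len(n)), sum, default = 0))
  comm <- seq_len(n)
  S_out <- s_out; S_in <- s_in
  # adjacency (excluding self-loops: they move with the node)
  nonself <- src != tgt
  out_adj <- split(data.frame(v = tgt[nonself], w = w[nonself]), factor(src[nonself], levels = seq_len(n)))
  in_adj <- split(data.frame(v = src[nonself], w = w[nonself]), factor(tgt[nonself], levels = seq_len(n)))
  sweep_order <- sample.int(n)
  repeat {
    moved <- FALSE
    for (i in sweep_order) {
      oa <- out_adj[[i]]; ia <- in_adj[[i]]
      nb_comm <- c(comm[oa$v], comm[ia$v])
      if (!length(nb_comm)) next
      nb_w <- c(oa$w, ia$w)
      wlink <- tapply(nb_w, nb_comm, sum)      # w(i->c) + w(c->i)
      cand <- as.integer(names(wlink))
      cur <- comm[i]
      if (!cur %in% cand) { cand <- c(cand, cur); wlink <- c(wlink, 0) }
      # gain of i being in community c (relative, excluding i itself)
      So <- S_out[cand]; Si <- S_in[cand]
      own <- cand == cur
      So[own] <- So[own] - s_out[i]; Si[own] <- Si[own] - s_in[i]
      gain <- wlink / m - (s_out[i] * Si + s_in[i] * So) / m^2
      ordc <- order(-gain, cand)
      best <- cand[ordc[1L]]
      if (best != cur && gain[ordc[1L]] > gain[match(cur, cand)] + 1e-12) {
        S_out[cur] <- S_out[cur] - s_out[i]; S_in[cur] <- S_in[cur] - s_in[i]
        S_out[best] <- S_out[best] + s_out[i]; S_in[best] <- S_in[best] + s_in[i]
        comm[i] <- best
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  comm
}

#' Largest communities of a partition
#'
#' @param p community_partition
#' @param k how many communities to keep
#' @return list of gene sets, size descending, re-indexed 0..k-1 (names
#'   `"0"`, `"1"`, ...); if fewer than `k` communities exist, all are
#'   returned with a warning
#' @export
top_communities <- function(p, k) {
  stopifnot(inherits(p, "community_partition"), k >= 1)
  if (k > length(p$communities)) {
    warning(sprintf("requested %d communities but partition has %d; returning all",
                    k, length(p$communities)))
    k <- length(p$communities)
  }
  out <- p$communities[seq_len(k)]
  names(out) <- as.character(seq_len(k) - 1L)
  out
}

#' Community-aware node ordering for adjacency spy plots
#'
#' Orders nodes by community size ascending (ties by smallest member gene),
#' then within each community by out-degree descending (ties alphabetical),
#' the ordering under which block structure is visible in the adjacency
#' matrix.
#'
#' @param g gene_network
#' @param p community_partition
#' @return character vector of node names
#' @export
spy_order <- function(g, p) {
  stopifnot(inherits(p, "community_partition"))
  ex <- directed_expansion(g)
  outdeg <- table(factor(ex$source, levels = g$nodes))
  comms <- p$communities
  ord <- order(lengths(comms), vapply(comms, `[`, "", 1L))
  comms <- comms[ord]
  unlist(lapply(comms, function(members) {
    members[order(-as.integer(outdeg[members]), members)]
  }), use.names = FALSE)
}

#' Normalized mutual information between two partitions
#'
#' Agreement between two community assignments over the same genes
#' (matched by name), 1 for identical partitions, ~0 for independent ones.
#'
#' @param p1,p2 `community_partition` objects or named label vectors
#' @return NMI in \[0, 1\]
#' @export
partition_nmi <- function(p1, p2) {
  lab <- function(p) if (inherits(p, "community_partition")) p$assignment else p
  a <- lab(p1); b <- lab(p2)
  common <- intersect(names(a), names(b))
  if (!length(common)) stop("partitions share no genes")
  igraph::compare(as.integer(factor(a[common])),
                  as.integer(factor(b[common])), method = "nmi")
}
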