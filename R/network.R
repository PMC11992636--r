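#' Build the social contact network
#'
#' Distance-biased small-world graph: each agent is linked to its
#' `mean_degree` nearest neighbours, then each edge is rewired with
#' probability `rewiring_prob` to a distant agent chosen with probability
#' decaying exponentially over `distance_scale_km`. Edges are symmetric and
#' carry a cumulative interaction count (at most one interaction per edge per
#' day). Seeded and reproducible.
#'
#' @param agents agent data frame (columns `x`, `y`), or anything with those
#'   columns.
#' @param params model parameters (`network` section).
#' @param seed integer seed.
#' @return An object of class `careseek_network`: a list with integer edge
#'   endpoint vectors `i` and `k` (i < k), the per-edge interaction count
#'   `fq`, and the number of agents `n`.
#' @export
#' @examples
#' pop <- synthesize_population(region_config("gilgandra"), seed = 1)
#' net <- build_network(pop[1:200, ], seed = 1)
build_network <- function(agents, params = default_params(), seed = 1) {
  np <- params$network
  x <- agents$x
  y <- agents$y
  n <- length(x)
  if (n < 2) config_error("a network needs at least 2 agents")
  k <- np$mean_degree
  if (k >= n) config_error("network.mean_degree must be smaller than the number of agents")
  set.seed(as.integer(seed))

  # nearest-neighbour search on a coarse grid (3x3 cell neighbourhoods)
  side <- max(1L, floor(sqrt(n / (2 * (k + 1)))))
  cx <- pmin(side, pmax(1L, ceiling(x / (max(x) + 1e-9) * side)))
  cy <- pmin(side, pmax(1L, ceiling(y / (max(y) + 1e-9) * side)))
  cell <- (cx - 1L) * side + cy
  members <- split(seq_len(n), cell)
  ei <- integer(0); ek <- integer(0)
  from <- rep(seq_len(n), each = k)
  to <- integer(n * k)
  for (cl in names(members)) {
    mem <- members[[cl]]
    ci <- (as.integer(cl) - 1L) %/% side + 1L
    cj <- (as.integer(cl) - 1L) %% side + 1L
    nb_cells <- as.vector(outer(pmax(1L, ci - 1L):pmin(side, ci + 1L) - 1L,
                                pmax(1L, cj - 1L):pmin(side, cj + 1L),
                                function(a, b) a * side + b))
    cand <- unlist(members[as.character(nb_cells)], use.names = FALSE)
    if (length(cand) < k + 1) cand <- seq_len(n)  # sparse corner: widen
    dx <- outer(x[mem], x[cand], "-"); dy <- outer(y[mem], y[cand], "-")
    d2 <- dx * dx + dy * dy
    for (r in seq_along(mem)) {
      ord <- cand[order(d2[r, ])]
      to[(mem[r] - 1L) * k + seq_len(k)] <- ord[ord != mem[r]][seq_len(k)]
    }
  }
  lo <- pmin(from, to); hi <- pmax(from, to)
  key <- (lo - 1) * n + hi
  keep <- !duplicated(key)
  ei <- lo[keep]; ek <- hi[keep]

  # distance-decayed rewiring: the retained endpoint keeps the edge, the new
  # partner is sampled from random candidates with weight exp(-d / scale)
  m <- length(ei)
  rw <- which(stats::runif(m) < np$rewiring_prob)
  for (e in rw) {
    keep_i <- if (stats::runif(1) < 0.5) ei[e] else ek[e]
    cand <- sample.int(n, min(30L, n))
    cand <- cand[cand != keep_i]
    d <- sqrt((x[cand] - x[keep_i])^2 + (y[cand] - y[keep_i])^2)
    new_k <- cand[sample.int(length(cand), 1, prob = exp(-d / np$distance_scale_km))]
    ei[e] <- min(keep_i, new_k); ek[e] <- max(keep_i, new_k)
  }
  key <- (ei - 1) * n + ek
  keep <- !duplicated(key)
  structure(list(i = ei[keep], k = ek[keep], fq = integer(sum(keep)), n = n),
            class = c("careseek_network", "list"))
}

#' @export
print.careseek_network <- function(x, ...) {
  cat("careseek social network:", x$n, "agents,", length(x$i), "edges\n")
  invisible(x)
}

#' @export
as.data.frame.careseek_network <- function(x, ...) {
  data.frame(agent_i = x$i, agent_k = x$k, fq = x$fq)
}

# compressed adjacency (both directions) with parallel edge ids, for fast
# neighbour lookups during the daily loop
build_adjacency <- function(net) {
  n <- net$n
  m <- length(net$i)
  src <- c(net$i, net$k)
  dst <- c(net$k, net$i)
  eid <- c(seq_len(m), seq_len(m))
  ord <- order(src)
  deg <- tabulate(src, nbins = n)
  list(deg = deg, start = c(0L, cumsum(deg))[seq_len(n)] + 1L,
       nbr = dst[ord], eid = eid[ord])
}

#' One day of social-network interactions
#'
#' Each edge fires with the daily interaction probability; a firing edge
#' increments its cumulative interaction count. Pending post-visit feedback
#' messages are delivered to each of the sender's contacts independently with
#' the same probability, and then discarded (each queued score reaches a
#' given neighbour at most once).
#'
#' @param net a `careseek_network`.
#' @param pending data frame of queued feedback (`sender`, `provider`,
#'   `score`), or `NULL`.
#' @param params model parameters.
#' @param adj precomputed adjacency from an earlier call (internal use).
#' @return A list with the updated `net` and a `delivered` data frame
#'   (`agent`, `provider`, `score`) of feedback that reached a neighbour.
#' @export
daily_interactions <- function(net, pending = NULL, params = default_params(),
                               adj = NULL) {
  p_int <- params$network$interaction_prob * params$intervention$social_mult
  p_int <- min(1, p_int)
  m <- length(net$i)
  nf <- stats::rbinom(1, m, p_int)
  if (nf > 0) {
    idx <- sample.int(m, nf)
    net$fq[idx] <- net$fq[idx] + 1L
  }
  delivered <- NULL
  if (!is.null(pending) && nrow(pending)) {
    if (is.null(adj)) adj <- build_adjacency(net)
    outs <- vector("list", nrow(pending))
    for (r in seq_len(nrow(pending))) {
      s <- pending$sender[r]
      if (adj$deg[s] == 0) next
      nbrs <- adj$nbr[adj$start[s] + seq_len(adj$deg[s]) - 1L]
      hit <- nbrs[stats::runif(length(nbrs)) < p_int]
      if (length(hit)) {
        outs[[r]] <- data.frame(agent = hit, provider = pending$provider[r],
                                score = pending$score[r])
      }
    }
    outs <- outs[!vapply(outs, is.null, TRUE)]
    if (length(outs)) delivered <- do.call(rbind, outs)
  }
  if (is.null(delivered)) {
    delivered <- data.frame(agent = integer(0), provider = integer(0),
                            score = numeric(0))
  }
  list(net = net, delivered = delivered)
}

# slow emergent rewiring: with a small monthly probability an agent drops its
# least-interacted edge and gains a uniformly random new contact
network_churn <- function(net, params, adj = NULL) {
  prob <- params$network$churn_monthly_prob
  if (prob <= 0 || length(net$i) == 0) return(net)
  if (is.null(adj)) adj <- build_adjacency(net)
  movers <- which(stats::runif(net$n) < prob)
  if (!length(movers)) return(net)
  keys <- sort((net$i - 1) * net$n + net$k)  # duplicate-edge lookup
  for (a in movers) {
    dg <- adj$deg[a]
    mine <- if (dg > 0) adj$eid[adj$start[a] + seq_len(dg) - 1L] else integer(0)
    if (!length(mine)) next
    drop <- mine[which.min(net$fq[mine])]
    new_k <- sample.int(net$n, 1)
    if (new_k == a) next
    lo <- min(a, new_k); hi <- max(a, new_k)
    key <- (lo - 1) * net$n + hi
    pos <- findInterval(key, keys)
    if (pos > 0 && keys[pos] == key) next  # edge already present
    net$i[drop] <- lo; net$k[drop] <- hi; net$fq[drop] <- 0L
  }
  net
}
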