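# Independent reference implementations used as oracles. Each deliberately
# uses a different formulation than the package code it checks.

# memoisation-free recursive edit distance (exponential; short inputs only)
lev_rec_r <- function(a, b) {
  if (!length(a)) return(length(b))
  if (!length(b)) return(length(a))
  min(lev_rec_r(a[-1], b) + 1L,
      lev_rec_r(a, b[-1]) + 1L,
      lev_rec_r(a[-1], b[-1]) + (a[1] != b[1]))
}

# memoised top-down recursion (same recurrence, evaluated lazily rather than
# as an iterative table)
lev_memo_r <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    v <- get0(key, envir = memo)
    if (!is.null(v)) return(v)
    v <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L,
             rec(i - 1L, j - 1L) + (a[i] != b[j]))
    assign(key, v, envir = memo)
    v
  }
  rec(length(a), length(b))
}

# all token sequences up to max_len over an alphabet (including the empty one)
enumerate_seqs <- function(alphabet, max_len) {
  seqs <- list(character(0))
  for (L in seq_len(max_len)) {
    g <- do.call(expand.grid,
                 c(rep(list(alphabet), L), stringsAsFactors = FALSE))
    seqs <- c(seqs, lapply(seq_len(nrow(g)), function(i) unlist(g[i, ], use.names = FALSE)))
  }
  seqs
}

# brute-force AOI containment: scan over every rectangle for every point
brute_assign <- function(x, y, aoiset) {
  a <- aoiset$aois
  vapply(seq_along(x), function(i) {
    for (j in seq_len(nrow(a))) {
      if (x[i] >= a$x0[j] && x[i] < a$x1[j] &&
          y[i] >= a$y0[j] && y[i] < a$y1[j]) return(a$label[j])
    }
    off_aoi()
  }, character(1))
}

# DBSCAN reference: core points from pairwise distances, clusters as igraph
# connected components of the core-core neighbourhood graph, border points
# attached to their nearest core neighbour (lowest index on a tie)
dbscan_oracle <- function(points, eps, min_pts) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts
  cluster <- integer(n)
  core_idx <- which(core)
  if (length(core_idx)) {
    adj <- nb[core_idx, core_idx, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    cluster[core_idx] <- comp
    for (i in which(!core)) {
      cand <- core_idx[nb[i, core_idx]]
      if (length(cand)) {
        best <- cand[order(d[i, cand], cand)][1]
        cluster[i] <- cluster[best]
      }
    }
  }
  list(cluster = cluster, core = core)
}

# partitions equal up to relabelling of cluster ids (noise id 0 fixed)
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  ka <- paste(a)[a != 0L]; kb <- paste(b)[b != 0L]
  map <- tapply(kb, ka, function(v) length(unique(v)))
  pam <- tapply(ka, kb, function(v) length(unique(v)))
  all(map == 1L) && all(pam == 1L)
}

# exhaustive Mann-Whitney permutation oracle: U of x over all C(n, n_x)
# group labelings of the pooled values (tie-free input assumed)
mw_enum <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(x, y)
  combos <- utils::combn(n, length(x))
  u_all <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  p <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  list(U = u_obs, p = p)
}

# random token scanpath over a given alphabet
random_scanpath <- function(alphabet, len, participant = "P", stimulus = "s") {
  new_scanpath_test(participant, stimulus,
                    sample(alphabet, len, replace = TRUE))
}

# scanpath construction without going through fixations
new_scanpath_test <- function(participant, stimulus, tokens) {
  structure(list(participant = participant, stimulus = stimulus,
                 tokens = as.character(tokens), truncated = FALSE),
            class = "scanpath")
}
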