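# Shared fixtures and independent brute-force oracles for the test suite.
# The oracles deliberately avoid the code paths (and, where possible, the
# libraries) used by the implementation they check.

t3_network <- function() {
  parse_boolnet("targets, factors\nA, C\nB, A & C\nC, !B", name = "T3")
}

# Adjacency matrix (0/1, self-loops dropped) from an igraph object, by names.
adj_matrix_of <- function(graph) {
  nodes <- igraph::V(graph)$name
  m <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  e <- igraph::as_edgelist(graph)
  for (i in seq_len(nrow(e))) if (e[i, 1] != e[i, 2]) m[e[i, 1], e[i, 2]] <- 1L
  m
}

# --- betweenness oracle -----------------------------------------------------
# Explicit enumeration of every shortest directed path per ordered pair:
# BFS distances by hand, then a depth-first walk constrained to states that
# stay on a shortest path. Independent of igraph's betweenness.
oracle_betweenness <- function(graph) {
  adj <- adj_matrix_of(graph)
  nodes <- rownames(adj)
  n <- length(nodes)
  bfs_dist <- function(src) {
    d <- rep(Inf, n); names(d) <- nodes
    d[src] <- 0
    queue <- src
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nodes[adj[v, ] == 1L]) {
        if (is.infinite(d[w])) { d[w] <- d[v] + 1; queue <- c(queue, w) }
      }
    }
    d
  }
  dists <- t(vapply(nodes, bfs_dist, numeric(n)))
  vb <- stats::setNames(numeric(n), nodes)
  for (s in nodes) for (t in nodes) {
    if (s == t || is.infinite(dists[s, t])) next
    # enumerate all paths of exactly shortest length
    paths <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { paths[[length(paths) + 1L]] <<- path; return() }
      for (w in nodes[adj[v, ] == 1L]) {
        if (dists[s, w] == length(path) && dists[w, t] == dists[s, t] - length(path)) {
          walk(c(path, w))
        }
      }
    }
    walk(s)
    through <- table(unlist(lapply(paths, function(p) p[-c(1, length(p))])))
    for (g in names(through)) vb[g] <- vb[g] + through[[g]] / length(paths)
  }
  vb
}

# --- determinative-power oracle ---------------------------------------------
# Empirical mutual information over the full 2^n state space: every full
# state x gets probability prod(bias^x (1-bias)^(1-x)); the joint of
# (X_g, f_g'(x)) is accumulated state by state.
oracle_dp <- function(net, bias = 0.5) {
  genes <- net$genes
  n <- length(genes)
  states <- as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
  colnames(states) <- genes
  px <- apply(states, 1, function(s) prod(ifelse(s == 1, bias, 1 - bias)))
  f_out <- vapply(genes, function(g) {
    apply(states, 1, function(s) {
      f <- net$functions[[g]]
      if (length(f$inputs) == 0) return(f$table[1L])
      bits <- s[f$inputs]
      f$table[sum(bits * 2^((length(bits) - 1):0)) + 1L]
    })
  }, numeric(nrow(states)))
  mi_pair <- function(g, g2) {
    joint <- matrix(0, 2, 2)  # [X_g + 1, F + 1]
    for (i in seq_len(nrow(states))) {
      joint[states[i, g] + 1, f_out[i, g2] + 1] <-
        joint[states[i, g] + 1, f_out[i, g2] + 1] + px[i]
    }
    mi <- 0
    for (a in 1:2) for (b in 1:2) {
      p <- joint[a, b]
      if (p > 0) mi <- mi + p * log2(p / (sum(joint[a, ]) * sum(joint[, b])))
    }
    mi
  }
  vapply(genes, function(g) {
    sum(vapply(genes, function(g2) {
      if (g %in% net$functions[[g2]]$inputs) mi_pair(g, g2) else 0
    }, numeric(1)))
  }, numeric(1))
}

# --- simple-path oracle -----------------------------------------------------
# Recursive depth-first enumeration over an adjacency matrix.
oracle_simple_paths <- function(graph, s, t, max_len = Inf) {
  adj <- adj_matrix_of(graph)
  nodes <- rownames(adj)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) { paths[[length(paths) + 1L]] <<- path; return() }
    if (length(path) - 1 >= max_len) return()
    for (w in nodes[adj[v, ] == 1L]) if (!w %in% path) walk(c(path, w))
  }
  walk(s)
  key <- vapply(paths, paste, character(1), collapse = "\r")
  paths[order(lengths(paths), key)]
}

# --- motif oracle -----------------------------------------------------------
# Exhaustive scan over all ordered node triples (FFLs) and over all pairs of
# source/target node pairs (bifans).
oracle_motifs <- function(graph, signs) {
  adj <- adj_matrix_of(graph)
  nodes <- rownames(adj)
  sign_of <- function(a, b) {
    s <- signs$sign[signs$from == a & signs$to == b]
    if (length(s) == 0) NA_character_ else s
  }
  c1 <- 0L; i1 <- 0L
  trips <- expand.grid(x = nodes, y = nodes, z = nodes, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(trips))) {
    x <- trips$x[i]; y <- trips$y[i]; z <- trips$z[i]
    if (anyDuplicated(c(x, y, z))) next
    if (adj[x, y] == 1 && adj[y, z] == 1 && adj[x, z] == 1) {
      s <- c(sign_of(x, y), sign_of(y, z), sign_of(x, z))
      if (any(is.na(s)) || any(s == "ambivalent")) next
      if (all(s == "positive")) c1 <- c1 + 1L
      if (s[1] == "positive" && s[3] == "positive" && s[2] == "negative") i1 <- i1 + 1L
    }
  }
  bifan <- 0L
  if (length(nodes) >= 4) {
    pairs <- utils::combn(nodes, 2, simplify = FALSE)
    for (src in pairs) for (tgt in pairs) {
      if (length(intersect(src, tgt)) > 0) next
      if (adj[src[1], tgt[1]] == 1 && adj[src[1], tgt[2]] == 1 &&
          adj[src[2], tgt[1]] == 1 && adj[src[2], tgt[2]] == 1) bifan <- bifan + 1L
    }
  }
  list(c1ffl = c1, i1ffl = i1, bifan = bifan)
}

# Confusion-matrix recount for the sweep oracle: independent top-set logic
# (sort + head instead of rank arithmetic).
oracle_confusion <- function(df, T, selector = "intersection") {
  n <- nrow(df)
  m <- ceiling(T * n / 100)
  top_of <- function(score) {
    ord <- df$gene[order(-score, df$gene)]
    ord[seq_len(m)]
  }
  vb_top <- top_of(df$vb); dp_top <- top_of(df$dp)
  predicted <- switch(selector,
                      intersection = intersect(vb_top, dp_top),
                      union = union(vb_top, dp_top),
                      vb = vb_top, dp = dp_top)
  labelled <- top_of(df$impact)
  pos <- df$gene %in% labelled; pred <- df$gene %in% predicted
  tp <- sum(pos & pred); fn <- sum(pos & !pred)
  tn <- sum(!pos & !pred); fp <- sum(!pos & pred)
  c(sensitivity = if (tp + fn == 0) 1 else tp / (tp + fn),
    specificity = if (tn + fp == 0) 1 else tn / (tn + fp))
}
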