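# Shared fixtures and independent brute-force oracles for the metric tests.

# Build a network from an edge table (from, to, w).
net_from_edges <- function(from, to, w = 1, nodes = NULL) {
  if (length(w) == 1L) w <- rep(w, length(from))
  if (is.null(nodes)) nodes <- unique(c(from, to))
  m <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (k in seq_along(from)) m[from[k], to[k]] <- m[from[k], to[k]] + w[k]
  scanpath_network(m)
}

# Complete directed graph on n nodes, unit weights both directions.
complete_net <- function(n) {
  m <- matrix(1, n, n, dimnames = list(paste0("v", 1:n), paste0("v", 1:n)))
  diag(m) <- 0
  scanpath_network(m)
}

# Undirected graph from a symmetric binary adjacency, stored as reciprocal
# unit arcs.
net_from_symmetric <- function(a) {
  dimnames(a) <- list(paste0("v", seq_len(nrow(a))), paste0("v", seq_len(nrow(a))))
  scanpath_network(a + 0)
}

# The transition matrix of the eight-word example sentence, as printed in a
# transition table (directed entries exactly as displayed; off-diagonal sum
# is 14).
table1_matrix <- function() {
  words <- c("could", "human", "on", "mars", "day", "scientist", "this",
             "question")
  m <- matrix(0, 8, 8, dimnames = list(words, words))
  m["could", "human"] <- 1
  m["human", "on"] <- 1
  m["human", "mars"] <- 1
  m["human", "scientist"] <- 1
  m["on", "mars"] <- 1
  m["mars", "human"] <- 1
  m["mars", "day"] <- 3
  m["day", "mars"] <- 3
  m["scientist", "this"] <- 1
  m["this", "question"] <- 1
  m
}

# Same vocabulary with each undirected transition stored once (unique-edge
# reading): mars touches human (1), on (1) and day (3), so its degree is 5.
table1_unique_edges <- function() {
  net_from_edges(
    from = c("could", "human", "human", "on", "mars", "scientist", "this"),
    to = c("human", "on", "mars", "mars", "day", "this", "question"),
    w = c(1, 1, 1, 1, 3, 1, 1)
  )
}

# ---- brute-force oracles (independent of the package implementation) ----

# Directed weighted transitivity straight from the triple-sum definition.
bf_transitivity <- function(w) {
  n <- nrow(w)
  t_sum <- 0
  denom <- 0
  for (i in seq_len(n)) {
    k_i <- sum(w[i, ]) + sum(w[, i])
    recip <- sum(w[i, ] * w[, i])
    denom <- denom + k_i * (k_i - 1) - 2 * recip
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          t_sum <- t_sum + 0.5 * (w[i, j] + w[j, i]) * (w[i, h] + w[h, i]) *
            (w[j, h] + w[h, j])
        }
      }
    }
  }
  if (denom <= 0) return(0)
  t_sum / denom
}

# Classic global clustering coefficient of a binary symmetric graph by
# exhaustive triangle / connected-triple counting.
bf_transitivity_binary <- function(a) {
  n <- nrow(a)
  tri <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (h in (j + 1):n) {
    if (a[i, j] && a[j, h] && a[i, h]) tri <- tri + 1
  }
  deg <- rowSums(a)
  triples <- sum(deg * (deg - 1)) / 2
  if (triples == 0) return(0)
  3 * tri / triples
}

# Mean local clustering straight from the per-node definition.
bf_clustering <- function(w) {
  n <- nrow(w)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    k_i <- sum(w[i, ]) + sum(w[, i])
    t_i <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h) {
        t_i <- t_i + 0.5 * (w[i, j] + w[j, i]) * (w[i, h] + w[h, i]) *
          (w[j, h] + w[h, j])
      }
    }
    vals[i] <- if (k_i * (k_i - 1) > 0) 2 * t_i / (k_i * (k_i - 1)) else 0
  }
  mean(vals)
}

bf_centralization <- function(w) {
  n <- nrow(w)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(w[i, ]) + sum(w[, i])
  sum(max(k) - k) / ((n - 1) * (n - 2))
}

# All-pairs shortest distances (edge length 1/weight) by exhaustive simple
# path enumeration; exponential, for n <= 5 only.
bf_distances <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  best_path <- function(i, j, visited) {
    if (i == j) return(0)
    best <- Inf
    for (k in which(is.finite(len[i, ]))) {
      if (!(k %in% visited)) {
        sub <- best_path(k, j, c(visited, k))
        best <- min(best, len[i, k] + sub)
      }
    }
    best
  }
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) d[i, j] <- best_path(i, j, i)
  }
  d
}

# Enumerate the i-th of the 2^10 undirected binary graphs on 5 labeled nodes.
symmetric_graph_5 <- function(index) {
  bits <- as.integer(intToBits(index))[1:10]
  a <- matrix(0, 5, 5)
  a[lower.tri(a)] <- bits
  a + t(a)
}

# Random weighted directed graph on n nodes for property tests.
random_weighted_net <- function(n, p_edge = 0.4, max_w = 3) {
  m <- matrix(0, n, n, dimnames = list(paste0("v", 1:n), paste0("v", 1:n)))
  for (i in 1:n) for (j in 1:n) {
    if (i != j && stats::runif(1) < p_edge) {
      m[i, j] <- sample(1:max_w, 1)
    }
  }
  scanpath_network(m)
}

# Toy stimulus: the example question sentence.
mars_stimulus <- function() {
  text_stimulus(list(c("Could", "humans", "live", "on", "Mars", "some",
                       "day?")), text_id = "mars")
}
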