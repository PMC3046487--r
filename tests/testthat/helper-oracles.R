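# Independent brute-force oracles.  These deliberately avoid the code
# paths (and libraries) used by the implementation they check.

# Betweenness by exhaustive enumeration of all shortest paths: BFS
# distances, then recursive expansion of every shortest path between
# every unordered vertex pair.
oracle_betweenness <- function(net) {
  verts <- net$vertices
  n <- length(verts)
  adjl <- rep(list(integer(0)), n)
  ia <- match(net$edges$gene_a, verts)
  ib <- match(net$edges$gene_b, verts)
  for (k in seq_along(ia)) {
    adjl[[ia[k]]] <- c(adjl[[ia[k]]], ib[k])
    adjl[[ib[k]]] <- c(adjl[[ib[k]]], ia[k])
  }
  bfs <- function(s) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    q <- s
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      for (w in adjl[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          q <- c(q, w)
        }
      }
    }
    dist
  }
  bc <- rep(0, n)
  if (n >= 3) {
    for (s in seq_len(n - 1)) {
      dist <- bfs(s)
      for (t in (s + 1):n) {
        if (is.infinite(dist[t])) next
        paths <- list()
        expand <- function(v, acc) {
          if (v == s) {
            paths[[length(paths) + 1]] <<- acc
            return(invisible())
          }
          for (w in adjl[[v]]) {
            if (dist[w] == dist[v] - 1) expand(w, c(w, acc))
          }
        }
        expand(t, t)
        P <- length(paths)
        interior <- unlist(lapply(paths, function(p) p[p != s & p != t]))
        if (length(interior) > 0) {
          tab <- table(interior)
          ix <- as.integer(names(tab))
          bc[ix] <- bc[ix] + as.numeric(tab) / P
        }
      }
    }
    bc <- bc / ((n - 1) * (n - 2) / 2)
  }
  stats::setNames(bc, verts)
}

# Exact two-sided Mann-Whitney p by full enumeration of rank
# arrangements (no ties assumed).
oracle_mann_whitney_p <- function(a, b) {
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(N, na)
  Us <- apply(combs, 2, function(ix) sum(ix) - na * (na + 1) / 2)
  mu <- na * nb / 2
  p <- if (U_obs > mu) {
    2 * mean(Us >= U_obs)
  } else if (U_obs < mu) {
    2 * mean(Us <= U_obs)
  } else 1
  min(1, p)
}

# Upper-tail hypergeometric by direct summation over the urn.
oracle_hyper_tail <- function(k, K, N, n) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Connected components by repeated frontier expansion on the edge list.
oracle_components <- function(net) {
  verts <- net$vertices
  comp <- stats::setNames(rep(NA_integer_, length(verts)), verts)
  cid <- 0L
  for (v in verts) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    frontier <- v
    comp[v] <- cid
    while (length(frontier) > 0) {
      nb <- unique(c(net$edges$gene_b[net$edges$gene_a %in% frontier],
                     net$edges$gene_a[net$edges$gene_b %in% frontier]))
      frontier <- nb[is.na(comp[nb])]
      comp[frontier] <- cid
    }
  }
  comp
}

# All simple graphs realizing a given degree sequence, by brute force
# over every subset of possible edges (tiny n only).  Returns a character
# vector of canonical edge-set signatures.
oracle_degree_realizations <- function(degrees) {
  n <- length(degrees)
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  out <- character(0)
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    deg <- tabulate(c(pairs[, sel]), nbins = n)
    if (all(deg == degrees)) {
      sig <- paste(sort(apply(pairs[, sel, drop = FALSE], 2, paste,
                              collapse = "-")), collapse = ",")
      out <- c(out, sig)
    }
  }
  out
}

edge_signature <- function(net) {
  ia <- match(net$edges$gene_a, net$vertices)
  ib <- match(net$edges$gene_b, net$vertices)
  paste(sort(paste(pmin(ia, ib), pmax(ia, ib), sep = "-")), collapse = ",")
}
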