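# Small in-code fixtures shared across test files.

# Three-individual toy: A focal twice with B within 5 m; B focal once with
# A and C within 5 m. Hand-enumerated 5 m counts: A:1, B:2, C:1.
toy_records <- function() {
  rec <- data.frame(
    focal_id = c("A", "A", "B"),
    year = "2018",
    time_period = 1L,
    end_observer_distance_m = c(3, 4, 5),
    n5 = c("B", "B", "A;C"),
    n2_5 = c("", "", "A"),
    n1 = "",
    touch = "",
    stringsAsFactors = FALSE
  )
  rec$stratum <- factor("close", levels = c("far", "close"))
  rec
}

# deterministic symmetric matrix with zero diagonal
sym_matrix <- function(n, seed = 1) {
  set.seed(seed)
  M <- matrix(stats::runif(n * n), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  dimnames(M) <- list(paste0("I", 1:n), paste0("I", 1:n))
  M
}

# a small complete study used by several files (cheap: 12 individuals)
small_study <- function(seed = 7, ...) {
  simulate_study(group_config(n_individuals = 12, seed = seed, ...))
}

# brute-force Spearman used as an independent check: Pearson on average ranks
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Independent all-simple-paths oracle for weighted shortest-path metrics on
# tiny graphs: enumerates every simple path between each ordered pair.
path_oracle <- function(W) {
  n <- nrow(W)
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) { out[[length(out) + 1]] <<- path; return() }
      for (v in seq_len(n)) {
        if (!v %in% path && W[last, v] > 0) walk(c(path, v))
      }
    }
    walk(s)
    out
  }
  len <- function(p) sum(W[cbind(p[-length(p)], p[-1])])
  D <- matrix(Inf, n, n); diag(D) <- 0
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    ps <- paths_between(s, t)
    if (!length(ps)) next
    ls <- vapply(ps, len, numeric(1))
    D[s, t] <- D[t, s] <- min(ls)
    short <- ps[abs(ls - min(ls)) < 1e-12]
    for (p in short) {
      mid <- setdiff(p, c(s, t))
      btw[mid] <- btw[mid] + 1 / length(short)
    }
  }
  clo <- vapply(1:n, function(i) {
    d <- D[i, -i]
    if (all(is.infinite(d))) 0 else sum(is.finite(d)) / sum(d[is.finite(d)])
  }, numeric(1))
  list(D = D, closeness = clo, betweenness = btw)
}
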