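#' Build a proportion-weighted association matrix for one cell
#'
#' The raw strength of dyad (i, j) is the number of focal records in the
#' (buffer, stratum, year) cell where i was focal with j in the buffer set
#' plus those where j was focal with i in the set (focal-to-neighbour
#' associations only; two neighbours co-occurring in a third animal's focal
#' are not counted). Because individuals are sampled unevenly across
#' observation distances, the strength is converted to a proportion of the
#' dyad's combined sampling effort: weight = count / (f_i + f_j), with f_x
#' the number of focal samples of x in the stratum/year.
#'
#' @param records Stratified focal records ([split_by_distance()]).
#' @param buffer Buffer column label.
#' @param stratum `"close"` or `"far"`.
#' @param year Year label.
#' @param ids Id universe (default: every individual appearing in `records`
#'   as a focal or neighbour).
#' @return List of class `assoc_matrix`: `ids`, `weights` (symmetric, zero
#'   diagonal, in \[0, 1\]), `counts` (raw symmetric dyad counts),
#'   `dyad_exposure` (f_i + f_j), `focal_effort` (per-individual f_x),
#'   `undefined` (logical mask of dyads where both members have zero
#'   focals; their weight is recorded as 0), `buffer`, `stratum`, `year`.
#' @export
build_association_matrix <- function(records, buffer, stratum, year,
                                     ids = NULL) {
  if (!buffer %in% names(records)) stop("unknown buffer label: ", buffer)
  if (is.null(ids)) ids <- id_universe(records)
  if (length(ids) < 2) stop("need >= 2 individuals")
  cell <- records[records$stratum == stratum &
                    as.character(records$year) == as.character(year), ,
                  drop = FALSE]
  n <- length(ids)
  counts <- matrix(0L, n, n, dimnames = list(ids, ids))
  sets <- split_ids(cell[[buffer]])
  for (k in seq_len(nrow(cell))) {
    f <- cell$focal_id[k]
    nb <- intersect(sets[[k]], ids)
    counts[f, nb] <- counts[f, nb] + 1L
  }
  counts <- counts + t(counts)  # symmetrize focal->neighbour tallies
  effort <- table(factor(cell$focal_id, levels = ids))
  dyad_exp <- outer(as.integer(effort), as.integer(effort), "+")
  dimnames(dyad_exp) <- list(ids, ids)
  undefined <- dyad_exp == 0
  weights <- ifelse(undefined, 0, counts / pmax(dyad_exp, 1L))
  diag(weights) <- 0
  diag(undefined) <- FALSE
  structure(list(ids = ids, weights = weights, counts = counts,
                 dyad_exposure = dyad_exp, focal_effort = effort,
                 undefined = undefined,
                 buffer = buffer, stratum = stratum,
                 year = as.character(year)),
            class = "assoc_matrix")
}

as_weights <- function(A) {
  if (inherits(A, "assoc_matrix")) A$weights else as.matrix(A)
}

# upper-triangle pair-index map; M[p, p][upper.tri] re-indexes the triangle
# vector under a joint row/column permutation p
tri_index_map <- function(n) {
  M <- matrix(0L, n, n)
  M[upper.tri(M)] <- seq_len(n * (n - 1L) / 2L)
  M + t(M)
}

#' Mantel permutation test between two association matrices
#'
#' Correlates the upper triangles of two symmetric matrices (Spearman rank
#' with average-rank ties by default) and builds the null by jointly
#' permuting the rows and columns of the second matrix. The p-value is
#' one-sided greater with the add-one rule,
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`, so the smallest
#' attainable p at 999 permutations is 0.001. With `exact = TRUE` all `n!`
#' relabelings are enumerated instead (feasible for n <= 8) and
#' `p = #\{r_perm >= r_obs\} / n!` over the full group (identity included).
#'
#' @param A,B Symmetric matrices (or `assoc_matrix` objects) with identical
#'   id ordering.
#' @param n_perm Number of random permutations (default 999).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param seed Optional integer seed for the permutation stream.
#' @param exact Enumerate all relabelings instead of sampling.
#' @return List of class `mantel_result`: `r`, `p`, `n_perm`, `method`,
#'   `perm_r` (null statistics).
#' @export
mantel <- function(A, B, n_perm = 999L, method = c("spearman", "pearson"),
                   seed = NULL, exact = FALSE) {
  method <- match.arg(method)
  WA <- as_weights(A); WB <- as_weights(B)
  n <- nrow(WA)
  if (!all(dim(WA) == dim(WB))) stop("matrices must have identical dimensions")
  if (n < 3) stop("need n >= 3")
  tri <- upper.tri(WA)
  a <- WA[tri]; b <- WB[tri]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("degenerate matrix: zero variance")
  xa <- if (method == "spearman") rank(a) else a
  xb <- if (method == "spearman") rank(b) else b
  ca <- xa - mean(xa)
  ssa <- sum(ca^2)
  ssb <- sum((xb - mean(xb))^2)
  stat <- function(bv) sum(ca * bv) / sqrt(ssa * ssb)  # means cancel
  r_obs <- stat(xb)

  M <- tri_index_map(n)
  if (exact) {
    perms <- all_permutations(n)
    perm_r <- vapply(perms, function(p) stat(xb[M[p, p][tri]]), numeric(1))
    p_val <- mean(perm_r >= r_obs - 1e-12)  # identity included in the group
    n_perm <- length(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    perm_r <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      stat(xb[M[p, p][tri]])
    }, numeric(1))
    p_val <- (1 + sum(perm_r >= r_obs - 1e-12)) / (1 + n_perm)
  }
  structure(list(r = r_obs, p = p_val, n_perm = n_perm, method = method,
                 perm_r = perm_r, exact = exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.3f, p = %.4g (%s, %d %s permutations)\n",
              x$r, x$p, x$method, x$n_perm,
              if (x$exact) "exact" else "random"))
  invisible(x)
}

all_permutations <- function(n) {
  if (n > 8) stop("exact enumeration limited to n <= 8")
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(s, n, after = pos - 1L)
  }
  out
}

#' Weighted network centralities
#'
#' Degree (count of nonzero incident edges), strength (sum of incident
#' weights), closeness and betweenness on the undirected graph whose edge
#' *lengths* are the association weights used directly as distances (absent
#' edges are non-edges, not zero-length). Closeness is
#' `(n_reachable - 1) / sum(d)` within each component; a harmonic-closeness
#' column (which handles disconnection gracefully) is reported alongside.
#' Betweenness uses the standard shortest-path pair-dependency accumulation
#' with fractional credit for tied paths. With `distance = "inverse"` edge
#' lengths are `1/weight`, so strong associations are short — clearly
#' labelled as the non-default convention.
#'
#' @param A Symmetric nonnegative matrix or `assoc_matrix`.
#' @param distance `"weight"` (weights are distances; default) or
#'   `"inverse"`.
#' @return Data frame: `individual_id, degree, strength, closeness,
#'   harmonic_closeness, betweenness`.
#' @export
centralities <- function(A, distance = c("weight", "inverse")) {
  distance <- match.arg(distance)
  W <- as_weights(A)
  if (any(W < 0)) stop("negative weights")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- igraph::E(g)$weight
  if (distance == "inverse") len <- 1 / len
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  strength <- igraph::strength(g)
  D <- igraph::distances(g, weights = len)
  clo <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    reach <- is.finite(d)
    if (!any(reach)) return(0)
    sum(reach) / sum(d[reach])
  }, numeric(1))
  harm <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    sum(1 / d[is.finite(d) & d > 0]) / (n - 1)
  }, numeric(1))
  btw <- igraph::betweenness(g, weights = len, directed = FALSE)
  data.frame(individual_id = rownames(W) %||% as.character(seq_len(n)),
             degree = as.integer(deg), strength = unname(strength),
             closeness = clo, harmonic_closeness = harm,
             betweenness = unname(btw),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank concordance of centralities across observation distances
#'
#' Spearman rank correlation (average ranks, two-sided p from the
#' t-approximation) per centrality metric between the close- and
#' far-stratum networks of the same individuals. Constant metric vectors
#' yield a flagged `NA` row rather than a silent zero.
#'
#' @param close,far Centrality data frames from [centralities()] for the
#'   same individuals in the same order.
#' @param metrics Metric columns to compare.
#' @return Data frame: `metric, rho, df, p, defined`.
#' @export
compare_centralities <- function(close, far,
                                 metrics = c("degree", "closeness",
                                             "betweenness")) {
  stopifnot(identical(close$individual_id, far$individual_id))
  out <- do.call(rbind, lapply(metrics, function(m) {
    x <- close[[m]]; y <- far[[m]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(metric = m, rho = NA_real_,
                        df = length(x) - 2L, p = NA_real_,
                        defined = FALSE))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    data.frame(metric = m, rho = unname(ct$estimate),
               df = length(x) - 2L, p = ct$p.value, defined = TRUE)
  }))
  rownames(out) <- NULL
  out
}

#' Export an association matrix
#'
#' @param A An `assoc_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix_csv <- function(A, path) {
  utils::write.csv(as.data.frame(as_weights(A)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
write_graphml <- function(A, path) {
  g <- igraph::graph_from_adjacency_matrix(as_weights(A),
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
write_edgelist_csv <- function(A, path) {
  W <- as_weights(A)
  tri <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  utils::write.csv(
    data.frame(from = rownames(W)[tri[, 1]], to = colnames(W)[tri[, 2]],
               weight = W[tri]),
    path, row.names = FALSE)
  invisible(path)
}
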