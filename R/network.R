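# Weighted bipartite plant x animal networks and their comparison:
# valued/binary Hamming distance, graph correlation, and a two-mode
# label-permutation QAP test.

#' Construct a weighted bipartite network
#'
#' @param weights Nonnegative numeric matrix, plants in rows and animal
#'   species in columns (event counts by default).
#' @param plants,animals Optional label vectors; default to the matrix
#'   dimnames.
#' @return Object of class `bipartite_network`: list with `plants`,
#'   `animals`, `weights` (a labeled matrix).
#' @export
bipartite_network <- function(weights, plants = rownames(weights),
                              animals = colnames(weights)) {
  weights <- as.matrix(weights)
  if (is.null(plants) || is.null(animals))
    stop("plant and animal labels are required")
  plants <- as.character(plants); animals <- as.character(animals)
  if (anyDuplicated(plants)) stop("duplicate plant labels")
  if (anyDuplicated(animals)) stop("duplicate animal labels")
  stopifnot(nrow(weights) == length(plants),
            ncol(weights) == length(animals))
  if (any(is.na(weights)) || any(weights < 0))
    stop("weights must be nonnegative and non-missing")
  dimnames(weights) <- list(plants, animals)
  structure(list(plants = plants, animals = animals, weights = weights),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat("bipartite_network:", length(x$plants), "plants x",
      length(x$animals), "animals, total weight", sum(x$weights), "\n")
  invisible(x)
}

#' Build a network from a long edge list
#'
#' @param edges Data frame with columns `plant`, `animal`, `weight`
#'   (duplicate pairs are summed).
#' @return A [bipartite_network()].
#' @export
edgelist_to_network <- function(edges) {
  w <- tapply(edges$weight, list(factor(edges$plant), factor(edges$animal)),
              sum)
  w[is.na(w)] <- 0
  bipartite_network(w)
}

#' @rdname edgelist_to_network
#' @param net A `bipartite_network`.
#' @param drop_zero Omit zero-weight cells (default `TRUE`).
#' @export
network_to_edgelist <- function(net, drop_zero = TRUE) {
  df <- expand.grid(plant = net$plants, animal = net$animals,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$weight <- as.vector(net$weights)
  if (drop_zero) df <- df[df$weight != 0, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read / write a network as a labeled CSV matrix
#'
#' @param net A `bipartite_network`.
#' @param path CSV file (first column = plant labels, header = animals).
#' @return `write_network` invisibly returns `path`; `read_network` returns
#'   a `bipartite_network`.
#' @export
write_network <- function(net, path) {
  df <- data.frame(plant = net$plants, as.data.frame(net$weights),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  w <- as.matrix(df[, -1, drop = FALSE])
  rownames(w) <- df[[1]]
  bipartite_network(w)
}

#' Align two networks on the union of their label sets
#'
#' Expands both weight matrices to the sorted union of plant labels and of
#' animal labels, filling absent cells with 0, so cell-wise comparison is
#' well defined.
#'
#' @param a,b `bipartite_network` objects.
#' @return List with the two aligned networks (`a`, `b`).
#' @export
align_networks <- function(a, b) {
  plants <- sort(union(a$plants, b$plants))
  animals <- sort(union(a$animals, b$animals))
  expand <- function(n) {
    w <- matrix(0, length(plants), length(animals),
                dimnames = list(plants, animals))
    w[n$plants, n$animals] <- n$weights
    bipartite_network(w)
  }
  list(a = expand(a), b = expand(b))
}

#' @noRd
.check_aligned <- function(a, b) {
  if (!identical(dim(a$weights), dim(b$weights)) ||
      !identical(a$plants, b$plants) || !identical(a$animals, b$animals))
    stop("networks are not aligned; call align_networks() first")
}

#' Hamming distance between two aligned networks
#'
#' Valued mode (default) sums absolute cell-wise weight differences;
#' binary mode counts cells whose presence/absence state differs.
#'
#' @param a,b Aligned `bipartite_network` objects.
#' @param mode `"valued"` or `"binary"`.
#' @return Nonnegative scalar.
#' @export
hamming_distance <- function(a, b, mode = c("valued", "binary")) {
  mode <- match.arg(mode)
  .check_aligned(a, b)
  if (mode == "valued") sum(abs(a$weights - b$weights))
  else sum((a$weights > 0) != (b$weights > 0))
}

#' Graph correlation between two aligned networks
#'
#' Product-moment correlation over all vectorized cells.
#'
#' @param a,b Aligned `bipartite_network` objects.
#' @return Value in `[-1, 1]`, or `NA` (with a warning) when either matrix
#'   is constant.
#' @export
graph_correlation <- function(a, b) {
  .check_aligned(a, b)
  x <- as.vector(a$weights); y <- as.vector(b$weights)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("graph correlation undefined: a matrix has zero variance")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' @noRd
.qap_stat <- function(statistic, mode) {
  switch(statistic,
         hamming = function(a, b) hamming_distance(a, b, mode = mode),
         gcor = graph_correlation)
}

#' Two-mode QAP permutation test between bipartite networks
#'
#' Compares an observed network statistic (valued Hamming distance or graph
#' correlation) against its distribution under random relabeling of the
#' second network: each iteration independently permutes `b`'s plant labels
#' and animal labels (the two-mode analogue of one-mode QAP node-label
#' permutation) and recomputes the statistic against `a`. The p-value uses
#' the add-one estimator `(#extreme + 1) / (n_perm + 1)` with ties counted
#' as extreme.
#'
#' @param a,b `bipartite_network` objects (aligned automatically).
#' @param statistic `"hamming"` or `"gcor"`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for reproducibility (RNG state is restored).
#' @param alternative `"less"`, `"greater"` or `"two_sided"`. Defaults to
#'   `"less"` for Hamming (similar networks have smaller distance than the
#'   null) and `"greater"` for gcor.
#' @param mode Hamming mode, `"valued"` (default) or `"binary"`.
#' @return Object of class `qap_result`: list with `statistic_name`,
#'   `observed`, `null_values`, `p_value`, `n_perm`, `seed`, `alternative`.
#' @export
qap_test <- function(a, b, statistic = c("hamming", "gcor"),
                     n_perm = 1000, seed = NULL, alternative = NULL,
                     mode = c("valued", "binary")) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  stopifnot(n_perm >= 1)
  al <- align_networks(a, b)
  a <- al$a; b <- al$b
  if (length(a$plants) * length(a$animals) <= 1)
    stop("degenerate (1x1) network: QAP permutation is vacuous")
  if (is.null(alternative))
    alternative <- if (statistic == "hamming") "less" else "greater"
  alternative <- match.arg(alternative, c("less", "greater", "two_sided"))

  fn <- .qap_stat(statistic, mode)
  observed <- fn(a, b)
  np <- length(b$plants); na <- length(b$animals)
  null_values <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      w <- b$weights[sample.int(np), sample.int(na), drop = FALSE]
      dimnames(w) <- list(b$plants, b$animals)
      fn(a, bipartite_network(w))
    }, numeric(1))
  })
  n_extreme <- switch(alternative,
    less = sum(null_values <= observed),
    greater = sum(null_values >= observed),
    two_sided = {
      ctr <- mean(null_values)
      sum(abs(null_values - ctr) >= abs(observed - ctr))
    })
  structure(list(statistic_name = statistic, observed = observed,
                 null_values = null_values,
                 p_value = (n_extreme + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed, alternative = alternative),
            class = "qap_result")
}

#' @export
print.qap_result <- function(x, ...) {
  cat(sprintf("QAP test (%s, alternative = %s): observed = %g, p = %g (%d permutations)\n",
              x$statistic_name, x$alternative, x$observed, x$p_value, x$n_perm))
  invisible(x)
}

#' Serialize a QAP result to JSON
#'
#' @param x A `qap_result`.
#' @param path Output file.
#' @param include_null Store the full null distribution (default `FALSE`).
#' @return Invisibly, `path`.
#' @export
write_qap_result <- function(x, path, include_null = FALSE) {
  obj <- x[c("statistic_name", "observed", "p_value", "n_perm", "seed",
             "alternative")]
  if (include_null) obj$null_values <- x$null_values
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
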