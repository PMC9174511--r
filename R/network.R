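#' Network estimation configuration
#'
#' @param gamma EBIC hyperparameter (default 0.5, the conservative value
#'   standard in symptom-network work).
#' @param n_lambda number of penalty values on the log-spaced grid
#'   (default 100).
#' @param lambda_min_ratio smallest penalty as a fraction of
#'   \eqn{\lambda_{max}} (default 0.01).
#' @param correlation_input \code{"polychoric"} (default; the items are
#'   5-category ordinal) or \code{"pearson"}.
#' @return list of class \code{"network_config"}.
#' @export
network_config <- function(gamma = 0.5, n_lambda = 100, lambda_min_ratio = 0.01,
                           correlation_input = c("polychoric", "pearson")) {
  if (gamma < 0) stop_input("gamma must be nonnegative")
  if (lambda_min_ratio <= 0 || lambda_min_ratio >= 1) {
    stop_input("lambda_min_ratio must lie in (0, 1)")
  }
  structure(list(gamma = gamma, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 correlation_input = match.arg(correlation_input)),
            class = "network_config")
}

#' EBIC-selected regularized partial-correlation network
#'
#' EBICglasso: the graphical lasso is solved along a grid of
#' \code{n_lambda} penalties log-spaced from \eqn{\lambda_{max}} (the
#' largest absolute off-diagonal correlation, at which the network is
#' empty) down to \eqn{\lambda_{max} \cdot} \code{lambda_min_ratio}; each
#' solution is scored by the Extended Bayesian Information Criterion
#' \deqn{EBIC = -n(\log\det K - \mathrm{tr}(SK)) + E \ln n + 4\gamma E \ln p}
#' with E the number of nonzero upper-triangle edges, and the minimizer is
#' returned as a partial-correlation network.
#'
#' @param data either an n x p matrix/data frame of item scores, or a
#'   precomputed correlation matrix (then \code{n} must be given).
#' @param config \code{\link{network_config}}.
#' @param n sample size, required when \code{data} is a correlation matrix.
#' @return object of class \code{"gaussian_network"}: \code{weights}
#'   (p x p partial correlations, exact zeros off the selected support),
#'   \code{K}, \code{lambda_selected}, \code{ebic_at_selection},
#'   \code{lambda_grid}, \code{edge_counts}, \code{n}, \code{config}.
#' @export
estimate_network <- function(data, config = network_config(), n = NULL) {
  if (is_corr_matrix(as.matrix(data))) {
    S <- as.matrix(data)
    if (is.null(n)) stop_input("n must be supplied with a correlation-matrix input")
  } else {
    m <- as.matrix(data)
    n <- nrow(m)
    if (n <= ncol(m)) stop_input("need more subjects than items")
    if (min(apply(m, 2, function(x) length(unique(x)))) < 2) {
      stop_input("degenerate item with a single observed value")
    }
    S <- if (config$correlation_input == "polychoric") {
      polychoric_matrix(m)$R
    } else {
      stats::cor(m)
    }
  }
  p <- nrow(S)
  labels <- colnames(S) %||% paste0("V", seq_len(p))
  lambda_max <- max(abs(S[upper.tri(S)]))
  if (lambda_max <= 0) stop_input("all correlations are zero")
  grid <- exp(seq(log(lambda_max), log(lambda_max * config$lambda_min_ratio),
                  length.out = config$n_lambda))
  ebic <- numeric(length(grid))
  edges <- integer(length(grid))
  fits <- vector("list", length(grid))
  warm <- NULL
  for (i in seq_along(grid)) {
    fit <- glasso_solve(S, grid[i], warm = warm)
    warm <- list(W = fit$W, Beta = fit$Beta)
    K <- fit$K
    E <- sum(K[upper.tri(K)] != 0)
    ll <- n / 2 * (determinant(K, logarithm = TRUE)$modulus[1] - sum(S * K))
    ebic[i] <- -2 * ll + E * log(n) + 4 * config$gamma * E * log(p)
    edges[i] <- E
    fits[[i]] <- fit
  }
  best <- which.min(ebic)
  K <- fits[[best]]$K
  wts <- precision_to_partial(K)
  dimnames(wts) <- list(labels, labels)
  structure(
    list(weights = wts, K = K, lambda_selected = grid[best],
         ebic_at_selection = ebic[best], lambda_grid = grid,
         ebic_grid = ebic, edge_counts = edges, n = n, config = config),
    class = "gaussian_network"
  )
}

#' Sparsity of a network
#'
#' Fraction of the \eqn{p(p-1)/2} node pairs with a zero edge weight.
#'
#' @param net \code{"gaussian_network"} or a weights matrix.
#' @return number in [0, 1].
#' @export
network_sparsity <- function(net) {
  w <- if (inherits(net, "gaussian_network")) net$weights else as.matrix(net)
  u <- w[upper.tri(w)]
  mean(u == 0)
}

#' Node centrality indices of a weighted network
#'
#' Edge distances are the reciprocal absolute weights; betweenness is
#' Brandes shortest-path counting with fractional credit for ties;
#' closeness is the reciprocal of the summed shortest-path distances from
#' the node (over reachable nodes only, with a disconnection flag, since
#' the usual verbal definition does not cover disconnected graphs);
#' strength is the sum of absolute incident weights and expected influence
#' its signed counterpart. Each index is reported raw and z-standardized
#' across nodes (symptom-network convention for reporting).
#'
#' @param net \code{"gaussian_network"} or a symmetric zero-diagonal
#'   weights matrix.
#' @return tibble of class \code{"centrality_table"}: \code{node}, raw
#'   \code{betweenness}, \code{closeness}, \code{strength},
#'   \code{expected_influence}, their \code{z_} versions, and
#'   \code{disconnected}.
#' @export
centrality_measures <- function(net) {
  w <- if (inherits(net, "gaussian_network")) net$weights else as.matrix(net)
  p <- nrow(w)
  if (p < 2) stop_input("need at least two nodes")
  labels <- rownames(w) %||% paste0("V", seq_len(p))
  strength <- rowSums(abs(w))
  ei <- rowSums(w)
  dist_w <- ifelse(w == 0, 0, 1 / abs(w))
  g <- igraph::graph_from_adjacency_matrix(dist_w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  btw <- igraph::betweenness(g, weights = igraph::E(g)$weight)
  D <- igraph::distances(g, weights = igraph::E(g)$weight)
  diag(D) <- NA
  disconnected <- apply(D, 1, function(r) any(is.infinite(r)))
  closeness <- apply(D, 1, function(r) {
    r <- r[is.finite(r)]
    if (length(r) == 0) 0 else 1 / sum(r)
  })
  zstd <- function(x) {
    s <- sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  structure(
    tibble::tibble(
      node = labels,
      betweenness = unname(btw), closeness = unname(closeness),
      strength = unname(strength), expected_influence = unname(ei),
      z_betweenness = zstd(unname(btw)), z_closeness = zstd(unname(closeness)),
      z_strength = zstd(unname(strength)),
      z_expected_influence = zstd(unname(ei)),
      disconnected = unname(disconnected)
    ),
    class = c("centrality_table", class(tibble::tibble()))
  )
}

#' Tidy edge list of a network
#'
#' @param x \code{"gaussian_network"}.
#' @param ... unused.
#' @return tibble with \code{from}, \code{to}, \code{weight} for nonzero
#'   edges.
#' @export
tidy.gaussian_network <- function(x, ...) {
  w <- x$weights
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  tibble::tibble(
    from = rownames(w)[idx[, 1]],
    to = colnames(w)[idx[, 2]],
    weight = w[idx]
  )
}

#' @export
glance.gaussian_network <- function(x, ...) {
  tibble::tibble(
    nodes = nrow(x$weights),
    edges = sum(x$weights[upper.tri(x$weights)] != 0),
    sparsity = network_sparsity(x),
    lambda_selected = x$lambda_selected,
    ebic = x$ebic_at_selection,
    gamma = x$config$gamma,
    n = x$n
  )
}

#' @export
print.gaussian_network <- function(x, ...) {
  g <- glance.gaussian_network(x)
  cat(sprintf("Partial-correlation network: %d nodes, %d edges (sparsity %.2f), lambda = %.4f (EBIC gamma = %.2f)\n",
              g$nodes, g$edges, g$sparsity, g$lambda_selected, g$gamma))
  invisible(x)
}

#' Plot a symptom network
#'
#' Circle-layout rendering of a partial-correlation network: edge width
#' scales with the absolute partial correlation, blue for positive and red
#' for negative edges.
#'
#' @param object \code{"gaussian_network"}.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gaussian_network <- function(object, ...) {
  w <- object$weights
  p <- nrow(w)
  ang <- seq(0, 2 * pi, length.out = p + 1)[-(p + 1)]
  nodes <- tibble::tibble(node = rownames(w), x = cos(ang), y = sin(ang))
  edges <- tidy.gaussian_network(object)
  edges <- dplyr::left_join(edges, nodes, by = c("from" = "node"))
  edges <- dplyr::rename(edges, x0 = "x", y0 = "y")
  edges <- dplyr::left_join(edges, nodes, by = c("to" = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y,
                   linewidth = abs(.data$weight),
                   colour = .data$weight > 0),
      alpha = 0.7, show.legend = FALSE
    ) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b")) +
    ggplot2::scale_linewidth(range = c(0.2, 2.5)) +
    ggplot2::geom_label(data = nodes, ggplot2::aes(.data$x, .data$y, label = .data$node)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot z-standardized centrality profiles
#'
#' @param object \code{"centrality_table"}.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.centrality_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("node", "z_betweenness", "z_closeness", "z_strength",
               "z_expected_influence")],
    -"node", names_to = "metric", values_to = "z"
  )
  long$metric <- sub("^z_", "", long$metric)
  ggplot2::ggplot(long, ggplot2::aes(.data$z, .data$node)) +
    ggplot2::geom_point() +
    ggplot2::geom_path(ggplot2::aes(group = .data$metric)) +
    ggplot2::facet_wrap(~metric, nrow = 1) +
    ggplot2::labs(x = "z-score", y = NULL) +
    ggplot2::theme_minimal()
}

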