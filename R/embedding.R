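# 2-D embedding of binary attractor states.
#
# Attractor states are rows of 0/1 over the network nodes; cycles contribute
# one row per state. The embedding is exact t-SNE (pairwise affinities with
# per-point perplexity calibration by bisection, then gradient descent on the
# Kullback-Leibler divergence with early exaggeration and momentum). Row
# counts here are tens, so the O(m^2) exact algorithm is the right tool; no
# Barnes-Hut approximation is used and results are deterministic for a fixed
# seed.

#' Build the state matrix of an attractor set
#'
#' One row per attractor state (fixed points contribute one row, a period-p
#' cycle contributes p rows), in deterministic order: attractors in canonical
#' order, states in cycle order. Rows that are bit-identical share a
#' duplicate-group id.
#'
#' @param aset an `attractor_set`.
#' @param scheme a [phenotype_scheme()] for the row metadata.
#' @return a `state_matrix`: list with `X` (0/1 matrix, columns = nodes) and
#'   `meta` (data frame: attractor id, state index, class, composite name,
#'   duplicate group).
#' @export
state_matrix <- function(aset, scheme) {
  if (length(aset$attractors) == 0L) stop("empty attractor set")
  net <- aset$network
  rows <- list()
  meta <- list()
  for (i in seq_along(aset$attractors)) {
    a <- aset$attractors[[i]]
    ann <- classify_attractor(a, scheme, net)
    for (s in seq_len(a$period)) {
      rows[[length(rows) + 1L]] <- a$states[s, ]
      meta[[length(meta) + 1L]] <- data.frame(
        attractor = i, state_index = s, class = ann$class,
        name = ann$state_names[s], attractor_name = ann$name,
        stringsAsFactors = FALSE)
    }
  }
  X <- do.call(rbind, rows)
  colnames(X) <- net$nodes
  meta <- do.call(rbind, meta)
  key <- apply(X, 1L, paste, collapse = "")
  meta$group <- match(key, unique(key))
  structure(list(X = X, meta = meta), class = "state_matrix")
}

# Perplexity calibration: find per-row Gaussian precisions such that the
# Shannon entropy of each conditional distribution equals log2(perplexity).
tsne_affinities <- function(D2, perplexity, tol = 1e-5, max_iter = 60L) {
  m <- nrow(D2)
  P <- matrix(0, m, m)
  target <- log(perplexity)
  for (i in seq_len(m)) {
    beta <- 1
    lo <- -Inf
    hi <- Inf
    di <- D2[i, -i]
    for (it in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < .Machine$double.xmin) {
        h <- 0
        p <- rep(0, length(w))
        p[which.min(di)] <- 1
      } else {
        p <- w / sw
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      diff <- h - target
      if (abs(diff) < tol) break
      if (diff > 0) {        # entropy too high -> sharpen
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * m)
  pmax(P, 1e-12)
}

tsne_exact <- function(X, perplexity, seed, n_iter = 1000L, eta = 100,
                       exaggeration = 4, exaggerate_iter = 100L) {
  m <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- tsne_affinities(D2, perplexity)
  set.seed(seed)
  Y <- matrix(stats::rnorm(m * 2L, sd = 1e-4), m, 2L)
  V <- matrix(0, m, 2L)
  Pex <- P * exaggeration
  for (it in seq_len(n_iter)) {
    Pi <- if (it <= exaggerate_iter) Pex else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pi - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    mom <- if (it <= 250L) 0.5 else 0.8
    V <- mom * V - eta * grad
    Y <- Y + V
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}

#' Embed attractor states in two dimensions
#'
#' Deduplicates bit-identical rows, runs exact t-SNE on the distinct rows,
#' then re-expands duplicates at their group's coordinates plus a small
#' deterministic jitter (uniform in a disk of radius `jitter_radius`) so
#' coincident states remain visually coincident but individually pickable.
#'
#' @param m a [state_matrix()].
#' @param seed RNG seed; fixed seed + parameters give identical coordinates.
#' @param perplexity t-SNE perplexity; default `min(5, distinct rows - 1)`.
#'   Values >= the number of distinct rows are shrunk with a warning.
#' @param n_iter gradient-descent iterations (default 1000).
#' @param jitter_radius jitter disk radius for duplicate rows, in embedding
#'   units (default 0.01 of the coordinate range).
#' @return an `embedding_result`: the metadata of `m` plus columns `x`, `y`
#'   and `group`; attribute `params` records seed, perplexity and iterations.
#' @export
embed_states <- function(m, seed, perplexity = NULL, n_iter = 1000L,
                         jitter_radius = NULL) {
  if (!inherits(m, "state_matrix")) stop("m must be a state_matrix")
  X <- m$X
  key <- apply(X, 1L, paste, collapse = "")
  ukey <- unique(key)
  Xu <- X[match(ukey, key), , drop = FALSE]
  mu <- nrow(Xu)
  if (mu < 3L) {
    stop(sprintf(paste("only %d distinct state(s); a 2-D embedding needs at",
                       "least 3 - plot the states directly instead"), mu))
  }
  if (is.null(perplexity)) perplexity <- min(5, mu - 1)
  if (perplexity >= mu) {
    warning(sprintf("perplexity %.1f >= %d distinct rows; shrunk to %.1f",
                    perplexity, mu, (mu - 1) / 3))
    perplexity <- (mu - 1) / 3
  }
  Yu <- tsne_exact(Xu, perplexity, seed = seed, n_iter = n_iter)
  span <- max(apply(Yu, 2L, function(v) diff(range(v))), 1e-8)
  if (is.null(jitter_radius)) jitter_radius <- 0.01 * span
  gi <- match(key, ukey)
  Y <- Yu[gi, , drop = FALSE]
  # deterministic jitter for every member of a duplicated group
  set.seed(seed + 1L)
  dup <- duplicated(gi) | duplicated(gi, fromLast = TRUE)
  ndup <- sum(dup)
  if (ndup) {
    r <- jitter_radius * sqrt(stats::runif(ndup))
    th <- stats::runif(ndup, 0, 2 * pi)
    Y[dup, 1L] <- Y[dup, 1L] + r * cos(th)
    Y[dup, 2L] <- Y[dup, 2L] + r * sin(th)
  }
  out <- m$meta
  out$x <- Y[, 1L]
  out$y <- Y[, 2L]
  out$group <- gi
  attr(out, "params") <- list(seed = seed, perplexity = perplexity,
                              n_iter = n_iter,
                              jitter_radius = jitter_radius)
  class(out) <- c("embedding_result", class(out))
  out
}

#' Write embedding coordinates as CSV
#'
#' @param emb an `embedding_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  utils::write.csv(as.data.frame(emb), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Plot an embedding colored by attractor class
#'
#' Base-graphics scatter of the 2-D map; points are colored by attractor
#' class (fixed points vs cycles) and labeled with composite phenotype names.
#'
#' @param x an `embedding_result`.
#' @param labels draw composite names next to points.
#' @param ... passed to [plot()].
#' @export
plot.embedding_result <- function(x, labels = TRUE, ...) {
  cls <- factor(x$class,
                levels = c("pure fixed point", "hybrid fixed point", "cycle"))
  cols <- c("#1b9e77", "#d95f02", "#7570b3")[as.integer(cls)]
  graphics::plot(x$x, x$y, col = cols, pch = 19,
                 xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  if (labels) graphics::text(x$x, x$y, x$name, pos = 3, cex = 0.7, col = cols)
  graphics::legend("topleft", legend = levels(cls), col = c("#1b9e77",
                   "#d95f02", "#7570b3"), pch = 19, bty = "n", cex = 0.8)
  invisible(x)
}
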