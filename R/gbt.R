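# Second-order gradient boosted trees for binary logistic loss, supporting
# depth-wise (XGBoost-style) and leaf-wise (LightGBM-style) growth. Exact
# greedy split finding; deterministic (first feature / smallest threshold
# wins ties).

# Best split of the rows `idx`. Returns NULL when no admissible split has
# positive gain.
gbt_best_split <- function(x, g, h, idx, lambda, min_hess, min_data) {
  if (length(idx) < 2L * min_data) return(NULL)
  G <- sum(g[idx]); H <- sum(h[idx])
  if (H < 2 * min_hess) return(NULL)
  parent <- G^2 / (H + lambda)
  best <- NULL
  best_gain <- 0
  for (j in seq_len(ncol(x))) {
    v <- x[idx, j]
    r <- range(v)
    if (r[1] == r[2]) next
    # Histogram aggregation of (g, h, count) by feature value; rowsum sorts
    # the distinct values, so cumulative sums scan left-to-right cuts.
    s <- rowsum(cbind(g[idx], h[idx], 1), v)
    nv <- nrow(s)
    if (nv < 2L) next
    vals <- as.numeric(rownames(s))
    GL <- cumsum(s[, 1])[-nv]
    HL <- cumsum(s[, 2])[-nv]
    NL <- cumsum(s[, 3])[-nv]
    GR <- G - GL; HR <- H - HL
    ok <- NL >= min_data & (length(idx) - NL) >= min_data &
      HL >= min_hess & HR >= min_hess
    if (!any(ok)) next
    gain <- 0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) - parent)
    gain[!ok] <- -Inf
    k <- which.max(gain)
    if (gain[k] > best_gain + 1e-12) {
      best_gain <- gain[k]
      thr <- (vals[k] + vals[k + 1L]) / 2
      left <- v <= vals[k]
      best <- list(feature = j, threshold = thr, gain = gain[k],
                   left = idx[left], right = idx[!left])
    }
  }
  best
}

gbt_leaf_value <- function(g, h, idx, lambda) {
  -sum(g[idx]) / (sum(h[idx]) + lambda)
}

new_tree_state <- function() {
  env <- new.env(parent = emptyenv())
  env$feature <- integer(0); env$threshold <- numeric(0)
  env$left <- integer(0); env$right <- integer(0)
  env$value <- numeric(0); env$is_leaf <- logical(0)
  env
}

tree_add_node <- function(tr) {
  k <- length(tr$is_leaf) + 1L
  tr$feature[k] <- 0L; tr$threshold[k] <- 0
  tr$left[k] <- 0L; tr$right[k] <- 0L
  tr$value[k] <- 0; tr$is_leaf[k] <- TRUE
  k
}

tree_as_df <- function(tr) {
  data.frame(feature = tr$feature, threshold = tr$threshold, left = tr$left,
             right = tr$right, value = tr$value, is_leaf = tr$is_leaf)
}

# Depth-wise growth to max_depth (root is depth 0).
gbt_grow_depthwise <- function(x, g, h, max_depth, eta, lambda, min_hess,
                               min_data) {
  tr <- new_tree_state()
  root <- tree_add_node(tr)
  queue <- list(list(node = root, idx = seq_len(nrow(x)), depth = 0L))
  while (length(queue) > 0L) {
    it <- queue[[1]]; queue <- queue[-1]
    split <- if (it$depth < max_depth) {
      gbt_best_split(x, g, h, it$idx, lambda, min_hess, min_data)
    } else NULL
    if (is.null(split)) {
      tr$value[it$node] <- eta * gbt_leaf_value(g, h, it$idx, lambda)
    } else {
      l <- tree_add_node(tr); r <- tree_add_node(tr)
      tr$is_leaf[it$node] <- FALSE
      tr$feature[it$node] <- split$feature
      tr$threshold[it$node] <- split$threshold
      tr$left[it$node] <- l; tr$right[it$node] <- r
      queue <- c(queue,
                 list(list(node = l, idx = split$left, depth = it$depth + 1L),
                      list(node = r, idx = split$right, depth = it$depth + 1L)))
    }
  }
  tree_as_df(tr)
}

# Leaf-wise growth: repeatedly split the leaf with the largest gain until
# num_leaves is reached or no admissible split remains.
gbt_grow_leafwise <- function(x, g, h, num_leaves, eta, lambda, min_hess,
                              min_data) {
  tr <- new_tree_state()
  root <- tree_add_node(tr)
  leaves <- list(list(node = root, idx = seq_len(nrow(x)),
                      split = gbt_best_split(x, g, h, seq_len(nrow(x)),
                                             lambda, min_hess, min_data)))
  n_leaves <- 1L
  while (n_leaves < num_leaves) {
    gains <- vapply(leaves, function(l)
      if (is.null(l$split)) -Inf else l$split$gain, numeric(1))
    b <- which.max(gains)
    if (!is.finite(gains[b]) || gains[b] <= 0) break
    it <- leaves[[b]]; leaves <- leaves[-b]
    l <- tree_add_node(tr); r <- tree_add_node(tr)
    tr$is_leaf[it$node] <- FALSE
    tr$feature[it$node] <- it$split$feature
    tr$threshold[it$node] <- it$split$threshold
    tr$left[it$node] <- l; tr$right[it$node] <- r
    leaves <- c(leaves, list(
      list(node = l, idx = it$split$left,
           split = gbt_best_split(x, g, h, it$split$left, lambda, min_hess,
                                  min_data)),
      list(node = r, idx = it$split$right,
           split = gbt_best_split(x, g, h, it$split$right, lambda, min_hess,
                                  min_data))))
    n_leaves <- n_leaves + 1L
  }
  for (l in leaves) tr$value[l$node] <- eta * gbt_leaf_value(g, h, l$idx, lambda)
  tree_as_df(tr)
}

gbt_predict_tree <- function(tree, x) {
  node_of <- rep(1L, nrow(x))
  for (k in seq_len(nrow(tree))) {
    if (tree$is_leaf[k]) next
    rows <- which(node_of == k)
    if (length(rows) == 0L) next
    goleft <- x[rows, tree$feature[k]] < tree$threshold[k]
    node_of[rows[goleft]] <- tree$left[k]
    node_of[rows[!goleft]] <- tree$right[k]
  }
  tree$value[node_of]
}

# Fit a boosted ensemble. growth = "depthwise" uses max_depth; "leafwise"
# uses num_leaves.
gbt_fit <- function(x, y, nrounds = 100L, eta = 0.3,
                    growth = c("depthwise", "leafwise"), max_depth = 3L,
                    num_leaves = 31L, lambda = 1, min_hess = 1, min_data = 1L) {
  growth <- match.arg(growth)
  raw <- rep(0, nrow(x))
  trees <- vector("list", nrounds)
  for (m in seq_len(nrounds)) {
    p <- plogis(raw)
    g <- p - y
    h <- pmax(p * (1 - p), 1e-16)
    tree <- if (growth == "depthwise") {
      gbt_grow_depthwise(x, g, h, max_depth, eta, lambda, min_hess, min_data)
    } else {
      gbt_grow_leafwise(x, g, h, num_leaves, eta, lambda, min_hess, min_data)
    }
    trees[[m]] <- tree
    raw <- raw + gbt_predict_tree(tree, x)
  }
  list(trees = trees, base = 0)
}

gbt_predict <- function(fit, x) {
  raw <- rep(fit$base, nrow(x))
  for (tree in fit$trees) raw <- raw + gbt_predict_tree(tree, x)
  raw
}
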