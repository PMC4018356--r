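# Depth-bounded CART-style recursive partitioning over mixed features.
#
# Features enter as a single numeric matrix with a per-column kind:
# "binary" columns split on presence (absent -> left, present -> right) and
# "numeric" columns on thresholds at midpoints between sorted distinct
# values (value <= threshold -> left). Splits are chosen greedily by Gini
# impurity decrease; ties are broken by the lexicographically smallest
# column name, then the smallest threshold, making the grown tree invariant
# to feature-column permutation.

#' Build a model matrix from feature sets and descriptors
#'
#' @param fsets list of [featureset]s (binary presence columns), or `NULL`.
#' @param descriptors numeric matrix of continuous descriptors (numeric
#'   threshold columns), or `NULL`.
#' @param keys fixed structural-feature universe; defaults to all keys seen.
#' @param min_support drop binary features present in fewer than this many
#'   of the supplied compounds (a split on such a column could never satisfy
#'   a comparable `min_leaf` anyway).
#' @return numeric matrix with attribute `kinds` (per-column
#'   `"binary"`/`"numeric"`).
#' @export
build_model_matrix <- function(fsets = NULL, descriptors = NULL, keys = NULL,
                               min_support = 1) {
  parts <- list(); kinds <- character(0)
  if (!is.null(fsets)) {
    fm <- feature_matrix(fsets, keys) * 1
    if (min_support > 1) {
      fm <- fm[, colSums(fm) >= min_support, drop = FALSE]
    }
    parts[[length(parts) + 1L]] <- fm
    kinds <- c(kinds, rep("binary", ncol(fm)))
  }
  if (!is.null(descriptors)) {
    parts[[length(parts) + 1L]] <- descriptors
    kinds <- c(kinds, rep("numeric", ncol(descriptors)))
  }
  if (length(parts) == 0L) stop("no features supplied")
  m <- do.call(cbind, parts)
  attr(m, "kinds") <- kinds
  m
}

gini_impurity <- function(n1, n0) {
  n <- n1 + n0
  if (n == 0) return(0)
  p <- n1 / n
  2 * p * (1 - p)
}

# count-weighted Gini (scalar and vectorized): gini(n1, n0) * (n1 + n0)
wgini <- function(n1, n0) if (n1 + n0 == 0) 0 else 2 * n1 * n0 / (n1 + n0)
wgini_v <- function(n1, n0) {
  n <- n1 + n0
  out <- numeric(length(n))
  pos <- n > 0
  out[pos] <- 2 * n1[pos] * n0[pos] / n[pos]
  out
}

#' Grow a classification tree
#'
#' @param features numeric matrix (rows = compounds) with column names and a
#'   `kinds` attribute as produced by [build_model_matrix]; a plain 0/1
#'   matrix is treated as all-binary.
#' @param labels `"inhibitor"` / `"non_inhibitor"` vector.
#' @param max_depth maximum path length from root to leaf.
#' @param min_leaf minimum training examples in a leaf.
#' @return object of class `rp_tree`.
#' @export
grow_tree <- function(features, labels, max_depth = 8, min_leaf = 10) {
  kinds <- attr(features, "kinds")
  if (is.null(kinds)) kinds <- rep("binary", ncol(features))
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("f%05d", seq_len(ncol(features)))
  y <- as.character(labels) == "inhibitor"
  if (length(y) < 1L) stop("no training examples")

  nodes <- list()
  new_node <- function(node) {
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }

  build <- function(idx, depth) {
    n1 <- sum(y[idx]); n0 <- length(idx) - n1
    node <- list(leaf = TRUE, n_inh = n1, n_non = n0,
                 feature = NA_character_, kind = NA_character_,
                 threshold = NA_real_, left = NA_integer_, right = NA_integer_,
                 missing_dir = NA_character_)
    if (n1 == 0L || n0 == 0L || depth >= max_depth ||
        length(idx) < 2L * min_leaf) {
      return(new_node(node))
    }
    nidx <- length(idx)
    parent_imp <- wgini(n1, n0)
    # candidate splits: (gain, name, kind, threshold); best = max gain,
    # ties by smallest column name then smallest threshold
    cand_gain <- numeric(0); cand_name <- character(0)
    cand_kind <- character(0); cand_thr <- numeric(0)

    bcols <- which(kinds == "binary")
    if (length(bcols) > 0L) {
      vsub <- features[idx, bcols, drop = FALSE] > 0
      nr <- colSums(vsub)
      r1 <- as.numeric(crossprod(vsub, y[idx]))
      nl <- nidx - nr; l1 <- n1 - r1
      valid <- nr >= min_leaf & nl >= min_leaf
      gain <- parent_imp - (wgini_v(r1, nr - r1) + wgini_v(l1, nl - l1))
      keep <- valid & gain > -1e-12
      if (any(keep)) {
        cand_gain <- c(cand_gain, gain[keep])
        cand_name <- c(cand_name, colnames(features)[bcols][keep])
        cand_kind <- c(cand_kind, rep("binary", sum(keep)))
        cand_thr <- c(cand_thr, rep(NA_real_, sum(keep)))
      }
    }
    for (ci in which(kinds == "numeric")) {
      v <- features[idx, ci]
      ok <- !is.na(v)
      if (sum(ok) < 2L * min_leaf) next
      vo <- v[ok]; yo <- y[idx][ok]
      ord <- order(vo)
      vs <- vo[ord]; ys <- yo[ord]
      cum1 <- cumsum(ys); m <- length(vs)
      tot1 <- cum1[m]
      ts <- which(vs[-m] < vs[-1])  # split after position t
      ts <- ts[ts >= min_leaf & (m - ts) >= min_leaf]
      if (length(ts) == 0L) next
      l1 <- cum1[ts]; nl <- ts; r1 <- tot1 - l1; nr <- m - ts
      gain <- wgini(tot1, m - tot1) -
        (wgini_v(l1, nl - l1) + wgini_v(r1, nr - r1))
      keep <- gain > -1e-12
      if (any(keep)) {
        cand_gain <- c(cand_gain, gain[keep])
        cand_name <- c(cand_name, rep(colnames(features)[ci], sum(keep)))
        cand_kind <- c(cand_kind, rep("numeric", sum(keep)))
        cand_thr <- c(cand_thr, ((vs[ts] + vs[ts + 1L]) / 2)[keep])
      }
    }
    if (length(cand_gain) == 0L) return(new_node(node))
    top <- max(cand_gain)
    # zero-gain splits are allowed only when a child could still act on
    # them (depth budget left); this lets parity-style interactions (XOR)
    # be solved while pure-noise nodes still terminate at the depth bound
    if (top <= 1e-12 && depth + 1L >= max_depth) return(new_node(node))
    tied <- which(cand_gain >= top - 1e-12)
    pick <- tied[order(cand_name[tied], cand_thr[tied])][1L]
    best <- list(gain = cand_gain[pick], name = cand_name[pick],
                 ci = match(cand_name[pick], colnames(features)),
                 kind = cand_kind[pick], threshold = cand_thr[pick])
    v <- features[idx, best$ci]
    if (best$kind == "binary") {
      go_right <- v > 0
    } else {
      go_right <- !is.na(v) & v > best$threshold
      # missing values: route with the larger child
      nr <- sum(go_right); nl <- sum(!is.na(v)) - nr
      miss_dir <- if (nr >= nl) "right" else "left"
      go_right[is.na(v)] <- miss_dir == "right"
      node$missing_dir <- miss_dir
    }
    node$leaf <- FALSE
    node$feature <- best$name
    node$kind <- best$kind
    node$threshold <- best$threshold
    self <- new_node(node)
    nodes[[self]]$left <<- build(idx[!go_right], depth + 1L)
    nodes[[self]]$right <<- build(idx[go_right], depth + 1L)
    self
  }

  root <- build(seq_along(y), 0L)
  structure(list(nodes = nodes, root = root, max_depth = max_depth,
                 min_leaf = min_leaf),
            class = "rp_tree")
}

#' @export
print.rp_tree <- function(x, ...) {
  n_leaf <- sum(vapply(x$nodes, `[[`, FALSE, "leaf"))
  cat(sprintf("<rp_tree: %d nodes (%d leaves), max_depth=%d>\n",
              length(x$nodes), n_leaf, x$max_depth))
  invisible(x)
}

#' Predict from a grown tree
#'
#' Routes each row through the splits; the label is the leaf majority and
#' the reported fraction is the leaf purity for the predicted class. Missing
#' numeric values follow the recorded surrogate direction (the child that
#' received more training examples).
#'
#' @param tree an `rp_tree`.
#' @param features numeric matrix with the training column names (absent
#'   binary columns are treated as feature-absent).
#' @return data.frame with `label` and `fraction`.
#' @export
predict_tree <- function(tree, features) {
  n <- nrow(features)
  labs <- character(n); fracs <- numeric(n)
  cn <- colnames(features)
  for (i in seq_len(n)) {
    cur <- tree$root
    repeat {
      node <- tree$nodes[[cur]]
      if (node$leaf) break
      j <- match(node$feature, cn)
      v <- if (is.na(j)) NA_real_ else features[i, j]
      go_right <- if (node$kind == "binary") {
        !is.na(v) && v > 0
      } else if (is.na(v)) {
        identical(node$missing_dir, "right")
      } else v > node$threshold
      cur <- if (go_right) node$right else node$left
    }
    tot <- node$n_inh + node$n_non
    if (node$n_inh >= node$n_non) {
      labs[i] <- "inhibitor"; fracs[i] <- node$n_inh / tot
    } else {
      labs[i] <- "non_inhibitor"; fracs[i] <- node$n_non / tot
    }
  }
  data.frame(label = labs, fraction = fracs, stringsAsFactors = FALSE)
}

#' Depth sweep with cross-validated Matthews correlation
#'
#' Grows trees at each depth and evaluates them by stratified k-fold
#' cross-validation on the training data (pooled confusion per depth); the
#' selected depth maximizes the Matthews coefficient, smallest depth on
#' ties. Supplying `eval_features`/`eval_labels` instead selects the depth
#' by performance on that external set (the replication mode; note it leaks
#' the external set into model selection).
#'
#' @param features model matrix (see [build_model_matrix]).
#' @param labels class labels.
#' @param depths integer vector of depths to sweep (default 3..20).
#' @param folds number of CV folds.
#' @param seed integer seed for fold assignment.
#' @param min_leaf minimum leaf size passed to [grow_tree].
#' @param eval_features,eval_labels optional external evaluation set
#'   replacing cross-validation.
#' @return list with `sweep` (data.frame depth x metrics) and
#'   `selected_depth`.
#' @export
tune_depth <- function(features, labels, depths = 3:20, folds = 5, seed = 1,
                       min_leaf = 10, eval_features = NULL,
                       eval_labels = NULL) {
  y <- as.character(labels)
  external <- !is.null(eval_features)
  if (!external) {
    fold_id <- make_folds(y, folds, seed, stratified = TRUE)
  }
  rows <- list()
  for (d in depths) {
    if (external) {
      tree <- grow_tree(features, y, max_depth = d, min_leaf = min_leaf)
      pred <- predict_tree(tree, eval_features)$label
      cc <- confusion_counts(pred, eval_labels)
    } else {
      cc <- c(TP = 0L, FN = 0L, TN = 0L, FP = 0L)
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        tree <- grow_tree(features[tr, , drop = FALSE] |>
                            `attr<-`("kinds", attr(features, "kinds")),
                          y[tr], max_depth = d, min_leaf = min_leaf)
        pred <- predict_tree(tree, features[!tr, , drop = FALSE])$label
        cc <- cc + unlist(confusion_counts(pred, y[!tr]))
      }
      cc <- as.list(cc)
    }
    m <- compute_metrics(cc)
    rows[[length(rows) + 1L]] <-
      data.frame(depth = d, TP = cc$TP, FN = cc$FN, TN = cc$TN, FP = cc$FP,
                 SE = m$SE, SP = m$SP, Q = m$Q, C = m$C)
  }
  sweep <- do.call(rbind, rows)
  best <- sweep$depth[which.max(sweep$C)]  # which.max: first max = smallest depth
  list(sweep = sweep, selected_depth = best)
}

#' Export a tree as JSON or indented text
#'
#' @param tree an `rp_tree`.
#' @param format `"json"` or `"text"`.
#' @return character scalar.
#' @export
export_tree <- function(tree, format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(tree$nodes, auto_unbox = TRUE,
                                         digits = NA)))
  }
  lines <- character(0)
  walk <- function(id, indent, prefix) {
    node <- tree$nodes[[id]]
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cls <- if (node$n_inh >= node$n_non) "inhibitor" else "non_inhibitor"
      lines <<- c(lines, sprintf("%s%s-> %s (%d/%d)", pad, prefix, cls,
                                 node$n_inh, node$n_non))
    } else {
      desc <- if (node$kind == "binary") node$feature
              else sprintf("%s <= %.4g", node$feature, node$threshold)
      lines <<- c(lines, sprintf("%s%s%s?", pad, prefix, desc))
      walk(node$left, indent + 1L, "not: ")
      walk(node$right, indent + 1L, "yes: ")
    }
  }
  walk(tree$root, 0L, "")
  paste(lines, collapse = "\n")
}
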