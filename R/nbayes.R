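# Laplacian-corrected naive Bayesian classifier over sparse structural
# features.
#
# Per-feature evidence: with class prior P = (# inhibitors)/n and correction
# strength K = 1/P, a feature F contained in N_F training compounds, A_F of
# them inhibitors, receives the corrected conditional probability
#     P_corr(F) = (A_F + P K) / (N_F + K)  =  (A_F + 1) / (N_F + 1/P)
# and the additive weight w_F = ln(P_corr(F) / P). A feature never seen in
# training therefore contributes exactly 0, and a compound's Bayesian score
# is the sum of the weights of its (present) features. Features are counted
# by presence, not multiplicity.

#' Fit a Laplacian-corrected naive Bayes model
#'
#' @param fsets list of [featureset]s (training compounds).
#' @param labels character vector parallel to `fsets`, values `"inhibitor"` /
#'   `"non_inhibitor"`.
#' @param prune_singletons drop features contained in exactly one training
#'   compound (default keeps all features).
#' @param zone_bounds numeric length-2: the uncertain-zone score interval
#'   (default `c(-20, 0)`).
#' @return object of class `nb_model`.
#' @export
nb_fit <- function(fsets, labels, prune_singletons = FALSE,
                   zone_bounds = c(-20, 0)) {
  stopifnot(length(fsets) == length(labels))
  labels <- as.character(labels)
  if (!all(labels %in% c("inhibitor", "non_inhibitor")))
    stop("labels must be 'inhibitor' or 'non_inhibitor'")
  y <- labels == "inhibitor"
  if (all(y) || !any(y))
    stop("training set must contain both classes")
  n <- length(fsets)
  p_active <- sum(y) / n

  all_keys <- unlist(lapply(fsets, names), use.names = FALSE)
  act_keys <- unlist(lapply(fsets[y], names), use.names = FALSE)
  keys <- sort(unique(all_keys))
  N_F <- as.integer(table(factor(all_keys, levels = keys)))
  A_F <- as.integer(table(factor(act_keys, levels = keys)))
  if (prune_singletons) {
    keep <- N_F > 1L
    keys <- keys[keep]; N_F <- N_F[keep]; A_F <- A_F[keep]
  }
  model <- structure(
    list(prior = p_active, laplace_K = 1 / p_active, n_train = n,
         keys = keys, N_F = N_F, A_F = A_F,
         zone_bounds = as.numeric(zone_bounds),
         n_active = sum(y)),
    class = "nb_model"
  )
  model$weights <- nb_weights(model)
  model
}

# weights recomputed deterministically from integer counts + prior
nb_weights <- function(model) {
  p <- model$prior
  K <- model$laplace_K
  p_corr <- (model$A_F + p * K) / (model$N_F + K)
  log(p_corr / p)
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("<nb_model: %d features, n_train=%d, prior=%.3f>\n",
              length(x$keys), x$n_train, x$prior))
  invisible(x)
}

#' Bayesian score of a compound
#'
#' Sum of fitted feature weights over the features present in `fs`; features
#' unseen in training contribute 0. The score zone follows the configured
#' uncertain-zone bounds: `score >= upper` is a reliable inhibitor call,
#' `score < lower` a reliable non-inhibitor call, anything between is
#' uncertain.
#'
#' @param model an `nb_model`.
#' @param fs a [featureset].
#' @return list with `compound_id`, `score`, `zone`.
#' @export
nb_score <- function(model, fs) {
  hit <- match(names(fs), model$keys)
  score <- sum(model$weights[hit[!is.na(hit)]])
  if (length(score) == 0L) score <- 0
  zb <- model$zone_bounds
  zone <- if (score >= zb[2]) "reliable_inhibitor"
          else if (score < zb[1]) "reliable_noninhibitor"
          else "uncertain"
  list(compound_id = attr(fs, "compound_id"), score = score, zone = zone)
}

#' Predict the activity class from the Bayesian score
#'
#' @param model an `nb_model`.
#' @param fs a [featureset].
#' @param threshold decision threshold on the score; the default 0 calls a
#'   compound an inhibitor iff its score is strictly greater than 0.
#' @return `"inhibitor"` or `"non_inhibitor"`.
#' @export
nb_predict <- function(model, fs, threshold = 0) {
  if (nb_score(model, fs)$score > threshold) "inhibitor" else "non_inhibitor"
}

#' Score a list of feature sets
#'
#' @param model an `nb_model`.
#' @param fsets list of [featureset]s.
#' @param threshold decision threshold (see [nb_predict]).
#' @return data.frame with `compound_id`, `score`, `zone`, `label`.
#' @export
nb_score_all <- function(model, fsets, threshold = 0) {
  rows <- lapply(fsets, function(fs) nb_score(model, fs))
  data.frame(
    compound_id = vapply(rows, `[[`, "", "compound_id"),
    score = vapply(rows, `[[`, 0, "score"),
    zone = vapply(rows, `[[`, "", "zone"),
    label = ifelse(vapply(rows, `[[`, 0, "score") > threshold,
                   "inhibitor", "non_inhibitor"),
    stringsAsFactors = FALSE
  )
}

#' Rank fragments by Bayesian weight
#'
#' Returns the `top_k` most favorable (largest weight) and most unfavorable
#' (smallest weight) features, each with its weight and active/total
#' occurrence counts. Ties are broken by active count, total count, then key.
#'
#' @param model an `nb_model`.
#' @param top_k entries per list.
#' @return list with data.frames `favorable` and `unfavorable` (columns
#'   `key`, `weight`, `A_F`, `N_F`).
#' @export
rank_fragments <- function(model, top_k = 20) {
  stopifnot(top_k >= 1)
  nf <- length(model$keys)
  if (top_k > nf) {
    warning(sprintf("top_k = %d exceeds feature count %d; returning all",
                    top_k, nf))
    top_k <- nf
  }
  tab <- data.frame(key = model$keys, weight = model$weights,
                    A_F = model$A_F, N_F = model$N_F,
                    stringsAsFactors = FALSE)
  up <- tab[order(-tab$weight, -tab$A_F, -tab$N_F, tab$key), , drop = FALSE]
  dn <- tab[order(tab$weight, -tab$N_F, -tab$A_F, tab$key), , drop = FALSE]
  list(favorable = utils::head(up, top_k),
       unfavorable = utils::head(dn, top_k))
}

#' Minimum rank of a feature among favorable fragments
#'
#' Rank 1 means no feature has a strictly larger weight. Useful for checking
#' recovery of a planted fragment, where symmetric fragment keys tie exactly.
#'
#' @param model an `nb_model`.
#' @param key feature key.
#' @return integer rank (`NA` if the key is absent from the model).
#' @export
fragment_rank <- function(model, key) {
  i <- match(key, model$keys)
  if (is.na(i)) return(NA_integer_)
  sum(model$weights > model$weights[i]) + 1L
}

#' Learn equal-frequency descriptor bins
#'
#' Discretizes each continuous descriptor column into `n_bins`
#' equal-frequency bins; edges are learned on training data and frozen for
#' prediction. Each (descriptor, bin) pair becomes a categorical feature
#' (`"BIN:<name>:<k>"`) usable alongside structural features. Values outside
#' the training range clamp to the boundary bins; `NA` values produce no
#' feature.
#'
#' @param descriptor_matrix numeric matrix (training compounds x descriptors)
#'   with column names.
#' @param n_bins number of bins.
#' @return object of class `descriptor_bins`.
#' @export
bin_descriptors <- function(descriptor_matrix, n_bins = 10) {
  stopifnot(n_bins >= 1, !is.null(colnames(descriptor_matrix)))
  edges <- lapply(colnames(descriptor_matrix), function(cn) {
    x <- descriptor_matrix[, cn]
    x <- x[!is.na(x)]
    if (length(x) == 0L || length(unique(x)) == 1L) return(numeric(0))
    qs <- stats::quantile(x, probs = seq_len(n_bins - 1L) / n_bins,
                          type = 7, names = FALSE)
    unique(qs)
  })
  names(edges) <- colnames(descriptor_matrix)
  structure(list(edges = edges, n_bins = n_bins), class = "descriptor_bins")
}

#' Convert descriptor rows to binned categorical features
#'
#' @param descriptor_matrix numeric matrix with the same columns the bins
#'   were learned on; rownames are compound ids.
#' @param bins a `descriptor_bins` object.
#' @return list of [featureset]s with `"BIN:"` keys.
#' @export
apply_bins <- function(descriptor_matrix, bins) {
  ids <- rownames(descriptor_matrix)
  out <- vector("list", nrow(descriptor_matrix))
  for (i in seq_len(nrow(descriptor_matrix))) {
    keys <- character(0)
    for (cn in names(bins$edges)) {
      e <- bins$edges[[cn]]
      v <- descriptor_matrix[i, cn]
      if (is.na(v)) next
      k <- if (length(e) == 0L) 1L else findInterval(v, e) + 1L
      keys <- c(keys, sprintf("BIN:%s:%d", cn, k))
    }
    out[[i]] <- featureset(ids[i], keys)
  }
  names(out) <- ids
  out
}

#' Merge structural and binned-descriptor feature sets compound-wise
#'
#' @param a,b lists of [featureset]s with identical compound order.
#' @return list of merged [featureset]s.
#' @export
merge_featuresets <- function(a, b) {
  stopifnot(length(a) == length(b))
  out <- vector("list", length(a))
  for (i in seq_along(a)) {
    keys <- c(rep(names(a[[i]]), a[[i]]), rep(names(b[[i]]), b[[i]]))
    out[[i]] <- featureset(attr(a[[i]], "compound_id"), keys)
  }
  names(out) <- names(a)
  out
}

#' Save a fitted model as JSON
#'
#' Integer counts and the prior are stored; weights are recomputed on load,
#' so a loaded model scores bit-identically to the model before saving.
#'
#' @param model an `nb_model`.
#' @param path output path.
#' @param config optional featurization-provenance list echoed in the file.
#' @export
nb_save <- function(model, path, config = list()) {
  doc <- list(
    type = "nb_model",
    prior = model$prior, n_train = model$n_train, n_active = model$n_active,
    zone_bounds = model$zone_bounds,
    features = list(keys = model$keys, N_F = model$N_F, A_F = model$A_F),
    config = config
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [nb_save]
#'
#' @param path JSON path.
#' @return an `nb_model` (with attribute `config`).
#' @export
nb_load <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$type) || doc$type != "nb_model")
    stop("not an nb_model file")
  model <- structure(
    list(prior = doc$prior, laplace_K = 1 / doc$prior, n_train = doc$n_train,
         keys = as.character(doc$features$keys),
         N_F = as.integer(doc$features$N_F),
         A_F = as.integer(doc$features$A_F),
         zone_bounds = as.numeric(doc$zone_bounds),
         n_active = doc$n_active),
    class = "nb_model"
  )
  model$weights <- nb_weights(model)
  attr(model, "config") <- doc$config
  model
}

#' Leave-one-out Bayesian scores
#'
#' For each compound, its score under the model fitted on all other
#' compounds, computed by decrementing the count tables (fast path). The
#' result equals scoring under `n` explicitly refitted models.
#'
#' @param fsets list of [featureset]s.
#' @param labels character labels parallel to `fsets`.
#' @return numeric vector of LOO scores.
#' @export
loo_bayes_scores <- function(fsets, labels) {
  if (length(fsets) < 3L) stop("need at least 3 compounds for LOO")
  model <- nb_fit(fsets, labels)
  y <- labels == "inhibitor"
  n <- model$n_train
  scores <- numeric(length(fsets))
  for (i in seq_along(fsets)) {
    n_act <- model$n_active - as.integer(y[i])
    n_i <- n - 1L
    if (n_act == 0L || n_act == n_i)
      stop("leave-one-out removes the last example of a class")
    p <- n_act / n_i
    K <- 1 / p
    hit <- match(names(fsets[[i]]), model$keys)
    hit <- hit[!is.na(hit)]
    Nf <- model$N_F[hit] - 1L
    Af <- model$A_F[hit] - as.integer(y[i])
    keep <- Nf > 0L
    scores[i] <- sum(log((Af[keep] + 1) / (Nf[keep] + K) / p))
  }
  scores
}
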