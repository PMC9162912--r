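# Temporal co-editing patterns: mean imputation, seeded k-means with
# restarts, an SSE elbow curve, ordinary-least-squares association of
# overall editing with ADAR expression (BH-corrected), and per-pattern
# composition tables.

#' Impute missing editing levels by the site mean
#'
#' Missing entries are replaced by the site's observed mean; observed values
#' are untouched. Only used on the way into clustering — the editing matrix
#' itself preserves missingness.
#'
#' @param matrix An `editing_matrix` from [build_matrix()].
#' @return The matrix with `levels` completed (and `missing` preserved).
#' @export
impute_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "editing_matrix"))
  lv <- matrix$levels
  all_missing <- rowSums(!is.na(lv)) == 0L
  if (any(all_missing))
    stopf("impute_matrix: site %s has no observed value",
          rownames(lv)[all_missing][1L])
  rm <- rowMeans(lv, na.rm = TRUE)
  idx <- which(is.na(lv), arr.ind = TRUE)
  lv[idx] <- rm[idx[, 1L]]
  matrix$levels <- lv
  matrix
}

# Best-of-restarts Lloyd k-means; optionally accepts warm-start centers
# that are tried in addition to the random restarts.
#' @noRd
kmeans_best <- function(x, k, n_init, warm = NULL) {
  best <- NULL
  run <- function(centers) {
    tryCatch(kmeans(x, centers = centers, iter.max = 100L,
                    algorithm = "Lloyd"),
             error = function(e) NULL,
             warning = function(w) suppressWarnings(
               kmeans(x, centers = centers, iter.max = 200L,
                      algorithm = "Lloyd")))
  }
  for (i in seq_len(n_init)) {
    init <- x[sample.int(nrow(x), k), , drop = FALSE]
    if (anyDuplicated(init)) init <- init + rnorm(length(init), 0, 1e-9)
    fit <- run(init)
    if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss))
      best <- fit
  }
  if (!is.null(warm)) {
    fit <- run(warm)
    if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss))
      best <- fit
  }
  if (is.null(best)) stopf("k-means failed to converge for k = %d", k)
  best
}

PATTERN_LABELS <- c("high", "medium", "low")

#' Cluster sites into temporal co-editing patterns
#'
#' Lloyd's k-means on the (imputed) site-by-stage level matrix with
#' `n_init` seeded restarts keeping the lowest within-cluster sum of
#' squares. For `k = 3` clusters are labelled `high`/`medium`/`low` by
#' descending centroid grand mean; other `k` get `p1`, `p2`, ... in the
#' same order.
#'
#' @param matrix An `editing_matrix` (missing entries are mean-imputed on
#'   the fly).
#' @param k Number of clusters (default 3).
#' @param n_init Random restarts (default 10).
#' @param seed Integer seed.
#' @param scale_rows Standardize rows before clustering (default `FALSE`;
#'   raw levels are what the published analysis clustered).
#' @return Object of class `pattern_assignment`: list with `cluster`
#'   (integer per site), `label` (character per site), `centroids`
#'   (k x stages, on the clustered scale), `sse`, `sites`, `k`.
#' @export
kmeans_patterns <- function(matrix, k = 3L, n_init = 10L, seed = 1L,
                            scale_rows = FALSE) {
  stopifnot(inherits(matrix, "editing_matrix"))
  matrix <- impute_matrix(matrix)
  x <- matrix$levels
  if (nrow(x) < k) stopf("kmeans_patterns: %d rows < k = %d", nrow(x), k)
  if (scale_rows) {
    s <- apply(x, 1L, sd)
    x <- (x - rowMeans(x)) / ifelse(s > 0, s, 1)
  }
  set.seed(seed)
  fit <- kmeans_best(x, k, n_init)
  grand <- rowMeans(fit$centers)
  ord <- order(-grand)                 # descending centroid grand mean
  relabel <- match(seq_len(k), ord)    # old cluster id -> rank
  labels <- if (k == 3L) PATTERN_LABELS else paste0("p", seq_len(k))
  cluster <- relabel[fit$cluster]
  centroids <- fit$centers[ord, , drop = FALSE]
  rownames(centroids) <- labels
  structure(list(cluster = cluster,
                 label = labels[cluster],
                 centroids = centroids,
                 sse = fit$tot.withinss,
                 sites = matrix$sites, k = k,
                 labels = labels), class = "pattern_assignment")
}

#' SSE elbow curve over k
#'
#' Computes the k-means within-cluster sum of squares for `k = 1..k_max`.
#' Each k is warm-started from the previous solution (plus the point
#' farthest from its centre) in addition to the random restarts, which
#' enforces a non-increasing curve. The suggested k maximizes the second
#' difference of log(SSE) (curvature of the curve on the relative scale);
#' it is advisory — the pipeline default stays at k = 3.
#'
#' @param matrix An `editing_matrix`.
#' @param k_max Largest k (default 8; truncated with a warning when the
#'   matrix has fewer rows).
#' @param n_init,seed,scale_rows As in [kmeans_patterns()].
#' @return List with `sse` (named numeric, k = 1..k_max) and `suggested_k`.
#' @export
elbow_curve <- function(matrix, k_max = 8L, n_init = 10L, seed = 1L,
                        scale_rows = FALSE) {
  stopifnot(inherits(matrix, "editing_matrix"))
  matrix <- impute_matrix(matrix)
  x <- matrix$levels
  if (scale_rows) {
    s <- apply(x, 1L, sd)
    x <- (x - rowMeans(x)) / ifelse(s > 0, s, 1)
  }
  if (k_max > nrow(x)) {
    warnf("elbow_curve: k_max %d > %d rows; truncated", k_max, nrow(x))
    k_max <- nrow(x)
  }
  set.seed(seed)
  sse <- numeric(k_max)
  centers_prev <- NULL
  for (k in seq_len(k_max)) {
    if (k == 1L) {
      ctr <- colMeans(x)
      sse[k] <- sum(sweep(x, 2L, ctr)^2)
      centers_prev <- rbind(ctr)
      next
    }
    dmat <- proxy_dist2(x, centers_prev)
    d2 <- dmat[cbind(seq_len(nrow(x)), max.col(-dmat, ties.method = "first"))]
    warm <- rbind(centers_prev, x[which.max(d2), ])
    if (anyDuplicated(warm)) warm <- warm + rnorm(length(warm), 0, 1e-9)
    fit <- kmeans_best(x, k, n_init, warm = warm)
    sse[k] <- fit$tot.withinss
    centers_prev <- fit$centers
  }
  names(sse) <- seq_len(k_max)
  # elbow = max second difference of log(SSE): curvature on the relative
  # scale, i.e. the k after which proportional improvement collapses (the
  # raw-scale version always fires at the first big drop)
  suggested <- if (k_max >= 3L) {
    ls <- log(pmax(sse, .Machine$double.eps))
    d2 <- ls[seq_len(k_max - 2L)] - 2 * ls[2:(k_max - 1L)] + ls[3:k_max]
    as.integer(names(which.max(d2))) + 1L
  } else NA_integer_
  list(sse = sse, suggested_k = suggested)
}

# Squared Euclidean distances between rows of a and rows of b.
#' @noRd
proxy_dist2 <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  outer(an, bn, "+") - 2 * a %*% t(b)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b Integer or character label vectors of equal length.
#' @return The adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Regress overall editing level on ADAR expression
#'
#' Per gene, ordinary least squares of the overall editing level (response)
#' on FPKM (predictor) across stages, with a two-sided t-test on the slope
#' and Benjamini-Hochberg correction across the gene list.
#'
#' @param overall Named numeric vector: overall editing level per stage.
#' @param expression Expression `data.frame` (`gene` column + one column
#'   per stage) as from [simulate_expression()].
#' @param genes Genes to test (default `c("Adar1", "Adar2")`).
#' @return `data.frame`: gene, slope, intercept, pearson_r, p_value,
#'   q_value. Zero-variance predictors are flagged (`NA` statistics).
#' @export
adar_regression <- function(overall, expression,
                            genes = c("Adar1", "Adar2")) {
  stages <- names(overall)
  if (length(stages) < 3L) stopf("adar_regression: need >= 3 stages")
  miss <- setdiff(genes, expression$gene)
  if (length(miss)) stopf("gene %s absent from expression table", miss[1L])
  rows <- lapply(genes, function(g) {
    x <- as.numeric(expression[expression$gene == g, stages])
    y <- as.numeric(overall)
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L || sd(x) == 0) {
      return(data.frame(gene = g, slope = NA_real_, intercept = NA_real_,
                        pearson_r = NA_real_, p_value = NA_real_,
                        flagged = TRUE, stringsAsFactors = FALSE))
    }
    fit <- lm(y ~ x)
    sm <- summary(fit)
    data.frame(gene = g, slope = coef(fit)[[2L]],
               intercept = coef(fit)[[1L]],
               pearson_r = sign(coef(fit)[[2L]]) * sqrt(sm$r.squared),
               p_value = sm$coefficients[2L, 4L],
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- p.adjust(out$p_value[ok], method = "BH")
  out
}

#' Per-pattern composition tables
#'
#' Fractions of region categories, recoding kinds and repeat status within
#' each temporal pattern; every row sums to 1. Empty patterns are flagged.
#'
#' @param assignment A `pattern_assignment` from [kmeans_patterns()].
#' @param annotated Annotated site `data.frame` from [annotate_sites()],
#'   row-aligned with `assignment$sites`.
#' @return List of `data.frame`s `region`, `recoding`, `repeat_status`,
#'   each with a `pattern` column and fraction columns, plus
#'   `empty_patterns`.
#' @export
pattern_composition <- function(assignment, annotated) {
  stopifnot(inherits(assignment, "pattern_assignment"))
  if (nrow(annotated) != length(assignment$label))
    stopf("pattern_composition: site tables are not aligned")
  labels <- assignment$labels
  frac_table <- function(values, categories) {
    rows <- lapply(labels, function(lb) {
      v <- values[assignment$label == lb]
      if (length(v) == 0L) return(setNames(rep(0, length(categories)),
                                           categories))
      tab <- table(factor(v, levels = categories))
      as.numeric(tab) / length(v)
    })
    df <- as.data.frame(do.call(rbind, rows))
    names(df) <- categories
    cbind(pattern = labels, df, stringsAsFactors = FALSE)
  }
  region <- frac_table(annotated$region, REGION_CATEGORIES)
  recoding <- frac_table(annotated$recoding,
                         c("synonymous", "nonsynonymous", "not_coding"))
  repeat_status <- frac_table(
    ifelse(is.na(annotated$repeat_family), "non_repeat", "repeat"),
    c("repeat", "non_repeat"))
  empty <- labels[!labels %in% assignment$label]
  list(region = region, recoding = recoding, repeat_status = repeat_status,
       empty_patterns = empty)
}
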