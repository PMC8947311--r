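# Minimal second-order gradient-boosted tree classifier (logistic loss, exact
# greedy splits, gain-type feature importance). No boosted-tree engine is
# available in the supported dependency set, so the fitter is provided here;
# it follows the standard regularized formulation: for a candidate split with
# gradient/hessian sums (GL, HL), (GR, HR),
#   gain = 1/2 [ GL^2/(HL+lambda) + GR^2/(HR+lambda) - (GL+GR)^2/(HL+HR+lambda) ] - gamma
# and a leaf takes value -eta * G/(H + lambda). The "multi:softprob, 2 classes"
# objective reduces to this binary-logistic form up to a constant factor on
# the learning rate.

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Build one regression tree on (g, h) pseudo-statistics. Returns a list tree
# and, via the accumulator environment, per-feature total split gain.
.build_tree <- function(x, g, h, rows, depth, max_depth, lambda, gamma,
                        min_child_weight, eta, acc) {
  G <- sum(g[rows]); H <- sum(h[rows])
  make_leaf <- function() list(leaf = TRUE, value = -eta * G / (H + lambda))
  if (depth >= max_depth || length(rows) < 2) return(make_leaf())
  base_score <- G * G / (H + lambda)
  best <- list(gain = 0)
  for (j in seq_len(ncol(x))) {
    xj <- x[rows, j]
    ord <- order(xj, method = "radix")
    xs <- xj[ord]
    n <- length(xs)
    cut_ok <- which(xs[-n] < xs[-1])     # split between distinct values only
    if (length(cut_ok) == 0) next
    gl <- cumsum(g[rows][ord])[cut_ok]
    hl <- cumsum(h[rows][ord])[cut_ok]
    gr <- G - gl; hr <- H - hl
    valid <- hl >= min_child_weight & hr >= min_child_weight
    if (!any(valid)) next
    gain <- 0.5 * (gl^2 / (hl + lambda) + gr^2 / (hr + lambda) - base_score) -
      gamma
    gain[!valid] <- -Inf
    i <- which.max(gain)
    if (gain[i] > best$gain) {
      best <- list(gain = gain[i], feature = j,
                   split = (xs[cut_ok[i]] + xs[cut_ok[i] + 1]) / 2)
    }
  }
  if (best$gain <= 0) return(make_leaf())
  acc$gain[best$feature] <- acc$gain[best$feature] + best$gain
  go_left <- x[rows, best$feature] < best$split
  list(leaf = FALSE, feature = best$feature, split = best$split,
       left = .build_tree(x, g, h, rows[go_left], depth + 1, max_depth,
                          lambda, gamma, min_child_weight, eta, acc),
       right = .build_tree(x, g, h, rows[!go_left], depth + 1, max_depth,
                           lambda, gamma, min_child_weight, eta, acc))
}

.predict_tree <- function(tree, x, rows, out) {
  if (tree$leaf) {
    out[rows] <- out[rows] + tree$value
    return(out)
  }
  go_left <- x[rows, tree$feature] < tree$split
  out <- .predict_tree(tree$left, x, rows[go_left], out)
  .predict_tree(tree$right, x, rows[!go_left], out)
}

#' Fit a gradient-boosted tree classifier
#'
#' Binary-logistic boosting over depth-limited regression trees with the
#' standard second-order split criterion, shrinkage `eta`, minimum split gain
#' `gamma`, row subsampling, and L2 leaf regularization `lambda`. Intended for
#' feature-importance recalibration, not as a general-purpose learner.
#'
#' @param x Numeric feature matrix (rows = cases).
#' @param y 0/1 integer response.
#' @param nrounds Number of boosting rounds (default 100).
#' @param eta Learning rate (default 0.4).
#' @param max_depth Maximum tree depth (default 4).
#' @param gamma Minimum loss reduction required to split (default 1).
#' @param subsample Row subsampling fraction per round (default 0.7).
#' @param lambda L2 regularization on leaf values (default 1).
#' @param min_child_weight Minimum hessian sum per child (default 1).
#' @param seed Integer seed driving the row subsampling.
#' @return Object of class `igri_gbt`: list with `trees`, `gain` (per-feature
#'   total split gain), and the call parameters.
#' @export
fit_gbt <- function(x, y, nrounds = 100L, eta = 0.4, max_depth = 4L,
                    gamma = 1, subsample = 0.7, lambda = 1,
                    min_child_weight = 1, seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  stopifnot(length(y) == n, all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("response must contain both classes")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))
  acc <- new.env()
  acc$gain <- numeric(ncol(x))
  f <- numeric(n)
  trees <- vector("list", nrounds)
  m_sub <- max(2L, as.integer(floor(subsample * n)))
  for (m in seq_len(nrounds)) {
    p <- .sigmoid(f)
    g <- p - y
    h <- pmax(p * (1 - p), 1e-16)
    rows <- if (subsample < 1) sort(sample.int(n, m_sub)) else seq_len(n)
    tree <- .build_tree(x, g, h, rows, 0L, max_depth, lambda, gamma,
                        min_child_weight, eta, acc)
    trees[[m]] <- tree
    f <- .predict_tree(tree, x, seq_len(n), f)
  }
  gain <- acc$gain
  names(gain) <- colnames(x)
  structure(list(trees = trees, gain = gain, nrounds = nrounds, eta = eta,
                 max_depth = max_depth, gamma = gamma, subsample = subsample,
                 lambda = lambda, min_child_weight = min_child_weight,
                 seed = seed),
            class = "igri_gbt")
}

#' @describeIn fit_gbt Predicted glaucoma probability for new rows.
#' @param object Fitted `igri_gbt`.
#' @param newdata Numeric matrix with the training columns.
#' @param ... Unused.
#' @export
predict.igri_gbt <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  f <- numeric(nrow(newdata))
  for (tree in object$trees) {
    f <- .predict_tree(tree, newdata, seq_len(nrow(newdata)), f)
  }
  .sigmoid(f)
}
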